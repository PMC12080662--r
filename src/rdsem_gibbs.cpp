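// Gibbs sampler for the two-level residual-DSEM (RI-CLPM with lag-0 variants).
//
// Model, per person i and grid slot t = 1..T (K observed variables):
//   y_it = mu_i + d_it
//   M0_i d_it = M1_i d_i,t-1 + e_it,   e_it ~ N(0, Psi_i)
// where M0 = I - B0 carries the directed lag-0 paths (B0 = 0 and Psi full for
// the covariance variant; Psi diagonal otherwise), M1 the lag-1 paths.
// mu_i ~ N(nu, Sigma_B).  Random slopes: person coefficient ~ N(g0 + X_i g,
// tau^2).  Random residual variances: log sigma^2_ik ~ N(lambda_k, omega^2_k),
// updated by a Metropolis step.  Missing slots are imputed from their Gaussian
// full conditionals (single-site); slot 1 uses the stationary prior N(0, V).
// Parameter updates use the conditional likelihood given slot 1.
//
// All randomness goes through R's RNG so set.seed() fully determines a run.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::cube;
using arma::uvec;

static const double LOG2PI = 1.8378770664093454836;

// ---- small fixed-size helpers (K <= 3), raw arrays, no allocation ----------

static inline void mm(const double* A, const double* B, double* C, int K) {
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) {
      double s = 0;
      for (int l = 0; l < K; ++l) s += A[i + l * K] * B[l + j * K];
      C[i + j * K] = s;
    }
}
static inline void mmt(const double* A, const double* B, double* C, int K) {
  // C = A * B'
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) {
      double s = 0;
      for (int l = 0; l < K; ++l) s += A[i + l * K] * B[j + l * K];
      C[i + j * K] = s;
    }
}

// V = sum_{j>=0} A^j Q (A')^j  by doubling; solves V = A V A' + Q.
static void lyapunov(const double* A, const double* Q, int K, double* V) {
  double Ak[9], Qk[9], T1[9], T2[9];
  std::copy(A, A + K * K, Ak);
  std::copy(Q, Q + K * K, Qk);
  for (int it = 0; it < 60; ++it) {
    mm(Ak, Qk, T1, K);
    mmt(T1, Ak, T2, K);
    double amax = 0;
    for (int j = 0; j < K * K; ++j) { Qk[j] += T2[j]; }
    mm(Ak, Ak, T1, K);
    std::copy(T1, T1 + K * K, Ak);
    for (int j = 0; j < K * K; ++j) amax = std::max(amax, std::fabs(Ak[j]));
    if (amax < 1e-14) break;
  }
  std::copy(Qk, Qk + K * K, V);
}

// Wishart(df, S) via Bartlett using R's RNG; then inverse-Wishart.
static mat rwishart(double df, const mat& S) {
  int K = S.n_rows;
  mat L = arma::chol(S, "lower");
  mat A(K, K, arma::fill::zeros);
  for (int i = 0; i < K; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  mat LA = L * A;
  return LA * LA.t();
}
static mat riwishart(double df, const mat& S) {
  return arma::inv_sympd(rwishart(df, arma::inv_sympd(S)));
}

// draw x ~ N(P^{-1} b, P^{-1}) for small symmetric positive definite P
static vec mvn_prec(const mat& P, const vec& b) {
  mat U = arma::chol(P);                 // P = U'U
  vec m = arma::solve(arma::trimatu(U), arma::solve(arma::trimatl(U.t()), b));
  vec z(b.n_elem);
  for (arma::uword i = 0; i < z.n_elem; ++i) z(i) = R::norm_rand();
  return m + arma::solve(arma::trimatu(U), z);
}

struct PathTab {
  // parallel vectors over all dynamic paths (lag-1 first, then lag-0 edges)
  arma::ivec type;   // 1 = lag-1, 0 = lag-0
  arma::ivec out;    // 0-based outcome variable
  arma::ivec pred;   // 0-based predictor variable
  arma::ivec random; // 1 if person-level random slope
  arma::ivec moder;  // 1 if the random slope is moderated by X
};

// observed-data log-likelihood of one person by Kalman filter with exact
// (noise-free) observation of the observed components
static double person_loglik(const mat& Yi, const vec& mu, const double* Atil,
                            const double* Q, const double* V0) {
  int T = Yi.n_rows, K = Yi.n_cols;
  double x[3] = {0, 0, 0};
  double P[9], Pp[9], xp[3];
  std::copy(V0, V0 + K * K, P);
  std::copy(x, x + K, xp);
  double ll = 0;
  bool first = true;
  for (int t = 0; t < T; ++t) {
    if (!first) {
      // predict
      for (int i = 0; i < K; ++i) {
        double s = 0;
        for (int l = 0; l < K; ++l) s += Atil[i + l * K] * x[l];
        xp[i] = s;
      }
      double T1[9];
      mm(Atil, P, T1, K);
      mmt(T1, Atil, Pp, K);
      for (int j = 0; j < K * K; ++j) Pp[j] += Q[j];
    } else {
      std::copy(V0, V0 + K * K, Pp);
      for (int i = 0; i < K; ++i) xp[i] = 0;
      first = false;
    }
    // observation
    int obs[3], nob = 0;
    for (int k = 0; k < K; ++k)
      if (std::isfinite(Yi(t, k))) obs[nob++] = k;
    if (nob == 0) {
      std::copy(Pp, Pp + K * K, P);
      std::copy(xp, xp + K, x);
      continue;
    }
    double S[9], innov[3];
    for (int a = 0; a < nob; ++a) {
      innov[a] = Yi(t, obs[a]) - mu(obs[a]) - xp[obs[a]];
      for (int b = 0; b < nob; ++b) S[a + b * nob] = Pp[obs[a] + obs[b] * K];
    }
    // chol of S (nob <= 3)
    double L[9];
    std::fill(L, L + 9, 0.0);
    for (int a = 0; a < nob; ++a) {
      for (int b = 0; b <= a; ++b) {
        double s = S[a + b * nob];
        for (int c = 0; c < b; ++c) s -= L[a + c * nob] * L[b + c * nob];
        if (a == b) {
          if (s < 1e-12) s = 1e-12;
          L[a + a * nob] = std::sqrt(s);
        } else
          L[a + b * nob] = s / L[b + b * nob];
      }
    }
    double w[3], logdet = 0;
    for (int a = 0; a < nob; ++a) {
      double s = innov[a];
      for (int c = 0; c < a; ++c) s -= L[a + c * nob] * w[c];
      w[a] = s / L[a + a * nob];
      logdet += 2.0 * std::log(L[a + a * nob]);
    }
    double q = 0;
    for (int a = 0; a < nob; ++a) q += w[a] * w[a];
    ll += -0.5 * (nob * LOG2PI + logdet + q);
    // Sinv * innov  via L
    double v[3];
    for (int a = nob - 1; a >= 0; --a) {
      double s = w[a];
      for (int c = a + 1; c < nob; ++c) s -= L[c + a * nob] * v[c];
      v[a] = s / L[a + a * nob];
    }
    // gain G = Pp[, obs] * Sinv ; x = xp + Pp[,obs] v ; P = Pp - G * Pp[obs, ]
    double G[9]; // K x nob
    for (int i = 0; i < K; ++i) {
      // columns of Sinv: solve S z = e_b
      for (int b = 0; b < nob; ++b) {
        // forward/back solve for column b
        double wb[3], zb[3];
        for (int a = 0; a < nob; ++a) {
          double s = (a == b) ? 1.0 : 0.0;
          for (int c = 0; c < a; ++c) s -= L[a + c * nob] * wb[c];
          wb[a] = s / L[a + a * nob];
        }
        for (int a = nob - 1; a >= 0; --a) {
          double s = wb[a];
          for (int c = a + 1; c < nob; ++c) s -= L[c + a * nob] * zb[c];
          zb[a] = s / L[a + a * nob];
        }
        double s = 0;
        for (int a = 0; a < nob; ++a) s += Pp[i + obs[a] * K] * zb[a];
        G[i + b * K] = s;
      }
    }
    for (int i = 0; i < K; ++i) {
      double s = 0;
      for (int a = 0; a < nob; ++a) s += Pp[i + obs[a] * K] * v[a];
      x[i] = xp[i] + s;
    }
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j) {
        double s = 0;
        for (int a = 0; a < nob; ++a) s += G[i + a * K] * Pp[obs[a] + j * K];
        P[i + j * K] = Pp[i + j * K] - s;
      }
    // symmetrize
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < i; ++j) {
        double m = 0.5 * (P[i + j * K] + P[j + i * K]);
        P[i + j * K] = P[j + i * K] = m;
      }
  }
  return ll;
}

// build Atil = M0^{-1} M1 and Q = M0^{-1} Psi M0^{-T}, plus stationary V
static void implied_mats(const mat& M0, const mat& M1, const mat& Psi, int K,
                         double* Atil, double* Q, double* V) {
  mat M0i = arma::inv(M0);
  mat A = M0i * M1;
  mat Qm = M0i * Psi * M0i.t();
  std::copy(A.memptr(), A.memptr() + K * K, Atil);
  std::copy(Qm.memptr(), Qm.memptr() + K * K, Q);
  lyapunov(Atil, Q, K, V);
}

// deviance (-2 loglik) over all persons with person-specific parameters
// [[Rcpp::export]]
double rdsem_deviance_cpp(const arma::cube& Y, const arma::cube& B1p,
                          const arma::cube& B0p, const arma::cube& Psip,
                          const arma::mat& Mu) {
  int K = Y.n_cols, N = Y.n_slices;
  double ll = 0;
  double Atil[9], Q[9], V[9];
  for (int i = 0; i < N; ++i) {
    mat M0 = arma::eye(K, K) - B0p.slice(i);
    implied_mats(M0, B1p.slice(i), Psip.slice(i), K, Atil, Q, V);
    ll += person_loglik(Y.slice(i), Mu.row(i).t(), Atil, Q, V);
  }
  return -2.0 * ll;
}

// ------------------------------------------------------------------------
// main kernel
// ------------------------------------------------------------------------

// [[Rcpp::export]]
List rdsem_gibbs_cpp(const arma::cube& Y, const List& spec, const List& prior,
                     const List& init, int n_iter, const List& control) {
  const int T = Y.n_rows, K = Y.n_cols, N = Y.n_slices;
  const bool lag0_cov = as<bool>(spec["lag0_cov"]);
  const bool random_resid = as<bool>(spec["random_resid"]);
  const mat X = as<mat>(spec["X"]); // N x P (possibly 0 cols)
  const int P = X.n_cols;

  PathTab pt;
  pt.type = as<arma::ivec>(spec["path_type"]);
  pt.out = as<arma::ivec>(spec["path_out"]);
  pt.pred = as<arma::ivec>(spec["path_pred"]);
  pt.random = as<arma::ivec>(spec["path_random"]);
  pt.moder = as<arma::ivec>(spec["path_moderated"]);
  const int npath = pt.type.n_elem;
  std::vector<int> ridx; // random path ids
  for (int j = 0; j < npath; ++j)
    if (pt.random[j]) ridx.push_back(j);
  const int nR = ridx.size();

  const double coef_prec = as<double>(prior["coef_prec"]);
  const double mean_prec = as<double>(prior["mean_prec"]);
  const double ig_a = as<double>(prior["ig_a"]), ig_b = as<double>(prior["ig_b"]);
  const double tau_a = as<double>(prior["tau_a"]), tau_b = as<double>(prior["tau_b"]);
  const double om_a = as<double>(prior["omega_a"]), om_b = as<double>(prior["omega_b"]);
  const double mh_step = as<double>(prior["mh_step"]);
  const double iw_df = as<double>(prior["iw_df"]);

  const bool fix_coef = as<bool>(control["fix_coef"]);
  const bool fix_resid = as<bool>(control["fix_resid"]);
  const bool fix_mu = as<bool>(control["fix_mu"]);
  const bool fix_between = as<bool>(control["fix_between"]);
  const bool store_imp = as<bool>(control["store_imp"]);
  const int dev_every = as<int>(control["dev_every"]); // 0 = never

  // ---- state ----
  mat Bmat = as<mat>(init["Bmat"]);      // K x K, (out, pred)
  vec cvec = as<vec>(init["cvec"]);      // lag-0 fixed coefficients (per edge)
  mat Psi = as<mat>(init["Psi"]);        // K x K (cov mode); diag otherwise
  vec sigma2 = as<vec>(init["sigma2"]);  // K
  mat Mu = as<mat>(init["Mu"]);          // N x K
  vec nu = as<vec>(init["nu"]);          // K
  mat SigB = as<mat>(init["SigB"]);      // K x K
  mat Slopes = as<mat>(init["slopes"]);  // N x nR (0 cols if none)
  List gl = init["g"];                   // per random path: vec (1 [+ P])
  vec tau2 = as<vec>(init["tau2"]);      // nR
  mat Vlog = as<mat>(init["vlog"]);      // N x K (random_resid)
  vec lambda = as<vec>(init["lambda"]);  // K
  vec omega2 = as<vec>(init["omega2"]);  // K
  cube D = as<cube>(init["D"]);          // T x K x N deviations (imputed filled)

  std::vector<vec> g(nR);
  for (int j = 0; j < nR; ++j) g[j] = as<vec>(gl[j]);

  // lag-0 edge list (out, pred) in path-table order
  std::vector<int> e_out, e_pred;
  for (int j = 0; j < npath; ++j)
    if (pt.type[j] == 0) { e_out.push_back(pt.out[j]); e_pred.push_back(pt.pred[j]); }
  const int nE = e_out.size();

  // missing registry
  std::vector<int> mi_p, mi_t, mi_k;
  for (int i = 0; i < N; ++i)
    for (int t = 0; t < T; ++t)
      for (int k = 0; k < K; ++k)
        if (!std::isfinite(Y(t, k, i))) { mi_p.push_back(i); mi_t.push_back(t); mi_k.push_back(k); }
  const int nmiss = mi_p.size();

  // parameter vector layout
  int npar = K * K + nE;
  npar += lag0_cov ? K * (K + 1) / 2 : (random_resid ? 2 * K : K);
  npar += K + K * (K + 1) / 2; // nu + SigB lower tri
  for (int j = 0; j < nR; ++j) npar += (pt.moder[ridx[j]] ? 1 + P : 1) + 1;

  mat draws(n_iter, npar);
  vec devs(n_iter);
  devs.fill(NA_REAL);
  mat Mu_draws(n_iter, N * K);
  mat Slope_draws(n_iter, N * nR);
  mat Vlog_draws;
  if (random_resid) Vlog_draws.set_size(n_iter, N * K);
  mat Imp_draws;
  if (store_imp) Imp_draws.set_size(n_iter, nmiss);

  // workspace
  mat M0s(K, K), M1s(K, K);                   // shared effective matrices
  cube M0p, M1p;                              // person matrices if random slopes
  const bool per_person_dyn = (nR > 0);
  if (per_person_dyn) { M0p.set_size(K, K, N); M1p.set_size(K, K, N); }
  const bool per_person_var = random_resid;

  int n_rows = N * (T - 1);
  mat X1(n_rows, K), X0(n_rows, K); // lagged / current deviations, stacked
  vec wrow(n_rows, arma::fill::ones);

  double mh_prop = 0, mh_acc = 0;

  // random-path position within its equation design:
  // eq k design = [d_{t-1,0..K-1}, d_t(lag0 preds of eq k in edge order)]
  // Build per-eq predictor lists once.
  std::vector<std::vector<int>> eq_path(K); // global path ids per eq, design order
  for (int k = 0; k < K; ++k) {
    for (int q = 0; q < K; ++q)
      for (int j = 0; j < npath; ++j)
        if (pt.type[j] == 1 && pt.out[j] == k && pt.pred[j] == q) eq_path[k].push_back(j);
    for (int j = 0; j < npath; ++j)
      if (pt.type[j] == 0 && pt.out[j] == k) eq_path[k].push_back(j);
  }
  // map path id -> index in ridx
  std::vector<int> rpos(npath, -1);
  for (int j = 0; j < nR; ++j) rpos[ridx[j]] = j;
  // map lag-0 path id -> index in cvec/edge order
  std::vector<int> epos(npath, -1);
  {
    int c = 0;
    for (int j = 0; j < npath; ++j)
      if (pt.type[j] == 0) epos[j] = c++;
  }

  auto eff_mats = [&](int i, mat& M0, mat& M1) {
    M1 = Bmat;
    mat B0(K, K, arma::fill::zeros);
    for (int j = 0; j < npath; ++j) {
      double val;
      if (pt.random[j])
        val = Slopes(i, rpos[j]);
      else
        val = (pt.type[j] == 1) ? Bmat(pt.out[j], pt.pred[j]) : cvec(epos[j]);
      if (pt.type[j] == 1)
        M1(pt.out[j], pt.pred[j]) = val;
      else
        B0(pt.out[j], pt.pred[j]) = val;
    }
    M0 = arma::eye(K, K) - B0;
  };

  auto psi_of = [&](int i) -> mat {
    if (lag0_cov) return Psi;
    vec s(K);
    for (int k = 0; k < K; ++k) s(k) = per_person_var ? std::exp(Vlog(i, k)) : sigma2(k);
    return arma::diagmat(s);
  };

  for (int it = 0; it < n_iter; ++it) {
    if (it % 50 == 0) Rcpp::checkUserInterrupt();

    // effective dynamic matrices
    if (per_person_dyn) {
      for (int i = 0; i < N; ++i) { mat a(K, K), b(K, K); eff_mats(i, a, b); M0p.slice(i) = a; M1p.slice(i) = b; }
    } else {
      eff_mats(0, M0s, M1s);
    }

    // ---- 1. imputation of missing slots ------------------------------
    if (nmiss > 0) {
      // per-person precision of residuals and stationary V
      double Atil[9], Q[9], V[9], Vinv_[9];
      mat Pm; // residual precision
      int last_i = -1;
      mat M0c, M1c, Psic, Vinv(K, K);
      for (int m = 0; m < nmiss; ++m) {
        int i = mi_p[m], t = mi_t[m], k = mi_k[m];
        if (i != last_i) {
          M0c = per_person_dyn ? M0p.slice(i) : M0s;
          M1c = per_person_dyn ? M1p.slice(i) : M1s;
          Psic = psi_of(i);
          Pm = arma::inv_sympd(Psic);
          implied_mats(M0c, M1c, Psic, K, Atil, Q, V);
          for (int a = 0; a < K * K; ++a) Vinv_[a] = V[a];
          Vinv = arma::inv_sympd(mat(Vinv_, K, K));
          last_i = i;
        }
        double* Di = D.slice_memptr(i); // T x K col-major
        double prec = 0, lin = 0;
        double xold = Di[t + k * T];
        if (t == 0) {
          prec += Vinv(k, k);
          double s = 0;
          for (int j = 0; j < K; ++j)
            if (j != k) s += Vinv(k, j) * Di[0 + j * T];
          lin += -s;
        } else {
          // r_t = M0 d_t - M1 d_{t-1}; coefficient of x is a0 = M0[,k]
          for (int a = 0; a < K; ++a) {
            double ra = 0;
            for (int j = 0; j < K; ++j)
              ra += M0c(a, j) * Di[t + j * T] - M1c(a, j) * Di[(t - 1) + j * T];
            ra -= M0c(a, k) * xold; // rest with x = 0
            for (int b = 0; b < K; ++b) lin += -M0c(b, k) * Pm(b, a) * ra;
          }
          for (int a = 0; a < K; ++a)
            for (int b = 0; b < K; ++b) prec += M0c(a, k) * Pm(a, b) * M0c(b, k);
        }
        if (t < T - 1) {
          // r_{t+1} = M0 d_{t+1} - M1 d_t; coefficient of x is a1 = -M1[,k]
          for (int a = 0; a < K; ++a) {
            double ra = 0;
            for (int j = 0; j < K; ++j)
              ra += M0c(a, j) * Di[(t + 1) + j * T] - M1c(a, j) * Di[t + j * T];
            ra += M1c(a, k) * xold;
            for (int b = 0; b < K; ++b) lin += M1c(b, k) * Pm(b, a) * ra;
          }
          for (int a = 0; a < K; ++a)
            for (int b = 0; b < K; ++b) prec += M1c(a, k) * Pm(a, b) * M1c(b, k);
        }
        double sd = std::sqrt(1.0 / prec);
        double xn = lin / prec + sd * R::norm_rand();
        Di[t + k * T] = xn;
        if (store_imp) Imp_draws(it, m) = xn + Mu(i, k);
      }
    }

    // stack lag matrices (deviations)
    for (int i = 0; i < N; ++i) {
      const mat& Di = D.slice(i);
      X0.rows(i * (T - 1), (i + 1) * (T - 1) - 1) = Di.rows(1, T - 1);
      X1.rows(i * (T - 1), (i + 1) * (T - 1) - 1) = Di.rows(0, T - 2);
    }

    // ---- 2. coefficients ---------------------------------------------
    if (!fix_coef) {
      if (lag0_cov) {
        // multivariate regression X0 = X1 * Gamma + E, E ~ N(0, Psi)
        mat XtX = X1.t() * X1;
        XtX.diag() += coef_prec;
        mat XtY = X1.t() * X0;
        mat XtXi = arma::inv_sympd(XtX);
        mat Gh = XtXi * XtY;
        mat Z(K, K);
        for (int a = 0; a < K * K; ++a) Z(a) = R::norm_rand();
        mat Gd = Gh + arma::chol(XtXi, "lower") * Z * arma::chol(Psi, "lower").t();
        Bmat = Gd.t();
      } else {
        for (int k = 0; k < K; ++k) {
          const std::vector<int>& paths = eq_path[k];
          int nf = 0;
          std::vector<int> fidx, rid_here;
          for (size_t a = 0; a < paths.size(); ++a) {
            if (pt.random[paths[a]]) rid_here.push_back((int)a); else { fidx.push_back((int)a); ++nf; }
          }
          int np = paths.size();
          // residual weights per row
          if (per_person_var) {
            for (int i = 0; i < N; ++i)
              wrow.subvec(i * (T - 1), (i + 1) * (T - 1) - 1).fill(1.0 / std::exp(Vlog(i, k)));
          } else {
            wrow.fill(1.0 / sigma2(k));
          }
          // design columns (views): lag-1 = X1 col pred; lag-0 = X0 col pred
          auto dcol = [&](int a) -> vec {
            int j = paths[a];
            return (pt.type[j] == 1) ? X1.col(pt.pred[j]) : X0.col(pt.pred[j]);
          };
          vec yk = X0.col(k);
          // subtract random-slope contributions
          vec yadj = yk;
          for (size_t b = 0; b < rid_here.size(); ++b) {
            int a = rid_here[b];
            int j = paths[a];
            vec col = dcol(a);
            for (int i = 0; i < N; ++i)
              yadj.subvec(i * (T - 1), (i + 1) * (T - 1) - 1) -=
                  Slopes(i, rpos[j]) * col.subvec(i * (T - 1), (i + 1) * (T - 1) - 1);
          }
          if (nf > 0) {
            mat Xf(n_rows, nf);
            for (int a = 0; a < nf; ++a) Xf.col(a) = dcol(fidx[a]);
            mat Xw = Xf.each_col() % wrow;
            mat A = Xf.t() * Xw;
            A.diag() += coef_prec;
            vec b = Xw.t() * yadj;
            vec beta = mvn_prec(A, b);
            for (int a = 0; a < nf; ++a) {
              int j = paths[fidx[a]];
              if (pt.type[j] == 1) Bmat(pt.out[j], pt.pred[j]) = beta(a);
              else cvec(epos[j]) = beta(a);
            }
          }
          // random slopes for this equation (joint per person)
          if (!rid_here.empty()) {
            int nr = rid_here.size();
            // fixed-part prediction
            vec fpred(n_rows, arma::fill::zeros);
            for (int a = 0; a < nf; ++a) {
              int j = paths[fidx[a]];
              double bval = (pt.type[j] == 1) ? Bmat(pt.out[j], pt.pred[j]) : cvec(epos[j]);
              fpred += bval * dcol(fidx[a]);
            }
            vec yr = yk - fpred;
            for (int i = 0; i < N; ++i) {
              double s2 = per_person_var ? std::exp(Vlog(i, k)) : sigma2(k);
              mat A(nr, nr, arma::fill::zeros);
              vec b(nr, arma::fill::zeros);
              arma::span rows(i * (T - 1), (i + 1) * (T - 1) - 1);
              for (int a = 0; a < nr; ++a) {
                vec ca = dcol(rid_here[a]).rows(rows.a, rows.b);
                vec yi = yr.subvec(rows.a, rows.b);
                b(a) = arma::dot(ca, yi) / s2;
                for (int b2 = 0; b2 <= a; ++b2) {
                  vec cb = dcol(rid_here[b2]).rows(rows.a, rows.b);
                  A(a, b2) = A(b2, a) = arma::dot(ca, cb) / s2;
                }
              }
              for (int a = 0; a < nr; ++a) {
                int j = paths[rid_here[a]];
                int rj = rpos[j];
                double pm = g[rj](0);
                if (pt.moder[j])
                  for (int pcol = 0; pcol < P; ++pcol) pm += g[rj](1 + pcol) * X(i, pcol);
                A(a, a) += 1.0 / tau2(rj);
                b(a) += pm / tau2(rj);
              }
              vec sl = mvn_prec(A, b);
              for (int a = 0; a < nr; ++a) Slopes(i, rpos[paths[rid_here[a]]]) = sl(a);
            }
          }
        }
        // hyper-parameters of random slopes
        for (int j = 0; j < nR; ++j) {
          int pj = ridx[j];
          int q = pt.moder[pj] ? 1 + P : 1;
          mat Z(N, q, arma::fill::ones);
          if (pt.moder[pj]) Z.cols(1, P) = X;
          mat A = Z.t() * Z / tau2(j);
          A.diag() += mean_prec;
          vec b = Z.t() * Slopes.col(j) / tau2(j);
          g[j] = mvn_prec(A, b);
          vec resid = Slopes.col(j) - Z * g[j];
          double sa = tau_a + N / 2.0, sb = tau_b + arma::dot(resid, resid) / 2.0;
          tau2(j) = sb / R::rgamma(sa, 1.0);
        }
      }
    }

    // ---- 3. residual (co)variances -----------------------------------
    if (!fix_resid) {
      // residuals with current coefficients
      if (lag0_cov) {
        mat E = X0 - X1 * Bmat.t();
        mat S = arma::eye(K, K) + E.t() * E;
        Psi = riwishart(iw_df + n_rows, S);
      } else {
        // per-equation residuals
        for (int k = 0; k < K; ++k) {
          vec r = X0.col(k);
          for (size_t a = 0; a < eq_path[k].size(); ++a) {
            int j = eq_path[k][a];
            vec col = (pt.type[j] == 1) ? X1.col(pt.pred[j]) : X0.col(pt.pred[j]);
            if (pt.random[j]) {
              for (int i = 0; i < N; ++i)
                r.subvec(i * (T - 1), (i + 1) * (T - 1) - 1) -=
                    Slopes(i, rpos[j]) * col.subvec(i * (T - 1), (i + 1) * (T - 1) - 1);
            } else {
              double bval = (pt.type[j] == 1) ? Bmat(pt.out[j], pt.pred[j]) : cvec(epos[j]);
              r -= bval * col;
            }
          }
          if (!random_resid) {
            double ssr = arma::dot(r, r);
            double sa = ig_a + n_rows / 2.0, sb = ig_b + ssr / 2.0;
            sigma2(k) = sb / R::rgamma(sa, 1.0);
          } else {
            // per-person Metropolis on v = log sigma^2
            for (int i = 0; i < N; ++i) {
              vec ri = r.subvec(i * (T - 1), (i + 1) * (T - 1) - 1);
              double ssr = arma::dot(ri, ri);
              double v0 = Vlog(i, k);
              double v1 = v0 + mh_step * R::norm_rand();
              double nt = T - 1.0;
              double l0 = -0.5 * nt * v0 - 0.5 * ssr * std::exp(-v0) -
                          0.5 * (v0 - lambda(k)) * (v0 - lambda(k)) / omega2(k);
              double l1 = -0.5 * nt * v1 - 0.5 * ssr * std::exp(-v1) -
                          0.5 * (v1 - lambda(k)) * (v1 - lambda(k)) / omega2(k);
              mh_prop += 1;
              if (std::log(R::unif_rand()) < l1 - l0) { Vlog(i, k) = v1; mh_acc += 1; }
            }
            // lambda, omega2
            double vbar = arma::mean(Vlog.col(k));
            double postv = 1.0 / (N / omega2(k) + mean_prec);
            lambda(k) = postv * (N * vbar / omega2(k)) + std::sqrt(postv) * R::norm_rand();
            vec dv = Vlog.col(k) - lambda(k);
            double sa = om_a + N / 2.0, sb = om_b + arma::dot(dv, dv) / 2.0;
            omega2(k) = sb / R::rgamma(sa, 1.0);
          }
        }
      }
    }

    // ---- 4. person intercepts, grand means, between covariance -------
    if (!fix_mu) {
      mat SigBinv = arma::inv_sympd(SigB);
      double Atil[9], Q[9], V[9];
      mat M0c = M0s, M1c = M1s, Psic;
      if (!per_person_dyn && !per_person_var) {
        Psic = psi_of(0);
        implied_mats(M0c, M1c, Psic, K, Atil, Q, V);
      }
      for (int i = 0; i < N; ++i) {
        if (per_person_dyn) { M0c = M0p.slice(i); M1c = M1p.slice(i); }
        if (per_person_dyn || per_person_var) {
          Psic = psi_of(i);
          implied_mats(M0c, M1c, Psic, K, Atil, Q, V);
        } else if (i == 0) {
          Psic = psi_of(0);
        }
        mat Pm = arma::inv_sympd(Psic);
        mat Vm(K, K);
        for (int a = 0; a < K; ++a)
          for (int b = 0; b < K; ++b) Vm(a, b) = V[a + b * K];
        mat Vinv = arma::inv_sympd(Vm);
        mat W = M0c - M1c;
        // column sums of y_t (t>=2) and y_t (t<=T-1), y = D + mu
        const mat& Di = D.slice(i);
        arma::rowvec s0 = arma::sum(Di.rows(1, T - 1), 0) + (T - 1.0) * Mu.row(i);
        arma::rowvec s1 = arma::sum(Di.rows(0, T - 2), 0) + (T - 1.0) * Mu.row(i);
        vec zsum = M0c * s0.t() - M1c * s1.t();
        vec y1 = Di.row(0).t() + Mu.row(i).t();
        mat Prec = (T - 1.0) * W.t() * Pm * W + Vinv + SigBinv;
        vec b = W.t() * Pm * zsum + Vinv * y1 + SigBinv * nu;
        vec mun = mvn_prec(Prec, b);
        arma::rowvec shift = Mu.row(i) - mun.t();
        D.slice(i).each_row() += shift;
        Mu.row(i) = mun.t();
      }
    }
    if (!fix_between) {
      mat SigBinv = arma::inv_sympd(SigB);
      mat Pn = (double)N * SigBinv;
      Pn.diag() += mean_prec;
      vec b = SigBinv * arma::sum(Mu, 0).t();
      nu = mvn_prec(Pn, b);
      mat S = arma::eye(K, K);
      for (int i = 0; i < N; ++i) {
        vec d = Mu.row(i).t() - nu;
        S += d * d.t();
      }
      SigB = riwishart(iw_df + N, S);
    }

    // ---- 5. deviance --------------------------------------------------
    if (dev_every > 0 && ((it + 1) % dev_every == 0)) {
      double Atil[9], Q[9], V[9];
      double ll = 0;
      mat M0c = M0s, M1c = M1s;
      bool shared = (!per_person_dyn && !per_person_var);
      if (shared) implied_mats(M0c, M1c, psi_of(0), K, Atil, Q, V);
      for (int i = 0; i < N; ++i) {
        if (!shared) {
          if (per_person_dyn) { M0c = M0p.slice(i); M1c = M1p.slice(i); }
          implied_mats(M0c, M1c, psi_of(i), K, Atil, Q, V);
        }
        ll += person_loglik(Y.slice(i), Mu.row(i).t(), Atil, Q, V);
      }
      devs(it) = -2.0 * ll;
    }

    // ---- 6. store -----------------------------------------------------
    {
      int c = 0;
      for (int pcol = 0; pcol < K; ++pcol)
        for (int r = 0; r < K; ++r) draws(it, c++) = Bmat(r, pcol);
      for (int a = 0; a < nE; ++a) draws(it, c++) = cvec(a);
      if (lag0_cov) {
        for (int pcol = 0; pcol < K; ++pcol)
          for (int r = pcol; r < K; ++r) draws(it, c++) = Psi(r, pcol);
      } else if (random_resid) {
        for (int k = 0; k < K; ++k) draws(it, c++) = lambda(k);
        for (int k = 0; k < K; ++k) draws(it, c++) = omega2(k);
      } else {
        for (int k = 0; k < K; ++k) draws(it, c++) = sigma2(k);
      }
      for (int k = 0; k < K; ++k) draws(it, c++) = nu(k);
      for (int pcol = 0; pcol < K; ++pcol)
        for (int r = pcol; r < K; ++r) draws(it, c++) = SigB(r, pcol);
      for (int j = 0; j < nR; ++j) {
        for (arma::uword a = 0; a < g[j].n_elem; ++a) draws(it, c++) = g[j](a);
        draws(it, c++) = tau2(j);
      }
      for (int k = 0; k < K; ++k)
        for (int i = 0; i < N; ++i) Mu_draws(it, i + k * N) = Mu(i, k);
      for (int j = 0; j < nR; ++j)
        for (int i = 0; i < N; ++i) Slope_draws(it, i + j * N) = Slopes(i, j);
      if (random_resid)
        for (int k = 0; k < K; ++k)
          for (int i = 0; i < N; ++i) Vlog_draws(it, i + k * N) = Vlog(i, k);
    }
  }

  List gout(nR);
  for (int j = 0; j < nR; ++j) gout[j] = g[j];
  List state = List::create(
      _["Bmat"] = Bmat, _["cvec"] = cvec, _["Psi"] = Psi, _["sigma2"] = sigma2,
      _["Mu"] = Mu, _["nu"] = nu, _["SigB"] = SigB, _["slopes"] = Slopes,
      _["g"] = gout, _["tau2"] = tau2, _["vlog"] = Vlog, _["lambda"] = lambda,
      _["omega2"] = omega2, _["D"] = D);

  return List::create(
      _["draws"] = draws, _["dev"] = devs, _["mu_draws"] = Mu_draws,
      _["slope_draws"] = Slope_draws,
      _["vlog_draws"] = random_resid ? wrap(Vlog_draws) : R_NilValue,
      _["imp_draws"] = store_imp ? wrap(Imp_draws) : R_NilValue,
      _["state"] = state,
      _["mh_accept"] = mh_prop > 0 ? mh_acc / mh_prop : NA_REAL,
      _["n_missing"] = nmiss);
}

// stationary covariance of the within-person process (used for
// standardization and oracles)
// [[Rcpp::export]]
arma::mat rdsem_stationary_cov(const arma::mat& B1, const arma::mat& B0,
                               const arma::mat& Psi) {
  int K = B1.n_rows;
  mat M0 = arma::eye(K, K) - B0;
  double Atil[9], Q[9], V[9];
  implied_mats(M0, B1, Psi, K, Atil, Q, V);
  return mat(V, K, K);
}
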