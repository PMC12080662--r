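#' Potential scale reduction
#'
#' Gelman-Rubin between/within variance-ratio diagnostic computed, per
#' parameter, from the second half of each chain: with m chains of n kept
#' draws, `W` the mean within-chain variance and `B` the between-chain
#' variance of the chain means, PSR = sqrt((((n-1)/n) W + B/n) / W).  Values
#' near 1 indicate convergence.
#'
#' @param chains list of draw matrices (iterations x parameters), one per
#'   chain, equal dimensions.
#' @param second_half use only the second half of each chain (default).
#' @return numeric vector of PSR values, one per parameter.
#' @export
psr <- function(chains, second_half = TRUE) {
  if (length(chains) < 2)
    stop("PSR requires at least 2 chains", call. = FALSE)
  n0 <- unique(vapply(chains, nrow, integer(1)))
  if (length(n0) != 1) stop("chains must have equal length", call. = FALSE)
  if (second_half)
    chains <- lapply(chains, function(m)
      m[seq.int(floor(n0 / 2) + 1L, n0), , drop = FALSE])
  n <- nrow(chains[[1]]); m <- length(chains)
  means <- vapply(chains, colMeans, numeric(ncol(chains[[1]])))
  vars <- vapply(chains, function(x) apply(x, 2, stats::var),
                 numeric(ncol(chains[[1]])))
  means <- matrix(means, ncol = m); vars <- matrix(vars, ncol = m)
  W <- rowMeans(vars)
  B <- n * apply(means, 1, stats::var)
  out <- sqrt(((n - 1) / n * W + B / n) / W)
  out[W == 0 & B == 0] <- 1
  out[W == 0 & B > 0] <- Inf
  out
}

# split a stored parameter row into dynamic matrices
row_to_mats <- function(v, spec) {
  K <- length(spec$vars)
  B1 <- matrix(v[seq_len(K * K)], K, K)
  idx <- K * K
  e <- spec$paths[spec$paths$type == "lag0", , drop = FALSE]
  B0 <- matrix(0, K, K)
  if (nrow(e)) {
    B0[cbind(e$out, e$pred)] <- v[idx + seq_len(nrow(e))]
    idx <- idx + nrow(e)
  }
  if (spec$lag0_mode == "covariance") {
    Psi <- matrix(0, K, K)
    for (pc in seq_len(K)) for (r in pc:K) {
      idx <- idx + 1
      Psi[r, pc] <- Psi[pc, r] <- v[idx]
    }
  } else {
    # fixed-variance layout; person-specific variances handled by caller
    Psi <- diag(v[idx + seq_len(K)], K)
    idx <- idx + if (spec$random_resid_var) 2 * K else K
  }
  list(B1 = B1, B0 = B0, Psi = Psi)
}

# names of standardized quantities
std_names <- function(spec) {
  v <- spec$vars
  nm <- paste0("std:", spec$paths$label)
  if (spec$lag0_mode == "covariance")
    nm <- c(nm, paste0("std:lag0:", v[1], "<->", v[2]))
  K <- length(v)
  for (pc in seq_len(K - 1)) for (r in (pc + 1):K)
    nm <- c(nm, paste0("std:between_cor:", v[r], ".", v[pc]))
  nm
}

#' Standardized posterior draws
#'
#' Within-level coefficients are standardized per draw by the ratio of the
#' model-implied within-person stationary SDs of predictor and outcome;
#' with person-level random slopes or residual variances the standardized
#' value is computed per person and averaged over persons within each draw.
#' The undirected lag-0 covariance is reported as the residual correlation,
#' and the between-person covariance as a correlation.
#'
#' @param fit an `rdsem_fit`.
#' @return matrix of standardized draws (kept iterations x quantities).
#' @export
standardized_draws <- function(fit) {
  spec <- fit$spec
  K <- length(spec$vars)
  draws <- kept_draws(fit, "draws")
  nms <- colnames(draws)
  n <- nrow(draws)
  tab <- spec$paths
  e <- tab[tab$type == "lag0", , drop = FALSE]
  has_person <- length(spec$random_paths) > 0 || spec$random_resid_var
  slopes <- if (length(spec$random_paths)) kept_draws(fit, "slope_draws")
  vlogs <- if (spec$random_resid_var) kept_draws(fit, "vlog_draws")
  N <- if (has_person) dim(fit$Y)[3] else 1L
  rnd <- match(spec$random_paths, tab$label)

  out <- matrix(NA_real_, n, length(std_names(spec)))
  colnames(out) <- std_names(spec)
  npaths <- nrow(tab)
  for (d in seq_len(n)) {
    v <- draws[d, ]
    mats <- row_to_mats(v, spec)
    acc <- numeric(npaths + (spec$lag0_mode == "covariance"))
    for (i in seq_len(N)) {
      B1 <- mats$B1; B0 <- mats$B0; Psi <- mats$Psi
      if (length(rnd)) {
        for (j in seq_along(rnd)) {
          pr <- tab[rnd[j], ]
          val <- slopes[d, i + (j - 1) * N]
          if (pr$type == "lag1") B1[pr$out, pr$pred] <- val
          else B0[pr$out, pr$pred] <- val
        }
      }
      if (spec$random_resid_var)
        Psi <- diag(exp(vlogs[d, i + (seq_len(K) - 1) * N]), K)
      V <- rdsem_stationary_cov(B1, B0, Psi)
      sds <- sqrt(pmax(diag(V), 0))
      if (any(sds == 0)) next
      for (j in seq_len(npaths)) {
        b <- if (tab$type[j] == "lag1") B1[tab$out[j], tab$pred[j]]
             else B0[tab$out[j], tab$pred[j]]
        acc[j] <- acc[j] + b * sds[tab$pred[j]] / sds[tab$out[j]]
      }
      if (spec$lag0_mode == "covariance")
        acc[npaths + 1] <- acc[npaths + 1] +
          Psi[2, 1] / sqrt(Psi[1, 1] * Psi[2, 2])
    }
    out[d, seq_along(acc)] <- acc / N
  }
  # between-level correlations straight from the stored draws
  col <- sum(spec$lag0_mode == "covariance") + npaths
  for (pc in seq_len(K - 1)) for (r in (pc + 1):K) {
    col <- col + 1
    cv <- draws[, paste0("b_cov:", spec$vars[r], ".", spec$vars[pc])]
    v1 <- draws[, paste0("b_var:", spec$vars[r])]
    v2 <- draws[, paste0("b_var:", spec$vars[pc])]
    out[, col] <- cv / sqrt(v1 * v2)
  }
  out
}

# observed-data DIC: Dbar from the stored per-iteration deviances, Dhat at
# the posterior means of all parameters (including person-level ones)
compute_dic <- function(fit) {
  spec <- fit$spec
  K <- length(spec$vars); N <- dim(fit$Y)[3]
  devs <- unlist(lapply(fit$chains, function(ch) ch$dev[fit$kept]))
  devs <- devs[is.finite(devs)]
  if (length(devs) == 0)
    return(c(DIC = NA_real_, pD = NA_real_, Dbar = NA_real_,
             Dhat = NA_real_))
  Dbar <- mean(devs)
  pm <- colMeans(kept_draws(fit, "draws"))
  mats <- row_to_mats(pm, spec)
  tab <- spec$paths
  mu_m <- colMeans(kept_draws(fit, "mu_draws"))
  Mu <- matrix(mu_m, N, K)
  B1p <- array(rep(mats$B1, N), c(K, K, N))
  B0p <- array(rep(mats$B0, N), c(K, K, N))
  if (length(spec$random_paths)) {
    sl <- colMeans(kept_draws(fit, "slope_draws"))
    rnd <- match(spec$random_paths, tab$label)
    for (j in seq_along(rnd)) {
      pr <- tab[rnd[j], ]
      for (i in seq_len(N)) {
        if (pr$type == "lag1") B1p[pr$out, pr$pred, i] <- sl[i + (j - 1) * N]
        else B0p[pr$out, pr$pred, i] <- sl[i + (j - 1) * N]
      }
    }
  }
  Psip <- array(rep(mats$Psi, N), c(K, K, N))
  if (spec$random_resid_var) {
    s2m <- colMeans(exp(kept_draws(fit, "vlog_draws")))
    for (i in seq_len(N)) Psip[, , i] <- diag(s2m[i + (seq_len(K) - 1) * N], K)
  }
  Dhat <- rdsem_deviance_cpp(fit$Y, B1p, B0p, Psip, Mu)
  pD <- Dbar - Dhat
  c(DIC = Dbar + pD, pD = pD, Dbar = Dbar, Dhat = Dhat)
}

#' Deviance information criterion of a fit
#'
#' The deviance is -2 times the observed-data log likelihood conditional on
#' the person-level parameters and the dynamic parameters, with the missing
#' grid slots marginalized analytically (Kalman filter over the slotted
#' state space).  `pD = mean(D) - D(posterior means)`; `DIC = mean(D) + pD`.
#' This conditioning is one of several DIC variants and is logged with every
#' pipeline run.
#'
#' @param fit an `rdsem_fit`.
#' @return named vector with `DIC`, `pD`, `Dbar`, `Dhat`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "rdsem_fit"))
  fit$dic
}

# one-tailed posterior probability of the minority sign
sign_p <- function(x) min(mean(x > 0), mean(x < 0))

#' Posterior summary table
#'
#' One row per quantity: posterior mean, median, 95% credible interval
#' (2.5/97.5 percentiles), the one-tailed posterior probability of the
#' minority sign (values below 0.025 flag a two-tailed-significant path),
#' and the potential scale reduction of the underlying stored parameter.
#'
#' @param object an `rdsem_fit`.
#' @param standardized summarize standardized quantities (default) or the
#'   raw stored parameters.
#' @param ... unused.
#' @return a data.frame, one row per parameter.
#' @export
summary.rdsem_fit <- function(object, standardized = TRUE, ...) {
  draws <- if (standardized) object$std else kept_draws(object, "draws")
  spec <- object$spec
  rows <- lapply(colnames(draws), function(nm) {
    x <- draws[, nm]
    x <- x[is.finite(x)]
    q <- stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
    is_path <- grepl("^(std:)?(lag[01]|mod|slope_mean|b_cov|rescov)",
                     nm) || grepl("between_cor|<->", nm)
    data.frame(parameter = nm, est = mean(x), median = q[2],
               lci = q[1], uci = q[3],
               p = if (is_path) sign_p(x) else NA_real_,
               psr = map_psr(object, nm))
  })
  out <- do.call(rbind, rows)
  out$sig <- !is.na(out$p) & out$p < 0.025
  attr(out, "dic") <- object$dic
  attr(out, "iterations") <- object$iterations
  attr(out, "converged") <- object$converged
  out
}

# PSR of the raw parameter underlying a (possibly standardized) quantity
map_psr <- function(fit, nm) {
  raw <- sub("^std:", "", nm)
  v <- fit$spec$vars
  if (grepl("^between_cor:", raw))
    raw <- sub("^between_cor:", "b_cov:", raw)
  if (grepl("<->", raw))
    raw <- paste0("rescov:", v[2], ".", v[1])
  if (raw %in% fit$spec$random_paths) raw <- paste0("slope_mean:", raw)
  if (raw %in% names(fit$psr)) unname(fit$psr[raw]) else NA_real_
}

#' @export
print.rdsem_fit <- function(x, ...) {
  cat("Residual-DSEM fit:", length(x$spec$vars), "variables (",
      paste(x$spec$vars, collapse = ", "), "), lag0 =", x$spec$lag0_mode,
      "\n")
  cat(sprintf("  %d persons, %d chains x %d iterations (%s)\n",
              dim(x$Y)[3], x$mcmc$chains, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  max PSR = %.3f, DIC = %.2f (pD = %.1f)\n",
              suppressWarnings(max(x$psr, na.rm = TRUE)), x$dic["DIC"],
              x$dic["pD"]))
  invisible(x)
}
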