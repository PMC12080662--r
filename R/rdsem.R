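#' Specify a residual-DSEM model
#'
#' Defines the two-level VAR(1) model fitted to gridded EMA data: which
#' observed variables enter, how the contemporaneous (lag-0) association is
#' wired, which paths carry person-level random slopes, whether residual
#' variances vary by person, and which person covariates moderate which
#' random slopes.
#'
#' The three canonical bivariate structures are available through
#' [rdsem_model()]: model A wires the lag-0 association as an undirected
#' residual covariance, model B as a directed path from the first variable
#' (stress) to the second, model C as a directed path from the second
#' (symptom composite) to the first.
#'
#' @param vars observed variables (2 for the basic models, 3 for the
#'   symptom-split models); `vars[1]` is the stress-side variable.
#' @param lag0_mode `"covariance"`, `"x_to_y"` or `"y_to_x"` (see above).
#' @param random_paths character vector of path labels (as in
#'   `spec$paths$label`) that receive person-level random slopes; only
#'   supported for directed lag-0 modes.
#' @param random_resid_var person-level (log-normal) residual variances?
#' @param moderators names of person covariates regressed on the moderated
#'   random slopes (z-scored internally).
#' @param moderated_paths which random paths are moderated (default: all
#'   lag-0 random paths, falling back to all random paths).
#' @return an object of class `rdsem_spec`; element `paths` is the path
#'   table with labels.
#' @export
rdsem_spec <- function(vars = c("stress", "mchr"),
                       lag0_mode = c("y_to_x", "x_to_y", "covariance"),
                       random_paths = character(),
                       random_resid_var = FALSE,
                       moderators = character(),
                       moderated_paths = NULL) {
  lag0_mode <- match.arg(lag0_mode)
  K <- length(vars)
  stopifnot(K >= 2)
  if (lag0_mode == "covariance") {
    if (K != 2)
      stop("covariance lag-0 mode is defined for exactly 2 variables",
           call. = FALSE)
    if (length(random_paths) || random_resid_var)
      stop("random effects are supported for the directed lag-0 modes only",
           call. = FALSE)
  }
  paths <- make_path_table(vars, lag0_mode)
  bad <- setdiff(random_paths, paths$label)
  if (length(bad))
    stop("unknown path label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(moderated_paths)) {
    lag0_r <- intersect(random_paths,
                        paths$label[paths$type == "lag0"])
    moderated_paths <- if (length(lag0_r)) lag0_r else random_paths
  }
  if (length(moderators) == 0) moderated_paths <- character()
  bad <- setdiff(moderated_paths, random_paths)
  if (length(bad))
    stop("moderated paths must be random: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(vars = vars, lag0_mode = lag0_mode, paths = paths,
                 random_paths = random_paths,
                 random_resid_var = random_resid_var,
                 moderators = moderators,
                 moderated_paths = moderated_paths),
            class = "rdsem_spec")
}

#' @rdname rdsem_spec
#' @param model `"A"`, `"B"` or `"C"`.
#' @param ... passed on to [rdsem_spec()].
#' @export
rdsem_model <- function(model = c("A", "B", "C"),
                        vars = c("stress", "mchr"), ...) {
  model <- match.arg(model)
  rdsem_spec(vars = vars,
             lag0_mode = switch(model, A = "covariance", B = "x_to_y",
                                C = "y_to_x"), ...)
}

#' Prior settings
#'
#' Diffuse proper priors in the spirit of standard Bayesian SEM software
#' defaults: essentially flat normals (precision `coef_prec`) for regression
#' coefficients and means, inverse-gamma(`ig_a`, `ig_b`) for residual
#' variances, inverse-Wishart(identity, K + 1) for covariance matrices, and
#' inverse-gammas for random-slope and log-residual-variance variances.
#' `mh_step` is the random-walk SD of the Metropolis update for person log
#' residual variances.
#'
#' @param coef_prec,mean_prec prior precisions of coefficients / means.
#' @param ig_a,ig_b residual-variance inverse-gamma shape and scale.
#' @param tau_a,tau_b random-slope variance inverse-gamma shape and scale.
#' @param omega_a,omega_b log-residual-variance variance hyperprior.
#' @param mh_step Metropolis step SD.
#' @export
rdsem_priors <- function(coef_prec = 1e-10, mean_prec = 1e-10,
                         ig_a = 0.001, ig_b = 0.001,
                         tau_a = 0.001, tau_b = 0.001,
                         omega_a = 0.001, omega_b = 0.001,
                         mh_step = 0.3) {
  structure(list(coef_prec = coef_prec, mean_prec = mean_prec,
                 ig_a = ig_a, ig_b = ig_b, tau_a = tau_a, tau_b = tau_b,
                 omega_a = omega_a, omega_b = omega_b, mh_step = mh_step),
            class = "rdsem_priors")
}

#' MCMC settings
#'
#' At least `min_iterations` iterations are run per chain; convergence is
#' then checked with the potential scale reduction (PSR) on the second half
#' of each chain every `check_every` iterations until all monitored
#' parameters fall below `psr_threshold` or `max_iterations` is reached.
#' Posterior summaries use the second half of each chain.
#'
#' @param chains number of chains (at least 2 for PSR).
#' @param min_iterations minimum iterations per chain before convergence is
#'   assessed (default 2000).
#' @param max_iterations hard cap per chain.
#' @param psr_threshold convergence threshold for PSR.
#' @param check_every iterations between PSR checks past the minimum.
#' @param seed integer seed; a fit is bit-reproducible given the seed.
#' @param dev_every compute the observed-data deviance every this many
#'   iterations (for the DIC).
#' @export
mcmc_settings <- function(chains = 2, min_iterations = 2000,
                          max_iterations = 10000, psr_threshold = 1.05,
                          check_every = 100, seed = 1, dev_every = 5) {
  stopifnot(chains >= 1, min_iterations >= 1,
            max_iterations >= min_iterations, psr_threshold > 1)
  structure(list(chains = as.integer(chains),
                 min_iterations = as.integer(min_iterations),
                 max_iterations = as.integer(max_iterations),
                 psr_threshold = psr_threshold,
                 check_every = as.integer(check_every),
                 seed = as.integer(seed), dev_every = as.integer(dev_every)),
            class = "mcmc_settings")
}

#' Assemble gridded data for fitting
#'
#' Converts a gridded long table (one row per person and slot) into the
#' slots x variables x persons array the sampler consumes, excluding persons
#' with fewer than two observed slots (they carry no dynamic information)
#' with a warning.
#'
#' @param gridded output of [grid_ema_dataset()] or any data.frame with
#'   `person_id`, `slot` and the model variables.
#' @param spec an [rdsem_spec()].
#' @return list with `Y` (array), `persons` (ids in slice order) and
#'   `n_obs` per person.
#' @export
build_rdsem_data <- function(gridded, spec) {
  stopifnot(all(c("person_id", "slot") %in% names(gridded)))
  miss <- setdiff(spec$vars, names(gridded))
  if (length(miss))
    stop("variables not in data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  ids <- unique(gridded$person_id)
  if (length(ids) == 0) stop("empty dataset", call. = FALSE)
  T_ <- max(gridded$slot) + 1L
  keep <- list(); dropped <- character()
  for (pid in ids) {
    sub <- gridded[gridded$person_id == pid, ]
    m <- matrix(NA_real_, T_, length(spec$vars))
    m[sub$slot + 1L, ] <- as.matrix(sub[, spec$vars])
    if (sum(stats::complete.cases(m)) < 2) {
      dropped <- c(dropped, as.character(pid)); next
    }
    keep[[as.character(pid)]] <- m
  }
  if (length(dropped))
    warning("excluded person(s) with fewer than 2 observations: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  if (length(keep) == 0) stop("no person has 2+ observations", call. = FALSE)
  Y <- array(unlist(keep), dim = c(T_, length(spec$vars), length(keep)),
             dimnames = list(NULL, spec$vars, names(keep)))
  list(Y = Y, persons = names(keep),
       n_obs = vapply(keep, function(m) sum(stats::complete.cases(m)),
                      integer(1)))
}

# names of the stored raw parameter vector, mirroring the kernel layout
param_names <- function(spec) {
  v <- spec$vars; K <- length(v)
  nm <- character()
  for (p in v) for (o in v) nm <- c(nm, path_label("lag1", p, o))
  tab <- spec$paths
  for (j in which(tab$type == "lag0"))
    nm <- c(nm, tab$label[j])
  if (spec$lag0_mode == "covariance") {
    for (pc in seq_len(K)) for (r in pc:K)
      nm <- c(nm, if (r == pc) paste0("resvar:", v[r])
              else paste0("rescov:", v[r], ".", v[pc]))
  } else if (spec$random_resid_var) {
    nm <- c(nm, paste0("resvar_logmean:", v), paste0("resvar_logvar:", v))
  } else {
    nm <- c(nm, paste0("resvar:", v))
  }
  nm <- c(nm, paste0("mean:", v))
  for (pc in seq_len(K)) for (r in pc:K)
    nm <- c(nm, if (r == pc) paste0("b_var:", v[r])
            else paste0("b_cov:", v[r], ".", v[pc]))
  for (lb in spec$random_paths) {
    nm <- c(nm, paste0("slope_mean:", lb))
    if (lb %in% spec$moderated_paths)
      nm <- c(nm, paste0("mod:", spec$moderators, ":", lb))
    nm <- c(nm, paste0("slope_var:", lb))
  }
  nm
}

# kernel spec list from an rdsem_spec + moderator matrix
kernel_spec <- function(spec, X) {
  tab <- spec$paths
  list(lag0_cov = spec$lag0_mode == "covariance",
       random_resid = spec$random_resid_var,
       X = X,
       path_type = as.integer(tab$type == "lag1"),
       path_out = as.integer(tab$out - 1L),
       path_pred = as.integer(tab$pred - 1L),
       path_random = as.integer(tab$label %in% spec$random_paths),
       path_moderated = as.integer(tab$label %in% spec$moderated_paths))
}

default_init <- function(Y, spec, jitter = 0) {
  T_ <- dim(Y)[1]; K <- dim(Y)[2]; N <- dim(Y)[3]
  Mu <- t(apply(Y, 3, function(m) colMeans(m, na.rm = TRUE)))
  Mu <- matrix(Mu, N, K)
  gm <- colMeans(Mu, na.rm = TRUE)
  for (k in seq_len(K)) Mu[!is.finite(Mu[, k]), k] <- gm[k]
  D <- array(0, dim(Y))
  for (i in seq_len(N)) {
    d <- sweep(Y[, , i, drop = FALSE][, , 1], 2, Mu[i, ])
    d[!is.finite(d)] <- 0
    D[, , i] <- d
  }
  s2 <- apply(Y, 2, function(m) stats::var(as.vector(m), na.rm = TRUE))
  s2[!is.finite(s2) | s2 <= 0] <- 1
  nR <- length(spec$random_paths)
  P <- length(spec$moderators)
  g <- lapply(spec$random_paths, function(lb) {
    q <- if (lb %in% spec$moderated_paths) 1 + P else 1
    rep(0, q)
  })
  list(Bmat = matrix(stats::rnorm(K * K, 0, jitter), K, K),
       cvec = stats::rnorm(sum(spec$paths$type == "lag0"), 0, jitter),
       Psi = diag(s2, K), sigma2 = s2, Mu = Mu, nu = gm,
       SigB = diag(pmax(apply(Mu, 2, stats::var), 0.01), K),
       slopes = matrix(0, N, nR), g = g,
       tau2 = rep(0.01, nR),
       vlog = matrix(log(s2), N, K, byrow = TRUE),
       lambda = log(s2), omega2 = rep(0.1, K), D = D)
}

merge_init <- function(base, override, Y = NULL) {
  if (is.null(override)) return(base)
  for (nm in names(override)) base[[nm]] <- override[[nm]]
  if (!is.null(Y) && "Mu" %in% names(override) &&
      !("D" %in% names(override))) {
    # keep deviations consistent with the supplied intercepts
    for (i in seq_len(dim(Y)[3])) {
      d <- sweep(Y[, , i, drop = FALSE][, , 1], 2, base$Mu[i, ])
      d[!is.finite(d)] <- 0
      base$D[, , i] <- d
    }
  }
  base
}

#' Fitting control
#'
#' Advanced switches, mainly for validation against closed-form oracles:
#' individual parameter blocks can be clamped at the values supplied in
#' `init`, and the per-iteration draws of the imputed missing slots can be
#' stored.
#'
#' @param fix_coef,fix_resid,fix_mu,fix_between clamp the corresponding
#'   block at its initial value.
#' @param store_imputations store raw-scale draws of every missing slot.
#' @param init named list overriding entries of the default initial state
#'   (`Bmat`, `cvec`, `sigma2`, `Psi`, `Mu`, `nu`, `SigB`, `D`, ...).
#' @export
rdsem_control <- function(fix_coef = FALSE, fix_resid = FALSE,
                          fix_mu = FALSE, fix_between = FALSE,
                          store_imputations = FALSE, init = NULL) {
  list(fix_coef = fix_coef, fix_resid = fix_resid, fix_mu = fix_mu,
       fix_between = fix_between, store_imputations = store_imputations,
       init = init)
}

#' Fit a residual-DSEM model by Gibbs sampling
#'
#' Runs the blocked Gibbs sampler: conjugate normal updates of regression
#' coefficients, inverse-gamma (or inverse-Wishart) updates of residual
#' (co)variances, normal updates of person intercepts and random slopes,
#' inverse-Wishart update of the between-person covariance, a Metropolis
#' step for person log residual variances, and single-site Gaussian
#' imputation of every missing grid slot.  Chains run at least
#' `mcmc$min_iterations` iterations and continue until the potential scale
#' reduction of every stored parameter is below the threshold or the
#' iteration cap is hit (then the fit is flagged, not discarded).
#'
#' @param gridded gridded data (see [grid_ema_dataset()]), or a prebuilt
#'   list from [build_rdsem_data()].
#' @param spec an [rdsem_spec()].
#' @param priors an [rdsem_priors()].
#' @param mcmc an [mcmc_settings()].
#' @param covariates person covariate table (needed when the spec has
#'   moderators); persons with missing moderator values are excluded with a
#'   message.
#' @param control an [rdsem_control()].
#' @return an object of class `rdsem_fit` with the raw and standardized
#'   draws, PSR, DIC, posterior summaries and convergence log.
#' @export
rdsem_fit <- function(gridded, spec, priors = rdsem_priors(),
                      mcmc = mcmc_settings(), covariates = NULL,
                      control = rdsem_control()) {
  stopifnot(inherits(spec, "rdsem_spec"))
  dat <- if (is.list(gridded) && !is.null(gridded$Y)) gridded
         else build_rdsem_data(gridded, spec)
  Y <- dat$Y
  K <- dim(Y)[2]; N <- dim(Y)[3]
  # moderator matrix
  X <- matrix(0, N, 0)
  if (length(spec$moderators)) {
    if (is.null(covariates))
      stop("spec has moderators but no covariates were given", call. = FALSE)
    idx <- match(dat$persons, covariates$person_id)
    if (anyNA(idx))
      stop("covariates missing for person(s): ",
           paste(dat$persons[is.na(idx)], collapse = ", "), call. = FALSE)
    Xr <- as.matrix(covariates[idx, spec$moderators, drop = FALSE])
    ok <- stats::complete.cases(Xr)
    if (!all(ok)) {
      message(sum(!ok), " person(s) excluded: missing moderator values")
      Y <- Y[, , ok, drop = FALSE]
      dat$persons <- dat$persons[ok]
      Xr <- Xr[ok, , drop = FALSE]
      N <- sum(ok)
    }
    X <- scale(Xr)
    attr(X, "scaled:center") <- NULL; attr(X, "scaled:scale") <- NULL
  }
  kspec <- kernel_spec(spec, X)
  kprior <- c(unclass(priors), list(iw_df = K + 1))
  nms <- param_names(spec)
  kcontrol <- list(fix_coef = isTRUE(control$fix_coef),
                   fix_resid = isTRUE(control$fix_resid),
                   fix_mu = isTRUE(control$fix_mu),
                   fix_between = isTRUE(control$fix_between),
                   store_imp = isTRUE(control$store_imputations),
                   dev_every = mcmc$dev_every)

  chains <- vector("list", mcmc$chains)
  states <- vector("list", mcmc$chains)
  rngs <- vector("list", mcmc$chains)
  n_done <- 0L
  run_chunk <- function(n_iter) {
    for (ch in seq_len(mcmc$chains)) {
      if (is.null(states[[ch]])) {
        set.seed(mcmc$seed + 7919L * ch)
        init <- merge_init(default_init(Y, spec,
                                        jitter = 0.05 * (ch - 1)),
                           control$init, Y)
      } else {
        assign(".Random.seed", rngs[[ch]], envir = globalenv())
        init <- states[[ch]]
        init$D <- states[[ch]]$D
      }
      res <- rdsem_gibbs_cpp(Y, kspec, kprior, init, n_iter, kcontrol)
      rngs[[ch]] <<- get(".Random.seed", envir = globalenv())
      states[[ch]] <<- res$state
      res$state <- NULL
      chains[[ch]] <<- if (is.null(chains[[ch]])) res else
        list(draws = rbind(chains[[ch]]$draws, res$draws),
             dev = c(chains[[ch]]$dev, res$dev),
             mu_draws = rbind(chains[[ch]]$mu_draws, res$mu_draws),
             slope_draws = rbind(chains[[ch]]$slope_draws, res$slope_draws),
             vlog_draws = if (is.null(res$vlog_draws)) NULL else
               rbind(chains[[ch]]$vlog_draws, res$vlog_draws),
             imp_draws = if (is.null(res$imp_draws)) NULL else
               rbind(chains[[ch]]$imp_draws, res$imp_draws),
             mh_accept = res$mh_accept, n_missing = res$n_missing)
    }
    n_done <<- n_done + n_iter
  }

  run_chunk(mcmc$min_iterations)
  psr_now <- function() {
    psr(lapply(chains, `[[`, "draws"), second_half = TRUE)
  }
  converged <- TRUE
  if (mcmc$chains >= 2) {
    while (any(psr_now() > mcmc$psr_threshold, na.rm = TRUE)) {
      if (n_done >= mcmc$max_iterations) { converged <- FALSE; break }
      run_chunk(min(mcmc$check_every, mcmc$max_iterations - n_done))
    }
  }
  psr_final <- if (mcmc$chains >= 2) psr_now() else
    rep(NA_real_, length(nms))
  names(psr_final) <- nms

  kept <- seq.int(floor(n_done / 2) + 1L, n_done)
  for (ch in seq_along(chains)) colnames(chains[[ch]]$draws) <- nms

  fit <- structure(list(
    spec = spec, priors = priors, mcmc = mcmc, persons = dat$persons,
    n_obs = dat$n_obs, Y = Y, X = X,
    chains = chains, kept = kept, iterations = n_done,
    converged = converged, psr = psr_final,
    mh_accept = mean(vapply(chains, function(c)
      ifelse(is.null(c$mh_accept), NA_real_, c$mh_accept), numeric(1)),
      na.rm = TRUE)), class = "rdsem_fit")
  fit$dic <- compute_dic(fit)
  fit$std <- standardized_draws(fit)
  fit
}

# stack kept draws of all chains for one component
kept_draws <- function(fit, what = "draws") {
  do.call(rbind, lapply(fit$chains, function(ch) {
    m <- ch[[what]]
    if (is.null(m)) return(NULL)
    m[fit$kept, , drop = FALSE]
  }))
}

#' Raw posterior draws
#'
#' Kept (second-half, all chains stacked) draws of the model parameters.
#'
#' @param fit an `rdsem_fit`.
#' @export
posterior_draws <- function(fit) kept_draws(fit, "draws")
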