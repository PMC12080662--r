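#' Population parameters of the generating model
#'
#' Describes the two-level data-generating process the analysis assumes: a
#' within-person VAR(1) on deviations from person-specific means, with a
#' contemporaneous (lag-0) association wired either as an undirected residual
#' covariance or as a directed path, person means drawn from a between-level
#' multivariate normal, and optional person-level variation in slopes and in
#' (log) residual variances.  The first variable plays the role of momentary
#' stress, the remaining variable(s) the symptom composite(s).
#'
#' Coefficients are interpreted on the standardized within-person scale: by
#' default residual variances are calibrated so every within-person
#' stationary variance equals 1, which makes the generating coefficients
#' equal to their standardized values.
#'
#' @param vars variable names; `vars[1]` is the stress-side variable.
#' @param means grand means, one per variable.
#' @param between_sd between-person SDs of the person means.
#' @param between_cor between-person correlation (scalar for 2 variables, or
#'   a full correlation matrix).
#' @param ar autoregressive coefficients (diagonal of the lag-1 matrix).
#' @param cross named cross-lagged coefficients, e.g.
#'   `c("lag1:mchr->stress" = 0.09)`; unnamed paths are 0.
#' @param lag0_mode `"covariance"`, `"x_to_y"` (stress to symptoms) or
#'   `"y_to_x"` (symptoms to stress).
#' @param lag0 value(s) of the directed lag-0 path(s) (recycled over edges),
#'   or the residual correlation when `lag0_mode = "covariance"`.
#' @param resid_var residual variances; `NULL` (default) calibrates them so
#'   all within-person stationary variances equal 1.
#' @param resid_logvar_sd per-variable SD of the person-level log residual
#'   variances (0 = homogeneous).
#' @param slope_sd named person-level SDs of random slopes, by path label.
#' @param moderation optional list `list(path =, gamma =)` giving moderator
#'   effects (named by covariate) on the random slope of `path`; moderators
#'   act on z-scored covariates.
#' @return an object of class `population_params`.
#' @export
population_params <- function(vars = c("stress", "mchr"),
                              means = c(2.0, 0.8),
                              between_sd = c(0.5, 0.4),
                              between_cor = 0.34,
                              ar = c(0.45, 0.60),
                              cross = NULL,
                              lag0_mode = c("y_to_x", "x_to_y", "covariance"),
                              lag0 = 0.28,
                              resid_var = NULL,
                              resid_logvar_sd = 0,
                              slope_sd = NULL,
                              moderation = NULL) {
  lag0_mode <- match.arg(lag0_mode)
  K <- length(vars)
  stopifnot(K >= 2, length(means) == K, length(between_sd) == K,
            length(ar) == K)
  if (lag0_mode == "covariance" && K != 2)
    stop("covariance lag-0 mode is defined for exactly 2 variables",
         call. = FALSE)
  B1 <- diag(ar, K)
  dimnames(B1) <- list(vars, vars)
  if (!is.null(cross)) {
    for (lb in names(cross)) {
      m <- regmatches(lb, regexec("^lag1:(.+)->(.+)$", lb))[[1]]
      if (length(m) != 3 || !(m[2] %in% vars) || !(m[3] %in% vars))
        stop("bad cross-lag label: ", lb, call. = FALSE)
      B1[m[3], m[2]] <- cross[[lb]]
    }
  }
  B0 <- matrix(0, K, K, dimnames = list(vars, vars))
  if (lag0_mode == "x_to_y") B0[2:K, 1] <- rep_len(lag0, K - 1)
  if (lag0_mode == "y_to_x") B0[1, 2:K] <- rep_len(lag0, K - 1)
  if (companion_radius(B1, B0) >= 1)
    stop("invariant violated: nonstationary dynamics (companion spectral ",
         "radius >= 1)", call. = FALSE)
  if (is.matrix(between_cor)) R <- between_cor
  else { R <- diag(K); R[upper.tri(R)] <- R[lower.tri(R)] <- between_cor }
  SigB <- diag(between_sd, K) %*% R %*% diag(between_sd, K)
  dimnames(SigB) <- list(vars, vars)
  if (any(between_sd > 0)) { # all-zero = degenerate hierarchy, allowed
    ev <- eigen(SigB, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0))
      stop("invariant violated: between-person covariance not positive ",
           "definite", call. = FALSE)
  }
  pop <- structure(list(vars = vars, means = stats::setNames(means, vars),
                        B1 = B1, B0 = B0, lag0_mode = lag0_mode,
                        lag0 = lag0, SigB = SigB,
                        resid_logvar_sd = rep_len(resid_logvar_sd, K),
                        slope_sd = slope_sd, moderation = moderation),
                   class = "population_params")
  pop$resid_var <- if (is.null(resid_var)) calibrate_resid_var(pop)
                   else stats::setNames(rep_len(resid_var, K), vars)
  if (any(pop$resid_var <= 0))
    stop("invariant violated: residual variances must be positive ",
         "(requested coefficients admit no unit-variance calibration)",
         call. = FALSE)
  pop$Psi <- psi_matrix(pop)
  if (!is.null(slope_sd)) {
    tab <- make_path_table(vars, lag0_mode)
    bad <- setdiff(names(slope_sd), tab$label)
    if (length(bad)) stop("unknown random path label(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  pop
}

# residual covariance implied by the population parameters
psi_matrix <- function(pop) {
  K <- length(pop$vars)
  if (pop$lag0_mode == "covariance") {
    s <- sqrt(pop$resid_var)
    R <- matrix(c(1, pop$lag0, pop$lag0, 1), 2, 2)
    Psi <- diag(s) %*% R %*% diag(s)
  } else {
    Psi <- diag(pop$resid_var, K)
  }
  dimnames(Psi) <- list(pop$vars, pop$vars)
  Psi
}

# Solve for residual variances giving unit within-person stationary
# variances.  Directed modes: diag(V) is linear in the residual variances, so
# one K x K solve; covariance mode: fixed-point iteration on the scales.
calibrate_resid_var <- function(pop) {
  K <- length(pop$vars)
  if (pop$lag0_mode != "covariance") {
    FF <- vapply(seq_len(K), function(k) {
      Psi <- matrix(0, K, K); Psi[k, k] <- 1
      diag(rdsem_stationary_cov(pop$B1, pop$B0, Psi))
    }, numeric(K))
    s <- solve(FF, rep(1, K))
    return(stats::setNames(s, pop$vars))
  }
  R <- matrix(c(1, pop$lag0, pop$lag0, 1), 2, 2)
  s <- rep(0.5, 2)
  for (i in 1:500) {
    Psi <- diag(sqrt(s)) %*% R %*% diag(sqrt(s))
    v <- diag(rdsem_stationary_cov(pop$B1, pop$B0 * 0, Psi))
    s_new <- s / v
    if (max(abs(s_new - s)) < 1e-12) { s <- s_new; break }
    s <- s_new
  }
  stats::setNames(s, pop$vars)
}

#' Draw person-level parameters and covariates
#'
#' Samples person means from the between-level multivariate normal, random
#' slopes (with moderator effects on z-scored covariates plus residual
#' person noise), person log residual variances, and person covariates:
#' age uniform on 11--36 years, sex Bernoulli(0.506), interview severity
#' scores as bounded integer counts, and a person adherence probability from
#' a beta distribution with the given moments.
#'
#' @param pop a [population_params()] object.
#' @param n_persons number of persons (at least 2).
#' @param seed integer seed.
#' @param adherence_mean,adherence_sd moments of the per-person adherence
#'   distribution; `adherence_sd = 0` gives every person the same rate.
#' @return list with `params` (person means, slopes, log residual variances)
#'   and `covariates` (age, sex, aps_severity, bs_severity, adherence).
#' @export
draw_persons <- function(pop, n_persons, seed = NULL,
                         adherence_mean = 0.6924, adherence_sd = 0.2465) {
  stopifnot(inherits(pop, "population_params"), n_persons >= 2)
  K <- length(pop$vars)
  with_seed(seed, {
    ids <- sprintf("p%03d", seq_len(n_persons))
    age <- stats::runif(n_persons, 11, 36)
    sex <- stats::rbinom(n_persons, 1, 0.506)
    aps <- stats::rbinom(n_persons, 5, 0.4)
    bs <- stats::rbinom(n_persons, 14, 0.35)
    adh <- if (adherence_sd <= 0) rep(adherence_mean, n_persons) else {
      m <- adherence_mean; v <- adherence_sd^2
      ab <- m * (1 - m) / v - 1
      pmin(pmax(stats::rbeta(n_persons, m * ab, (1 - m) * ab), 0.05), 1)
    }
    covariates <- data.frame(person_id = ids, age = age, sex = sex,
                             aps_severity = aps, bs_severity = bs,
                             adherence = adh)
    L <- if (all(pop$SigB == 0)) matrix(0, K, K) else chol(pop$SigB)
    Mu <- matrix(stats::rnorm(n_persons * K), n_persons, K) %*% L
    Mu <- sweep(Mu, 2, pop$means, "+")
    colnames(Mu) <- pop$vars
    params <- data.frame(person_id = ids)
    for (k in seq_len(K))
      params[[paste0("mu_", pop$vars[k])]] <- Mu[, k]
    if (!is.null(pop$slope_sd)) {
      Xz <- scale(as.matrix(covariates[, c("age", "sex", "aps_severity",
                                           "bs_severity")]))
      for (lb in names(pop$slope_sd)) {
        base <- path_value(pop, lb)
        slope <- rep(base, n_persons)
        if (!is.null(pop$moderation) && identical(pop$moderation$path, lb)) {
          g <- pop$moderation$gamma
          for (cv in names(g)) slope <- slope + g[[cv]] * Xz[, cv]
        }
        slope <- slope + stats::rnorm(n_persons, 0, pop$slope_sd[[lb]])
        params[[paste0("slope_", lb)]] <- slope
      }
    }
    for (k in seq_len(K)) {
      sdk <- pop$resid_logvar_sd[k]
      params[[paste0("logvar_", pop$vars[k])]] <-
        stats::rnorm(n_persons, log(pop$resid_var[k]), sdk)
    }
    list(params = params, covariates = covariates)
  })
}

# population value of a labelled path
path_value <- function(pop, label) {
  m <- regmatches(label, regexec("^(lag[01]):(.+)->(.+)$", label))[[1]]
  if (length(m) != 4) stop("bad path label: ", label, call. = FALSE)
  if (m[2] == "lag1") pop$B1[m[4], m[3]] else pop$B0[m[4], m[3]]
}

# person-specific dynamic matrices (slopes override population values)
person_mats <- function(pop, params_row) {
  B1 <- pop$B1; B0 <- pop$B0
  if (!is.null(pop$slope_sd)) {
    for (lb in names(pop$slope_sd)) {
      m <- regmatches(lb, regexec("^(lag[01]):(.+)->(.+)$", lb))[[1]]
      v <- params_row[[paste0("slope_", lb)]]
      if (m[2] == "lag1") B1[m[4], m[3]] <- v else B0[m[4], m[3]] <- v
    }
  }
  sig2 <- exp(unlist(params_row[paste0("logvar_", pop$vars)]))
  Psi <- if (pop$lag0_mode == "covariance") pop$Psi else
    diag(as.numeric(sig2), length(pop$vars))
  list(B1 = B1, B0 = B0, Psi = Psi)
}

#' Simulate the latent within-person series on the grid
#'
#' Generates the bivariate (or trivariate) series slot by slot from the
#' VAR(1) with the chosen lag-0 wiring: with directed lag-0 paths the
#' predictor variable's innovation enters the outcome within the same slot
#' (e.g. for symptom-to-stress wiring, the symptom value is generated first
#' and the same-slot stress value depends on it).  The initial state is drawn
#' from the exact stationary distribution.  Person means are added to the
#' deviations, giving the observation-scale series.
#'
#' @param pop a [population_params()] object.
#' @param params_row one row of `draw_persons()$params` (or `NULL` to use
#'   the population values with zero person effects).
#' @param grid a [grid_spec()].
#' @param seed integer seed.
#' @return a `n_slots` x K matrix of observation-scale values.
#' @export
simulate_within <- function(pop, params_row = NULL, grid = grid_spec(),
                            seed = NULL) {
  K <- length(pop$vars)
  if (is.null(params_row)) {
    params_row <- as.data.frame(as.list(c(
      stats::setNames(pop$means, paste0("mu_", pop$vars)),
      stats::setNames(log(pop$resid_var), paste0("logvar_", pop$vars)))))
  }
  pm <- person_mats(pop, params_row)
  if (companion_radius(pm$B1, pm$B0) >= 1)
    stop("nonstationary person parameters", call. = FALSE)
  M0 <- diag(K) - pm$B0
  V <- rdsem_stationary_cov(pm$B1, pm$B0, pm$Psi)
  Lv <- chol(V)
  Le <- chol(pm$Psi)
  T_ <- grid$n_slots
  with_seed(seed, {
    D <- matrix(0, T_, K)
    D[1, ] <- drop(crossprod(Lv, stats::rnorm(K)))
    E <- matrix(stats::rnorm((T_ - 1) * K), T_ - 1, K) %*% Le
    M0i <- solve(M0)
    A <- M0i %*% pm$B1
    for (t in 2:T_)
      D[t, ] <- A %*% D[t - 1, ] + M0i %*% E[t - 1, ]
    mu <- unlist(params_row[paste0("mu_", pop$vars)])
    Y <- sweep(D, 2, mu, "+")
    colnames(Y) <- pop$vars
    Y
  })
}

#' Measurement model for the 21 momentary symptom items
#'
#' Items are continuous linear-Gaussian functions of the latent momentary
#' symptom level: `item_j = intercept_j + loading_j * latent + noise`,
#' optionally rounded and clamped to the rating scale.  The analysis only
#' uses composite means, so composite-level fidelity (the item mean tracking
#' the latent level) is the contract, not item psychometrics.
#'
#' @param loadings,intercepts numeric length 21.
#' @param noise_sd item noise SD.
#' @param round round and clamp ratings to the integer scale?
#' @param rating_min,rating_max bounds of the rating scale.
#' @export
item_model <- function(loadings = rep(1, 21), intercepts = rep(0, 21),
                       noise_sd = 0.5, round = FALSE,
                       rating_min = 0, rating_max = 6) {
  stopifnot(length(loadings) == 21, length(intercepts) == 21, noise_sd >= 0)
  structure(list(loadings = loadings, intercepts = intercepts,
                 noise_sd = noise_sd, round = round,
                 rating_min = rating_min, rating_max = rating_max),
            class = "item_model")
}

#' Generate item ratings from latent symptom levels
#'
#' @param latent matrix (observations x latent variables) of latent levels.
#' @param model an [item_model()].
#' @param assignment integer vector of length 21 mapping each item to a
#'   column of `latent` (default: all items load on column 1).
#' @param seed integer seed.
#' @return an observations x 21 matrix of item ratings.
#' @export
simulate_items <- function(latent, model = item_model(),
                           assignment = rep(1L, 21), seed = NULL) {
  latent <- as.matrix(latent)
  stopifnot(length(assignment) == 21, all(assignment >= 1),
            all(assignment <= ncol(latent)))
  n <- nrow(latent)
  with_seed(seed, {
    out <- matrix(0, n, 21)
    for (j in 1:21) {
      out[, j] <- model$intercepts[j] +
        model$loadings[j] * latent[, assignment[j]] +
        if (model$noise_sd > 0) stats::rnorm(n, 0, model$noise_sd) else 0
    }
    if (model$round)
      out <- pmin(pmax(round(out), model$rating_min), model$rating_max)
    colnames(out) <- sprintf("item_%02d", 1:21)
    out
  })
}

# item -> latent column assignment for a given set of symptom variables
item_assignment <- function(vars, catalog) {
  symp <- vars[-1]
  if (length(symp) == 1) return(rep(1L, 21))
  if (setequal(symp, c("aps", "bs"))) {
    key <- ifelse(catalog$instrument == "SIPS", "aps", "bs")
  } else if (setequal(symp, c("perc", "nonp"))) {
    key <- ifelse(catalog$partition == "perceptive", "perc", "nonp")
  } else {
    stop("cannot map items to symptom variables: ",
         paste(symp, collapse = ", "), call. = FALSE)
  }
  match(key, symp)
}

#' Simulate a full EMA dataset
#'
#' End-to-end generator emulating the study design: per person a prompt
#' schedule from the design (with postponement), adherence thinning, a latent
#' series on the hourly grid, item ratings at answered prompts, and a
#' person-level covariate table.  Answered prompts take the latent value of
#' the grid slot they fall into.
#'
#' @param pop a [population_params()] object.
#' @param n_persons number of persons.
#' @param design an [ema_design()].
#' @param grid a [grid_spec()]; defaults to hourly slots over the design days.
#' @param adherence_mean,adherence_sd per-person adherence distribution
#'   (beta); `adherence_sd = 0` fixes the rate for everyone.
#' @param postpone_prob probability a prompt is postponed once.
#' @param model an [item_model()].
#' @param catalog item catalog, see [default_item_catalog()].
#' @param seed integer seed governing the whole dataset.
#' @return an object of class `ema_dataset`: list with `long` (one row per
#'   answered prompt: `person_id`, `day`, `time_minutes`, `stress`,
#'   `item_01`..`item_21`), `covariates`, `truth` (generating person
#'   parameters), `design`, `grid`, `catalog`.
#' @export
simulate_ema_dataset <- function(pop, n_persons = 79, design = ema_design(),
                                 grid = grid_spec(design$n_days),
                                 adherence_mean = 0.6924,
                                 adherence_sd = 0.2465,
                                 postpone_prob = 0.1,
                                 model = item_model(),
                                 catalog = default_item_catalog(),
                                 seed = NULL) {
  check_catalog(catalog)
  with_seed(seed, {
    pers <- draw_persons(pop, n_persons, seed = NULL,
                         adherence_mean = adherence_mean,
                         adherence_sd = adherence_sd)
    assign_ <- item_assignment(pop$vars, catalog)
    symp <- pop$vars[-1]
    long <- vector("list", n_persons)
    latents <- vector("list", n_persons)
    for (i in seq_len(n_persons)) {
      prow <- pers$params[i, , drop = FALSE]
      sch <- build_schedule(design, seed = NULL)
      sch <- apply_postponement(sch, design, postpone_prob, seed = NULL)
      sch <- apply_adherence(sch, pers$covariates$adherence[i], seed = NULL)
      lat <- simulate_within(pop, prow, grid, seed = NULL)
      latents[[i]] <- lat
      ans <- sch[sch$answered, , drop = FALSE]
      slot <- floor((ans$day * 1440 + ans$time) / grid$slot_width)
      slot <- pmin(slot, grid$n_slots - 1L) # postponement past the last slot
      items <- simulate_items(lat[slot + 1L, symp, drop = FALSE], model,
                              assign_, seed = NULL)
      df <- data.frame(person_id = pers$params$person_id[i],
                       day = ans$day, time_minutes = ans$time,
                       stress = lat[slot + 1L, 1])
      long[[i]] <- cbind(df, as.data.frame(items))
    }
    structure(list(long = do.call(rbind, long),
                   covariates = pers$covariates,
                   truth = list(pop = pop, persons = pers$params,
                                latent = latents),
                   design = design, grid = grid, catalog = catalog),
              class = "ema_dataset")
  })
}

#' Align an EMA dataset to the analysis grid with composite scores
#'
#' Computes the momentary composites for every answered prompt and aligns
#' them (plus stress) onto the uniform grid per person, inserting missing
#' values in empty slots.
#'
#' @param long long-format data as in `simulate_ema_dataset()$long`.
#' @param grid a [grid_spec()].
#' @param catalog item catalog.
#' @return data.frame with columns `person_id`, `slot`, `stress`, `mchr`,
#'   `aps`, `bs`, `perc`, `nonp`; attribute `"grid"` carries the grid and
#'   `"n_collisions"` the total number of dropped same-slot observations.
#' @export
grid_ema_dataset <- function(long, grid = grid_spec(),
                             catalog = default_item_catalog()) {
  item_cols <- sprintf("item_%02d", 1:21)
  stopifnot(all(c("person_id", "day", "time_minutes", "stress")
                %in% names(long)), all(item_cols %in% names(long)))
  comps <- ema_composites(as.matrix(long[, item_cols]), catalog)
  base <- data.frame(person_id = long$person_id, day = long$day,
                     time = long$time_minutes, stress = long$stress)
  base <- cbind(base, comps)
  out <- list(); n_coll <- 0L
  for (pid in unique(base$person_id)) {
    sub <- base[base$person_id == pid, setdiff(names(base), "person_id")]
    g <- withCallingHandlers(
      align_to_grid(sub, grid),
      warning = function(w) invokeRestart("muffleWarning"))
    n_coll <- n_coll + attr(g, "n_collisions")
    out[[length(out) + 1L]] <- cbind(person_id = pid, g)
  }
  res <- do.call(rbind, out)
  if (n_coll > 0)
    warning(n_coll, " observation(s) dropped in slot collisions ",
            "(earliest kept)", call. = FALSE)
  attr(res, "grid") <- grid
  attr(res, "n_collisions") <- n_coll
  res
}

# full-precision CSV writer so that write -> read round-trips exactly
write_csv17 <- function(df, path) {
  fmt <- vapply(df, function(col) {
    if (is.double(col)) formatC(col, digits = 17, format = "g")
    else as.character(col)
  }, character(nrow(df)))
  fmt[is.na(as.matrix(df))] <- ""
  lines <- c(paste(names(df), collapse = ","),
             apply(matrix(fmt, nrow = nrow(df)), 1, paste, collapse = ","))
  writeLines(lines, path)
}

#' Write / read an EMA dataset as delimited text
#'
#' `write_ema_dataset()` stores the long table and the covariate table as
#' CSV (full double precision, so the round trip is lossless) plus a JSON
#' sidecar with the generating person parameters; `read_ema_dataset()`
#' restores them.
#'
#' @param ds an `ema_dataset`.
#' @param dir output directory (created if needed).
#' @export
write_ema_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_csv17(ds$long, file.path(dir, "long.csv"))
  write_csv17(ds$covariates, file.path(dir, "covariates.csv"))
  truth <- list(persons = ds$truth$persons,
                design = unclass(ds$design), grid = unclass(ds$grid))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_ema_dataset
#' @export
read_ema_dataset <- function(dir) {
  long <- utils::read.csv(file.path(dir, "long.csv"))
  covariates <- utils::read.csv(file.path(dir, "covariates.csv"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(long = long, covariates = covariates, truth = truth)
}
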