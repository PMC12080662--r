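test_that("degenerate hierarchy makes every person identical", {
  pop <- population_params(between_sd = c(0, 0), resid_logvar_sd = 0)
  p <- draw_persons(pop, 5, seed = 1)
  expect_true(all(p$params$mu_stress == pop$means["stress"]))
  expect_true(all(p$params$mu_mchr == pop$means["mchr"]))
  expect_true(all(p$params$logvar_stress == log(pop$resid_var["stress"])))
})

test_that("drawn intercepts recover the between-person correlation", {
  pop <- population_params(between_cor = 0.34)
  p <- draw_persons(pop, 5000, seed = 2)
  r <- cor(p$params$mu_stress, p$params$mu_mchr)
  se <- (1 - 0.34^2) / sqrt(5000) # delta-method SE of a correlation
  expect_lt(abs(r - 0.34), 3 * se)
})

test_that("moderated slopes regress on the covariates as specified", {
  pop <- population_params(
    slope_sd = c("lag0:mchr->stress" = 0.05),
    moderation = list(path = "lag0:mchr->stress",
                      gamma = c(age = 0.02)))
  p <- draw_persons(pop, 4000, seed = 3)
  z_age <- scale(cbind(p$covariates$age, p$covariates$sex,
                       p$covariates$aps_severity,
                       p$covariates$bs_severity))[, 1]
  fitlm <- stats::lm(p$params[["slope_lag0:mchr->stress"]] ~ z_age)
  est <- coef(fitlm)[2]
  se <- summary(fitlm)$coefficients[2, 2]
  expect_lt(abs(est - 0.02), 3 * se)
})

test_that("the within-person process has the implied moments", {
  big <- grid_spec(420) # 10080 hourly slots
  # white noise: no dynamic paths at all
  wn <- population_params(ar = c(0, 0), lag0 = 0, resid_var = c(1, 1))
  y <- simulate_within(wn, NULL, big, seed = 4)
  r1 <- cor(y[-1, 1], y[-nrow(y), 1])
  expect_lt(abs(r1), 3 / sqrt(nrow(y)))
  # AR(1) phi = .5, sigma2 = .75 -> stationary variance 1
  ar <- population_params(ar = c(0.5, 0.5), lag0 = 0,
                          resid_var = c(0.75, 0.75))
  y2 <- simulate_within(ar, NULL, big, seed = 5)
  expect_lt(abs(stats::var(y2[, 1]) - 1), 0.08)
  # pure lag-0 path c = .5, unit residuals: corr = .5/sqrt(1.25)
  l0 <- population_params(ar = c(0, 0), lag0 = 0.5, resid_var = c(1, 1))
  y3 <- simulate_within(l0, NULL, big, seed = 6)
  expect_lt(abs(cor(y3[, 1], y3[, 2]) - 0.5 / sqrt(1.25)), 0.03)
  # zero cross and lag-0 paths: series independent at all small lags
  ind <- population_params(lag0 = 0)
  y4 <- simulate_within(ind, NULL, big, seed = 7)
  for (h in -1:1) {
    n <- nrow(y4)
    cc <- cor(y4[(1 + max(0, h)):(n + min(0, h)), 1],
              y4[(1 - min(0, h)):(n - max(0, h)), 2])
    expect_lt(abs(cc), 4 / sqrt(n))
  }
})

test_that("covariance and directed lag-0 wirings can be moment-matched", {
  # directed m->s with c: residual cov of (s, m) | past is c * sig2_m;
  # an undirected-covariance process with that residual correlation has
  # the same first and second moments
  big <- grid_spec(420)
  popC <- population_params(lag0_mode = "y_to_x", lag0 = 0.28)
  c_ <- 0.28
  s2 <- popC$resid_var
  psi <- c_ * s2["mchr"]                   # reduced-form residual covariance
  var_s_cond <- c_^2 * s2["mchr"] + s2["stress"]
  rho <- psi / sqrt(var_s_cond * s2["mchr"])
  # the reduced-form conditional mean of the directed process carries an
  # implied cross-lag c * ar_m
  popA <- population_params(lag0_mode = "covariance", lag0 = unname(rho),
                            cross = c("lag1:mchr->stress" =
                                        c_ * popC$B1["mchr", "mchr"]),
                            resid_var = unname(c(var_s_cond, s2["mchr"])))
  yC <- simulate_within(popC, NULL, big, seed = 8)
  yA <- simulate_within(popA, NULL, big, seed = 9)
  n <- nrow(yC)
  tol <- 4 / sqrt(n)
  expect_lt(abs(cor(yC[, 1], yC[, 2]) - cor(yA[, 1], yA[, 2])), 2 * tol)
  expect_lt(abs(cor(yC[-1, 1], yC[-n, 2]) - cor(yA[-1, 1], yA[-n, 2])),
            2 * tol)
  expect_lt(abs(stats::var(yC[, 1]) - stats::var(yA[, 1])), 0.1)
})

test_that("unit-variance calibration solves for the residual variances", {
  pop <- population_params()
  V <- stat_cov_kron(pop$B1, pop$B0, pop$Psi)
  expect_equal(diag(V), c(1, 1), tolerance = 1e-8)
  popA <- population_params(lag0_mode = "covariance", lag0 = 0.25)
  VA <- stat_cov_kron(popA$B1, popA$B0, popA$Psi)
  expect_equal(diag(VA), c(1, 1), tolerance = 1e-6)
  expect_error(population_params(ar = c(1.2, 0.5)), "nonstationary")
})

test_that("item generation tracks the latent level", {
  m0 <- item_model(loadings = rep(0, 21), intercepts = seq(0.1, 2.1, 0.1),
                   noise_sd = 0)
  it <- simulate_items(matrix(5, 1, 1), m0)
  expect_equal(as.vector(it), seq(0.1, 2.1, 0.1))
  it2 <- simulate_items(matrix(2, 1, 1), item_model(noise_sd = 0))
  expect_equal(mean(it2), 2)
  set.seed(10)
  lat <- matrix(rnorm(10000), ncol = 1)
  it3 <- simulate_items(lat, item_model(noise_sd = 0.2), seed = 11)
  expect_gt(cor(rowMeans(it3), lat[, 1]), 0.9)
})

test_that("assembled datasets have the study shape and adherence", {
  res <- make_test_data(20, 7, adherence = 0.69, seed = 12,
                        noise_sd = 0.5)
  g <- res$gridded
  expect_equal(nrow(g), 20 * 168)
  n_ans <- nrow(res$ds$long)
  se <- sqrt(0.69 * 0.31 / (20 * 56))
  expect_lt(abs(n_ans / (20 * 56) - 0.69), 3 * se)
  # full adherence: every prompt observed up to slot collisions
  res2 <- make_test_data(5, 7, adherence = 1, seed = 13)
  g2 <- res2$gridded
  for (pid in unique(g2$person_id)) {
    obs <- sum(!is.na(g2$stress[g2$person_id == pid]))
    expect_lte(obs, 56)
  }
  expect_equal(sum(!is.na(g2$stress)) + attr(g2, "n_collisions"), 5 * 56)
})

test_that("write -> read round trip preserves the dataset", {
  pop <- population_params()
  ds <- simulate_ema_dataset(pop, n_persons = 4,
                             design = ema_design(n_days = 2),
                             grid = grid_spec(2), seed = 14)
  dir <- tempfile("ema")
  write_ema_dataset(ds, dir)
  back <- read_ema_dataset(dir)
  expect_equal(back$long, ds$long, tolerance = 1e-15,
               ignore_attr = TRUE)
  expect_equal(back$covariates, ds$covariates, tolerance = 1e-15,
               ignore_attr = TRUE)
})
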