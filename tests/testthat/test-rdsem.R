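test_that("model specs wire the expected path structure", {
  a <- rdsem_model("A")
  expect_equal(sum(a$paths$type == "lag1"), 4)
  expect_equal(sum(a$paths$type == "lag0"), 0)
  expect_equal(a$lag0_mode, "covariance")
  cc <- rdsem_model("C")
  expect_true("lag0:mchr->stress" %in% cc$paths$label)
  expect_false("lag0:stress->mchr" %in% cc$paths$label)
  b <- rdsem_model("B")
  expect_true("lag0:stress->mchr" %in% b$paths$label)
  tri <- rdsem_spec(c("stress", "aps", "bs"), "y_to_x")
  expect_equal(sum(tri$paths$type == "lag1"), 9) # 3 AR + 6 cross-lags
  expect_equal(tri$paths$label[tri$paths$type == "lag0"],
               c("lag0:aps->stress", "lag0:bs->stress"))
  expect_error(rdsem_spec(c("s", "a", "b"), "covariance"), "2 variables")
  expect_error(rdsem_model("A", random_paths = "lag1:mchr->stress"),
               "directed")
})

test_that("data assembly excludes persons without dynamic information", {
  g <- make_test_data(4, 2, adherence = 0.9, seed = 1)$gridded
  # strip one person down to a single observation
  pid <- unique(g$person_id)[1]
  idx <- which(g$person_id == pid & !is.na(g$stress))
  g[idx[-1], c("stress", "mchr", "aps", "bs", "perc", "nonp")] <- NA
  expect_warning(dat <- build_rdsem_data(g, rdsem_model("C")), "fewer than 2")
  expect_equal(dim(dat$Y)[3], 3)
  expect_error(build_rdsem_data(g, rdsem_spec(c("stress", "nope"))),
               "not in data")
  expect_error(build_rdsem_data(g[0, ], rdsem_model("C")), "empty")
})

test_that("PSR matches the between/within variance-ratio formula", {
  set.seed(2)
  same <- matrix(rnorm(1000), 500, 2)
  expect_equal(psr(list(same, same)), c(1, 1), tolerance = 5e-3)
  apart <- list(matrix(rnorm(1000, 0), ncol = 1),
                matrix(rnorm(1000, 5), ncol = 1))
  expect_gt(psr(apart), 2)
  mixed <- list(matrix(rnorm(2000), ncol = 2),
                matrix(rnorm(2000), ncol = 2))
  expect_true(all(psr(mixed) >= 0.995 & psr(mixed) < 1.05))
  expect_error(psr(list(same)), "2 chains")
  # hand check on summary stats (no halving)
  c1 <- matrix(c(1, 2, 3, 4), ncol = 1); c2 <- matrix(c(2, 3, 4, 7), ncol = 1)
  n <- 4
  W <- mean(c(var(c1), var(c2))); B <- n * var(c(mean(c1), mean(c2)))
  expect_equal(psr(list(c1, c2), second_half = FALSE),
               sqrt(((n - 1) / n * W + B / n) / W))
})

test_that("posterior sign probabilities follow the counting rule", {
  expect_equal(emadsem:::sign_p(c(1, 2, 3)), 0)
  expect_equal(emadsem:::sign_p(c(1, 2, 3, -1)), 0.25)
  z <- rnorm(5000)
  expect_equal(emadsem:::sign_p(c(z, -z)), 0.5, tolerance = 1e-6)
})

test_that("the Wald test matches the chi-square reference", {
  set.seed(3)
  x <- as.vector(scale(rnorm(5000))) + 2 # mean 2, sd 1 exactly
  w <- wald_joint_test(x)
  expect_equal(w$W, 4, tolerance = 1e-9)
  expect_equal(w$df, 1)
  expect_equal(w$p, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-9)
  expect_error(wald_joint_test(cbind(x, x)), "collinearity")
})

test_that("the Wald test is calibrated on synthetic posteriors", {
  # sampling model: ghat ~ N(0, S/n); posterior ~ N(ghat, S/n)
  set.seed(4)
  q <- 4; n <- 200
  S <- diag(q) + 0.3
  rej <- replicate(400, {
    ghat <- MASS::mvrnorm(1, rep(0, q), S / n)
    draws <- MASS::mvrnorm(500, ghat, S / n)
    wald_joint_test(draws)$p < 0.05
  })
  expect_gt(mean(rej), 0.05 - 1.96 * sqrt(0.05 * 0.95 / 400))
  expect_lt(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("fits are bit-reproducible given the seed", {
  g <- make_test_data(6, 2, adherence = 0.9, seed = 5)$gridded
  f1 <- rdsem_fit(g, rdsem_model("C"), mcmc = fast_mcmc(150, seed = 9))
  f2 <- rdsem_fit(g, rdsem_model("C"), mcmc = fast_mcmc(150, seed = 9))
  expect_identical(f1$chains[[1]]$draws, f2$chains[[1]]$draws)
  expect_identical(f1$chains[[2]]$draws, f2$chains[[2]]$draws)
  expect_identical(f1$dic, f2$dic)
  f3 <- rdsem_fit(g, rdsem_model("C"), mcmc = fast_mcmc(150, seed = 10))
  expect_false(identical(f1$chains[[1]]$draws, f3$chains[[1]]$draws))
})

test_that("standardization matches an independent implied-moments oracle", {
  g <- make_test_data(8, 3, adherence = 0.9, seed = 6)$gridded
  fit <- rdsem_fit(g, rdsem_model("C"), mcmc = fast_mcmc(300, seed = 11))
  draws <- posterior_draws(fit)
  std <- fit$std
  # autoregressions standardize to themselves (same SD in and out)
  expect_equal(std[, "std:lag1:stress->stress"],
               unname(draws[, "lag1:stress->stress"]), tolerance = 1e-12)
  # cross-check a handful of draws against the kron-solve oracle
  spec <- fit$spec
  for (d in c(1, 50, 200)) {
    B1 <- matrix(draws[d, 1:4], 2, 2)
    B0 <- matrix(0, 2, 2); B0[1, 2] <- draws[d, "lag0:mchr->stress"]
    Psi <- diag(draws[d, c("resvar:stress", "resvar:mchr")], 2)
    V <- stat_cov_kron(B1, B0, Psi)
    sds <- sqrt(diag(V))
    expect_equal(std[d, "std:lag0:mchr->stress"],
                 draws[d, "lag0:mchr->stress"] * sds[2] / sds[1],
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(std[d, "std:lag1:mchr->mchr"],
                 unname(draws[d, "lag1:mchr->mchr"]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # between-level covariance reported as a correlation
  bc <- draws[, "b_cov:mchr.stress"] /
    sqrt(draws[, "b_var:mchr"] * draws[, "b_var:stress"])
  expect_equal(unname(std[, "std:between_cor:mchr.stress"]), unname(bc),
               tolerance = 1e-12)
  expect_true(all(abs(std[, "std:between_cor:mchr.stress"]) <= 1))
})

test_that("a degenerate posterior has zero effective parameters", {
  pop <- population_params()
  lat <- simulate_within(pop, NULL, grid_spec(2), seed = 7)
  Y <- array(lat, c(48, 2, 1), dimnames = list(NULL, c("stress", "mchr"),
                                               "p1"))
  ctrl <- rdsem_control(fix_coef = TRUE, fix_resid = TRUE, fix_mu = TRUE,
                        fix_between = TRUE,
                        init = list(Bmat = pop$B1, cvec = pop$B0[1, 2],
                                    sigma2 = unname(pop$resid_var),
                                    Mu = matrix(pop$means, 1, 2),
                                    nu = unname(pop$means), SigB = diag(2)))
  fit <- rdsem_fit(list(Y = Y, persons = "p1", n_obs = 48), rdsem_model("C"),
                   mcmc = fast_mcmc(100, seed = 12, dev_every = 1),
                   control = ctrl)
  d <- dic(fit)
  expect_equal(unname(d["pD"]), 0, tolerance = 1e-8)
  expect_equal(unname(d["DIC"]), unname(d["Dbar"]), tolerance = 1e-8)
})

test_that("moderation fits exclude persons with missing moderators", {
  res <- make_test_data(8, 3, adherence = 0.9, seed = 8)
  cov <- res$ds$covariates
  cov$age[2] <- NA
  expect_message(
    fit <- fit_moderation(res$gridded, cov, moderators = c("age", "sex"),
                          mcmc = fast_mcmc(150, seed = 13))$fit,
    "excluded")
  expect_equal(dim(fit$Y)[3], 7)
})
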