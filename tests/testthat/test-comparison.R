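test_that("the comparison record is a pure function of the fits", {
  g <- make_test_data(8, 3, adherence = 0.9, seed = 1)$gridded
  cmp <- compare_lag0_models(g, mcmc = fast_mcmc(200, seed = 2))
  expect_setequal(cmp$table$model, c("A", "B", "C"))
  expect_true(all(is.finite(cmp$table$DIC)))
  expect_identical(selection_record(cmp), cmp$selection)
  expect_identical(selection_record(cmp), selection_record(cmp))
  expect_true(cmp$selection$recommended %in% c("A", "B", "C"))
})

test_that("null data leave all three lag-0 estimates covering zero", {
  g <- make_test_data(15, 4, adherence = 0.9, seed = 3,
                      pop = population_params(lag0 = 0))$gridded
  cmp <- compare_lag0_models(g, mcmc = fast_mcmc(500, seed = 4))
  for (m in c("A", "B", "C")) {
    s <- summary(cmp$fits[[m]])
    i <- grep("^std:lag0:", s$parameter)
    expect_lte(s$lci[i], 0)
    expect_gte(s$uci[i], 0)
  }
})

test_that("restricting the symptom-to-stress lag-0 path shifts its load onto the symptom cross-lag", {
  # under a symptom_t -> stress_t truth, the model without that path (B)
  # absorbs the association into the mCHR[t-1] -> stress[t] cross-lag
  g <- make_test_data(30, 7, adherence = 0.8, seed = 5)$gridded
  mc <- fast_mcmc(800, seed = 6)
  fB <- rdsem_fit(g, rdsem_model("B"), mcmc = mc)
  fC <- rdsem_fit(g, rdsem_model("C"), mcmc = mc)
  sB <- summary(fB); sC <- summary(fC)
  i <- match("std:lag1:mchr->stress", sB$parameter)
  expect_gt(sB$est[i], 0)
  expect_gt(sB$lci[i], 0) # spurious positive cross-lag, CI excludes 0
  expect_lt(abs(sC$est[match("std:lag1:mchr->stress", sC$parameter)]),
            sB$est[i]) # absent (smaller) under the generating wiring
})

test_that("random-effects augmentation leaves fixed paths stable on homogeneous data", {
  g <- make_test_data(20, 4, adherence = 0.9, seed = 7)$gridded
  base <- rdsem_fit(g, rdsem_model("C"), mcmc = fast_mcmc(600, seed = 8))
  re <- add_random_effects(base, g, mcmc = fast_mcmc(600, seed = 9))
  expect_true(all(c("lag1:stress->stress", "lag1:mchr->mchr",
                    "lag0:mchr->stress") %in% re$random_paths))
  ba <- re$before_after
  dyn <- grepl("^std:lag[01]:", ba$parameter)
  expect_lt(max(abs(ba$diff[dyn])), 0.1)
  # zero-heterogeneity truth: slope SDs shrink toward zero
  dr <- posterior_draws(re$fit)
  sv <- dr[, grep("^slope_var:", colnames(dr)), drop = FALSE]
  expect_lt(max(colMeans(sqrt(sv))), 0.15)
  expect_gt(re$fit$mh_accept, 0.15)
  expect_lt(re$fit$mh_accept, 0.7)
})

test_that("slope heterogeneity is recovered when present", {
  pop <- population_params(slope_sd = c("lag0:mchr->stress" = 0.12))
  g <- make_test_data(40, 5, adherence = 0.9, seed = 10, pop = pop)$gridded
  spec <- rdsem_spec(random_paths = "lag0:mchr->stress")
  fit <- rdsem_fit(g, spec, mcmc = fast_mcmc(800, seed = 11))
  dr <- posterior_draws(fit)
  sd_draws <- sqrt(dr[, "slope_var:lag0:mchr->stress"])
  ci <- stats::quantile(sd_draws, c(0.025, 0.975))
  expect_lt(ci[1], 0.12)
  expect_gt(ci[2], 0.12)
})

test_that("the bivariate lag-0 estimate interpolates the split estimates", {
  # moment-level oracle on a long trivariate series: regressing stress on
  # the pooled composite gives a lag-0 coefficient bracketed by the two
  # split-composite coefficients (all standardized)
  pop <- population_params(vars = c("stress", "aps", "bs"),
                           means = c(2, 0.8, 0.8),
                           between_sd = c(0.4, 0.3, 0.3),
                           between_cor = 0.3, ar = c(0.45, 0.5, 0.6),
                           lag0 = c(0.10, 0.30))
  y <- simulate_within(pop, NULL, grid_spec(840), seed = 12)
  n <- nrow(y)
  s <- scale(y[, 1]); a <- scale(y[, 2]); b <- scale(y[, 3])
  m <- scale((7 * y[, 2] + 14 * y[, 3]) / 21)
  co_split <- coef(lm(s[-1] ~ s[-n] + a[-n] + b[-n] + a[-1] + b[-1]))
  co_pool <- coef(lm(s[-1] ~ s[-n] + m[-n] + m[-1]))
  lo <- min(co_split[c("a[-1]", "b[-1]")])
  hi <- max(co_split[c("a[-1]", "b[-1]")])
  expect_gt(co_pool["m[-1]"], lo)
  expect_lt(co_pool["m[-1]"], hi + 0.1)
})

test_that("split fits produce a usable lag-0 contrast", {
  pop <- population_params(vars = c("stress", "aps", "bs"),
                           means = c(2, 0.8, 0.8),
                           between_sd = c(0.4, 0.3, 0.3),
                           between_cor = 0.3, ar = c(0.45, 0.5, 0.6),
                           lag0 = c(0.2, 0.2))
  ds <- simulate_ema_dataset(pop, n_persons = 15,
                             design = ema_design(n_days = 4),
                             grid = grid_spec(4), adherence_mean = 0.9,
                             adherence_sd = 0,
                             model = item_model(noise_sd = 0), seed = 13)
  sp <- fit_split_symptoms(ds$long, "aps_bs", grid_spec(4),
                           mcmc = fast_mcmc(500, seed = 14))
  expect_equal(sp$contrast$paths, c("lag0:aps->stress", "lag0:bs->stress"))
  # equal generating effects: overlapping CIs, difference covers zero
  expect_true(sp$contrast$ci_overlap)
  expect_lte(sp$contrast$difference$lci, 0)
  expect_gte(sp$contrast$difference$uci, 0)
  # composites in the fitted data obey the aggregation identity
  g <- suppressWarnings(grid_ema_dataset(ds$long, grid_spec(4)))
  ok <- !is.na(g$mchr)
  expect_equal((7 * g$aps[ok] + 14 * g$bs[ok]) / 21, g$mchr[ok],
               tolerance = 1e-12)
  expect_error(
    fit_split_symptoms(transform(ds$long, item_01 = 1)[
      , c("person_id", "day", "time_minutes", "stress",
          sprintf("item_%02d", 1:21))], "perc_nonp", grid_spec(4)),
    NA) # a single constant item does not make a composite degenerate
})

test_that("the DIC comparability harness tabulates selections and cross-lags", {
  scen <- data.frame(gen_model = "C", n_persons = 8, adherence = 0.9)
  tab <- dic_comparability_sim(scen, reps = 2, seed = 15,
                               fit_models = c("B", "C"),
                               design = ema_design(n_days = 3),
                               mcmc = fast_mcmc(200, seed = 1))
  expect_equal(nrow(tab), 4)
  expect_true(all(c("DIC", "cross_sm", "selected") %in% names(tab)))
  # exactly one DIC-selected model per replication
  agg <- tapply(tab$selected, tab$rep, sum)
  expect_true(all(agg == 1))
})
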