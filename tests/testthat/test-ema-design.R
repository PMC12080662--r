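test_that("schedules satisfy the design invariants across many seeds", {
  d <- ema_design()
  for (s in 1:100) {
    sch <- build_schedule(d, seed = s)
    expect_equal(nrow(sch), 56)
    expect_true(all(sch$time >= d$window_start))
    expect_true(all(sch$time <= d$window_end))
    spacing <- unlist(tapply(sch$time, sch$day, diff))
    expect_true(all(spacing >= d$min_spacing - 1e-9))
    expect_equal(as.vector(table(sch$day)), rep(8L, 7))
  }
})

test_that("a single prompt per day is placed inside the window", {
  d <- ema_design(prompts_per_day = 1)
  sch <- build_schedule(d, seed = 3)
  expect_equal(nrow(sch), 7)
  expect_true(all(sch$time >= 480 & sch$time <= 1320))
})

test_that("infeasible designs are rejected", {
  expect_error(ema_design(window_start = 480, window_end = 600,
                          prompts_per_day = 8, min_spacing = 25),
               "infeasible")
  expect_error(ema_design(window_start = 600, window_end = 480),
               "window_end")
})

test_that("postponement shifts prompts by an admissible delay at most once", {
  d <- ema_design()
  sch <- build_schedule(d, seed = 2)
  expect_identical(apply_postponement(sch, d, postpone_prob = 0), sch)
  sh <- apply_postponement(sch, d, postpone_prob = 1, seed = 4)
  delta <- sh$time - sch$time
  expect_true(all(delta %in% c(5, 10, 15)))
  expect_true(all(sh$postponed == 1L))
  # a second pass cannot postpone again (limit 1)
  sh2 <- apply_postponement(sh, d, postpone_prob = 1, seed = 5)
  expect_identical(sh2$time, sh$time)
  # order preserved
  expect_true(all(unlist(tapply(sh$time, sh$day, diff)) > 0))
})

test_that("a prompt near the window end may spill over by the delay", {
  d <- ema_design(postpone_options = 15)
  sch <- data.frame(day = 0L, time = 1315, answered = TRUE, postponed = 0L)
  sh <- apply_postponement(sch, d, postpone_prob = 1, seed = 1)
  expect_equal(sh$time, 1330) # 21:55 postponed 15 -> 22:10, retained
})

test_that("adherence thinning is Bernoulli with the requested rate", {
  d <- ema_design(n_days = 179) # ~10k prompts
  sch <- build_schedule(d, seed = 6)
  expect_true(all(apply_adherence(sch, 1)$answered))
  expect_error(apply_adherence(sch, 0), "probability")
  a <- apply_adherence(sch, 0.69, seed = 7)
  n <- nrow(sch)
  se <- sqrt(0.69 * 0.31 / n)
  expect_lt(abs(mean(a$answered) - 0.69), 3 * se)
})

test_that("grid alignment bins by floor and keeps the earliest on collision", {
  g <- grid_spec(7)
  expect_equal(g$n_slots, 168L)
  obs <- data.frame(day = c(0, 1), time = c(8 * 60 + 37, 9 * 60 + 5),
                    stress = c(1.5, 2.5))
  out <- align_to_grid(obs, g)
  expect_equal(nrow(out), 168)
  expect_equal(out$stress[out$slot == 8], 1.5)    # day 0, 08:37
  expect_equal(out$stress[out$slot == 33], 2.5)   # day 1, 09:05
  expect_equal(sum(!is.na(out$stress)), 2)
  # collision: both 10:10 and 10:40 fall in slot 10; earliest kept
  obs2 <- data.frame(day = 0, time = c(10 * 60 + 40, 10 * 60 + 10),
                     stress = c(9, 7))
  expect_warning(out2 <- align_to_grid(obs2, g), "dropped")
  expect_equal(out2$stress[out2$slot == 10], 7)
  expect_equal(attr(out2, "n_collisions"), 1L)
  # out of span
  expect_error(align_to_grid(data.frame(day = 9, time = 10, stress = 1), g),
               "outside")
})

test_that("alignment is idempotent on already-gridded data", {
  g <- grid_spec(2)
  obs <- data.frame(day = c(0, 0, 1), time = c(500, 900, 610),
                    stress = c(1, 2, 3))
  a1 <- align_to_grid(obs, g)
  back <- data.frame(day = a1$slot %/% 24, time = (a1$slot %% 24) * 60,
                     stress = a1$stress)
  back <- back[!is.na(back$stress), ]
  a2 <- align_to_grid(back, g)
  expect_equal(a2$stress, a1$stress)
  expect_equal(sum(!is.na(a1$stress)), nrow(obs) - attr(a1, "n_collisions"))
})

test_that("the default design can observe at most 56 of 168 slots", {
  dat <- make_test_data(3, 7, adherence = 1, seed = 8)$gridded
  for (pid in unique(dat$person_id)) {
    sub <- dat[dat$person_id == pid, ]
    expect_lte(sum(!is.na(sub$stress)), 56)
    expect_equal(nrow(sub), 168)
  }
})
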