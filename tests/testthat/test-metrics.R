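test_that("performance error follows the percentage-deviation formula", {
  expect_equal(performance_error(110, 100), 10)
  expect_equal(performance_error(100, 100), 0)
  expect_equal(performance_error(85, 108.9), -21.94674, tolerance = 1e-6)
  expect_equal(performance_error(c(90, 120), 100), c(-10, 20))
  expect_error(performance_error(100, 0), "positive")
})

test_that("per-subject statistics match hand-enumerated cases", {
  m <- per_patient_metrics(1:3, c(10, -10, 20))
  expect_equal(m$mdape, 10)
  expect_equal(m$mdpe, 10)
  expect_equal(m$wobble, 10)  # median of {0, 20, 10}

  m2 <- per_patient_metrics(1:5, rep(-7, 5))
  expect_equal(m2$mdape, 7)
  expect_equal(m2$mdpe, -7)
  expect_equal(m2$wobble, 0)
  expect_equal(m2$divergence, 0)

  # |PE| growing one percent per minute
  m3 <- per_patient_metrics(1:10, 1:10)
  expect_equal(m3$divergence, 1)

  # single observation: divergence undefined
  m4 <- per_patient_metrics(1, 5)
  expect_true(is.na(m4$divergence))
  expect_equal(m4$n_obs, 1L)

  expect_error(per_patient_metrics(numeric(0), numeric(0)), "non-empty")
  expect_error(per_patient_metrics(c(2, 1), c(0, 0)), "non-decreasing")
})

test_that("pooling weights per-subject statistics by observation count", {
  a <- per_patient_metrics(1:3, c(10, 10, 10), "a")
  b <- per_patient_metrics(1, 0, "b")
  pooled <- pool_metrics(rbind(a, b))
  expect_equal(pooled$mdape, (3 * 10 + 1 * 0) / 4)
  expect_equal(pooled$total_obs, 4L)
  # divergence pools only subjects where it is defined
  expect_equal(pooled$divergence, a$divergence)

  one <- pool_metrics(a)
  expect_equal(one$mdape, a$mdape)
  expect_equal(one$mdpe, a$mdpe)

  same <- rbind(per_patient_metrics(1:2, c(5, 5), "x"),
                per_patient_metrics(1:9, rep(5, 9), "y"))
  expect_equal(pool_metrics(same)$mdape, 5)
})

test_that("metric symmetries and bracketing hold on random instances", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(3:40, 1)
    t <- sort(runif(n, 0, 30))
    pe <- rnorm(n, sd = 15)
    m <- per_patient_metrics(t, pe)
    neg <- per_patient_metrics(t, -pe)
    expect_equal(neg$mdpe, -m$mdpe)
    expect_equal(neg$mdape, m$mdape)
    expect_equal(neg$wobble, m$wobble)

    c_ <- runif(1, 0.1, 4)
    sc <- per_patient_metrics(t, c_ * pe)
    expect_equal(sc$mdape, c_ * m$mdape)
    expect_equal(sc$mdpe, c_ * m$mdpe)
    expect_equal(sc$wobble, c_ * m$wobble)

    sh <- per_patient_metrics(t + 7, pe)
    expect_equal(sh$divergence, m$divergence)
  }

  # pooled values bracketed by the per-subject extremes
  set.seed(77)
  rows <- do.call(rbind, lapply(1:6, function(i) {
    n <- sample(2:30, 1)
    per_patient_metrics(sort(runif(n, 0, 20)), rnorm(n, sd = 10),
                        sprintf("s%d", i))
  }))
  pooled <- pool_metrics(rows)
  for (stat in c("mdape", "mdpe", "wobble", "divergence")) {
    expect_gte(pooled[[stat]], min(rows[[stat]]))
    expect_lte(pooled[[stat]], max(rows[[stat]]))
  }
})

test_that("outcome summary classifies readings by baseline fraction", {
  bs <- flat_series(n = 100, sbp = 100, baseline = 100)
  s <- outcome_summary(bs)
  expect_false(s$hypotension)
  expect_false(s$hypertension)
  expect_equal(s$n_within_80_120, 100L)
  expect_equal(s$n_below_80, 0L)

  sbp <- rep(100, 100); sbp[50] <- 79
  bs2 <- beat_series("s", 100, 1:100, sbp, rep(70, 100))
  s2 <- outcome_summary(bs2)
  expect_true(s2$hypotension)
  expect_equal(s2$n_below_80, 1L)

  # boundary readings at 80% and 120% belong to the "within" band
  bs3 <- beat_series("s", 100, 1:4, c(80, 120, 79.9, 120.1), rep(70, 4))
  s3 <- outcome_summary(bs3)
  expect_equal(s3$n_within_80_120, 2L)
  expect_equal(s3$n_below_80, 1L)
  expect_true(s3$hypertension)

  # random series against a naive per-reading classifier
  set.seed(8)
  sbp4 <- runif(200, 70, 130)
  hr4 <- runif(200, 55, 110)
  bs4 <- beat_series("s", 100, 1:200, sbp4, hr4)
  s4 <- outcome_summary(bs4)
  expect_equal(s4$n_below_80, sum(sbp4 / 100 < 0.8))
  expect_equal(s4$n_within_80_120, sum(sbp4 / 100 >= 0.8 & sbp4 / 100 <= 1.2))
  expect_equal(s4$bradycardia, any(hr4 < 60))
  expect_equal(s4$min_sbp, min(sbp4))
  expect_lte(s4$n_below_80 + s4$n_within_80_120, s4$n_readings)
})

test_that("dose totals come from events inside the observation window", {
  bs <- flat_series(n = 100, sbp = 90, baseline = 100)
  ev <- data.frame(start_s = c(10, 30, 50, 150),
                   drug = c("phenylephrine", "ephedrine", "phenylephrine",
                            "phenylephrine"),
                   amount = c(25, 2, 50, 75),
                   units = c("ug", "mg", "ug", "ug"),
                   duration_s = c(30, 30, 9, 4.5),
                   mode = c("slow", "slow", "rapid", "rapid"),
                   band = c(1L, 1L, 2L, 3L),
                   slope_mmhg_per_s = c(0.1, 0.2, -0.3, -0.4))
  s <- outcome_summary(bs, ev)  # window ends at t = 100
  expect_equal(s$total_phenylephrine_ug, 75)
  expect_equal(s$total_ephedrine_mg, 2)
})

test_that("band proportions pool counts, not per-subject proportions", {
  two <- rbind(
    outcome_summary(beat_series("a", 100, 1:100,
                                c(rep(100, 50), rep(70, 50)), rep(70, 100))),
    outcome_summary(beat_series("b", 100, 1:50, rep(70, 50), rep(70, 50))))
  bp <- band_proportion(two)
  # in-band 50/100 and 0/50 -> pooled 50/150, not mean of proportions 0.25
  expect_equal(bp$prop_within_80_120, 50 / 150)

  all_in <- band_proportion(outcome_summary(flat_series(100)))
  expect_equal(all_in$prop_within_80_120, 1)
  none_in <- band_proportion(
    outcome_summary(beat_series("c", 100, 1:10, rep(70, 10), rep(70, 10))))
  expect_equal(none_in$prop_within_80_120, 0)
})
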