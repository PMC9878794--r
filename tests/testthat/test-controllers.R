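adiva <- adiva_config()
diva <- diva_config()

test_that("SBP fractions map onto the documented dose bands", {
  expect_equal(classify_band(0.95, adiva), 1L)
  expect_equal(classify_band(0.85, adiva), 2L)
  expect_equal(classify_band(0.75, adiva), 3L)
  expect_true(is.na(classify_band(1.15, adiva)))
  expect_true(is.na(classify_band(1.05, diva)))
  expect_equal(classify_band(0.95, diva), 1L)
  expect_equal(classify_band(0.85, diva), 2L)
  # lower-inclusive edges
  expect_equal(classify_band(0.90, adiva), 1L)
  expect_equal(classify_band(0.80, adiva), 2L)
  expect_true(is.na(classify_band(1.10, adiva)))
  expect_true(is.na(classify_band(1.00, diva)))
  expect_error(classify_band(0, adiva), "positive")
  expect_error(classify_band(-0.2, diva), "positive")
})

test_that("drug and amount follow the heart-rate gate and tier", {
  d <- select_dose(2L, 70, adiva)
  expect_equal(d$drug, "phenylephrine")
  expect_equal(d$amount, 50)
  expect_equal(d$units, "ug")

  d <- select_dose(3L, 55, adiva)
  expect_equal(d$drug, "ephedrine")
  expect_equal(d$amount, 6)
  expect_equal(d$units, "mg")

  d <- select_dose(1L, 61, diva)
  expect_equal(d$drug, "phenylephrine")
  expect_equal(d$amount, 25)

  # hr exactly at the threshold resolves to phenylephrine
  expect_equal(select_dose(1L, 60, adiva)$drug, "phenylephrine")
  expect_equal(select_dose(1L, 59.9, adiva)$drug, "ephedrine")
  expect_error(select_dose(NA_integer_, 70, adiva), "valid tier")
})

test_that("trend slope equals the least-squares fit", {
  expect_equal(estimate_slope(data.frame(time_s = c(0, 5, 10),
                                         sbp = c(100, 95, 90))), -1)
  expect_equal(estimate_slope(data.frame(time_s = 1:10,
                                         sbp = rep(100, 10))), 0)
  for (seed in 1:5) {
    set.seed(seed)
    w <- data.frame(time_s = sort(runif(10, 0, 10)),
                    sbp = runif(10, 90, 120))
    expect_equal(estimate_slope(w), lm_slope(w$time_s, w$sbp),
                 tolerance = 1e-10)
  }
  expect_true(is.na(estimate_slope(data.frame(time_s = 3, sbp = 100))))
  expect_true(is.na(estimate_slope(data.frame(time_s = c(3, 3),
                                              sbp = c(100, 90)))))
})

test_that("delivery duration depends on tier, trend, and algorithm", {
  expect_equal(select_duration(1L, -0.5, adiva),
               list(duration_s = 4.5, mode = "rapid"))
  expect_equal(select_duration(2L, -0.5, adiva),
               list(duration_s = 9.0, mode = "rapid"))
  expect_equal(select_duration(3L, -0.1, adiva),
               list(duration_s = 13.5, mode = "rapid"))
  expect_equal(select_duration(2L, 0.3, adiva),
               list(duration_s = 30, mode = "slow"))
  # flat or indeterminate trend is not "trending downward"
  expect_equal(select_duration(1L, 0, adiva)$mode, "slow")
  expect_equal(select_duration(1L, NA_real_, adiva)$mode, "slow")
  # DIVA is slope-independent
  for (s in c(-5, -0.01, 0, 0.01, 5, NA_real_)) {
    expect_equal(select_duration(2L, s, diva),
                 list(duration_s = 30, mode = "slow"))
  }
})

test_that("a controller step composes banding, gating, trend and lockout", {
  # mean SBP 84% of baseline over the last 10 s, hr 72, falling trend
  t <- 1:30
  sbp <- c(rep(100, 20), seq(88, 80.27, length.out = 10))
  bs <- beat_series("s", 100, t, sbp, rep(72, 30))
  frac <- mean(sbp[t > 20 & t <= 30]) / 100
  expect_equal(round(frac, 2), 0.84)

  st <- new_controller_state()
  res <- controller_step(st, bs, 30, adiva)
  expect_equal(res$event$drug, "phenylephrine")
  expect_equal(res$event$amount, 50)
  expect_equal(res$event$mode, "rapid")
  expect_equal(res$event$duration_s, 9.0)
  expect_equal(res$state$busy_until_s, 30 + 9.0 + 10)

  # busy controller emits nothing
  res2 <- controller_step(res$state, bs, 40, adiva)
  expect_null(res2$event)
  expect_equal(res2$state$busy_until_s, res$state$busy_until_s)

  # SBP above every treatment band emits nothing
  hi <- flat_series(n = 30, sbp = 112, baseline = 100)
  res3 <- controller_step(new_controller_state(), hi, 30, adiva)
  expect_null(res3$event)
})

test_that("perturbing SBP within a band never flips the selected drug", {
  for (algo in list(adiva, diva)) {
    for (hr in c(50, 59, 60, 61, 80)) {
      drugs <- vapply(c(0.801, 0.85, 0.899), function(f) {
        select_dose(classify_band(f, algo), hr, algo)$drug
      }, character(1))
      expect_equal(length(unique(drugs)), 1L)
    }
  }
})

test_that("rescue detection flags sustained hypotension and bradycardia", {
  cfg <- adiva_config()
  ok <- flat_series(n = 250, sbp = 85, baseline = 100)
  expect_equal(nrow(detect_rescue(ok, cfg)), 0L)

  # 65% of baseline for 200 s -> flagged 180 s into the stretch
  t <- 1:300
  sbp <- ifelse(t >= 50 & t <= 250, 65, 100)
  low <- beat_series("s", 100, t, sbp, rep(75, 300))
  r <- detect_rescue(low, cfg)
  expect_equal(r$kind, "sustained_hypotension")
  expect_equal(r$time_s, 50 + 180)

  # a single dip is not sustained
  sbp2 <- rep(100, 300); sbp2[100] <- 68
  dip <- beat_series("s", 100, t, sbp2, rep(75, 300))
  expect_equal(nrow(detect_rescue(dip, cfg)), 0L)

  # a stretch of exactly 180 s is not "more than three minutes"
  sbp3 <- ifelse(t >= 50 & t <= 230, 65, 100)
  edge <- beat_series("s", 100, t, sbp3, rep(75, 300))
  expect_equal(nrow(detect_rescue(edge, cfg)), 0L)

  hr <- rep(75, 300); hr[120] <- 40
  brady <- beat_series("s", 100, t, rep(100, 300), hr)
  rb <- detect_rescue(brady, cfg)
  expect_equal(rb$kind, "bradycardia")
  expect_equal(rb$time_s, 120)
})

test_that("controller config round-trips and rejects malformed bands", {
  expect_error(controller_config("adiva", band_edges = c(0.9, 0.8, 1.1)),
               "increasing")
  expect_error(controller_config("adiva", phenylephrine_tiers = c(25, 50)),
               "match")
  cfg <- controller_config("adiva", hr_threshold = 65)
  expect_equal(cfg$hr_threshold, 65)
})
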