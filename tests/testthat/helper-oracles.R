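# Independent naive implementations used as oracles. They deliberately
# avoid the package's code paths: medians by explicit sorting, regression
# slopes via lm(), pooled statistics by scalar loops.

naive_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

lm_slope <- function(t, y) {
  if (length(unique(t)) < 2) return(NA_real_)
  unname(stats::coef(stats::lm(y ~ t))[2])
}

naive_subject_stats <- function(time_min, pe) {
  mdpe <- naive_median(pe)
  list(n = length(pe),
       mdape = naive_median(abs(pe)),
       mdpe = mdpe,
       wobble = naive_median(abs(pe - mdpe)),
       divergence = lm_slope(time_min, abs(pe)))
}

naive_pooled <- function(subjects) {
  num <- c(mdape = 0, mdpe = 0, wobble = 0)
  den <- 0
  dnum <- 0; dden <- 0
  for (s in subjects) {
    num <- num + s$n * c(s$mdape, s$mdpe, s$wobble)
    den <- den + s$n
    if (!is.na(s$divergence)) {
      dnum <- dnum + s$n * s$divergence
      dden <- dden + s$n
    }
  }
  list(mdape = num[["mdape"]] / den, mdpe = num[["mdpe"]] / den,
       wobble = num[["wobble"]] / den,
       divergence = if (dden > 0) dnum / dden else NA_real_)
}

# Independent restatement of the two controllers' dose maps: explicit
# threshold chains, no band/tier indexing.
expected_decision <- function(algorithm, frac, hr) {
  phe <- hr >= 60
  if (algorithm == "adiva") {
    if (frac >= 1.10) return(NULL)
    if (frac >= 0.90)
      return(if (phe) list("phenylephrine", 25) else list("ephedrine", 2))
    if (frac >= 0.80)
      return(if (phe) list("phenylephrine", 50) else list("ephedrine", 4))
    return(if (phe) list("phenylephrine", 75) else list("ephedrine", 6))
  }
  if (frac >= 1.00) return(NULL)
  if (frac >= 0.90)
    return(if (phe) list("phenylephrine", 25) else list("ephedrine", 2))
  if (phe) list("phenylephrine", 50) else list("ephedrine", 4)
}

# A short flat beat series useful across tests.
flat_series <- function(n = 30, sbp = 100, hr = 75, baseline = 100,
                        dt = 1, subject = "s1") {
  beat_series(subject, baseline, time_s = seq_len(n) * dt,
              sbp = rep_len(sbp, n), hr = rep_len(hr, n))
}
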