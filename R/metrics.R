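#' Percentage performance error
#'
#' The signed percentage deviation of a measured SBP reading from the
#' subject's baseline: `100 * (measured - baseline) / baseline`.
#'
#' @param measured Measured SBP reading(s), mmHg (vectorized).
#' @param baseline Baseline SBP, mmHg (> 0).
#' @return Performance error(s) in percent.
#' @export
#' @examples
#' performance_error(110, 100)  # 10
performance_error <- function(measured, baseline) {
  if (!is.numeric(baseline) || any(baseline <= 0))
    stop("baseline must be positive")
  100 * (measured - baseline) / baseline
}

#' Per-subject performance-error series
#'
#' Computes the beat-level performance-error series of a subject within the
#' observation window (spinal anesthesia to fetal delivery), with times
#' converted to minutes for the divergence regression.
#'
#' @param series A [beat_series()].
#' @return data.frame with columns `time_min` and `pe` (percent).
#' @export
pe_series <- function(series) {
  stopifnot(inherits(series, "beat_series"))
  keep <- series$samples$time_s <= series$delivery_time_s
  data.frame(time_min = series$samples$time_s[keep] / 60,
             pe = performance_error(series$samples$sbp[keep],
                                    series$baseline_sbp))
}

#' Per-subject performance-error statistics
#'
#' The four standard closed-loop performance measures for one subject:
#' MDAPE (median absolute PE, inaccuracy), MDPE (median PE, bias), wobble
#' (median absolute deviation of PE from MDPE, intra-subject variability),
#' and divergence (ordinary-least-squares slope of |PE| on time in minutes;
#' positive when control accuracy worsens over the run). Even-length
#' medians are the midpoint of the central pair. Divergence is `NA` for a
#' single observation (or no time spread) and such subjects are excluded
#' from the pooled divergence weighting.
#'
#' @param time_min Observation times in minutes, non-decreasing.
#' @param pe Performance errors in percent, same length.
#' @param subject_id Optional label carried into the result.
#' @return One-row data.frame with columns `subject_id`, `n_obs`, `mdape`,
#'   `mdpe`, `wobble`, `divergence`.
#' @export
#' @examples
#' per_patient_metrics(1:3, c(10, -10, 20))
per_patient_metrics <- function(time_min, pe, subject_id = NA_character_) {
  if (length(pe) == 0L) stop("pe series must be non-empty")
  if (length(time_min) != length(pe))
    stop("time_min and pe must have equal length")
  if (is.unsorted(time_min)) stop("time_min must be non-decreasing")
  mdpe <- stats::median(pe)
  data.frame(subject_id = as.character(subject_id),
             n_obs = length(pe),
             mdape = stats::median(abs(pe)),
             mdpe = mdpe,
             wobble = stats::median(abs(pe - mdpe)),
             divergence = ols_slope(time_min, abs(pe)),
             stringsAsFactors = FALSE)
}

#' @rdname per_patient_metrics
#' @param series A [beat_series()]; convenience wrapper computing the PE
#'   series with [pe_series()] first.
#' @export
series_metrics <- function(series) {
  p <- pe_series(series)
  per_patient_metrics(p$time_min, p$pe, subject_id = series$subject_id)
}

#' Pooled performance-error statistics
#'
#' Arm-level statistics under the pooled-data convention: each pooled value
#' is the mean of the per-subject values weighted by the subject's number
#' of PE observations (Ni), so subjects with longer recordings weigh more.
#' Pooled divergence weights only subjects whose divergence is defined.
#'
#' @param per_patient data.frame of per-subject rows from
#'   [per_patient_metrics()] (rows bound together).
#' @return One-row data.frame with columns `mdape`, `mdpe`, `wobble`,
#'   `divergence`, `total_obs`, `n_subjects`.
#' @export
pool_metrics <- function(per_patient) {
  if (nrow(per_patient) == 0L) stop("at least one subject required")
  w <- per_patient$n_obs
  wmean <- function(x, w) sum(w * x) / sum(w)
  div_ok <- !is.na(per_patient$divergence)
  data.frame(
    mdape = wmean(per_patient$mdape, w),
    mdpe = wmean(per_patient$mdpe, w),
    wobble = wmean(per_patient$wobble, w),
    divergence = if (any(div_ok))
      wmean(per_patient$divergence[div_ok], w[div_ok]) else NA_real_,
    total_obs = sum(w),
    n_subjects = nrow(per_patient)
  )
}

#' Hemodynamic and dosing outcome summary for one subject
#'
#' Classifies every SBP reading between spinal anesthesia and fetal
#' delivery against the baseline bands: hypotension is any reading strictly
#' below 80% of baseline, hypertension any reading strictly above 120%,
#' bradycardia any heart-rate reading below 60 beats/min; the "within"
#' band is closed on both ends (80% to 120% inclusive). Vasopressor
#' consumption is summed by drug over the dose events starting within the
#' window.
#'
#' @param series A [beat_series()].
#' @param events Dose-event log for the subject (may have zero rows).
#' @return One-row data.frame with the flags, extrema, band counts, and
#'   total doses.
#' @export
outcome_summary <- function(series,
                            events = empty_dose_events()) {
  stopifnot(inherits(series, "beat_series"))
  s <- series$samples[series$samples$time_s <= series$delivery_time_s, ]
  frac <- s$sbp / series$baseline_sbp
  n_below <- sum(frac < 0.80)
  n_within <- sum(frac >= 0.80 & frac <= 1.20)
  n_above <- sum(frac > 1.20)
  ev <- if (!is.null(events) && nrow(events) > 0L)
    events[events$start_s <= series$delivery_time_s, , drop = FALSE]
  else empty_dose_events()
  data.frame(
    subject_id = series$subject_id,
    hypotension = n_below >= 1L,
    hypertension = n_above >= 1L,
    bradycardia = any(s$hr < 60),
    min_sbp = min(s$sbp), max_sbp = max(s$sbp),
    min_hr = min(s$hr), max_hr = max(s$hr),
    n_readings = nrow(s),
    n_below_80 = n_below,
    n_within_80_120 = n_within,
    total_phenylephrine_ug = sum(ev$amount[ev$drug == "phenylephrine"]),
    total_ephedrine_mg = sum(ev$amount[ev$drug == "ephedrine"]),
    stringsAsFactors = FALSE
  )
}

#' Pooled band proportions across subjects
#'
#' Arm-level proportion of SBP readings in each band, computed by pooling
#' counts — sum of per-subject band counts over sum of per-subject reading
#' counts — not by averaging per-subject proportions.
#'
#' @param summaries data.frame of rows from [outcome_summary()].
#' @return One-row data.frame with `prop_below_80` and `prop_within_80_120`
#'   (proportions in \[0, 1\]) plus the pooled numerators/denominator.
#' @export
band_proportion <- function(summaries) {
  if (nrow(summaries) == 0L) stop("at least one subject required")
  n_tot <- sum(summaries$n_readings)
  if (n_tot == 0L) stop("no readings to pool")
  data.frame(
    n_readings = n_tot,
    n_below_80 = sum(summaries$n_below_80),
    n_within_80_120 = sum(summaries$n_within_80_120),
    prop_below_80 = sum(summaries$n_below_80) / n_tot,
    prop_within_80_120 = sum(summaries$n_within_80_120) / n_tot
  )
}
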