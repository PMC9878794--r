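#' Construct a beat-to-beat hemodynamic series
#'
#' A `beat_series` holds one subject's beat-to-beat systolic blood pressure
#' (SBP) and heart rate stream, recorded from intrathecal injection (t = 0)
#' to fetal delivery, together with the pre-anesthesia baseline SBP that all
#' fractional banding and performance errors are referenced to.
#'
#' @param subject_id Opaque subject label (coerced to character).
#' @param baseline_sbp Baseline systolic blood pressure in mmHg (mean of the
#'   pre-anesthesia oscillometric readings); must be positive.
#' @param time_s Numeric vector of beat times in seconds since spinal
#'   anesthesia; non-negative, strictly increasing.
#' @param sbp Numeric vector of systolic blood pressure readings (mmHg),
#'   one per beat; all positive.
#' @param hr Numeric vector of heart rates (beats/min), one per beat; all
#'   positive.
#' @param delivery_time_s Time of fetal delivery in seconds; the end of the
#'   observation window. Defaults to the last beat time.
#'
#' @return An object of class `beat_series`: a list with elements
#'   `subject_id`, `baseline_sbp`, `delivery_time_s` and `samples` (a
#'   data.frame with columns `time_s`, `sbp`, `hr`).
#' @export
#' @examples
#' bs <- beat_series("s1", 110, time_s = 1:5, sbp = c(108, 107, 105, 104, 102),
#'                   hr = rep(78, 5))
#' bs
beat_series <- function(subject_id, baseline_sbp, time_s, sbp, hr,
                        delivery_time_s = NULL) {
  time_s <- as.numeric(time_s)
  sbp <- as.numeric(sbp)
  hr <- as.numeric(hr)
  n <- length(time_s)
  if (n == 0L) stop("beat series must contain at least one sample")
  if (length(sbp) != n || length(hr) != n)
    stop("time_s, sbp and hr must have equal length")
  if (anyNA(time_s) || anyNA(sbp) || anyNA(hr))
    stop("beat samples must not contain NA")
  if (any(time_s < 0)) stop("beat times must be non-negative")
  if (is.unsorted(time_s, strictly = TRUE))
    stop("beat times must be strictly increasing")
  if (any(sbp <= 0)) stop("sbp must be positive")
  if (any(hr <= 0)) stop("hr must be positive")
  if (!is.numeric(baseline_sbp) || length(baseline_sbp) != 1L ||
      is.na(baseline_sbp) || baseline_sbp <= 0)
    stop("baseline_sbp must be a positive scalar")
  if (is.null(delivery_time_s)) delivery_time_s <- time_s[n]
  if (!is.numeric(delivery_time_s) || length(delivery_time_s) != 1L ||
      is.na(delivery_time_s) || delivery_time_s <= 0)
    stop("delivery_time_s must be a positive scalar")
  structure(
    list(
      subject_id = as.character(subject_id),
      baseline_sbp = as.numeric(baseline_sbp),
      delivery_time_s = as.numeric(delivery_time_s),
      samples = data.frame(time_s = time_s, sbp = sbp, hr = hr)
    ),
    class = "beat_series"
  )
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf(
    "<beat_series> subject %s: %d beats over %.1f s, baseline SBP %.1f mmHg\n",
    x$subject_id, nrow(x$samples), x$delivery_time_s, x$baseline_sbp
  ))
  invisible(x)
}

#' Moving-average SBP epochs
#'
#' Integrates the beat-to-beat SBP stream into trailing moving-average
#' values on a fixed cadence, the form the controllers consume. Epoch ticks
#' run from the first full window to `delivery_time_s`; the mean at tick
#' `t` covers beats with time in the half-open interval `(t - window_s, t]`,
#' so a beat landing exactly on an epoch boundary is counted once. Ticks
#' whose window contains no beats are omitted.
#'
#' @param series A [beat_series()].
#' @param window_s Averaging window length in seconds (default 10).
#' @param cadence_s Spacing of epoch ticks in seconds (default 10; equal to
#'   `window_s` gives tiled, non-overlapping windows).
#'
#' @return data.frame with columns `epoch_end_s` and `mean_sbp` (mmHg).
#' @export
moving_average_epochs <- function(series, window_s = 10, cadence_s = 10) {
  stopifnot(inherits(series, "beat_series"))
  if (!is.numeric(window_s) || window_s <= 0) stop("window_s must be > 0")
  if (!is.numeric(cadence_s) || cadence_s <= 0) stop("cadence_s must be > 0")
  ticks <- seq(window_s, series$delivery_time_s, by = cadence_s)
  if (length(ticks) == 0L)
    return(data.frame(epoch_end_s = numeric(0), mean_sbp = numeric(0)))
  tm <- series$samples$time_s
  sb <- series$samples$sbp
  means <- vapply(ticks, function(tk) {
    in_win <- tm > tk - window_s & tm <= tk
    if (!any(in_win)) return(NA_real_)
    mean(sb[in_win])
  }, numeric(1))
  keep <- !is.na(means)
  data.frame(epoch_end_s = ticks[keep], mean_sbp = means[keep])
}

#' Extract a trailing beat-level window
#'
#' Returns the beat samples in the half-open interval `(t - width_s, t]`,
#' time-ordered — the window the trend estimator runs on.
#'
#' @param series A [beat_series()].
#' @param t Window end time in seconds; must not exceed the last beat time.
#' @param width_s Window width in seconds (default 10).
#'
#' @return data.frame with columns `time_s` and `sbp` (possibly zero rows).
#' @export
trend_window <- function(series, t, width_s = 10) {
  stopifnot(inherits(series, "beat_series"))
  tm <- series$samples$time_s
  if (t > tm[length(tm)]) stop("t exceeds the last observed beat time")
  in_win <- tm > t - width_s & tm <= t
  series$samples[in_win, c("time_s", "sbp"), drop = FALSE]
}

# Ordinary-least-squares slope of y on t; NA when the window is degenerate
# (fewer than 2 points or no time spread). Closed form, avoids lm() overhead
# in the per-epoch controller loop.
ols_slope <- function(t, y) {
  if (length(t) < 2L) return(NA_real_)
  tc <- t - mean(t)
  den <- sum(tc^2)
  if (den == 0) return(NA_real_)
  sum(tc * (y - mean(y))) / den
}
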