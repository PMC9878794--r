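#' Controller configuration
#'
#' Builds the configuration for the two automated vasopressor controllers.
#' Both controllers band the 10-s moving-average SBP against the subject's
#' baseline and pick phenylephrine (heart rate at or above `hr_threshold`)
#' or ephedrine (below it) at the band's dose tier. ADIVA has three bands
#' with edges at 80%, 90% and 110% of baseline and additionally estimates
#' the SBP trend over the trailing `trend_window_s` seconds: a falling trend
#' triggers rapid delivery (4.5/9.0/13.5 s for tiers 1/2/3), otherwise the
#' bolus runs over `slow_duration_s`. DIVA has two bands with edges at 90%
#' and 100% and always delivers over `slow_duration_s`. Every bolus is
#' followed by a `lockout_s` refractory period.
#'
#' Band membership is lower-inclusive: a fraction exactly on an edge belongs
#' to the band above it, and a fraction at or above the top edge is left
#' untreated. Tier 1 is the lowest-dose band (nearest baseline); the highest
#' tier index is the deepest hypotension band.
#'
#' @param algorithm `"adiva"`, `"diva"`, or `"none"` (controller disabled;
#'   used for untreated reference runs).
#' @param hr_threshold Heart-rate gate in beats/min between phenylephrine
#'   (>=) and ephedrine (<); default 60.
#' @param band_edges Increasing fractions of baseline delimiting the dose
#'   bands; the region above the last edge is untreated.
#' @param phenylephrine_tiers Phenylephrine dose per tier, micrograms.
#' @param ephedrine_tiers Ephedrine dose per tier, milligrams.
#' @param lockout_s Refractory period after each bolus completes, seconds.
#' @param slow_duration_s Slow-infusion duration, seconds.
#' @param rapid_durations_s Rapid delivery duration per tier, seconds
#'   (ignored by DIVA, which delivers every bolus slowly).
#' @param trend_window_s Width of the beat-level trend window, seconds.
#' @param decision_cadence_s Spacing of controller decisions, seconds;
#'   also the moving-average window length.
#' @param rescue_sbp_fraction Fraction of baseline below which sustained
#'   hypotension triggers a manual-rescue flag.
#' @param rescue_sustain_s Duration the SBP must stay below
#'   `rescue_sbp_fraction` before the rescue flag is raised, seconds.
#' @param rescue_bradycardia_hr Heart rate (beats/min) below which a
#'   bradycardia rescue flag (atropine) is raised. Distinct from the
#'   ephedrine gate at 60 and from the bradycardia outcome definition.
#'
#' @return An object of class `controller_config`.
#' @seealso [adiva_config()], [diva_config()] for the shipped presets.
#' @export
controller_config <- function(algorithm = c("adiva", "diva", "none"),
                              hr_threshold = 60,
                              band_edges = NULL,
                              phenylephrine_tiers = NULL,
                              ephedrine_tiers = NULL,
                              lockout_s = 10,
                              slow_duration_s = 30,
                              rapid_durations_s = NULL,
                              trend_window_s = 10,
                              decision_cadence_s = 10,
                              rescue_sbp_fraction = 0.70,
                              rescue_sustain_s = 180,
                              rescue_bradycardia_hr = 45) {
  algorithm <- match.arg(algorithm)
  if (is.null(band_edges))
    band_edges <- switch(algorithm,
      adiva = c(0.80, 0.90, 1.10),
      diva = c(0.90, 1.00),
      none = numeric(0))
  if (is.null(phenylephrine_tiers))
    phenylephrine_tiers <- switch(algorithm,
      adiva = c(25, 50, 75), diva = c(25, 50), none = numeric(0))
  if (is.null(ephedrine_tiers))
    ephedrine_tiers <- switch(algorithm,
      adiva = c(2, 4, 6), diva = c(2, 4), none = numeric(0))
  if (is.null(rapid_durations_s))
    rapid_durations_s <- switch(algorithm,
      adiva = c(4.5, 9.0, 13.5), diva = c(30, 30), none = numeric(0))
  n_bands <- length(band_edges)
  if (algorithm != "none") {
    if (is.unsorted(band_edges, strictly = TRUE))
      stop("band_edges must be strictly increasing")
    if (length(phenylephrine_tiers) != n_bands ||
        length(ephedrine_tiers) != n_bands ||
        length(rapid_durations_s) != n_bands)
      stop("tier vectors must match the number of band edges")
    if (any(c(phenylephrine_tiers, ephedrine_tiers) <= 0))
      stop("dose tiers must be positive")
  }
  stopifnot(lockout_s >= 0, slow_duration_s > 0,
            trend_window_s > 0, decision_cadence_s > 0,
            rescue_sbp_fraction > 0, rescue_sbp_fraction < 1,
            rescue_sustain_s > 0)
  structure(
    list(algorithm = algorithm,
         hr_threshold = hr_threshold,
         band_edges = band_edges,
         phenylephrine_tiers = phenylephrine_tiers,
         ephedrine_tiers = ephedrine_tiers,
         lockout_s = lockout_s,
         slow_duration_s = slow_duration_s,
         rapid_durations_s = rapid_durations_s,
         trend_window_s = trend_window_s,
         decision_cadence_s = decision_cadence_s,
         rescue_sbp_fraction = rescue_sbp_fraction,
         rescue_sustain_s = rescue_sustain_s,
         rescue_bradycardia_hr = rescue_bradycardia_hr),
    class = "controller_config"
  )
}

#' @rdname controller_config
#' @export
adiva_config <- function(...) controller_config("adiva", ...)

#' @rdname controller_config
#' @export
diva_config <- function(...) controller_config("diva", ...)

#' @export
print.controller_config <- function(x, ...) {
  cat(sprintf("<controller_config> %s\n", toupper(x$algorithm)))
  if (x$algorithm != "none") {
    cat(sprintf("  bands (fraction of baseline): < %s\n",
                paste(format(x$band_edges), collapse = " < ")))
    cat(sprintf("  phenylephrine tiers (ug): %s | ephedrine tiers (mg): %s\n",
                paste(x$phenylephrine_tiers, collapse = "/"),
                paste(x$ephedrine_tiers, collapse = "/")))
    cat(sprintf("  lockout %gs, slow %gs, rapid %s s\n", x$lockout_s,
                x$slow_duration_s, paste(x$rapid_durations_s, collapse = "/")))
  }
  invisible(x)
}

#' Classify the SBP fraction into a dose band
#'
#' Maps the ratio of (moving-average) SBP to baseline onto the controller's
#' dose tiers. Tier 1 is the mildest band next to baseline; the highest tier
#' is the deepest hypotension. Fractions at or above the top band edge are
#' untreated (`NA`). Edges are lower-inclusive.
#'
#' @param sbp_fraction Numeric vector of measured/baseline SBP ratios (> 0).
#' @param config A [controller_config()].
#' @return Integer vector of tier indices, `NA` where no treatment band
#'   applies.
#' @export
#' @examples
#' cfg <- adiva_config()
#' classify_band(c(0.75, 0.85, 0.95, 1.15), cfg)  # 3 2 1 NA
classify_band <- function(sbp_fraction, config) {
  stopifnot(inherits(config, "controller_config"))
  if (any(!is.finite(sbp_fraction)) || any(sbp_fraction <= 0))
    stop("sbp_fraction must be positive and finite")
  edges <- config$band_edges
  if (length(edges) == 0L) return(rep(NA_integer_, length(sbp_fraction)))
  k <- findInterval(sbp_fraction, edges)  # [e_i, e_{i+1}) intervals
  tier <- length(edges) - k
  tier[tier == 0L] <- NA_integer_
  as.integer(tier)
}

#' Select drug and dose for a band
#'
#' Phenylephrine at the band's microgram tier when the heart rate is at or
#' above the threshold, ephedrine at the milligram tier when below it.
#'
#' @param band Tier index from [classify_band()]; must not be `NA`.
#' @param hr Latest observed heart rate, beats/min.
#' @param config A [controller_config()].
#' @return list with elements `drug` (`"phenylephrine"` or `"ephedrine"`),
#'   `amount`, and `units` (`"ug"` or `"mg"`).
#' @export
select_dose <- function(band, hr, config) {
  stopifnot(inherits(config, "controller_config"))
  if (is.na(band) || band < 1L || band > length(config$band_edges))
    stop("band must be a valid tier index for this algorithm")
  if (hr >= config$hr_threshold)
    list(drug = "phenylephrine", amount = config$phenylephrine_tiers[band],
         units = "ug")
  else
    list(drug = "ephedrine", amount = config$ephedrine_tiers[band],
         units = "mg")
}

#' Least-squares SBP trend
#'
#' Ordinary-least-squares slope of SBP on time over a beat-level window,
#' in mmHg per second. Returns `NA` for degenerate windows (fewer than two
#' points, or no spread in time); callers treat `NA` as "not falling".
#'
#' @param window data.frame with columns `time_s` and `sbp`, as returned by
#'   [trend_window()].
#' @return Slope in mmHg/s, or `NA`.
#' @export
estimate_slope <- function(window) {
  ols_slope(window$time_s, window$sbp)
}

#' Delivery duration for a bolus
#'
#' ADIVA delivers rapidly — over the tier's rapid duration — when the SBP
#' trend is strictly falling, and over the slow duration otherwise (rising,
#' flat, or indeterminate trend). DIVA delivers every bolus over the slow
#' duration regardless of trend.
#'
#' @param band Tier index.
#' @param slope Trend estimate in mmHg/s (may be `NA`).
#' @param config A [controller_config()].
#' @return list with `duration_s` and `mode` (`"rapid"` or `"slow"`).
#' @export
select_duration <- function(band, slope, config) {
  stopifnot(inherits(config, "controller_config"))
  if (config$algorithm == "adiva" && !is.na(slope) && slope < 0)
    list(duration_s = config$rapid_durations_s[band], mode = "rapid")
  else
    list(duration_s = config$slow_duration_s, mode = "slow")
}

#' Fresh controller state
#'
#' @return list with `busy_until_s` (time before which no new bolus may
#'   start) and `events` (accumulated dose-event log).
#' @export
new_controller_state <- function() {
  list(busy_until_s = -Inf, events = empty_dose_events())
}

empty_dose_events <- function() {
  data.frame(start_s = numeric(0), drug = character(0), amount = numeric(0),
             units = character(0), duration_s = numeric(0),
             mode = character(0), band = integer(0),
             slope_mmhg_per_s = numeric(0), stringsAsFactors = FALSE)
}

#' One controller decision
#'
#' Evaluates the controller at decision epoch `t` against the beats observed
#' so far: if the controller is idle (past any delivery + lockout), it forms
#' the trailing moving-average SBP, bands its fraction of baseline, gates
#' the drug on the latest heart rate, estimates the beat-level trend, and
#' emits a dose event. Returns the updated state and the event (or `NULL`).
#'
#' @param state Controller state from [new_controller_state()] or a prior
#'   step.
#' @param series [beat_series()] observed up to time `t`.
#' @param t Decision epoch, seconds.
#' @param config A [controller_config()].
#' @return list with elements `state` and `event` (one-row data.frame or
#'   `NULL`).
#' @export
controller_step <- function(state, series, t, config) {
  stopifnot(inherits(config, "controller_config"))
  if (config$algorithm == "none") return(list(state = state, event = NULL))
  if (t < state$busy_until_s) return(list(state = state, event = NULL))
  tm <- series$samples$time_s
  in_win <- tm > t - config$decision_cadence_s & tm <= t
  if (!any(in_win)) return(list(state = state, event = NULL))
  mean_sbp <- mean(series$samples$sbp[in_win])
  frac <- mean_sbp / series$baseline_sbp
  band <- classify_band(frac, config)
  if (is.na(band)) return(list(state = state, event = NULL))
  obs <- tm <= t
  hr <- series$samples$hr[max(which(obs))]
  dose <- select_dose(band, hr, config)
  slope <- estimate_slope(trend_window(series, min(t, tm[length(tm)]),
                                       config$trend_window_s))
  dur <- select_duration(band, slope, config)
  event <- data.frame(start_s = t, drug = dose$drug, amount = dose$amount,
                      units = dose$units, duration_s = dur$duration_s,
                      mode = dur$mode, band = band,
                      slope_mmhg_per_s = if (is.na(slope)) NA_real_ else slope,
                      stringsAsFactors = FALSE)
  state$busy_until_s <- t + dur$duration_s + config$lockout_s
  state$events <- rbind(state$events, event)
  list(state = state, event = event)
}

#' Detect manual-rescue conditions
#'
#' Flags the points at which the supervising investigator would intervene:
#' sustained hypotension — SBP below `rescue_sbp_fraction` of baseline over
#' a contiguous stretch of beats lasting strictly more than
#' `rescue_sustain_s` seconds, timestamped at the instant the criterion
#' first becomes true (stretch start + `rescue_sustain_s`) — and
#' bradycardia, the first beat with heart rate below
#' `rescue_bradycardia_hr`.
#'
#' @param series A [beat_series()].
#' @param config A [controller_config()].
#' @return data.frame with columns `time_s` and `kind`
#'   (`"sustained_hypotension"` or `"bradycardia"`); zero rows when no
#'   rescue criterion is met.
#' @export
detect_rescue <- function(series, config) {
  stopifnot(inherits(series, "beat_series"),
            inherits(config, "controller_config"))
  out <- data.frame(time_s = numeric(0), kind = character(0),
                    stringsAsFactors = FALSE)
  tm <- series$samples$time_s
  below <- series$samples$sbp < config$rescue_sbp_fraction * series$baseline_sbp
  if (any(below)) {
    r <- rle(below)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      span <- tm[ends[i]] - tm[starts[i]]
      if (span > config$rescue_sustain_s) {
        out <- rbind(out, data.frame(
          time_s = tm[starts[i]] + config$rescue_sustain_s,
          kind = "sustained_hypotension", stringsAsFactors = FALSE))
      }
    }
  }
  brady <- which(series$samples$hr < config$rescue_bradycardia_hr)
  if (length(brady) > 0L)
    out <- rbind(out, data.frame(time_s = tm[brady[1L]], kind = "bradycardia",
                                 stringsAsFactors = FALSE))
  out[order(out$time_s), , drop = FALSE]
}
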