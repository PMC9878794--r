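#' Virtual-patient parameters
#'
#' Generative parameters for one simulated parturient: baseline
#' hemodynamics, the sympathetic-block hypotension dynamics, effect-site
#' bolus pharmacodynamics for phenylephrine and ephedrine, measurement
#' noise, and the run length (spinal anesthesia to fetal delivery).
#'
#' The untreated SBP follows a mono-exponential decline,
#' `baseline_sbp * (1 - block_depth * (1 - exp(-t / block_tau_s)))`,
#' reaching a plateau `block_depth` below baseline with time constant
#' `block_tau_s`. Each bolus enters a linear one-compartment model with
#' zero-order infusion over its delivery duration, first-order elimination
#' (`elim_halflife_s`), and first-order effect-site equilibration
#' (`onset_tau_s`); the SBP rise is `potency` scaled so that an ideal
#' instantaneous reference bolus (25 ug phenylephrine / 2 mg ephedrine)
#' peaks at exactly `potency` mmHg. Heart-rate effects scale identically
#' through `phe_hr_effect` (reflex slowing, <= 0) and `eph_hr_effect`
#' (chronotropic, > 0).
#'
#' @param baseline_sbp Baseline systolic blood pressure, mmHg.
#' @param baseline_hr Baseline heart rate, beats/min.
#' @param block_depth Maximum fractional SBP depression from the spinal
#'   block, in (0, 1).
#' @param block_tau_s Block onset time constant, seconds.
#' @param phe_potency Peak SBP rise per 25 ug phenylephrine, mmHg.
#' @param phe_hr_effect Heart-rate change per 25 ug phenylephrine,
#'   beats/min (non-positive).
#' @param eph_potency Peak SBP rise per 2 mg ephedrine, mmHg.
#' @param eph_hr_effect Heart-rate change per 2 mg ephedrine, beats/min.
#' @param phe_onset_tau_s,eph_onset_tau_s Effect-site equilibration time
#'   constants, seconds.
#' @param phe_elim_halflife_s,eph_elim_halflife_s Elimination half-lives,
#'   seconds.
#' @param noise_sd SD of Gaussian measurement noise added to the measured
#'   SBP, mmHg.
#' @param delivery_time_s Seconds from spinal anesthesia to fetal delivery.
#' @param seed Integer RNG seed for this patient's simulation.
#'
#' @return An object of class `patient_params`.
#' @export
patient_params <- function(baseline_sbp = 108.9, baseline_hr = 80,
                           block_depth = 0.3, block_tau_s = 120,
                           phe_potency = 8, phe_hr_effect = -3,
                           eph_potency = 6, eph_hr_effect = 4,
                           phe_onset_tau_s = 20, eph_onset_tau_s = 60,
                           phe_elim_halflife_s = 180,
                           eph_elim_halflife_s = 600,
                           noise_sd = 3, delivery_time_s = 1260,
                           seed = 1L) {
  stopifnot(baseline_sbp > 0, baseline_hr > 0,
            block_depth >= 0, block_depth < 1, block_tau_s > 0,
            phe_potency > 0, eph_potency > 0, phe_hr_effect <= 0,
            phe_onset_tau_s > 0, eph_onset_tau_s > 0,
            phe_elim_halflife_s > 0, eph_elim_halflife_s > 0,
            noise_sd >= 0, delivery_time_s > 0)
  structure(
    list(baseline_sbp = baseline_sbp, baseline_hr = baseline_hr,
         block_depth = block_depth, block_tau_s = block_tau_s,
         phe_potency = phe_potency, phe_hr_effect = phe_hr_effect,
         eph_potency = eph_potency, eph_hr_effect = eph_hr_effect,
         phe_onset_tau_s = phe_onset_tau_s, eph_onset_tau_s = eph_onset_tau_s,
         phe_elim_halflife_s = phe_elim_halflife_s,
         eph_elim_halflife_s = eph_elim_halflife_s,
         noise_sd = noise_sd, delivery_time_s = delivery_time_s,
         seed = as.integer(seed)),
    class = "patient_params"
  )
}

#' Virtual-population configuration
#'
#' Distributions from which [sample_patient()] draws each
#' [patient_params()] field. Each entry is a list with a `dist` tag:
#' `list(dist = "tnorm", mean, sd, lower, upper)` (truncated normal by
#' rejection), `list(dist = "unif", min, max)`,
#' `list(dist = "lnorm", meanlog, sdlog, lower, upper)`, or
#' `list(dist = "const", value)`.
#'
#' @param ... Named distribution entries overriding the defaults of
#'   [default_population()].
#' @param arm_size Optional default number of subjects per arm.
#' @return Object of class `population_config`: a named list of
#'   distribution entries plus an `arm_size` attribute.
#' @export
population_config <- function(..., arm_size = NULL) {
  fields <- utils::modifyList(default_population_fields(), list(...))
  for (nm in names(fields)) {
    d <- fields[[nm]]
    if (!is.list(d) || is.null(d$dist))
      stop("field '", nm, "' must be a list with a 'dist' tag")
  }
  structure(fields, arm_size = arm_size, class = "population_config")
}

default_population_fields <- function() {
  list(
    # trial-population moments for baseline SBP; remaining fields are
    # model calibration defaults, not asserted as ground truth
    baseline_sbp = list(dist = "tnorm", mean = 108.9, sd = 9.7,
                        lower = 85, upper = 140),
    baseline_hr = list(dist = "tnorm", mean = 80, sd = 10,
                       lower = 55, upper = 110),
    block_depth = list(dist = "unif", min = 0.15, max = 0.40),
    block_tau_s = list(dist = "unif", min = 60, max = 240),
    phe_potency = list(dist = "tnorm", mean = 8, sd = 2, lower = 2, upper = 16),
    phe_hr_effect = list(dist = "const", value = -3),
    eph_potency = list(dist = "tnorm", mean = 6, sd = 2, lower = 1, upper = 14),
    eph_hr_effect = list(dist = "const", value = 4),
    phe_onset_tau_s = list(dist = "const", value = 20),
    eph_onset_tau_s = list(dist = "const", value = 60),
    phe_elim_halflife_s = list(dist = "const", value = 180),
    eph_elim_halflife_s = list(dist = "const", value = 600),
    noise_sd = list(dist = "const", value = 3),
    # median 21 min spinal-to-delivery; sdlog 0.35 gives IQR ~ 10 min
    delivery_time_s = list(dist = "lnorm", meanlog = log(21 * 60),
                           sdlog = 0.35, lower = 8 * 60, upper = 60 * 60)
  )
}

#' @rdname population_config
#' @export
default_population <- function() population_config()

draw_field <- function(d, max_retries = 1000L) {
  switch(d$dist,
    const = d$value,
    unif = stats::runif(1, d$min, d$max),
    tnorm = {
      for (i in seq_len(max_retries)) {
        x <- stats::rnorm(1, d$mean, d$sd)
        if (x >= d$lower && x <= d$upper) return(x)
      }
      stop("truncated-normal rejection failed; check bounds")
    },
    lnorm = {
      for (i in seq_len(max_retries)) {
        x <- stats::rlnorm(1, d$meanlog, d$sdlog)
        if (x >= d$lower && x <= d$upper) return(x)
      }
      stop("lognormal rejection failed; check bounds")
    },
    stop("unknown distribution '", d$dist, "'")
  )
}

#' Draw one virtual patient from a population
#'
#' Uses the current R RNG state, so results are deterministic after
#' `set.seed()`. The patient's own simulation seed must be supplied (or
#' assigned afterwards) so closed-loop runs are reproducible per subject.
#'
#' @param pop A [population_config()].
#' @param seed Simulation seed stored in the returned parameters.
#' @return A [patient_params()] object.
#' @export
sample_patient <- function(pop = default_population(), seed = 1L) {
  stopifnot(inherits(pop, "population_config"))
  vals <- lapply(unclass(pop), draw_field)
  do.call(patient_params, c(vals, list(seed = seed)))
}

#' Noise-free untreated SBP trajectory
#'
#' The latent SBP a patient would show with the controller disabled and no
#' vasopressor: a mono-exponential decline from baseline to the block
#' plateau.
#'
#' @param params A [patient_params()].
#' @param t Time(s) since spinal anesthesia, seconds (vectorized).
#' @return SBP in mmHg at each `t`.
#' @export
untreated_sbp <- function(params, t) {
  stopifnot(inherits(params, "patient_params"), all(t >= 0))
  params$baseline_sbp *
    (1 - params$block_depth * (1 - exp(-t / params$block_tau_s)))
}

drug_pd_constants <- function(drug, params) {
  switch(drug,
    phenylephrine = list(
      ke = log(2) / params$phe_elim_halflife_s,
      k0 = 1 / params$phe_onset_tau_s,
      potency = params$phe_potency, hr_effect = params$phe_hr_effect,
      ref_dose = 25),
    ephedrine = list(
      ke = log(2) / params$eph_elim_halflife_s,
      k0 = 1 / params$eph_onset_tau_s,
      potency = params$eph_potency, hr_effect = params$eph_hr_effect,
      ref_dose = 2),
    stop("unknown drug '", drug, "'")
  )
}

# Effect-site amount for a zero-order infusion of total `amount` over
# `duration` feeding a central compartment (elimination rate ke) that
# equilibrates into the effect site at rate k0. Closed form from
# superposing the bi-exponential impulse response
#   h(t) = k0/(k0-ke) * (exp(-ke t) - exp(-k0 t)).
# Fully elementwise: all arguments recycle.
effect_site_amount <- function(tt, amount, duration, ke, k0) {
  k0 <- ifelse(abs(k0 - ke) < 1e-12, k0 * (1 + 1e-9), k0)  # equal-rate pole
  R <- amount / duration
  m <- pmin(tt, duration)
  E <- R * (k0 / (k0 - ke)) *
    ((exp(-ke * (tt - m)) - exp(-ke * tt)) / ke -
     (exp(-k0 * (tt - m)) - exp(-k0 * tt)) / k0)
  E[tt <= 0] <- 0
  E
}

impulse_peak <- function(ke, k0) {
  if (abs(k0 - ke) < 1e-12) k0 <- k0 * (1 + 1e-9)
  tstar <- log(k0 / ke) / (k0 - ke)
  (k0 / (k0 - ke)) * (exp(-ke * tstar) - exp(-k0 * tstar))
}

#' Hemodynamic effect of one vasopressor bolus
#'
#' Evaluates the SBP and heart-rate contribution of a single dose event at
#' time(s) `t`, using the linear effect-site model described in
#' [patient_params()]. Effects of multiple events superpose by summation.
#'
#' @param event One-row data.frame (or list) with fields `start_s`, `drug`,
#'   `amount`, `duration_s`, as produced by [controller_step()].
#' @param params A [patient_params()].
#' @param t Evaluation time(s), seconds (vectorized). Times before
#'   `start_s` contribute zero.
#' @return list with numeric vectors `dsbp` (mmHg) and `dhr` (beats/min).
#' @export
drug_effect <- function(event, params, t) {
  stopifnot(inherits(params, "patient_params"))
  pd <- drug_pd_constants(as.character(event$drug), params)
  scale <- 1 / (pd$ref_dose * impulse_peak(pd$ke, pd$k0))
  E <- effect_site_amount(t - event$start_s, event$amount, event$duration_s,
                          pd$ke, pd$k0)
  list(dsbp = pd$potency * scale * E, dhr = pd$hr_effect * scale * E)
}

total_drug_effect <- function(events, params, t) {
  dsbp <- numeric(length(t))
  dhr <- numeric(length(t))
  if (!is.null(events) && nrow(events) > 0L) {
    for (i in seq_len(nrow(events))) {
      eff <- drug_effect(events[i, ], params, t)
      dsbp <- dsbp + eff$dsbp
      dhr <- dhr + eff$dhr
    }
  }
  list(dsbp = dsbp, dhr = dhr)
}

#' Closed-loop simulation of one virtual patient
#'
#' Generates a beat-to-beat SBP/heart-rate stream from spinal anesthesia to
#' fetal delivery, with the controller (if any) evaluated at every decision
#' epoch on the data observed so far. Beats are spaced by the instantaneous
#' heart rate (60/hr seconds); the measured SBP is the latent SBP (untreated
#' trajectory plus superposed bolus effects) plus i.i.d. Gaussian
#' measurement noise; heart rate combines the baseline, drug chronotropic
#' effects, and a linear baroreflex `-k_baro * (sbp_latent - baseline)`.
#' The run is fully reproducible from `params$seed`, which is used locally
#' without disturbing the caller's RNG state.
#'
#' @param params A [patient_params()].
#' @param config A [controller_config()]; use algorithm `"none"` (the
#'   default) for an untreated reference run.
#' @param k_baro Baroreflex gain, beats/min per mmHg of SBP deviation from
#'   baseline (default 0.2).
#' @param hr_bounds Physiological clamp on the simulated heart rate,
#'   beats/min.
#' @return list with elements `series` (a [beat_series()] of measured
#'   values), `events` (dose-event log), `rescues` (from
#'   [detect_rescue()]), `noise` (the per-beat measurement-noise draws) and
#'   `sbp_latent` (the noise-free SBP at each beat), the latter two
#'   supporting exact reconstruction of the superposition.
#' @export
simulate_closed_loop <- function(params,
                                 config = controller_config("none"),
                                 k_baro = 0.2, hr_bounds = c(30, 180)) {
  stopifnot(inherits(params, "patient_params"),
            inherits(config, "controller_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(params$seed)

  n_guess <- ceiling(params$delivery_time_s * 180 / 60) + 8L
  time_v <- numeric(n_guess); sbp_v <- numeric(n_guess)
  hr_v <- numeric(n_guess); noise_v <- numeric(n_guess)
  latent_v <- numeric(n_guess)

  state <- new_controller_state()
  cadence <- config$decision_cadence_s
  next_epoch <- cadence
  t <- 0
  k <- 0L
  # per-event pharmacodynamic constants, kept as flat vectors so the
  # superposed effect at each beat is one vectorized evaluation
  ev_start <- ev_amount <- ev_dur <- ev_ke <- ev_k0 <- numeric(0)
  ev_sbp_coef <- ev_hr_coef <- numeric(0)
  n_events_seen <- 0L
  effect_at <- function(t) {
    if (length(ev_start) == 0L) return(c(0, 0))
    E <- effect_site_amount(t - ev_start, ev_amount, ev_dur, ev_ke, ev_k0)
    c(sum(ev_sbp_coef * E), sum(ev_hr_coef * E))
  }
  repeat {
    eff0 <- effect_at(t)
    eff <- list(dsbp = eff0[1], dhr = eff0[2])
    latent <- untreated_sbp(params, t) + eff$dsbp
    hr_t <- params$baseline_hr + eff$dhr -
      k_baro * (latent - params$baseline_sbp)
    hr_t <- min(max(hr_t, hr_bounds[1]), hr_bounds[2])
    eps <- stats::rnorm(1, 0, params$noise_sd)
    k <- k + 1L
    time_v[k] <- t
    latent_v[k] <- latent
    noise_v[k] <- eps
    sbp_v[k] <- max(latent + eps, 1)  # keep measured SBP physical
    hr_v[k] <- hr_t

    t_next <- t + 60 / hr_t
    if (t_next > params$delivery_time_s) break
    # decide at every epoch before the next beat exists, so a bolus
    # starting between beats already shapes the following beat
    if (config$algorithm != "none") {
      while (next_epoch < t_next) {
        obs <- beat_series(params$seed, params$baseline_sbp,
                           time_v[seq_len(k)], sbp_v[seq_len(k)],
                           hr_v[seq_len(k)],
                           delivery_time_s = params$delivery_time_s)
        step <- controller_step(state, obs, next_epoch, config)
        state <- step$state
        if (!is.null(step$event)) {
          ev <- step$event
          pd <- drug_pd_constants(ev$drug, params)
          scl <- 1 / (pd$ref_dose * impulse_peak(pd$ke, pd$k0))
          n_events_seen <- n_events_seen + 1L
          ev_start <- c(ev_start, ev$start_s)
          ev_amount <- c(ev_amount, ev$amount)
          ev_dur <- c(ev_dur, ev$duration_s)
          ev_ke <- c(ev_ke, pd$ke)
          ev_k0 <- c(ev_k0, pd$k0)
          ev_sbp_coef <- c(ev_sbp_coef, pd$potency * scl)
          ev_hr_coef <- c(ev_hr_coef, pd$hr_effect * scl)
        }
        next_epoch <- next_epoch + cadence
      }
    }
    t <- t_next
  }

  idx <- seq_len(k)
  series <- beat_series(sprintf("seed%d", params$seed), params$baseline_sbp,
                        time_v[idx], sbp_v[idx], hr_v[idx],
                        delivery_time_s = params$delivery_time_s)
  rescues <- detect_rescue(series, config)
  list(series = series, events = state$events, rescues = rescues,
       noise = noise_v[idx], sbp_latent = latent_v[idx])
}
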