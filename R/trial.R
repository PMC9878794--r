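#' Two-proportion sample size
#'
#' Sample size per group for a two-sided comparison of two independent
#' proportions, from the pooled-variance normal approximation
#' \deqn{n = \frac{(z_{1-\alpha/2}\sqrt{2\bar p\bar q} +
#'   z_{1-\beta}\sqrt{p_1 q_1 + p_2 q_2})^2}{(p_1-p_2)^2}}
#' with \eqn{\bar p = (p_1+p_2)/2}, rounded up. The loss fraction inflates
#' the enrollment target — the number recruited so that `n_total` subjects
#' remain analyzable after the expected losses — and is reported as
#' `n_enroll_total = ceiling(n_total / (1 - loss_fraction))`; the required
#' analyzable sample itself is not inflated.
#'
#' @param p1,p2 Anticipated incidences in the two groups, in (0, 1),
#'   unequal.
#' @param alpha Two-sided type-I error rate (default 0.05).
#' @param power Target power (default 0.80).
#' @param loss_fraction Anticipated fraction of enrolled subjects lost
#'   before analysis (default 0).
#' @return Object of class `sample_size_result`: list with
#'   `n_per_group_raw` (unrounded), `n_per_group`, `n_total`,
#'   `n_enroll_total`, and an `assumptions` record.
#' @export
#' @examples
#' sample_size_two_proportions(0.135, 0.390, loss_fraction = 0.05)
sample_size_two_proportions <- function(p1, p2, alpha = 0.05, power = 0.80,
                                        loss_fraction = 0) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1,
            alpha > 0, alpha < 1, power > 0, power < 1,
            loss_fraction >= 0, loss_fraction < 1)
  if (p1 == p2) stop("p1 and p2 must differ")
  pbar <- (p1 + p2) / 2
  qbar <- 1 - pbar
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  n_raw <- (za * sqrt(2 * pbar * qbar) +
            zb * sqrt(p1 * (1 - p1) + p2 * (1 - p2)))^2 / (p1 - p2)^2
  n_per_group <- as.integer(ceiling(n_raw))
  n_total <- 2L * n_per_group
  structure(
    list(n_per_group_raw = n_raw,
         n_per_group = n_per_group,
         n_total = n_total,
         n_enroll_total = as.integer(ceiling(n_total / (1 - loss_fraction))),
         assumptions = list(p1 = p1, p2 = p2, alpha = alpha, power = power,
                            loss_fraction = loss_fraction)),
    class = "sample_size_result"
  )
}

#' @export
print.sample_size_result <- function(x, ...) {
  a <- x$assumptions
  cat(sprintf(
    "Two-proportion sample size: %.1f%% vs %.1f%%, alpha %.2f, power %.2f\n",
    100 * a$p1, 100 * a$p2, a$alpha, a$power))
  cat(sprintf("  n per group: %d (unrounded %.2f), total analyzable: %d\n",
              x$n_per_group, x$n_per_group_raw, x$n_total))
  cat(sprintf("  enrollment target at %.0f%% loss: %d\n",
              100 * a$loss_fraction, x$n_enroll_total))
  invisible(x)
}

#' Compare binary outcomes between two arms
#'
#' Chi-squared test of the 2x2 table of event counts, with Fisher's exact
#' test substituted unless every expected cell count exceeds 5.
#'
#' @param events_a,n_a Events and subjects in arm A.
#' @param events_b,n_b Events and subjects in arm B.
#' @param correct Apply Yates' continuity correction in the chi-squared
#'   branch (default `TRUE`).
#' @return list with `test`, `statistic` (NA for the exact test),
#'   `p_value`, and the two proportions.
#' @export
compare_binary <- function(events_a, n_a, events_b, n_b, correct = TRUE) {
  stopifnot(n_a > 0, n_b > 0, events_a >= 0, events_b >= 0,
            events_a <= n_a, events_b <= n_b)
  tab <- matrix(c(events_a, n_a - events_a, events_b, n_b - events_b),
                nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected <= 5)) {
    ft <- stats::fisher.test(tab)
    list(test = "fisher_exact", statistic = NA_real_, p_value = ft$p.value,
         prop_a = events_a / n_a, prop_b = events_b / n_b)
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    list(test = "chi_squared", statistic = unname(ct$statistic),
         p_value = ct$p.value,
         prop_a = events_a / n_a, prop_b = events_b / n_b)
  }
}

#' Compare continuous outcomes between two arms
#'
#' Two-sided two-sample t-test or Mann-Whitney U test.
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 2.
#' @param method `"t"` or `"mann_whitney"`.
#' @return list with `test`, `statistic`, `p_value`.
#' @export
compare_continuous <- function(sample_a, sample_b,
                               method = c("mann_whitney", "t")) {
  method <- match.arg(method)
  if (length(sample_a) < 2L || length(sample_b) < 2L)
    stop("each sample must contain at least two values")
  if (method == "t") {
    ht <- stats::t.test(sample_a, sample_b)
    list(test = "two_sample_t", statistic = unname(ht$statistic),
         p_value = ht$p.value)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(sample_a, sample_b,
                                              exact = FALSE, correct = TRUE))
    list(test = "mann_whitney_u", statistic = unname(ht$statistic),
         p_value = ht$p.value)
  }
}

#' Run a seeded two-arm in-silico trial
#'
#' Samples virtual patients from a shared population, simulates each
#' closed-loop under its arm's controller, and summarizes both arms with
#' the outcome counts, pooled performance-error statistics, and
#' between-arm comparisons. With `paired = TRUE` (the default) both arms
#' use the same patient draws and simulation seeds — common random numbers,
#' so arm differences are attributable to the algorithms alone; with
#' `paired = FALSE` the arms are independent draws, mirroring a parallel
#' randomized design.
#'
#' @param n_per_arm Subjects per arm.
#' @param arm_algorithms Named list of two [controller_config()]s (names
#'   become arm labels); defaults to the ADIVA and DIVA presets.
#' @param pop A [population_config()].
#' @param master_seed Integer seed controlling all randomness.
#' @param paired Use common random numbers across arms (default `TRUE`).
#' @param k_baro Baroreflex gain passed to [simulate_closed_loop()].
#' @return Object of class `trial_result`: list with per-arm elements
#'   (`summaries`, `per_patient`, `pooled`, `bands`, `n_rescues`) and a
#'   `comparisons` list.
#' @export
run_trial <- function(n_per_arm,
                      arm_algorithms = list(adiva = adiva_config(),
                                            diva = diva_config()),
                      pop = default_population(),
                      master_seed = 1L, paired = TRUE, k_baro = 0.2) {
  stopifnot(n_per_arm >= 1, length(arm_algorithms) == 2L)
  if (is.null(names(arm_algorithms)))
    names(arm_algorithms) <- vapply(arm_algorithms, `[[`, "", "algorithm")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(master_seed)
  n_draws <- if (paired) n_per_arm else 2L * n_per_arm
  draw_seeds <- sample.int(.Machine$integer.max - 1L, n_draws)
  sim_seeds <- sample.int(.Machine$integer.max - 1L, n_draws)

  arm_result <- function(cfg, idx, label) {
    summaries <- NULL
    per_patient <- NULL
    n_rescues <- 0L
    for (j in seq_along(idx)) {
      i <- idx[j]
      set.seed(draw_seeds[i])
      params <- sample_patient(pop, seed = sim_seeds[i])
      run <- simulate_closed_loop(params, cfg, k_baro = k_baro)
      run$series$subject_id <- sprintf("%s_%02d", label, j)
      summaries <- rbind(summaries, outcome_summary(run$series, run$events))
      per_patient <- rbind(per_patient, series_metrics(run$series))
      n_rescues <- n_rescues + nrow(run$rescues)
    }
    list(summaries = summaries, per_patient = per_patient,
         pooled = pool_metrics(per_patient),
         bands = band_proportion(summaries), n_rescues = n_rescues)
  }

  labels <- names(arm_algorithms)
  idx_a <- seq_len(n_per_arm)
  idx_b <- if (paired) idx_a else n_per_arm + idx_a
  arms <- list(arm_result(arm_algorithms[[1]], idx_a, labels[1]),
               arm_result(arm_algorithms[[2]], idx_b, labels[2]))
  names(arms) <- labels

  a <- arms[[1]]; b <- arms[[2]]
  comparisons <- list(
    hypotension = compare_binary(sum(a$summaries$hypotension), n_per_arm,
                                 sum(b$summaries$hypotension), n_per_arm),
    hypertension = compare_binary(sum(a$summaries$hypertension), n_per_arm,
                                  sum(b$summaries$hypertension), n_per_arm),
    mdape = compare_continuous(a$per_patient$mdape, b$per_patient$mdape),
    mdpe = compare_continuous(a$per_patient$mdpe, b$per_patient$mdpe),
    wobble = compare_continuous(a$per_patient$wobble, b$per_patient$wobble),
    phenylephrine = compare_continuous(a$summaries$total_phenylephrine_ug,
                                       b$summaries$total_phenylephrine_ug),
    ephedrine = compare_continuous(a$summaries$total_ephedrine_mg,
                                   b$summaries$total_ephedrine_mg)
  )
  structure(list(arms = arms, comparisons = comparisons,
                 n_per_arm = n_per_arm, master_seed = master_seed,
                 paired = paired),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("<trial_result> %d per arm, master seed %d%s\n",
              x$n_per_arm, x$master_seed,
              if (x$paired) ", paired (common random numbers)" else ""))
  for (nm in names(x$arms)) {
    a <- x$arms[[nm]]
    cat(sprintf(
      paste0("  %s: hypotension %d/%d, readings <80%% baseline %.1f%%, ",
             "MDAPE %.1f%%, MDPE %.1f%%, wobble %.1f%%\n"),
      nm, sum(a$summaries$hypotension), nrow(a$summaries),
      100 * a$bands$prop_below_80, a$pooled$mdape, a$pooled$mdpe,
      a$pooled$wobble))
  }
  cat(sprintf("  hypotension comparison: %s p = %.3f\n",
              x$comparisons$hypotension$test,
              x$comparisons$hypotension$p_value))
  invisible(x)
}
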