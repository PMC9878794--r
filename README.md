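# divasim

Hypotension complicates up to 80% of spinal anesthetics for cesarean
delivery. Closed-loop vasopressor systems treat it automatically: a
continuous non-invasive monitor streams beat-to-beat systolic blood
pressure (SBP), and a controller bands each 10-second moving average
against the patient's pre-anesthesia baseline and fires a phenylephrine or
ephedrine bolus from a syringe pump. `divasim` implements two such
controllers and everything needed to study them *in silico*:

- **Controllers.** DIVA delivers 25 µg phenylephrine (heart rate
  ≥ 60 beats·min⁻¹) or 2 mg ephedrine (< 60) when SBP falls to 90–100% of
  baseline, and 50 µg / 4 mg below 90%, every bolus infused over 30 s.
  ADIVA adds a pre-emptive band (25 µg / 2 mg at 90–110%), a deeper tier
  (75 µg / 6 mg below 80%), and a trend rule: when the least-squares slope
  of SBP over the preceding 10 s is negative, the bolus is delivered
  rapidly (4.5/9.0/13.5 s by tier) instead of over 30 s. Both controllers
  observe a 10-s lockout after each bolus, and both flag the manual-rescue
  criteria (sustained SBP < 70% of baseline for > 3 min; bradycardia).
- **Virtual patients.** A seeded generative model of a parturient from
  spinal injection to fetal delivery: mono-exponential block-induced SBP
  decline, effect-site bolus pharmacodynamics (so dose, delivery speed and
  drug identity all matter), a linear baroreflex, and Gaussian measurement
  noise, sampled from a population whose baseline SBP matches the reported
  trial population (108.9 ± 9.7 mmHg).
- **Performance metrics.** Per-subject performance error
  PEᵢⱼ = 100·(SBPᵢⱼ − baselineᵢ)/baselineᵢ and the standard closed-loop
  summaries — MDAPE (median |PE|, inaccuracy), MDPE (median PE, bias),
  wobble (median |PE − MDPE|, variability), divergence (OLS slope of |PE|
  per minute) — pooled across subjects by Nᵢ-weighted means, plus the
  outcome definitions (hypotension: any reading < 80% of baseline;
  hypertension: > 120%; bradycardia: heart rate < 60).
- **Trials.** A seeded two-arm in-silico trial runner (χ²/Fisher,
  t/Mann–Whitney comparisons) and the pooled-variance normal-approximation
  sample size for two proportions,
  n = (z₁₋α⁄₂√(2p̄q̄) + z₁₋β√(p₁q₁ + p₂q₂))² / (p₁ − p₂)².

## Worked example

```r
library(divasim)
set.seed(42)
params <- sample_patient(seed = 7L)           # one virtual parturient
run <- simulate_closed_loop(params, adiva_config())
run$series
#> <beat_series> subject seed7: 1267 beats over 1214.1 s, baseline SBP 122.2 mmHg
head(run$events, 3)
#>   start_s          drug amount units duration_s  mode band slope_mmhg_per_s
#> 1      10 phenylephrine     25    ug       30.0  slow    1        0.4690140
#> 2      50 phenylephrine     25    ug        4.5 rapid    1       -0.2135201
#> 3      70 phenylephrine     25    ug       30.0  slow    1        0.4669914
series_metrics(run$series)
#>   subject_id n_obs   mdape    mdpe   wobble divergence
#> 1      seed7  1267 10.0607 10.0607 2.301223  0.2506768
```

The event log reads directly as controller behavior: at t = 10 s the
moving-average SBP had drifted into ADIVA's pre-emptive 90–110% band with
a rising trend (slope +0.47 mmHg·s⁻¹), so 25 µg phenylephrine went in
slowly over 30 s; at t = 50 s the trend was falling (−0.21), so the same
tier-1 dose was pushed rapidly over 4.5 s. The per-subject metrics say the
controller held SBP a median of 10.1% *above* baseline (MDPE = MDAPE,
i.e. essentially never below it) with 2.3% wobble.

A paired two-arm trial (common random numbers, so arm differences are
purely algorithmic):

```r
run_trial(10, master_seed = 2026L)
#> <trial_result> 10 per arm, master seed 2026, paired (common random numbers)
#>   adiva: hypotension 0/10, readings <80% baseline 0.0%, MDAPE 10.1%, MDPE 9.9%, wobble 2.8%
#>   diva: hypotension 0/10, readings <80% baseline 0.0%, MDAPE 2.7%, MDPE 0.2%, wobble 2.2%
#>   hypotension comparison: fisher_exact p = 1.000
```

ADIVA's pre-emptive band keeps SBP further above baseline with more
fluctuation than DIVA — higher MDAPE, MDPE and wobble — the same ordering
the clinical comparison of these controllers reported.

A command-line front end with `simulate`, `run-controller`, `metrics`,
`trial` and `samplesize` subcommands ships at
`system.file("cli", "divasim.R", package = "divasim")`; every subcommand
taking `--seed` is byte-reproducible.

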