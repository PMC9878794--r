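---
title: "Closed-loop vasopressor delivery in silico: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop vasopressor delivery in silico: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divasim)
```

`divasim` studies automated vasopressor bolus controllers for spinal
hypotension during cesarean delivery. This vignette is the package's
account of the science it implements: the controller logic and the
conventions chosen where the published descriptions leave room, the
virtual-patient model and what it does and does not emulate, the pooled
performance-error statistics, and the trial and power machinery.

## The control problem

After intrathecal local anesthetic, sympathetic blockade drops systemic
vascular resistance and systolic blood pressure (SBP) falls over minutes;
untreated, a large majority of parturients cross the conventional
hypotension threshold of 80% of their pre-anesthesia baseline. A
closed-loop system measures SBP beat-to-beat with a continuous
non-invasive monitor, forms a 10-second moving average, and doses
phenylephrine (a pure α-agonist that raises SBP and reflexly slows the
heart) or ephedrine (mixed-acting, raises both SBP and heart rate) from
syringe pumps. The controller's entire state is the banded SBP fraction,
the latest heart rate, a short trend estimate, and a lockout clock.

## Controller logic and boundary conventions

Both controllers evaluate every `decision_cadence_s` (10 s) on the
trailing 10-s mean SBP as a fraction of baseline:

| fraction of baseline | ADIVA | DIVA |
|---|---|---|
| ≥ 110% | — | — |
| 100–110% | 25 µg phe / 2 mg eph | — |
| 90–100% | 25 µg phe / 2 mg eph | 25 µg phe / 2 mg eph |
| 80–90% | 50 µg phe / 4 mg eph | 50 µg phe / 4 mg eph |
| < 80% | 75 µg phe / 6 mg eph | 50 µg phe / 4 mg eph |

Drug choice is gated on heart rate at 60 beats·min⁻¹: phenylephrine at or
above, ephedrine below. ADIVA additionally regresses SBP on time over the
trailing 10 s of beats (ordinary least squares) and, when the slope is
strictly negative, infuses rapidly — 4.5, 9.0 or 13.5 s for tiers 1/2/3 —
instead of the 30-s slow infusion; DIVA always infuses over 30 s. A 10-s
lockout follows every bolus.

Where the published description does not pin a convention, the package
fixes one and keeps it consistent:

- **Band edges are lower-inclusive** (e.g. ADIVA's bands are [0.80, 0.90),
  [0.90, 1.10)): a fraction exactly at 0.80 takes the milder tier, and
  exactly 1.10 (ADIVA) or 1.00 (DIVA) is untreated. This makes the
  treatment region a half-open union with no double-owned points.
- **Heart rate exactly 60** selects phenylephrine: the published gates are
  "> 60" and "< 60", and phenylephrine is the default obstetric pressor,
  so the ephedrine path is reserved for genuinely bradycardic states.
- **Zero, positive or indeterminate slope** (fewer than two distinct beat
  times in the window) is "not trending downward" and yields the slow
  30-s infusion — the literal reading, and the conservative default
  against overshoot.
- **Rapid duration is linear in tier** (4.5/9.0/13.5 s): only the range
  endpoints are published ("4.5 to 13.5 s depending on dose"); a fixed
  pump flow rate makes duration proportional to volume, which matches
  both endpoints.
- **The lockout starts when the infusion ends** (`busy_until = start +
  duration + lockout`), so a slow bolus occupies the controller for 40 s;
  new decisions are suppressed during delivery. Both arms share this
  convention.
- **The trend runs on raw beats**, not the 10-s epoch means (which would
  give at most two points in a 10-s window).
- **Rescue flags**: sustained hypotension requires SBP < 70% of baseline
  over a contiguous beat stretch strictly longer than 180 s and is
  timestamped at stretch start + 180 s, the first instant the criterion
  holds. The bradycardia rescue threshold defaults to 45 beats·min⁻¹ —
  deliberately below the 60 beats·min⁻¹ ephedrine gate and outcome
  definition, since heart rates between 45 and 60 are already handled
  pharmacologically.

## The virtual patient

No patient-level model accompanies the clinical description, so the
generator is the simplest structure that makes every controller feature
consequential — dose, drug identity, delivery speed and timing all change
the trajectory — while staying exactly reconstructable in tests.

**Untreated SBP** declines mono-exponentially,
`baseline × (1 − depth × (1 − exp(−t/τ)))`, with depth ~ U(0.15, 0.40)
and τ ~ U(60, 240) s: onset over one to four minutes to a plateau 15–40%
below baseline, deep enough that untreated patients reliably cross the
80% threshold.

**Bolus pharmacodynamics** are linear: each bolus is a zero-order
infusion (amount/duration) into a central compartment with first-order
elimination (half-life 180 s phenylephrine, 600 s ephedrine), which
equilibrates into an effect site with time constant 20 s (phenylephrine)
or 60 s (ephedrine). The SBP rise is the effect-site amount normalized so
that an ideal instantaneous reference bolus (25 µg / 2 mg) peaks at
exactly the patient's potency (phenylephrine ~ N(8, 2²) mmHg per 25 µg,
ephedrine ~ N(6, 2²) per 2 mg, truncated positive). A 4.5-s rapid bolus
therefore peaks within a few percent of potency, while the same dose over
30 s peaks visibly lower and later — the mechanism the ADIVA trend rule
exploits. Heart-rate effects scale identically (−3 beats·min⁻¹ per 25 µg
phenylephrine, +4 per 2 mg ephedrine), and a linear baroreflex
(−0.2 beats·min⁻¹ per mmHg above baseline) couples pressure back to rate.
Effects superpose additively across boluses; the closed forms are exact
solutions of the two-state linear ODE, verified against numerical
integration in the test suite.

**Sampling and noise.** Beats are spaced by the instantaneous heart rate
(60/HR seconds), preserving the beat-to-beat character of the monitor
stream; i.i.d. Gaussian noise (SD 3 mmHg) is added to the *measured* SBP
only, leaving the latent state deterministic so the superposition
`measured = untreated + Σ bolus effects + noise` is testable to machine
precision. Baseline SBP is drawn N(108.9, 9.7²) truncated to [85, 140]
mmHg — the reported trial population — baseline heart rate N(80, 10²)
truncated to [55, 110], and run length lognormal with median 21 min
(sdlog 0.35, giving an interquartile range of about 10 min, truncated to
8–60 min). These calibration values are exposed in `population_config()`
and are defaults, not assertions about any real cohort.

**What the generator does not emulate** — and hence what passing tests do
not establish about real patients: measurement artifacts and dropouts,
within-patient tachyphylaxis or drug-response correlation, uteroplacental
physiology and fetal outcomes, nausea, and surgical events (exteriorization,
hemorrhage). Controller effectiveness results here are statements about
the model, not effect-size predictions for a ward.

## Performance statistics

For subject *i* with baseline Bᵢ and readings SBPᵢⱼ at times tᵢⱼ (minutes):

- PEᵢⱼ = 100 (SBPᵢⱼ − Bᵢ)/Bᵢ, computed on every beat in the window from
  spinal anesthesia to delivery (a 10-s-epoch variant is available via
  `moving_average_epochs()`, but beat-level is the default since
  monitoring was continuous);
- MDAPEᵢ = median |PEᵢⱼ| (inaccuracy), MDPEᵢ = median PEᵢⱼ (bias),
  wobbleᵢ = median |PEᵢⱼ − MDPEᵢ| (variability), divergenceᵢ = OLS slope
  of |PEᵢⱼ| on tᵢⱼ in %·min⁻¹ (accuracy drift);
- pooled statistics are Nᵢ-weighted means, Nᵢ the number of PE values of
  subject *i*, so subjects with longer recordings weigh proportionally.

Even-length medians take the midpoint of the central pair. Divergence is
undefined (NA) for subjects with one reading or no time spread, and such
subjects are dropped from the pooled divergence weighting only. Note that
MDAPEᵢ ≥ |MDPEᵢ| is *not* an invariant — medians do not commute with the
absolute value — so the tests assert symmetry and scale-equivariance
properties instead. Outcome bands share edges exclusively: "below 80%" is
strict, "within 80–120%" is closed on both ends, hypertension is strictly
above 120%. Arm-level band proportions pool counts
(Σ numerators / Σ denominators), never average per-subject proportions.

## Trials and sample size

`run_trial()` samples patients from a shared population and simulates
each arm. By default arms are **paired** (common random numbers: same
patients, same seeds, different algorithm), which removes between-patient
variance from the arm contrast and makes "identical algorithms give
identical arms" an exact invariant; `paired = FALSE` gives the
parallel-design analogue. Binary endpoints use the χ² test, replaced by
Fisher's exact test unless every expected cell exceeds 5; continuous
endpoints use the two-sided t or Mann–Whitney test.

The sample-size routine implements the pooled-variance normal
approximation for two proportions. With incidences 13.5% vs 39.0%,
two-sided α = 5% and power 80% it gives 45.54 → 46 per group, 92
analyzable in total. The 5% anticipated loss (failed spinal anesthesia)
inflates the *enrollment* target, ⌈92/0.95⌉ = 97, rather than the
analyzable sample: this is the only reading under which the published
figures (92 required, 97 enrolled) are mutually consistent, and the
result object reports the unrounded, per-group, total and enrollment
numbers separately so the reconciliation is visible. Alternative
formulas (arcsine, continuity-corrected) differ by one or two subjects
per group; the implemented formula is the one that reproduces the design.

## Numerical and scale choices

Controller arithmetic runs in seconds; divergence converts to minutes at
the metrics boundary. Slopes use the closed-form least-squares estimator
(the test suite cross-checks against `lm()`), medians use `stats::median`
(cross-checked against sorting oracles). Simulated runs draw from an RNG
stream seeded per patient and restore the caller's RNG state on exit, so
arm-level runs are order-independent. Measured SBP is floored at 1 mmHg
(the noise SD makes this unreachable in practice; it guards container
invariants). Default test and acceptance problem sizes — 200 randomized
metric instances of up to 5 subjects × 50 readings, 20-patient timing
sweeps, 50-patient effectiveness runs, 20-per-arm trials — were chosen as
the smallest sizes at which every property is exercised across all bands,
both drugs, and both delivery modes.

## Known limitations

ADIVA's pre-emptive 90–110% band means it doses at exactly baseline;
in this idealized simulator (no actuation lag, reliable drug response)
that keeps the controlled SBP *above* baseline almost always, so
simulated hypotension incidence is much lower than clinically observed,
and simulated ADIVA consumes *more* phenylephrine than DIVA where the
clinical comparison observed less. The qualitative orderings that are
robust in the model — ADIVA showing higher MDAPE, MDPE and wobble than
DIVA, and both controllers cutting hypotensive readings relative to no
treatment — are the quantities the acceptance script reports.
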