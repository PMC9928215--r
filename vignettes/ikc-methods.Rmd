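---
title: "Individualizing multi-activity gait: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualizing multi-activity gait: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ikcgait)
```

## The model

`ikcgait` treats one stride as a phase-normalized trajectory: joint angles
(degrees) at 150 evenly spaced samples of the gait cycle, from heel strike
to the next ipsilateral heel strike. The grid is left-closed — sample 1 sits
at 0% of the cycle and sample 150 at (149/150)·100%, with no duplicated
endpoint — so that the cycle tiles periodically and resampling a curve
already on the grid is the identity. A *task* is an operating point within
an ambulation mode: walking is a speed × treadmill-incline pair, running a
speed on level ground, stair ascent/descent a stair-inclination magnitude
(direction is carried by the mode, so descent inclines are stored unsigned).

A subject's individuality at a task and joint is their **Individual
Kinematic Contribution (IKC)**: the pointwise difference between their
representative cycle and the leave-one-out (LOO) mean of the other
subjects,

$$C_{\varphi,\chi,\eta} = d_{\varphi,\chi,\eta} - \bar d_{\varphi,\chi},
\qquad \varphi = 1,\dots,150 .$$

Two conventions here were genuinely open and are fixed as follows:

* **Equal subject weighting.** The LOO mean averages *per-subject mean
  cycles*, not pooled strides, so a subject recorded with more strides does
  not dominate the reference. With per-subject means $m_i$ this gives the
  closed form $\bar d_{-i} = (\sum_j m_j - m_i)/(n-1)$, and the identity
  $C_i = \frac{n}{n-1}(m_i - \bar m)$, which the test suite checks to
  1e-9° together with the zero-sum property $\sum_\eta C_{\varphi,\chi,\eta} = 0$.
* **Sign conventions pass through.** All computations are differences of
  like-convention curves, so dataset-native sagittal sign conventions are
  never rewritten.

### Transfer and scoring

Individuality is measured once per mode at a *baseline* task — walking
1.0 m/s level, running 2.0 m/s, stairs 30° — and transferred by pure
addition: the prediction at target task $\chi$ is the LOO mean at $\chi$
plus the baseline IKC. No phase re-alignment or amplitude scaling is
applied; phase individualization is deliberately out of scope. Two methods
are compared: `walking_baseline` transfers the level-ground walking IKC to
every mode, `modal_baseline` uses each mode's own baseline (for walking the
two coincide, so walking is evaluated once).

Predictions are scored with the cycle RMSE between predicted and observed
IKC (equivalently, between predicted and observed trajectories — the common
LOO mean cancels), and compared with the benchmark RMSE obtained with a
zero IKC, i.e. the error of the non-individualized population average.
*Improvement* is benchmark minus individualized RMSE (degrees, positive =
helped); group summaries report the mean improvement, the ratio-of-means
percentage (100 · mean improvement / mean benchmark RMSE — the source
convention for percentages is not stated, and the ratio of means is robust
to near-zero single-record benchmarks), and the fraction of records with
strictly positive improvement, where one "trial" is one
(subject × target task × joint × method) record.

### Stride policies

Walking and running tasks have ~30 strides, enough to guard against the
baseline IKC overfitting its own noise: strides are split into halves and
the baseline IKC is computed from the training half only. The split is
deterministic and *interleaved* (1st, 3rd, 5th … strides train; 2nd, 4th, …
validate) rather than first-half/second-half, so slow drift across a
30-second treadmill trial is balanced between halves. When the target task
is the baseline task itself, the observed IKC uses the held-out
validation-half mean (per-stride validation would be an alternative; the
half-mean is used because the transferred IKC is itself a mean-level
object). Observed IKCs at all *other* target tasks use all strides, and all
LOO means use the other subjects' full stride sets — overfitting only
concerns the same-subject baseline IKC.

Stair tasks have 5 strides: too few to split, so all strides train the
stair baseline IKC and the stair baseline task is omitted from the
evaluated targets — for *both* transfer methods, keeping the per-mode
designs comparable and the ANOVA balanced.

## Statistics

Each mode gets a main-effects, fixed-factor ANOVA of RMSE (untransformed,
degrees) with the mode-appropriate factors: walking — subject, velocity,
incline, joint, method; running — velocity, joint, method; stairs —
subject, incline, joint, method. Interactions are not modeled, and subject
enters as a fixed factor (a random-subject variant would change the error
strata; fixed matches the factor-list design). The non-individualized
benchmark is included as a `method` level (`"none"`) so post-hoc contrasts
of individualized vs non-individualized fits exist. The designs produced by
`evaluate_all()` are balanced, so sequential sums of squares equal marginal
ones. Post-hoc comparisons use Tukey-Kramer adjusted pairwise contrasts of
method within (mode, joint), via `TukeyHSD()`, which handles unequal group
sizes. Under a null simulation the per-factor type-I error is confirmed at
the nominal 5% (±2 percentage points over 1000 replicates) in the test
suite.

## The synthetic generator

`synthetic_config()` + `generate_gait()` produce cohorts whose
individuality structure is known exactly, so the pipeline can be verified
end to end. The generative model, per (mode, joint):

* a fixed population mean cycle, an order-6 Fourier series with
  per-joint coefficient templates shaped like sagittal gait curves, whose
  harmonic amplitude scales linearly with task speed and incline;
* per subject, a hierarchy of smooth deviation fields drawn in Fourier
  coefficient space: a subject-common field $u$, mode fields
  $m = \rho_{mode} u + \sqrt{1-\rho_{mode}^2}\, v$, and task deviations
  $\rho_{task} m + \sqrt{1-\rho_{task}^2}\, w$. Coefficient variances are
  normalized so a field's RMS amplitude over the cycle is
  $\sigma_{subj}$ (half the variance in the constant offset, half spread
  over the harmonics);
* per stride, independent smooth noise (order-3 Fourier, RMS
  $\sigma_{noise}$).

Deviation fields are band-limited because observed IKCs are smooth curves;
white per-sample noise would be unrealistically rough at 150 samples.

Defaults are the study conditions the package targets: 10 subjects; walking
at {0.8, 1.0, 1.2} m/s × {−10, −5, 0, +5, +10}° (decline tasks are included
by default; the grid is configurable), running at {1.8, 2.0, 2.2, 2.4} m/s,
stairs at {20, 25, 30, 35}°; 30 strides per walking/running task, 5 per
stair task. Where the emulated design gives no value, parameters were fixed
once at field-realistic levels: $\sigma_{subj} = 4°$ puts benchmark RMSEs
near 4° (within the 2–8° range typical of observed inter-subject deviation
magnitudes); $\sigma_{noise} = 1°$ is a plausible stride-to-stride
repeatability; $\rho_{task} = 0.95$ encodes strong within-mode persistence
(the regime in which baseline transfer is worthwhile); $\rho_{mode} = 0.35$
encodes weak cross-mode sharing. Persistence is a single correlation per
level rather than a task-distance kernel — the simplest structure
consistent with baseline transfer; it cannot represent, e.g., transfer that
degrades gradually with task distance, or cross-mode sharing that differs
by joint (in real cohorts the hip shares far more individuality across
modes than the ankle). Passing tests on this generator therefore
demonstrate correctness of the estimation and scoring machinery, not
biomechanical fidelity: no musculoskeletal constraints, no gait-event
timing variability, no left/right asymmetry.

The generator stores its injected deviations alongside the data
(`gait_truth()`, `truth_ikc()`), giving the oracle used by the tests: with
zero stride noise the empirical IKC equals the injected one to 1e-9°; with
$\rho_{task}=1$ and zero noise, modal transfer is exact and every record's
improvement equals its benchmark RMSE.

### What estimation noise does under the null

With $\sigma_{subj}=0$ there is no individuality to transfer, and the
transferred baseline IKC is pure estimation noise. Adding independent noise
to the prediction inflates the expected squared error, so the mean
improvement is negative and — because the baseline IKC's noise variance is
comparable to the observed IKC's — the fraction of improved records falls
well below one half (it would approach ½ only if the baseline IKC were
estimated essentially without noise). The test suite measures exactly this
behavior over 200 replicates; users comparing methods on real data should
likewise expect the *no-individuality* regime to show small negative mean
improvements, not a coin flip.

## Numerical choices

* Phase grid: 150 points, left-closed; `resample_cycle()` interpolates
  linearly, extends short cycles periodically, and is exact on constants
  and affine ramps and idempotent on the target grid.
* Degenerate inputs raise classed errors: single-stride groups cannot be
  split (`ikcgait_split_error`), single-subject tasks have no LOO mean
  (`ikcgait_loo_error`), single-level factors are rejected from the ANOVA
  by name (`ikcgait_design_error`), malformed CSVs report the offending
  column, stride, or row.
* Ties: a stride count of 2k+1 puts the extra stride in the training half.
* Determinism: one seed drives generation and the full pipeline;
  `run_full_analysis()` outputs are byte-identical across reruns of the
  same configuration and its manifest records seed, versions, and a
  configuration hash.

## Problem sizes

The test suite runs the full 10-subject default grid once (≈2.7 M rows) and
otherwise uses reduced cohorts (3–10 subjects, 2–6 tasks, 4–30 strides)
chosen so that replicated checks — 200-replicate null calibration,
1000-replicate ANOVA calibration — complete in a few minutes while keeping
their Monte-Carlo standard errors a factor of ~3 below the asserted
tolerances.

## Limitations

Kinetics (joint moments/powers), transitional and non-steady motions,
impaired gait, and phase/toe-off individualization are out of scope. The
bilateral-symmetry assumption of the data layout (left and right strides
pooled per subject) is inherited, not tested. Statistical results use
fixed-effects ANOVA on possibly correlated records (same subject appears in
many records); a mixed-effects treatment is a deliberate non-goal.
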