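# ikcgait

Quantify, transfer, and score gait individuality across walking, running,
and stair climbing.

## The problem

Able-bodied lower-limb kinematics are highly individual: each person's
ankle, knee, and hip angle trajectories deviate from the population average
in a way that is stable over time. Assistive devices (powered prostheses,
exoskeletons) that track able-bodied reference trajectories must be tuned to
each user, and tuning every combination of activity, speed, and incline in a
clinic is infeasible. If a subject's deviation pattern *persists* across the
tasks of an ambulation mode, measuring it once at a single, easy-to-replicate
baseline task is enough to individualize the whole mode.

`ikcgait` implements that analysis. Individuality is the **Individual
Kinematic Contribution (IKC)**: at gait phase φ = 1,…,150 of task χ, subject
η's deviation from the leave-one-out (LOO) mean of the other subjects,

    C[φ, χ, η] = d[φ, χ, η] − d̄[φ, χ]

where `d` is the subject's phase-normalized joint-angle cycle and `d̄` the
equal-weight mean cycle of the remaining subjects. The IKC measured at a
baseline task χ_B (walking 1.0 m/s level ground; running 2.0 m/s; stairs
±30°) is added to the LOO mean of any other task to predict that subject's
kinematics there. Predictions are scored over the cycle with

    RMSE[χ, η] = sqrt( Σ_φ (C[φ, χ_B, η] − C[φ, χ, η])² / I ),   I = 150,

and compared with the non-individualized benchmark (C[φ, χ_B, η] = 0, i.e.
using the population average as-is). The statistical layer reproduces the
per-mode N-way fixed-effects ANOVA of RMSE (factors: subject, velocity,
incline, joint, individualization method, as applicable per mode) and
Tukey-Kramer post-hoc contrasts of method within joint.

A synthetic multi-activity gait generator with controllable individuality
(subject deviation scale, within-mode and cross-mode persistence, stride
noise) makes every stage testable against known ground truth, without any
external dataset.

## Worked example

```r
library(ikcgait)

cfg     <- synthetic_config(seed = 7)   # 10 subjects, full task grid
gait    <- generate_gait(cfg)           # long tibble, 1 row per phase sample
records <- evaluate_all(gait)           # RMSE per subject x task x joint x method
summarize_improvement(records)
#> # A tibble: 21 × 7
#>    mode         joint method  n_records mean_improvement_deg percent_improvement
#>  1 run          ankle modal_…        40                 2.49                63.5
#>  2 run          ankle walkin…        40                -2.55               -65.0
#>  3 run          hip   modal_…        40                 2.52                63.9
#>  ...
```

`mean_improvement_deg` is the benchmark RMSE minus the individualized RMSE
(degrees; positive = individualization helped), `percent_improvement` the
ratio-of-means percentage, and `fraction_improved` the share of
(subject × task × joint) records that improved. Here modal transfer improves
the running-ankle fit by ~2.5° (64%), while transferring the *walking* IKC
to running degrades it — this synthetic cohort was generated with high
within-mode persistence and weak cross-mode persistence, and the pipeline
recovers exactly that structure.

```r
tukey_method_contrast(records, "run", "ankle")
#> # A tibble: 3 × 7
#>   mode  joint contrast                    estimate conf.low conf.high adj.p.value
#> 1 run   ankle none-modal_baseline             2.55     1.80      3.30    1.74e-12
#> 2 run   ankle walking_baseline-modal_ba…      5.04     4.24      5.83    3.06e-14
#> 3 run   ankle walking_baseline-none           2.49     1.73      3.24    5.12e-12
```

Modal individualization has significantly lower RMSE than both the
non-individualized benchmark and walking-baseline transfer at the running
ankle. `anova_rmse(records, "run")` gives the corresponding N-way ANOVA
(`tidy()`/`glance()` methods included), `autoplot(records)` draws the
improvement box plots, and `run_full_analysis(run_config(...))` executes the
whole pipeline — data, records, summaries, ANOVA and post-hoc tables, and a
reproducibility manifest — into an output directory, deterministically for a
given seed. Real data enter through `read_gait_csv()`, a long-form CSV with
one row per phase sample per stride (see `?read_gait_csv`).

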