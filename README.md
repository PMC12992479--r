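# bireach

Simulation and analysis of bimanual reaching interference experiments.

When one arm adapts to a perturbation — a rotated cursor, a
velocity-dependent force field, or both — how much of that adaptation
leaks into the other arm? `bireach` simulates a four-group bimanual
reaching experiment built around that question and ships the complete
analysis pipeline for it: per-trial kinematic error measures,
force-channel kinetics, and the mixed-design ANOVA battery with
post-hoc tests.

## The experiment

Four groups of 15 simulated participants make simultaneous 10 cm
reaches with both hands to forward (90°) and backward (270°) targets,
in four blocks — visual baseline (VBL, 30 trials), kinesthetic baseline
(KBL, 30; the left hand loses its cursor here and never gets it back),
exposure (EXP, 250) and post-exposure (POST, 50). During exposure the
right hand is perturbed:

| group      | right-hand perturbation                         |
|------------|-------------------------------------------------|
| control    | none                                             |
| visuomotor | 45° clockwise cursor rotation                    |
| dynamic    | 20 N·s/m clockwise velocity-dependent curl field |
| combined   | both                                             |

On 20 % of left-hand trials the hand is caught in a stiff force channel
(20 N/cm, 0.25 mm wide, 5 N·s/m damping) so the lateral force it
applies can be measured.

## The model

Each hand is a 1 kg point mass under a PD controller (kp = 800 N/m,
kd = 40 N·s/m) tracking a minimum-jerk reference
s(τ) = d(10τ³ − 15τ⁴ + 6τ⁵). Each perturbation drives a single-rate
state-space learner x_{t+1} = a x_t + b (P − x_t) (a = 0.995,
b = 0.08), whose state re-aims the reach (rotation) or adds a
feedforward opposing force (curl). The left hand's aim is biased by a
fraction of the right hand's adapting states — the interlimb crosstalk
that the experiment is designed to detect. See the methods vignette
(`vignettes/methods.Rmd`) for the full model, the measure definitions
and what is deliberately not modeled.

## Worked example

```r
library(bireach)
cfg <- reach_config()
print(cfg)
#> Bimanual reaching experiment configuration
#>   groups: control, visuomotor, dynamic, combined (15 participants each)
#>   blocks: VBL 30 / KBL 30 / EXP 250 / POST 50 trials
#>   reach: 10 cm to 90/270 deg; timing window 300-450 ms
#>   perturbations: 45 deg CW rotation, 20 N.s/m curl (CW)
#>   channel: 2000 N/m, half-width 0.000125 m, 20% of left-hand trials

report <- run_pipeline(cfg, seed = 1)   # ~15 s: simulate, measure, analyze
print(report)
#> Bimanual interference pipeline report
#>   seed 1, 10 planned mixed ANOVAs, 20 simple-effects tests, 20 post-hoc tables
#>   landmark fractions: f_peak=0.388 f_ballistic=0.778
#>   right_adaptation_rmse    group F(3,56)=4062.81 p=1.85e-65 ges=0.99
#>   right_adaptation_ide     group F(3,56)=3502.23 p=1.16e-63 ges=0.99
#>   right_aftereffect_rmse   group F(3,56)=3180.95 p=1.69e-62 ges=0.99
#>   left_interference_rmse   group F(3,56)=265.77 p=4.43e-33 ges=0.90
#>   left_interference_ide    group F(3,56)=239.73 p=6.48e-32 ges=0.91
#>   left_interference_iee    group F(3,56)=225.45 p=3.18e-31 ges=0.91
#>   left_interference_fee    group F(3,56)=222.59 p=4.42e-31 ges=0.91
#>   kinetic_peak_velocity    group F(3,56)=94.24 p=7.21e-22 ges=0.75
#>   kinetic_ballistic_end    group F(3,56)=95.31 p=5.54e-22 ges=0.75
#>   kinetic_movement_end     group F(3,56)=96.09 p=4.58e-22 ges=0.75
```

The headline result — left-hand interference in the last 30 exposure
trials, ordered across groups:

```r
bp <- bin_and_phase(report$measures)
interference_summary(bp$phases)
#>         group abs_mean_ide_deg    mean_rmse
#> 1:    control       0.01332145 0.0008863728
#> 2: visuomotor       5.60832722 0.0374166961
#> 3:    dynamic       2.14055345 0.0025623430
#> 4:   combined       7.66939051 0.0597819448
```

The unperturbed control group shows essentially no left-hand deviation,
the dynamic group a small bias, the visuomotor group a clear one, and
the combined group the largest — the crosstalk ordering the experiment
is built to detect. `run_pipeline(..., out_dir = "results")` writes all
ANOVA, post-hoc, t-test, bin-mean and force tables as TSV plus a JSON
manifest; `inst/cli/bireach.R` exposes the same workflow as a
command-line tool (`simulate`, `analyze`, `all`).

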