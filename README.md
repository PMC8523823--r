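# anklemsk

EMG-driven musculoskeletal estimation of **ankle joint moment and
rotational stiffness** during the stance phase of walking, with model
calibration and curve-level statistics across walking-surface conditions.

Gait labs that want more than quasi-stiffness (the slope of the measured
moment–angle loop) estimate ankle stiffness from the muscles themselves:
surface EMG of tibialis anterior (TA), soleus (SOL) and the two
gastrocnemii (GAL, GAM) drives a Hill-type model of each muscle–tendon
unit (MTU), and joint moment and stiffness follow from MTU forces,
stiffnesses and moment arms. `anklemsk` implements that chain end to end:

1. **EMG conditioning** — band-pass 30–450 Hz, rectification, low-pass
   6 Hz (zero-phase 2nd-order Butterworth), normalization to the
   across-trial maximum → excitations `e(t) ∈ [0,1]`.
2. **Activation dynamics** — recursive filter
   `u(t) = α e(t−d) − β₁ u(t−1) − β₂ u(t−2)` with `β₁ = C₁+C₂`,
   `β₂ = C₁·C₂`, `α − β₁ − β₂ = 1` (unit DC gain), electromechanical
   delay `d` = 40 ms, then the nonlinear shaping
   `a = (e^{Au} − 1)/(e^A − 1)`, `A ∈ [−3, 0]`.
3. **MTU kinematics** — per-muscle polynomial surrogates `l_mt(θ)`,
   `r(θ)` with analytic `dr/dθ`; no extrapolation outside the fit range.
4. **MTU dynamics** — Hill fiber force
   `F_m = F_max [f(l̃)f(ṽ)a + f_P(l̃)]` in series with the piecewise
   tendon model (quadratic toe `1480.3 F_max ε²` to ε = 0.0127, linear
   `(37.5ε − 0.2375) F_max` beyond); per-step elastic-tendon equilibrium
   `F_t = F_m cosΦ` solved with an implicit fiber-velocity scheme
   (compiled); stiffnesses `K_m`, `K_t`, `K_mt = (1/K_m + 1/K_t)⁻¹`.
5. **Joint mechanics** — `τ = Σ F_mt,i · r_i` (dorsiflexion positive) and
   `K_ankle = Σ (K_mt,i r_i² − F_mt,i dr_i/dθ)`, the exact
   moment–angle derivative at frozen activation; 101-node stance-percent
   curves; NRMSE fit metric (RMSE over RMS of the experimental moment).
6. **Calibration** — bounded Nelder–Mead (sine-squared reparameterized,
   Latin-hypercube multistarts) minimizing the mean squared moment error
   `J` against an inverse-dynamics moment; bounds: `C₁, C₂ ∈ [−1,1]`,
   `A ∈ [−3,0]`, group strength `γ ∈ [0.5,1.5]`, optimal fiber length
   ±2.5%, tendon slack length ±5%.
7. **1D SPM** — one-way repeated-measures ANOVA F-field over the stance
   grid with permutation (suprathreshold-cluster) inference across the
   four surface conditions.

A seeded synthetic gait generator with known ground truth
(`synthetic_truth()`, `generate_dataset()`) stands in for raw gait data
and underpins all end-to-end validation: excitation bursts phased for
walking, a canonical stance ankle-angle trajectory, excursion-consistent
geometry, forward-simulated "experimental" moments with additive noise,
and a configurable surface-compliance effect on plantar-flexor drive.

## Worked example

```r
library(anklemsk)

truth <- synthetic_truth()                  # ground-truth plant, seeded
trial <- generate_trial(truth, "epe", 1)    # most compliant surface
trial
#> gait_trial: subject 1, epe, trial 1; 71 samples @ 100 Hz (envelope EMG), peak |tau_ID| 240.9 N m

model <- ankle_model(truth$activation, truth$muscles, truth$geometry,
                     truth$gamma_df, truth$gamma_pf)
estimate_trial(model, trial)
#> joint_series (subject 1, epe, trial 1): peak |tau| 238.9 N m, peak K 69 N m/rad, NRMSE 0.015, 0.0% clamped steps

ds <- generate_dataset(synthetic_truth(surface_effect = 0.3, seed = 8),
                       n_subjects = 8, trials_per_condition = 2)
permutation_inference(curves_from_trials(ds, "tau_id"),
                      n_perm = 199, seed = 8)
#> spm_result: F(3,21) field, threshold 6.978 (alpha=0.05, 199 random permutations)
#>   cluster 1: 24.9-100.0% stance (extent 75.1), p=0.0050 *
```

Reading the output: the trial's experimental moment peaks at ~241 N m of
plantar flexion (dorsiflexion-positive sign convention, so the peak is
negative); the forward chain reproduces it to NRMSE 0.015 (the residual
is the generator's additive moment noise); and with a +30%-per-level
plantar-flexor drive effect, the repeated-measures SPM flags one
suprathreshold cluster from ~25% of stance to toe-off at p = 0.005 —
the mid/late-stance window where the plantar flexors act.

Per-subject calibration recovers model parameters from trials alone:

```r
trials <- lapply(1:4, function(i) generate_trial(synthetic_truth(noise_sd = 0), "plate", i))
res <- calibrate(trials, calibration_spec(seed = 42))   # ~2 min, 4 multistarts
res$nrmse_mean        # recovered-moment NRMSE, ~4e-4 on zero-noise data
res$par["gamma_pf"]   # plantar-flexor strength, recovered to ~0.002 of truth (1.1)
```

The pipeline stages (`run_simulate()`, `run_calibrate()`,
`run_estimate()`, `run_compare()`) wrap these functions with CSV/YAML
I/O and logging; `inst/scripts/anklemsk-pipeline.R` exposes them as
shell subcommands.

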