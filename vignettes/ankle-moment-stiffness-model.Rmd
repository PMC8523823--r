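---
title: "An EMG-driven model of ankle moment and stiffness during stance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An EMG-driven model of ankle moment and stiffness during stance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`anklemsk` estimates the net ankle joint moment and the ankle's rotational
stiffness through the stance phase of walking, driven by surface EMG of
four muscles: tibialis anterior (TA, the dorsiflexor) and soleus plus the
two gastrocnemii (SOL, GAL, GAM, the plantar flexors). The pipeline is the
classic EMG-driven musculoskeletal chain: EMG conditioning, activation
dynamics, muscle--tendon unit (MTU) kinematics, Hill-type MTU dynamics,
joint aggregation, subject-specific calibration, and curve-level
statistics across walking-surface conditions. Because the kind of raw gait
data this model consumes is rarely shareable, the package includes a
first-class synthetic generator with known ground truth; every stage is
validated end to end against that truth.

Conventions used throughout: angles, moments and moment arms are signed
with dorsiflexion positive, so TA has a positive moment arm and the
plantar flexors negative ones; stance runs from heel strike (0%) to
toe-off (100%).

# The model

## Excitation

Raw EMG is band-passed at 30--450 Hz, full-wave rectified and low-passed
at 6 Hz, each with a zero-phase (forward--backward) second-order
Butterworth filter; "second order" refers to the designed filter, so the
effective attenuation is fourth order. Per subject and muscle, envelopes
are divided by the maximum processed value across all recorded trials,
yielding excitations $e(t) \in [0,1]$. Two implementation details matter
on short stance records: ends are padded with odd (point-mirrored)
reflections over three low-pass cutoff periods before filtering, and
residual negative undershoot is clipped to zero, because everything
downstream assumes $e \in [0,1]$.

## Activation dynamics

Excitation drives a second-order recursive filter modelling the twitch
response,
$$u(t) = \alpha\,e(t-d) - \beta_1 u(t-1) - \beta_2 u(t-2),$$
with $\beta_1 = C_1 + C_2$, $\beta_2 = C_1 C_2$ and
$\alpha = 1 + \beta_1 + \beta_2$, which pins the DC gain at exactly 1.
The recursion poles are $-C_1$ and $-C_2$; we require $|C_1| < 1$ *and*
$|C_2| < 1$, since anything else is unstable (and the calibration bounds
keep both inside $[-1, 1]$ anyway). The electromechanical delay $d$
defaults to 40 ms — the conventional value in this model family — and is
applied as a whole-sample shift at the working rate; it is deliberately
not part of the calibrated parameter set, because a delay is poorly
identifiable from a single net moment trace. Neural activation is then
shaped by
$$a(t) = \frac{e^{A u(t)} - 1}{e^{A} - 1}, \qquad A \in [-3, 0),$$
with the analytic limit $a = u$ used when $|A| < 10^{-6}$; $u$ is clipped
to $[0,1]$ first so transient recursion overshoot cannot push $a$ outside
the admissible range.

## MTU kinematics

MTU length $l_{mt}(\theta)$ and moment arm $r(\theta)$ are degree-3
least-squares polynomial surrogates fitted per muscle to sampled geometry
(`fit_geometry()`); the moment-arm derivative $dr/d\theta$ entering joint
stiffness is the exact polynomial derivative. Evaluation outside the
fitted angle interval is an error, never extrapolation: polynomials are
wild outside their support and the $dr/d\theta$ term would corrupt
stiffness silently. A tendon-excursion consistency check
(`excursion_consistency()`) reports the ratio of the fitted arm to
$-dl_{mt}/d\theta$; since both quantities are fitted independently the
ratio is reported, not enforced. The gastrocnemii are treated as
functions of the ankle angle only — their knee-angle dependence is a
known simplification of the surrogate.

## MTU dynamics

Fiber force follows the Hill form
$F_m = F_{max}\,[f(\tilde l_m) f(\tilde v_m)\,a + f_P(\tilde l_m)]$ and
tendon force the piecewise strain model with a quadratic toe region
($1480.3\,F_{max}\,\varepsilon^2$ up to $\varepsilon = 0.0127$) and a
linear branch ($ (37.5\,\varepsilon - 0.2375)\,F_{max}$) beyond; the
printed constants make the junction continuous to about
$10^{-5} F_{max}$, and at exactly $\varepsilon = 0.0127$ the linear
branch is used. The normalized curves are standard phenomenological
choices, all constants exposed: a Gaussian active force--length
($\exp(-(\tilde l_m - 1)^2/0.45)$), a Hill hyperbola for shortening with
an eccentric plateau at $1.4$ (zero force at $\tilde v_m = -1$,
normalized by $v_{max} = 10\,l_{m0}/s$), and an exponential passive curve
that reaches $1\,F_{max}$ at $1.5\,l_{m0}$. Pennation obeys the
constant-thickness rule $l_m \sin\Phi = l_{m0} \sin\Phi_0$.

Each time step solves the series equilibrium
$F_t(\varepsilon) = F_m \cos\Phi$ for the tendon length
$l_t \in (0, l_{mt})$. Normalized fiber velocity is the backward
difference of fiber length against the previous accepted step (zero at
the first step) and is treated *implicitly* — it enters the residual of
the step being solved. An explicit velocity lag is violently unstable at
gait sampling rates whenever activation rises quickly, which is exactly
when TA loads up after heel strike; the implicit form is stable and keeps
the sweep sequential with the previous root as the warm start. The scalar
root is found by safeguarded Newton inside a sign bracket (compiled, in
`src/`), the accepted residual is at most $10^{-6}$ N, and a small
activation floor (0.005) avoids the degenerate flat residual of a fully
inactive muscle in series with an elastic tendon. A rigid-tendon mode
($l_t \equiv l_{st}$, closed-form fiber geometry) exists for comparison.

Stiffness components are analytic derivatives at frozen activation and
velocity: $K_t$ from the tendon branch derivative, and $K_m$ as the
length derivative of the Hill fiber force projected on the tendon line by
$\cos^2\Phi$ with the geometric pennation-change term
$F_m \sin^2\Phi / l_m$ included. No short-range (cross-bridge) stiffness
term is added — $K_m$ is literally the slope of the modelled force--length
relation, which makes the stiffness estimates conservative. The series
combination is $K_{mt} = (1/K_m + 1/K_t)^{-1}$, zero when either
component is zero; steps with negative $K_m$ (descending limb, little
passive support) are flagged, and $K_{mt}$ is floored at zero before
joint aggregation.

## Joint moment and stiffness

The joint moment is $\tau = \sum_i F_{mt,i}\, r_i$ with signed arms. For
stiffness, the package reports the negative moment--angle derivative at
frozen activation and velocity:
$$K_{ankle} = -\frac{d\tau}{d\theta}
  = \sum_i \left( K_{mt,i}\, r_i^2 - F_{mt,i}\,\frac{dr_i}{d\theta} \right).$$
A note on the sign of the second term, because the literature writes it
both ways: with *signed moment arms* (our convention,
$r = -\partial l_{mt}/\partial\theta$) the chain rule gives the minus
sign above; formulations that define the arm as the excursion derivative
$r = +\partial l_{mt}/\partial\theta$ carry the identical term with a
plus sign. The two agree wherever arms are constant. We chose the form
that is exactly the derivative of our own moment equation — the test
suite verifies it against a brute-force numerical $d\tau/d\theta$ through
the full chain to within 1%. The aggregate is reported clamped at zero
with a per-step flag count; the unclamped signed series is kept alongside
for diagnostics.

Curves are resampled by linear interpolation onto the standard 101-node
stance-percent grid. Model fit is summarized as NRMSE: the RMSE between
the EMG-driven and experimental moments divided by the RMS (not the
range, and not the root of the plain sum of squares) of the experimental
moment — the output labels the metric accordingly.

## Calibration

Subject-specific parameters minimize the mean squared moment error
$J = \frac1N \sum_i (\tau_{EMG}(i) - \tau_{ID}(i))^2$ pooled over all of
a subject's trials. Free parameters and bounds: shared $C_1, C_2 \in
[-1,1]$, $A \in [-3,0]$; group strength coefficients
$\gamma_{df}, \gamma_{pf} \in [0.5, 1.5]$ scaling $F_{max}$ of the
dorsiflexor and plantar-flexor groups; per-muscle multipliers on optimal
fiber length ($\pm 2.5\%$) and tendon slack length ($\pm 5\%$).
Activation constants are shared across muscles and strength within
groups because a single net moment cannot identify per-muscle activation
dynamics. The optimizer is Nelder--Mead under a smooth $\sin^2$
reparameterization of each coordinate onto its interval (hard clipping
flattens the simplex), with 4 seeded Latin-hypercube interior starts —
the objective is multimodal — and, per start, repeated simplex restarts
at the incumbent until the objective stops improving, which counters
simplex collapse in 13 dimensions. Forward-chain failures inside the
objective return a large finite penalty ($10^6$) so the simplex can walk
out of pathological corners. Everything is deterministic given the
spec's seed.

## Curve-level statistics (1D SPM)

Stance-phase curves (moment, stiffness, GRFs, excitations) are compared
across the four surface conditions with a one-way repeated-measures ANOVA
F statistic computed independently at every grid node (trials are first
averaged to one curve per subject and condition — the subject is the unit
of analysis). Inference over the whole curve is nonparametric: condition
labels are permuted within each subject, the critical threshold is the
$\lceil(1-\alpha)(n_{perm}+1)\rceil$-th order statistic of the permuted
field maxima, and each observed suprathreshold cluster receives a
p-value from the permutation distribution of the maximum cluster extent
above that same threshold. We use a permutation null rather than
random-field theory deliberately: it is self-contained, assumption-light
(no smoothness estimation, no sphericity correction — the permutation
null does not require sphericity), and the $\alpha = 0.05$ convention is
retained. Cluster extents are measured in stance percent with linear
interpolation of the threshold crossings, which makes the extent
statistic continuous; together with the $(1 + \#\{\cdot\})/(n_{perm}+1)$
p-value convention this keeps the family-wise error essentially exact at
$\alpha$ under exchangeability (heavily tied, integer-valued extents
would otherwise make the two-stage procedure conservative). When the
design is small enough that all within-subject relabelings fit in the
permutation budget, they are enumerated exhaustively and the result no
longer depends on the seed. Windowed effect sizes are Cohen's
$f = \sqrt{SS_{cond}/SS_{err}}$ averaged over the window (the windowed
mean is a labelling choice; other aggregations exist).

The node-wise decomposition is computed on per-node-centered,
subject-demeaned residuals; identical-curve designs would otherwise
produce garbage F values through catastrophic cancellation. Nodes with
(relatively) zero interaction variance report $F = \infty$ with a flag,
or 0 when the condition effect is also degenerate.

# The synthetic generator

`synthetic_truth()` defines the study conditions; `generate_trial()` and
`generate_dataset()` realize them. The generator emulates:

* **Excitations** as sums of at most two Gaussian bursts over stance
  percent, phased for walking: TA bursts just after heel strike (center
  4%, peak 0.5) and again before toe-off (97%, 0.25); SOL/GAL/GAM ramp
  through mid stance to push-off peaks (centers 62--68%, peaks
  0.6--0.85). Peaks near but below 1 reflect normalization to the
  across-trial maximum of walking itself.
* **Surface conditions** labelled plate, rubber, EVA, EPE with compliance
  levels 0, 0, 1, 2: the two stiff surfaces share a level because both
  are far stiffer than plantar tissue, so the foam steps carry the
  effect. The surface effect (default +8% plantar-flexor burst peak per
  level) is the known mid/late-stance ground truth that the SPM stage is
  expected to detect; setting it to 0 produces exchangeable null data.
* **Ankle angle** as a natural spline through canonical stance waypoints
  (0° at heel strike, -6° early plantar flexion, dorsiflexion to +11°
  by 70%, -17° at toe-off), amplitude configurable.
* **Geometry** from canonical curves: mildly sloped linear signed arms
  (e.g. TA $+0.040 - 0.004\,\theta$ m, SOL $-0.048 - 0.003\,\theta$ m)
  with MTU lengths integrated from them, so the synthetic geometry is
  exactly excursion-consistent and each MTU sits at tendon slack length
  in the neutral pose.
* **The experimental moment** by running the truth parameters through
  the package's own forward chain and adding i.i.d. Gaussian noise
  (default SD 2 N m) — the simplest stand-in for inverse-dynamics error.
* **GRF-like curves** (double-hump vertical, braking/propulsion
  anterior--posterior, 620 N body weight) for exercising the statistics
  on familiar shapes.
* **Between- and within-subject variability** as seeded jitter on burst
  peaks and centers: subject-level jitter (8%) is drawn once per subject
  and shared across that subject's conditions — which is what makes
  zero-effect datasets exchangeable across condition labels — and
  trial-level jitter (3%) is drawn per trial.

The plant runs at 100 Hz, a motion-capture kinematics time base: the
forward chain operates on joint-angle samples, not on the raw EMG clock.
The optional raw-EMG mode instead synthesizes 1500 Hz band-limited noise
amplitude-modulated by the true envelope, for exercising the EMG
conditioning stage end to end.

Seeding is counter-based: every per-subject, per-condition, per-trial
stream derives its seed from the base seed and its indices, so any trial
is reproducible in isolation and datasets are bit-identical across runs.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: real EMG spectra, crosstalk and motion
artifact; soft-tissue and marker error in the "experimental" moment
(white noise only); knee-coupled gastrocnemius kinematics; any
surface-driven change in joint kinematics or in the center of pressure
(the compliance effect enters through muscle drive only); and co-varying
GRF changes. Parameter-recovery results on this plant demonstrate that
the estimation machinery is correct and identifiable under the model's
own assumptions, not that the model is unbiased on real gait.

# Validation choices and problem sizes

The test suite validates each stage against independent oracles: analytic
filter responses (a rectified 100 Hz sine settles at $2/\pi$), hand
recursions for the activation filter, closed-form tendon values and
finite-difference checks of both stiffness components (0.1%), a
brute-force moment--angle derivative for joint stiffness (1%), textbook
`aov()` decompositions for the node-wise F statistic, and parameter
recovery on zero-noise data (recovered-moment NRMSE at most 0.05 and the
plantar-flexor strength coefficient within $\pm 0.1$ of truth with 4
multistarts; at 5%-of-peak moment noise the recovery criterion relaxes
to 0.15). Family-wise error of the permutation SPM is measured on 200
seeded null datasets of 10 subjects by 4 conditions and must land in
$[0.025, 0.075]$ at $\alpha = 0.05$ with 199 permutations each. These
sizes — 71-sample stance records, 4 calibration trials, 200 null
replicates — are the package's validation conditions, chosen to exercise
the full design at desk scale.

# Known limitations

* Four superficial muscles only; deep plantar flexors and co-contracting
  shank muscles are absent, so absolute stiffness is underestimated.
* $K_m$ has no short-range stiffness term; reported joint stiffness is a
  lower bound in that sense too.
* The elastic-tendon equilibrium treats activation as quasi-static within
  a step; no tendon damping or history dependence.
* Ankle-angle-only geometry for the biarticular gastrocnemii.
* The calibration identifies group strength and geometry multipliers from
  one net moment; individual activation constants C1/C2 are weakly
  identified (flat directions of $J$) and should be interpreted as
  filter shapes, not physiology.
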