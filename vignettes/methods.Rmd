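---
title: "Methods: EMG-informed estimation of knee contact force under added limb mass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EMG-informed estimation of knee contact force under added limb mass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Wearable devices add mass to the lower limbs, and the compressive force
transmitted across the tibiofemoral joint ("knee contact force", KCF,
expressed in multiples of body weight, BW) cannot be measured noninvasively.
It must be estimated from motion, ground reaction forces (GRF) and surface
electromyography (EMG). `kneeload` implements, at desk scale, a complete
EMG-informed estimation pipeline together with the statistical models that
relate added segment mass (thigh, shank, foot; in percent body weight per
leg) to percent change in the early- and late-stance KCF peaks, plus a
synthetic gait generator with a known ground truth so that every stage of
the pipeline can be validated quantitatively.

# The model

## Planar skeleton

The musculoskeletal model is a planar sagittal linkage with 9 degrees of
freedom: trunk translation and rotation, and hip/knee/ankle flexion per leg
(knee flexion zero at full extension and positive in flexion; ankle
dorsiflexion positive). Segment masses, lengths, centers of mass and planar
moments of inertia are standard anthropometric fractions of body mass and
stature, shipped as editable configuration — they are defaults, not
subject-specific ground truth. Added mass is lumped as a point mass at a
configurable fraction of segment length (default 0.43, a standard COM
location) on both legs; segment mass, COM and inertia (parallel-axis
theorem) update accordingly. The deliberate restriction to the sagittal
plane reflects that the axial (compressive) knee load is dominated by
sagittal mechanics, and it keeps every quantity checkable by free-body
oracles.

## Muscles

Twelve Hill-type muscle-tendon units actuate the right hip, knee and ankle:
soleus, medial/lateral gastrocnemius, tibialis anterior, semitendinosus,
semimembranosus, biceps femoris long and short head, the three vasti and
rectus femoris. Moment arms are polynomials in joint angle (positive arm =
moment toward the positive coordinate), and musculotendon length is the
consistent integral of the moment arms, so the tendon-excursion identity
holds by construction. Force generation uses a rigid tendon:
`F = f_max (a f_L f_V + f_pass) cos(pennation)`, with a Gaussian active
force-length curve, a hyperbolic force-velocity curve and a quadratic
passive curve. With prescribed kinematics the force is affine in
activation, which keeps the whole optimization a convex quadratic program
(see below). Peak isometric forces are chosen so that walking excitations
stay well below 1, leaving headroom for the submaximal-MVC inflation of the
synthetic EMG; all muscle parameters are configuration, and peak forces are
scaled to each subject by `(mass x height)/(75 kg x 1.70 m)`.

Activation dynamics are first order with activation/deactivation time
constants of 15 and 60 ms and a switching time constant (activation when
excitation exceeds activation). Knee-spanning muscles compress the joint by
a configured polynomial fraction of their force (quadriceps via the
patellar tendon ~0.9 near extension; hamstrings and gastrocnemii ~0.82-0.88).

# Signal processing

EMG: zero-phase 4th-order Butterworth high-pass at 20 Hz, full-wave
rectification, zero-phase low-pass at 6 Hz; normalization by the larger of
the 250 ms sliding-mean maximum over MVC trials and the gait maximum (so no
signal exceeds 1); a 53 ms electromechanical-delay shift; and mapping of
the nine measured channels onto the twelve modeled muscles (vastus medialis
to intermedius, biceps long to short head, semitendinosus to
semimembranosus). The filter family and order are unstated in typical
protocols and are configurable; zero-phase Butterworth is the field's
convention. Stance phases are segmented from the vertical GRF with a 20 N
threshold and 50 ms debounce (standard force-plate practice). GRF and
kinematics are low-pass filtered at 8 Hz before inverse dynamics when
processing measured data (a configuration flag); synthetic trials are
noise-free and band-limited, and their dynamic-consistency ground truth is
defined on the unfiltered signals, so the default pipeline leaves them
unfiltered.

# The two-stage EMG-informed optimization

For each stance phase, kinematics and GRF are prescribed; planar
Newton-Euler inverse dynamics (central-difference accelerations on the
native 100 Hz grid) gives the net hip/knee/ankle moments. The optimization
solves for adjusted excitations `e` and reserve torques `r` minimizing

`J = w1 J_excitation + w2 J_knee/ankle + w3 J_reserve + w4 J_EMG`

with trapezoidal activation dynamics and per-DOF moment equality at every
node. Design choices that matter:

* **Collocation on the native kinematic samples.** Nodes are the 100 Hz
  samples inside the stance window (~65 nodes for a 0.65 s stance). Using
  the measurement grid avoids cross-grid interpolation of moments and
  muscle gains, which otherwise injects spurious moment residuals an order
  of magnitude above the solver tolerance.
* **Analytic reserve elimination.** Reserves enter the moment equality as
  free variables penalized in the cost, so `r = M_ID - (muscle moment)` can
  be eliminated exactly; moment equality then holds identically and the
  problem becomes a box-constrained convex QP in the excitations.
* **Exact QP solves.** The knee/ankle reserve weight makes the Hessian
  ill-conditioned (condition number ~1e6); first-order solvers leave
  objective noise far larger than the calibration signal. The QP is solved
  by two-metric projected Newton iterations (Cholesky on the strictly
  interior block, scaled gradient for at-bound variables) to a KKT
  tolerance of 1e-8.
* **Initial activation state.** Muscles enter stance with late-swing
  activation history; the initial activation is obtained by integrating the
  reference excitations over a 0.5 s lead-in. Pinning `a(0) = e(0)` instead
  produces a spurious antagonist transient over the first ~10% of stance
  that biases the early-stance peak by several percent.
* **Fixed switching pattern.** The activation/deactivation switching
  pattern is derived once from the reference excitations (it is invariant
  to positive rescaling, hence valid for all scale-factor iterates);
  re-deriving it from the current iterate makes the quadratic model
  non-stationary and can limit-cycle.
* **Weights.** The magnitudes are not published for the reference
  implementation; defaults honor the stated ordering — calibration
  `w1 = 0.5, w2 = 1000`, execution `w1 = 0.002, w2 = 100`, with the
  EMG-tracking weight `w4 = 1` common to both stages. The hip reserve
  weight `w3` is zero: reserves are eliminated analytically so no weight is
  needed for convergence, and because the hip reserve carries ~100 N m any
  positive `w3` recruits the biarticular hamstrings/rectus femoris as hip
  actuators against their own EMG, measurably distorting knee compression.

**Calibration** runs on strides from the unloaded trials and additionally
estimates one EMG scale factor per measured channel, bounded to [0.5, 1]
(submaximal MVC efforts inflate normalized EMG; the bounds avoid
non-physiological excitations). For fixed scales the problem is the QP
above; for fixed excitations the scale update is a bounded least-squares
with a closed form; coordinate descent from three multistarts
(s = 0.5/0.75/1.0) keeps the best objective, and per-stride factors are
averaged. **Execution** scales the reference EMG by the calibrated factors
and solves every trial.

# Contact force

Total compressive tibiofemoral force is the intersegmental axial reaction
(free-body analysis of the shank+foot subsystem with pure joint torques,
projected on the tibia long axis, compression positive) plus the
compressive components of the knee-spanning muscle forces. Traces are
normalized by unweighted body weight (the percent-change outcomes need a
fixed denominator across loading conditions) and resampled to a 101-point
0-100% stance grid; early- and late-stance peaks are the maxima in the
15-40% and 60-90% windows.

# The synthetic-data generator

The generator emulates the structure of an added-mass treadmill study: 10
subjects (mass uniform 57-81 kg, stature 1.63-1.78 m), nine loading
conditions (none; thigh 2/4, shank 1.5/3, foot 1/2% BW per leg; and the
two all-segment combinations 4.5/9% BW), with the no-mass condition run first
and last, stance kinematics at 100 Hz and GRF/EMG at 1250 Hz.

* **Kinematics** are smooth periodic templates (wrapped-Gaussian joint-angle
  waveforms; baseline stride time 1.10 s, duty factor 0.60). Carried mass
  time-scales the templates through the response model's stride-time
  effects and induces two small documented gait adaptations — a stiffer
  loading-response knee and a shorter push-off lever — without which the
  purely mechanistic demand increase (GRF grows with carried mass) would
  exceed the modest per-segment effects the response model prescribes.
* **GRF** for both feet follows from whole-body dynamic consistency
  (total external force equals total mass times COM acceleration at every
  sample, with the same difference scheme the pipeline uses, so the
  round trip is exact to machine precision), with a smooth double-support
  force share and heel-to-toe COP progression.
* **Truth channel.** True activations solve a per-node minimum-effort
  redundancy problem (knee and ankle moment equality, shared-innervation
  ties matching the channel mapping), plus a tonic antagonist
  co-contraction floor (5% of the minimum-effort contact force), plus the
  injected added-mass response as moment-neutral vasti/hamstring
  co-contraction. A forward feasibility sweep enforces the deactivation
  rate limit (activations cannot fall faster than the 60 ms time constant)
  and closes the resulting moment residuals with the joint's uniarticular
  antagonists. True excitations follow by inverting the activation
  dynamics, and the realized (dynamics-consistent) activations define the
  trial's mechanical truth.
* **Response injection.** Percent changes in the two peaks are injected as
  `delta = a_thigh m_thigh + a_shank m_shank + a_foot m_foot + b_subject +
  noise` with the study's coefficients as defaults (early 1.5/2.1/5.9,
  late 1.6/0.9/3.0 % per % BW per leg; stride time 0.26/0/2.5). Effects are
  injected through the data (EMG and the implied mechanics), not merely
  recorded, so the pipeline must genuinely recover them. The truth record
  carries two channels: the *injection target* (whose peaks obey the linear
  response exactly — the reference for statistical recovery tests) and the
  *realized trace* (what the muscles actually produce; deactivation limits
  raise the inter-peak valley above the target, and the two channels agree
  at the peaks to ~1%).
* **EMG emulation.** Each measured channel is the true excitation advanced
  by 53 ms, multiplied by a per-muscle submaximal-MVC inflation factor
  (drawn so the implied recoverable scale factor is uniform in
  [0.55, 0.95]), plus optional Gaussian noise, clipped to [0, 1]; MVC
  trials are unit plateaus. The three unmeasured muscles emit no channel.
  Realistic raw-EMG spectra are out of scope: channels are envelope-scale
  signals and the pipeline's envelope stage is exercised by its own unit
  oracles instead.

What passing tests on this generator do **not** show: robustness to
marker/soft-tissue artifact, 3-D (frontal-plane) loading, true raw-EMG
processing noise, elastic-tendon effects beyond the quasi-static option, or
model personalization errors — all deliberately out of scope.

# Statistical layer

Percent change is computed per subject against the mean of the initial and
final unloaded trials (averaging reduces drift bias; a first-only rule is
available). The headline model is a through-origin regression of percent
change on the three segment masses (fit to the no-mass and single-segment
conditions; the all-segment conditions are held out for the additivity
check), with t-based 95% CIs, p-values and Pearson's r between observed and
predicted. Additivity is assessed by coefficient-wise CI propagation — the
bound construction of the original analysis, not a proper prediction
interval. Random-intercept mixed models (REML via `lme4`, Wald p-values)
relate the raw peaks to segment masses with subject as the random effect.
The a priori power analysis solves for the smallest R-squared detectable by
the overall F-test; the noncentrality convention is Cohen's
`lambda = f2 * nu_error` with `df = (p, n - p - 1)`, the convention that
reproduces the study's printed minimum detectable R-squared of 0.17 at
n = 60, p = 3, alpha = 0.05, power = 0.8.

A calibration caveat the package reports honestly: with the generator's
default between-subject random-intercept scale (1.5%), a subject's loaded
observations are correlated, and the pooled through-origin CI — which, like
the study's power analysis, treats percent-change observations as
independent — covers the generating coefficients in only ~88-93% of
replicates rather than the nominal 95%. The random-intercept mixed model is
the correctly calibrated analysis for that structure.

# Numerical choices and problem sizes

Default study size: 10 subjects x 10 trials (protocol order), 3 strides per
trial; calibration uses all strides of the two unloaded trials; execution
solves the first stance of each trial (noise-free strides within a trial
are identical by construction). The packaged acceptance runs use 2 strides
per trial — four calibration strides per subject — which the scale-factor
recovery results show is already converged for noise-free trials. A full
study runs in minutes on one core.
Known quantitative behavior of the defaults, measured by the test suite on
noise-free synthetic cohorts: contact-force peaks recovered within 3% of
truth, trace RMS within ~2%, EMG tracking RMSE ~0.002-0.02, knee/ankle
reserves below 1% of the peak knee moment, calibration scale factors
recovered to ~0.025 mean absolute error. Two known biases are documented
rather than hidden: recovered peaks carry a small systematic discount of
injected co-contraction (effort regularization and residual scale-factor
bias), so pipeline-level regression slopes are attenuated relative to the
generator's coefficients — a property shared by EMG-informed pipelines in
general — and the deactivation rate limit raises the realized mid-stance
valley above the injection target.

# Limitations

Planar mechanics only; no medial/lateral compartment split; rigid tendon by
default (a quasi-static elastic option exists in configuration); linear
EMG-to-activation mapping; the generator's gait adaptations are stylized;
and statistical defaults for between-subject variability are placeholders,
as no per-subject variance is published for these outcomes.
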