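---
title: "Quantifying inverted-pendulum validity in quiet standing: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying inverted-pendulum validity in quiet standing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipvi)
```

## The model and the index

Quiet standing is classically idealized as a single rigid link rotating about
the ankle joints. Linearized about the upright equilibrium, the sagittal-plane
dynamics are

$$ I_a \ddot\theta = m g h\, \theta - \tau_a, $$

with $\theta$ the lean angle, $m$ body mass excluding the feet, $h$ the COM
height above the ankle, $I_a$ the moment of inertia about the ankle and
$\tau_a$ the net ankle torque. Writing $x = h\theta$ for the AP COM
displacement and using the small-angle plate equation $p_x = \tau_a/(mg)$ for
the centre of pressure, the model collapses to a pointwise identity between
the *COP error* $e_x = x - p_x$ and the AP ground-reaction force
$\mathrm{GRF}_x = m\ddot x$:

$$ e_x(t) \;=\; \frac{I_a}{m g h}\,\ddot x(t) \;=\; \frac{I_a}{m^2 g h}\,\mathrm{GRF}_x(t). $$

If stance is genuinely single-jointed, $e_x$ and $\mathrm{GRF}_x$ are
perfectly linearly related. The **inverted-pendulum validity index** is the
Pearson correlation between the two over a trial or window. It is a *degree*
of validity: multi-segment coordination (above all ankle–hip) injects
components into $e_x$ that are not proportional to $\mathrm{GRF}_x$ and pulls
the index below 1. No detrending, transformation or robustification is
applied — the model predicts raw proportionality, so raw correlation is the
faithful statistic.

## COM reconstruction

The index needs $x(t)$, which force platforms do not measure. Newton's second
law ties the *shape* of the COM trajectory to the measured force for any
body, single- or multi-segment:

$$ x(t) = \frac{1}{m}\iint_{t_i}^{t} \mathrm{GRF}_x \, d\tau^2 + C_1 (t - t_i) + C_0 . $$

The two constants are fixed by a model-derived boundary condition: whenever
$\mathrm{GRF}_x = 0$ the COM is vertically above the COP, so on each span
between consecutive force zero instants $t_i < t_{i+1}$ we impose
$x(t_i) = p_x(t_i)$ and $x(t_{i+1}) = p_x(t_{i+1})$. This
zero-point-to-zero-point double integration is what `estimate_com()`
implements. Two properties are worth stating explicitly:

* Only the mass $m$ enters the reconstruction; $I_a$, $h$ and $g$ do not.
  Since the correlation is additionally invariant to rescaling $e_x$, the
  index is remarkably insensitive to anthropometric misspecification — a
  wrong $m$ rescales the reconstructed COP error without changing the index.
* Samples before the first and after the last zero crossing admit only one
  boundary condition. They are flagged invalid and excluded from every
  downstream feature, never extrapolated.

Numerical choices: the double integral uses the cumulative trapezoidal rule
on the native grid, with a partial first step starting at the (generally
off-grid) linearly interpolated crossing instant; COP values at crossing
instants are interpolated linearly. Segments spanning fewer than 3 samples
are underdetermined and flagged invalid. Sign-change ties: a sample exactly
at zero is a crossing at that sample time; runs of consecutive zeros collapse
to their first sample. Crossings closer than `min_gap_s` (default 0.02 s,
roughly ten samples at 512 Hz) to the previously retained one are merged:
segments shorter than the low-pass filter's resolvable timescale carry noise,
not COM information.

## Signal conditioning

Trials are filtered with a 6th-order Butterworth low-pass at 5 Hz, applied
forward and backward. Zero-phase application is deliberate: a causal pass
would delay the COP relative to the force channel and bias the correlation.
The cutoff-gain contract is therefore $|H|^2 = 0.5$ at 5 Hz. The filter runs
as a cascade of second-order sections. This is not cosmetic: at a normalized
cutoff of 5/512 a single 6th-order transfer function loses about seven
significant digits to coefficient cancellation, visibly violating linearity
at the $10^{-9}$ level, while the biquad cascade is exact to near machine
precision. Edges are handled by odd-reflection padding of `3 * order`
samples plus constant-steady-state initial conditions per section.

Resampling (used only for scatter exports, e.g. 30 s at 30 Hz giving 901
points) is plain linear interpolation: the signals are already band-limited
to 5 Hz, so no anti-aliasing stage is needed, and 512/30 being non-integer
rules out decimation. Features are computed at the filtered native rate; rate
reduction is an explicit, separate step.

## Windowed and cohort analyses

Each 30 s trial is cut into thirty non-overlapping 1 s windows *on the trial
clock*; the validity mask only filters samples within a window, so the window
count stays deterministic. The COM is reconstructed once per trial and then
windowed — 1 s windows rarely contain a usable pair of crossings on their
own. Windows with fewer than 2 valid samples or zero variance yield an
undefined (`NA`) index and are excluded from splits. The median split sorts
windows by index descending (stable among ties) and assigns the first
$\lceil n/2 \rceil$ to the larger half.

Group comparisons follow the repeated-measures design of a two-group,
12-trial-per-subject study: per-subject 12-trial means compared by
equal-variance Student's t-tests (the classical independent test, not
Welch's); classification of 3-trial-average samples ($\binom{12}{3} = 220$
per subject) by a single-feature threshold, reported as rank-formulation AUC
(ties count 1/2) and best-threshold resubstitution accuracy. Two caveats are
intentional mirrors of the analysed design rather than statistical
recommendations: samples from the same subject appear on both sides of the
threshold scan without subject-level partitioning, and accuracy is apparent
(resubstitution), not held-out. The threshold scan covers midpoints between
distinct scores plus the two all-one-class boundary rules, in both
orientations, so it always equals exhaustive enumeration.

## The simulators

Because no deposited force-plate data exist for this problem, the package
carries its own ground truth.

**Single link.** `simulate_ip()` integrates the linearized pendulum above
with a proportional–derivative ankle torque plus low-pass-filtered Gaussian
motor noise, $\tau_a = k_p \theta + k_d \dot\theta - \eta(t)$. The
linearized (not $\sin\theta$) form is used on purpose: it *is* the model
whose validity the index measures, so on its trajectories the identity holds
to integrator precision and the full pipeline can be held to
correlation ≥ 0.999 against ground truth. At quiet-stance amplitudes
(≈ 0.005 rad) the linearization error of real mechanics is $O(\theta^2)$ and
irrelevant to what the simulator is for. Lean beyond 0.5 rad raises a fall
condition.

**Two link.** `simulate_double_link()` adds a hip joint between a leg
segment and a head–arms–trunk segment (linearized manipulator form in
absolute angles, joint stiffness/damping, per-joint noise). The hip is the
canonical challenge to the pendulum model: in the stiff-hip limit the model
converges to the composite single link (verified against `simulate_ip()`
with `composite_anthro()` parameters, both as an analytic hip-locked
constraint and as a $10^4 \times$ stiffness limit), while a compliant hip
feeds upper-body motion into $e_x$ that the force channel cannot explain,
degrading the index. Sweeping hip stiffness over
$\{10^4, 10^2, 10^1, 10^0\} \times$ ankle stiffness with paired noise
realizations yields mean pipeline IPVI falling monotonically from ≈ 1.000 to
≈ 0.85.

**Integrator.** Both simulators propagate the linear dynamics by *exact*
matrix-exponential discretization (Van Loan augmented-exponential blocks)
with the noise taken piecewise linear on a half-step grid. A fixed-step
Runge–Kutta scheme at the output rate was rejected: the stiff-hip limit
places the fast hip mode (~1600 rad/s at $10^4\times$ ankle stiffness)
outside the RK4 stability region at 512 Hz. Exact discretization is
unconditionally stable, deterministic, and — because the consumed noise
stream does not depend on stiffness — keeps paired-seed sweeps genuinely
paired. Motor noise is white Gaussian torque shaped by a 2nd-order low-pass
at 2 Hz (a realistic 0.1–1 Hz sway spectrum results), scaled by the filter's
analytic white-noise gain so the requested SD is realization-independent.

## Default parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `mass_kg`, `com_height_m` | 70, 0.9 | kg, m | typical adult; composite values for two-link subjects |
| `I_a` | $m h^2$ | kg m² | point-mass pendulum; only enters the simulator, see above |
| `kp` | $1.2\, m g h$ | N m/rad | ankle stiffness slightly above the toppling threshold $mgh$, the empirically typical regime; sway resonance ≈ 0.24 Hz |
| `kd` | ratio 0.3 | N m s/rad | light damping about equilibrium |
| `noise_sd` | 0.4 | N m | produces COP sd ≈ 1–3 mm, MV_AP ≈ 5–7 mm/s, the normal quiet-stance range |
| `noise_cutoff_hz` | 2 | Hz | motor-noise bandwidth |
| `fs`, `duration_s` | 512, 30 | Hz, s | the acquisition rate and analysed span of the emulated protocol |
| two-link segments | 22.4 kg / 0.85 m legs; 47.6 kg HAT, COM 0.32 m above hip | — | 32/68 mass split of a 70 kg adult; rod inertias |
| `k_hip` | 10 × ankle | N m/rad | stiff-but-not-rigid default |

The synthetic cohort draws subject masses $N(70, 10^2)$ (truncated ±3 sd), a
stature scale $N(1, 0.04^2)$ applied to segment lengths, log-normal hip
stiffness multipliers and normal noise SDs per group. The default group
parameterization — older: stiffer hip (mean 20×) and stronger noise
(0.55 N m); younger: compliant hip (mean 1.5×) and weaker noise (0.40 N m) —
is a *modelling choice* to emulate the direction of reported age effects
(older adults: higher validity index and faster sway), not a claimed
mechanism, and the package makes no attempt to reproduce any published
subject table. Hip multiplier draws are truncated at 0.5× ankle stiffness,
comfortably inside the region where the linearized two-link system is stable
(checked by eigenvalue at construction).

## What passing tests do and do not show

The simulators emulate: band-limited noise-driven sway of realistic
amplitude, velocity and spectrum; the pendulum identity as an exact ground
truth; graded multi-segment contamination via hip compliance; and the full
repeated-measures study structure. They do not emulate: measurement noise
and drift of real force plates, intermittent or predictive control,
medial-lateral coupling, neuromuscular delays, breathing, or genuinely
nonlinear large-sway mechanics. A green test suite therefore certifies the
*estimation machinery* — that the pipeline recovers what the model says it
should, and degrades when the model is violated in the way the index is
meant to detect — not that any particular human population will show any
particular index value.

Validation problem sizes: 30 s trials at 512 Hz throughout; 12 seeded
single-link runs for the identity checks; 10 paired seeds per stiffness
level for the hip sweep; the default 2 × 20 × 12 cohort for the group
comparison.

## Known limitations

* The medial-lateral direction is pass-through only; the model and index are
  AP-specific.
* Trials whose force trace crosses zero fewer than twice yield an all-invalid
  reconstruction (correct but uninformative); extremely stiff, low-noise
  recordings can approach this.
* The per-window index inherits whole-trial boundary conditions; a window far
  from any crossing relies on integration carried across its boundaries.
* Classification figures are resubstitution values on correlated samples, by
  design of the emulated protocol; they should not be read as generalization
  estimates.
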