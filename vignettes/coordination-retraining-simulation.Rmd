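---
title: "Simulating gastrocnemius-avoidance coordination and knee contact force"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating gastrocnemius-avoidance coordination and knee contact force}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneeload)
```

## The model and its assumptions

`kneeload` resolves muscle redundancy during walking by per-timestep static
optimization over a sagittal-plane lower-limb model, and uses the resulting
muscle forces to compute the compressive knee contact force (KCF) along the
tibia's longitudinal axis. The pipeline exists to answer two questions:

1. *Design*: which muscles must compensate when walking kinetics are
   reproduced while heavily penalizing gastrocnemius activation, and what
   does that do to KCF?
2. *Evaluation*: given surface EMG from a subject who has changed their
   gastrocnemius-to-soleus coordination, what KCF change does an
   EMG-informed simulation estimate?

The main assumptions, in the order they enter the computation:

* **Static, per-frame resolution.** Activations at each timestep are chosen
  independently, subject to moment matching at that frame. The only coupling
  across time is that the fiber-equilibrium stage uses the previous frame's
  activation (see below). There are no activation dynamics.
* **Hill-type musculotendon with compliant tendon, no force–velocity.** The
  fiber length at each frame solves the static force balance between the
  tendon and the (active + passive) fiber force projected through the
  pennation angle. Omitting force–velocity is a deliberate modeling choice:
  with a compliant Achilles tendon, plantarflexor fibers operate
  near-isometrically through stance, and the compliant-tendon/no-velocity
  combination tracks plantarflexor EMG better than a rigid tendon with
  force–velocity.
* **Planar geometry with polynomial moment arms.** Moment arms are
  polynomials (order at most 2) in the DOF's own angle, and MTU length is
  the exact path integral of the moment arms from the reference posture, so
  the virtual-work identity r = −∂l/∂q holds analytically rather than
  approximately.
* **Constant axial projection at the knee.** Each knee-crossing muscle maps
  its force onto tibia-axis compression through a constant coefficient.
  This keeps the decomposition of KCF into group contributions exactly
  additive. A full 3D joint-reaction computation would make the projection
  posture-dependent; whether that materially changes KCF waveforms is an
  open question we note but do not resolve here.
* **Intersegmental force as input.** The intersegmental (torque-actuated)
  axial knee force is supplied as a data series, not recomputed from 3D
  dynamics. In the synthetic conditions it is a smooth double-bump stance
  profile scaled to bodyweight.

## The per-frame optimization

At frame `t_k`, with fiber lengths frozen at their equilibrium values, each
muscle's force is affine in its activation, `F_i = c0_i + c1_i a_i` with
`c0 = F_o f_PE cos(alpha)` and `c1 = F_o f_l cos(alpha) >= 0`. The moment
constraints are then linear in `a` and the problem is a strictly convex QP:

* objective: `sum_i w_i a_i^2 + w_res sum_j res_j^2`, with `w_i = 1`
  (natural) or `w_i = 100` on both gastrocnemius heads (avoidance);
* equality per DOF: `sum_i r_ij c1_i a_i + res_j = M_ID,j − sum_i r_ij c0_i`;
* bounds `0 <= a <= 1` (lower bound `1e-6` on the ratio-constrained muscles
  on enforced frames, so the ratio is well defined);
* optionally, per gastrocnemius head, the EMG ratio band
  `|r_EMG − a_g/(a_g + a_s)| <= tol` rewritten exactly as two linear
  inequalities `a_g (1 − (r ± tol)) ≶ (r ± tol) a_s`.

We solve it with the dual active-set method of `quadprog::solve.QP`, which
is deterministic and satisfies the equalities to machine precision; repeated
solves are bit-identical. A penalized box-constrained quasi-Newton fallback
exists for the (never observed in testing) case of a QP failure, and its use
is logged with a warning.

**Reserve actuators.** One ideal torque per DOF guarantees feasibility. We
penalize reserves quadratically at `1e6` per (N·m)². The weight matters: at
the optimum, the reserve on DOF `j` equals `lambda_j / (2 w_res)`, where
`lambda_j` is the moment constraint's multiplier (order 0.01 on these
problems). The chosen weight keeps reserves near `1e-8` N·m on achievable
trials, so the tests can assert that muscles, not reserves, produce the
moments; a weight three or four orders of magnitude smaller would leave
reserves of order 0.05 N·m and blur that assertion.

**Activation history.** The fiber-equilibrium stage uses `a(t_{k−1})`. The
first frame has no predecessor: we bootstrap it with `a_prev = 0`, solve the
whole trial, and then re-solve frame 1 once with its own optimized
activations (one warm-start pass).

**Verification oracle.** For toy problems (≤ 4 muscles, ≤ 2 effective DOFs)
`brute_force_oracle()` enumerates a grid over the free activations and
solves the remaining ones exactly from the moment equalities, so every
evaluated point is exactly feasible; the QP must match it within one grid
step. Two closed forms complement the oracle: single-muscle inversion
`a = (M/r − c0)/c1`, and Lagrange stationarity of the weighted objective on
a two-muscle toy with equal moment arms and force coefficients, which gives
an activation ratio of exactly `1/w` (1/100 at the default avoidance
weight).

## Musculotendon curves and the equilibrium solver

The literature defines the characteristic curves by tabulated control
points; we use smooth analytic surrogates with the same qualitative
properties, stated here so the model is fully reproducible:

* **Tendon**: zero at or below slack length; above it,
  `(exp(k s) − 1 − k s)` in tendon strain `s`, normalized to reach 1 at
  strain 0.049 (the strain at one maximum isometric force), with
  `k = 3/0.049`. Subtracting the linear term makes the derivative vanish at
  slack length, so the curve is C1 everywhere and strictly increasing above
  slack. Stiffening the tendon (for rigid-limit tests) divides the
  reference strain, preserving the shape.
* **Active fiber**: Gaussian `exp(−((l/l_o − 1)/0.45)^2)` — maximum exactly
  1 at optimal fiber length, positive everywhere.
* **Passive fiber**: same exponential-minus-linear form as the tendon,
  engaging at optimal length and reaching 1 at fiber strain 0.7.
* **Pennation**: fixed-height model `alpha(l_m) = asin(l_o sin(alpha_o) /
  l_m)`, capped at 84° to avoid the vertical-fiber singularity.

The equilibrium in fiber length is solved by Newton iteration with a
central-difference derivative (`h = 1e-7 l_o`), initialized from the
previous frame's fiber length (first frame: the rigid-tendon closed form),
iterates clamped to `[0.05, 2.5] l_o`, at most 50 iterations, absolute
residual tolerance `1e-10 F_o` (tested to hold below `1e-8 F_o`
everywhere). If Newton stalls, we bisect on `[0.3, 1.8] l_o`, widening once
to the full clamp window; only if no sign change exists does the solver
raise an error naming the muscle. The degenerate zero-activation,
slack-tendon case has a whole interval of equilibria; the rigid-tendon
initialization deterministically returns the geometric solution there. The
Newton tolerance and iteration cap are our implementation choices — the
reference workflow this mirrors does not publish its settings.

## EMG processing choices

Envelopes are computed by bandpass (30–500 Hz), rectification, and low-pass
(6 Hz) filtering, all zero-phase. Zero-phase filtering is forward–backward
application with odd-reflection padding of 3× the filter order at each end
(the padding scheme is unstated in the reference description; reflection is
the standard choice and the suite checks that a symmetric burst's envelope
peak stays centered). We design the bandpass as a 4th-order transfer
function (`butter(2, band)`) and the low-pass as `butter(4)`, so each
single pass is 4th order; magnitude-wise the zero-phase result is 8th
order. Envelopes are normalized by the scalar maximum of each channel's MVC
envelope; normalized values above 1 are reported, not clipped. The
electromechanical delay (default 40 ms) shifts the envelope later by
`round(delay · fs)` samples, holding the leading edge.

The ratio constraint is enforced only on stance frames where the delayed
gastrocnemius-plus-soleus envelope is at least 0.01 of MVC: below that
floor the measured ratio is a quotient of noise. Each gastrocnemius head is
constrained against the soleus separately.

## What the synthetic data emulate — and what they do not

The generator produces ground-truth activations as smooth Gaussian bumps in
cycle fraction (cycle 1.1 s, 60% stance, 10 ms steps — 111 frames), phased
so the hamstrings dominate early stance, the quadriceps early-to-mid
stance, and the plantarflexors late stance. Joint moments are computed
*forward* from the truth through the same musculotendon model and moment
arms, so they are exactly achievable and the solver's reserves should
vanish — which the suite asserts. Crucially, the truth is **not** the
solver's own output, so waveform-shape recovery is not circular. Because
redundancy makes only the minimum-cost solution unique, we do not expect —
or test — recovery of the raw truth activations; recovery assertions target
the moments, the activation ratio, and KCF.

Raw EMG is synthesized as band-limited (30–450 Hz) zero-mean noise,
amplitude-modulated by the truth activation advanced by 40 ms (so the
processed, delayed envelope re-aligns with the truth), plus additive sensor
noise; an MVC segment with modulator 1 provides the normalization
reference. The envelope pipeline recovers the modulator with correlation
above 0.95 and the stance-averaged activation ratio within 0.03.

The retention preset scales both gastrocnemius bump amplitudes by 0.7 and
solves in closed form for the soleus amplitude scale that reduces the
ground-truth medial gastrocnemius-to-soleus activation ratio by exactly
25%. The cohort generator jitters bodyweight (±10%) and per-muscle bump
amplitudes (±8%) per subject.

The default amplitudes and the intersegmental profile (double bump peaking
near 1.1–1.15 BW) were chosen once, from normative gait mechanics: ankle
plantarflexion moment peaking near 1.5–1.9 N·m per kg, early-stance knee
extension moment near 1 N·m per kg, total KCF between 2 and 4 BW with a
50–75% muscle share. These are the packaged study conditions, not tuning
knobs.

What the synthetic conditions do *not* emulate: measured marker-based
kinematics and kinetics (with their soft-tissue and filtering artifacts),
EMG crosstalk and electrode-placement variability, inter-subject variation
in muscle geometry (the fixture's moment arms are shared by all synthetic
subjects), co-contraction beyond the tonic baseline, and any frontal-plane
mechanics. Passing tests therefore demonstrate the machinery is correct and
the mechanism is as described; they do not validate magnitudes against
instrumented-implant data.

## The model fixture

`default_model()` carries 14 muscles with literature-plausible Hill
parameters and moment arms for a generic adult (75 kg, 736 N). Two
properties are imposed exactly as construction constraints rather than left
to the plausible values: the functional groupings used in the KCF
decomposition (quadriceps; hamstrings = biceps femoris long/short head,
semitendinosus, semimembranosus; gastrocnemius = medial and lateral heads;
tensor fasciae latae), and the optimal-force-weighted
hamstrings:gastrocnemius knee flexion moment-arm ratio at the 75%-stance
posture, set to 1.7 by uniformly rescaling the hamstring knee moment arms.
That ratio is the mechanical reason hamstring compensation is cheap: the
hamstrings can replace the gastrocnemius knee flexion moment with ~1/1.7 of
the force. All other fixture numbers are plausible defaults, not fitted
values. Reference MTU lengths are set so every fiber sits at optimal length
with a slack tendon in the upright reference posture, which also makes the
"zero moments at reference posture" case exactly silent (no passive force
anywhere).

## Degenerate inputs and tie-breaks

* Zero-moment frames: all activations and reserves are zero (strict
  convexity; verified to 1e-8).
* Identical agonists split load equally (uniqueness of the QP minimizer).
* Ratio targets with `r + tol >= 1` or `r − tol <= 0` yield one-sided,
  automatically satisfied inequalities and are kept for uniformity.
* An EMG ratio constraint whose target equals the unconstrained solution's
  own ratio is inactive and leaves the solution unchanged.
* Peaks: for KCF both half-stance extrema are maxima, since the contact
  force is compressive-positive throughout stance (the minimum-in-late-
  stance convention applies to signed angle/moment curves, not to KCF).

## Problem sizes and runtime

The packaged conditions are deliberately desk-scale: one gait cycle of 111
frames per trial, a 14-muscle model (17 QP variables per frame), EMG at
2 kHz for 1.1 s, and a 3-subject cohort in the analysis scripts. A full
trial solve takes ~2 s; the entire analysis workflow and the acceptance
script each run in well under a minute.

## Known limitations

Beyond the emulation gaps above: the solver treats each frame's QP exactly
but the fiber-equilibrium linearization lags activation by one frame (10 ms
here), so very rapid activation transients would see slightly stale force
coefficients; the constant knee-axial projection ignores posture dependence;
no medial/lateral compartment split is computed; and inferential statistics
are intentionally absent from the cohort summaries — a synthetic cohort can
only be described, not tested.
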