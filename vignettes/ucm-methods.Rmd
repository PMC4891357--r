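---
title: "Uncontrolled manifold analysis of tool-extended reaching: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncontrolled manifold analysis of tool-extended reaching: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ucmreach)
```

## The scientific problem

When a person points at a target, the arm has more degrees of freedom than
the task requires: many different joint configurations place the fingertip
(or the tip of a hand-held rod) at the same spot in space. The uncontrolled
manifold (UCM) method exploits this redundancy to ask *how* the motor system
uses it. Inter-trial variability of the joint angles is split into a
component that lies along the manifold of configurations leaving the tip
position unchanged — goal-equivalent variability (GEV) — and a component
orthogonal to it, which does displace the tip — non-goal-equivalent
variability (NGEV). When GEV exceeds NGEV, the tip position is said to be
stabilized by flexible joint covariation.

`ucmreach` implements this analysis for a nine-degree-of-freedom
arm-plus-rod chain (three shoulder angles, elbow flexion, forearm pronation,
two wrist angles, two finger angles), together with the endpoint-kinematics
battery used to characterize point-to-point reaches, and a synthetic trial
generator that emulates an eight-condition rod-pointing design (rod lengths
0/10/20/30 cm crossed with displacing the participant by the rod length), so
that the whole pipeline can be verified without motion-capture data.

## The kinematic model

The chain is described in a lab frame with the origin at the shoulder
center, +x pointing horizontally toward the target, +y to the participant's
left and +z up. Start and target points lie in a horizontal plane below the
shoulder. Each segment extends along its local +x axis and the zero posture
is the arm fully straightened along +x with the rod collinear with the
finger.

The rotation conventions are the package's own explicit definition (the
common guideline conventions for upper-limb angles leave the rotation
sequences to be fixed by the implementer, and reproducing any particular
marker-based convention is a non-goal here):

* shoulder: intrinsic `Rz(plane of elevation) · Ry(elevation) · Rx(axial
  rotation)`, with positive elevation lowering the arm from horizontal so
  that the hanging start posture has a positive elevation angle;
* elbow flexion, wrist flexion, finger flexion: rotations about the local
  −y axis, so positive flexion bends the distal segment forward/up from the
  hanging posture;
* forearm pronation: rotation about the forearm axis;
* wrist and finger abduction: rotations about the local +z axis, applied
  before the corresponding flexion.

With only shoulder elevation and elbow flexion nonzero the chain reduces to
a planar two-link arm (link 1 = upper arm, link 2 = forearm + hand + finger
+ rod), for which position and Jacobian have closed forms; the test suite
uses those closed forms as an independent oracle.

The Jacobian of tip position with respect to the nine angles is computed by
central finite differences with step `h = 1e-6` rad rather than symbolically:
the truncation error is of order `h² · chain length` (≈ 1e-9 mm), far below
anything the analysis resolves, and the numerical route remains correct if
the rotation conventions are ever revised. Null-space and orthogonal-space
bases come from the singular-value decomposition, with singular values below
`1e-10` of the largest treated as zero. A rank-deficient Jacobian (fully
stretched arm) is flagged rather than fatal, because callers may still want
the degenerate decomposition; synthetic postures are kept away from full
extension by construction.

## The UCM decomposition

For an ensemble of trials, the joint-angle covariance matrix `C` across
trials is computed at a movement instant (unbiased, n−1 denominator; the
choice of denominator is a package decision and the brute-force oracle uses
the same). With `E0` the null-space basis and `E⊥` the orthogonal basis of
the Jacobian at the ensemble-mean configuration,

```
NGEV = trace(E⊥ᵀ C E⊥) / d        d = 3 task dimensions
GEV  = trace(E0ᵀ C E0) / (n − d)  n = 9 joint dimensions
V_Ratio = GEV / NGEV
```

each normalized per dimension of its subspace. Because `E0` and `E⊥`
together form an orthonormal basis of the joint space, `d·NGEV + (n−d)·GEV =
trace(C)` holds exactly; the suite enforces it to 1e-10 relative. The
decomposition is invariant to orthonormal re-mixing within each basis, so
the arbitrariness of SVD basis vectors is immaterial.

UCM variables are log-transformed (natural log; any base gives the same sign
conclusions) before aggregation, since their sampling distributions are
strongly right-skewed. `V_RatioLog > 0` is the stabilization signature. A
zero NGEV (e.g. noise-free data) makes the ratio and the logs of
NGEV/V_Ratio undefined; the package returns `NA` with the rest of the result
intact rather than propagating infinities.

`ucm_decompose_oracle()` recomputes GEV/NGEV by explicitly projecting each
trial's deviation from the mean onto each basis vector and averaging the
squared projections — an independent arithmetic route that the tests hold to
1e-10 relative agreement against the trace formula.

## Endpoint kinematics

Tangential velocity is the norm of the sample-wise derivative of the 3-D tip
position (central differences, one-sided at the ends, no smoothing — an
optional low-pass exists nowhere because the analysis pipeline never needed
one and the generator produces band-limited data). Movement start is the
first sample with speed above 25 mm/s while outside a 10 mm radius of the
start point; movement end is the first subsequent sample with speed below
25 mm/s while inside 10 mm of the target. Both predicates are required
simultaneously, with strict inequalities.

One consequence worth stating explicitly: on an ideal minimum-jerk reach the
two bounds are *not* symmetric. The start fires when the tip leaves the
10 mm start radius (about 15% into the motion, since the velocity threshold
is crossed while still within a fraction of a millimetre of the start),
whereas the end fires at the 25 mm/s velocity crossing, which happens within
0.2 mm of the target — well inside the 10 mm radius. Acceleration time
measured from detected bounds is therefore genuinely shorter than
deceleration time even for a symmetric velocity profile. The package's
symmetry checks for `phase_times()` consequently use the nominal symmetric
movement window; the detection rule itself is verified against a brute-force
per-sample predicate scan.

Curvature is the unsigned maximum deviation of the in-bounds path from the
start–target chord after projection onto the transversal (x–y) or sagittal
(x–z) plane. Absolute error is the mean over trials of the endpoint–target
distance; variable error is its (n−1) standard deviation. Time normalization
interpolates linearly onto 100 points at fractions k/100 of the movement
time from the detected start, so "1%" is the first normalized point and the
100th point is exactly the end-of-movement sample; the UCM variables are
reported at the 100% instant by default (the instant at which the tip must
be stabilized), with an option to compute all 100 instants.

## The synthetic trial generator

The generator emulates the study design: 8 conditions (rod 0/100/200/300 mm
× displaced / not displaced), 25 trials per condition, 100 Hz sampling,
start and target 300 mm apart on a horizontal plane 250 mm below the
shoulder. In displaced conditions both points shift away from the shoulder
by the rod length, keeping the required tip amplitude and joint excursions
comparable across rods; in non-displaced conditions longer rods need smaller
joint excursions (the suite asserts strictly decreasing joint path length).

Each condition's reference movement is a straight minimum-jerk path
(`10τ³ − 15τ⁴ + 6τ⁵`) tracked by damped least-squares inverse kinematics
(damping 0.01, convergence at 0.01 mm tip residual), preceded and followed
by stationary holds (0.4 s and 0.8 s) so that threshold-based bounds
detection is actually exercised. The default movement time is 0.6 s, giving
a minimum-jerk peak speed of 0.94 m/s for the 300 mm reach — within the
1.0–1.2 m/s range typical of seated pointing at this amplitude. The default
start posture has the upper arm roughly alongside the body with the elbow
flexed ≈ 100°, the customary initial posture for tabletop pointing.

Inter-trial variability is injected in *joint* space, because that is the
space the UCM analysis decomposes, and isotropically *within* each subspace,
because that makes the ground truth analytic: at every sample the deviation
of trial j from the reference is

```
δⱼ(t) = [ σ_ngev · I + (σ_gev − σ_ngev) · P_null(t) ] · wⱼ(t)
```

where `P_null(t)` is the null-space projector of the Jacobian at the
reference posture of sample t and `wⱼ(t)` is a 9-channel unit-variance noise
process, smoothed in time by a Gaussian kernel (default 0.4 s standard
deviation) and rescaled to exactly unit instantaneous variance (the
smoothing matrix is row-normalized, so edges are exact too). Because
projectors — unlike SVD basis vectors — vary continuously along the
reference, δⱼ(t) is smooth and perturbed trials still pass velocity-based
bounds detection. By construction the cross-trial covariance at sample t is
`σ_gev² P_null + σ_ngev² P_orth`, so the true per-dimension GEV and NGEV at
any injection instant are exactly `σ_gev²` and `σ_ngev²`. Defaults are
σ_gev = 2°, σ_ngev = 0.5° (a 4:1 ratio, true V_Ratio 16), which yields
endpoint scatter of a few millimetres, the same order as the accuracy
reported for this kind of pointing task. Tip trajectories are recomputed
from the perturbed angles by forward kinematics — nothing is linearized in
the generated data.

What the generator does *not* emulate: signal-dependent motor noise,
inertial effects of the rod's mass, anatomical joint limits, measurement
noise of a motion-capture system, or the non-stationary, condition-dependent
covariance structure of real movements. Passing tests therefore demonstrate
the correctness of the computational pipeline under a known ground truth,
not fidelity of the generator to human data.

## Parameter recovery and the estimation instant

Two estimation paths exist, and they answer different questions.

`analyze_ensemble()` is the measured-data path: per-trial bounds detection,
per-trial time normalization, UCM at the 100% instant. Applied to synthetic
data it carries a subtle selection effect: a trial's detected end is a
sample at which the tip is *conditioned* to lie within 10 mm of the target,
which truncates the orthogonal-space deviations and deflates NGEV by
roughly 10–25% at the default noise level (trials whose deviations never
satisfy the landing predicate are additionally dropped, in the same
direction). Real movements do not have this problem to the same degree —
they genuinely land — but for the generator the injected deviations persist
through the holds by design, so the truth is only available on the common
time base.

`ensemble_ucm()` therefore evaluates the decomposition at an *injection
instant* — by default the reference end-of-movement sample on the ensemble's
shared clock — where the injected variances are exact. Parameter-recovery
checks use this estimator: over 20 replicate 500-trial ensembles the mean
estimated GEV and NGEV come back within a few percent of σ_gev² and σ_ngev²
(the suite requires 15%, and 30% on V_Ratio). The stabilization-signature
check — V_RatioLog > 0 at the study's own 25 trials per condition, required
in ≥ 95% of 200 replicates — deliberately uses the full `analyze_ensemble()`
path, because a sign conclusion should be robust to the detection-path
biases just described.

## Pipeline and determinism

`run_pipeline()` reads a YAML config (geometry, conditions, variability
model, thresholds, seed), simulates every condition (condition i uses seed
`base + i`), analyzes each ensemble, and writes per-condition JSON records,
three condition-by-metric CSV tables (accuracy errors; endpoint kinematics
as mean (SD) across trials; GEV/NGEV and their logs by condition), and a
plain-text log of every detection failure and singularity flag — trials are
never silently dropped; the summary tables carry `n_trials` and `n_failures`
per condition. All outputs are byte-identical across reruns of the same
config. Descriptive aggregation is the deliberate boundary of scope: no
repeated-measures ANOVA, effect sizes, or post-hoc tests are computed.

Problem sizes used by the verification suite — 100 random covariance/posture
pairs, 100 random ensembles of 5–50 trials, 20 replicates of 500 trials for
recovery, 200 replicates of 25 trials for the stabilization rate, and the
8 × 25 study pipeline run twice — were chosen so the full suite runs in a
few minutes on one core while keeping Monte-Carlo error well below the
tolerances being asserted.

## Known limitations

* The rotation conventions are a self-consistent package definition, not a
  reconstruction of any marker-based guideline; absolute joint-angle values
  are not comparable to published group means, though the variability
  decomposition (which depends on the chain only through its Jacobian) is.
* The damped least-squares inverse kinematics returns one of infinitely many
  joint-space solutions; it is deterministic and smooth but not a model of
  human posture selection.
* NGEV estimated through per-trial bounds detection on synthetic data is
  biased low by the landing-radius conditioning described above; use
  `ensemble_ucm()` when the ground truth matters.
* The generator's isotropic-within-subspace noise is a verification device;
  real joint-space covariance is anisotropic and task-dependent.

## Worked example

```{r example, eval = FALSE}
cond <- condition_spec(rod_length = 200, displaced = FALSE)
model <- variability_model()          # 2 deg GEV, 0.5 deg NGEV, seed 1
ens <- generate_condition_dataset(cond, model = model)
res <- analyze_ensemble(ens)
res$ucm                               # GEV, NGEV, V_Ratio and logs at 100%
summarize_results(list(res))$kinematics
```
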