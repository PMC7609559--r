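---
title: "Models and numerics behind coarctflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerics behind coarctflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coarctflow)
```

`coarctflow` chains five stages: measured (or synthesized) patient data →
boundary conditions → an axisymmetric stenotic-flow simulation →
hemodynamic descriptors → paired rest-versus-exercise cohort statistics.
This vignette records the models, the parameters that matter, the numerical
choices, and what the package's verification does and does not demonstrate.

## The reduced-order flow model

The aorta is represented as an axisymmetric tube of reference radius
$R_{ref}$ with radius profile $r(z) = R_{ref}\,(1 - D\,w(z))$, where
$w$ is a $C^1$ cosine bump of length $l_s$ centred at $z_s$ and $D$ is the
diameter-based degree of stenosis. The axial coordinate starts at the
sinotubular junction (the inlet). The vessels branching from the aortic
arch cannot be represented in an axisymmetric geometry; their net outflow
$Q_{asc} - Q_{desc}$ is instead extracted through a wall band upstream of
the stenosis as a uniform outward normal velocity (`build_sink_band()`).
This is the single largest geometric idealization in the package: arch
curvature, branch take-offs and patient-specific lumen shape are all
absent, so simulated fields are structurally comparable to, but not
quantitatively identical with, 3-D patient-specific simulations.

Blood is incompressible with density 1050 kg/m³ (a standard whole-blood
value) and shear-thinning Carreau–Yasuda viscosity

$$\mu(\dot\gamma) = \mu_\infty + (\mu_0-\mu_\infty)
  \bigl[1+(\lambda\dot\gamma)^a\bigr]^{(n-1)/a},$$

with defaults $\mu_0 = 0.16$ Pa·s, $\mu_\infty = 3.5$ mPa·s,
$\lambda = 8.2$ s, $a = 0.64$, $n = 0.2128$ — a widely used whole-blood
parameter set. All five constants and the density are configuration, not
ground truth (`carreau_yasuda()`, `solver_params()`); the shear rate uses
the full axisymmetric deformation-rate magnitude
$\dot\gamma = \sqrt{2\,\mathbf{D}\!:\!\mathbf{D}}$ including the
$u_r/r$ hoop term.

The flow is solved **steady at peak systole** and **laminar**. Peak-systolic
Reynolds numbers in a coarctation reach the transitional regime, and
3-D clinical solvers typically add a turbulence model; keeping the
desk-scale solver laminar is the central physical approximation, so every
`flow_field` carries its inlet Reynolds number and users should treat
results above Re ≈ 2000 as qualitative. One practical consequence: a
laminar axisymmetric jet recovers pressure almost completely, so absolute
desk-scale gradients are much smaller than clinical ones at the same flow.
The package therefore verifies the solver against closed-form laminar
theory and *monotonicity* of the gradient in flow, and reproduces the
clinical gradient statistics from the packaged cohort's tabulated values
rather than from desk-scale simulation.

## Meshing rules

`mesh_spec()` encodes the grid sizing: base cell size $\Delta$ = 0.4 mm; a
wall boundary layer of 3 cells whose total thickness is $\Delta/3$ with
each layer 50 % thicker than the one beneath it (hence $t = (\Delta/3)/4.75
\approx 28.07\,\mu$m at the wall); axial spacing refined from $\Delta$
towards a 0.1 mm floor wherever the wall slope $|dr/dz|$ exceeds 0.5 (the
slope is the available smooth proxy for "high curvature" on a parametric
profile). The grid lives in mapped coordinates $(z, \eta = r/r(z))$; layer
thicknesses are exact at the reference radius and scale with the local
radius inside the narrowing. Cell volumes use the axisymmetric $2\pi r$
weight with a midpoint rule in $z$, which makes the total mesh volume
second-order accurate against the analytic solid of revolution.

## The SIMPLE solver

Pressure–velocity coupling is the classic SIMPLE iteration on a staggered
arrangement: axial velocity on axial faces, radial velocity on radial
faces, pressure at cell centres. Face volume fluxes are formed in physical
space — radial faces of the mapped grid are conical, so their flux uses
$(v - u\,\eta\,r'(z))$ — which makes discrete continuity exact cell by cell
at convergence; the conservation suite checks every transverse plane
against the inlet-minus-sink budget to 0.1 % and in practice sees machine
precision. Convection is first-order upwind (robust, and exact for the
fully developed verification cases where convection cancels identically);
diffusion is central. The metric cross-diffusion terms of the mapping and
the radial projection of the axial pressure gradient are neglected — exact
for straight segments, a controlled approximation over the smooth, short
stenosis bump. Under-relaxation defaults to 0.7 (momentum), 0.3
(pressure), 0.5 (viscosity); normalized residuals (momentum scaled by
$\rho Q U_{in}$, continuity by $Q$) must all fall below $10^{-6}$ within
20 000 iterations, with a divergence guard that aborts with the residual
history. The outlet copies the upstream profile and rescales it to the
global mass balance; the axis is a symmetry line; walls are rigid no-slip.
Wall shear uses one-sided second-order differencing through the graded
wall layers (a quadratic through the no-slip point and two cell centres),
with viscosity evaluated at the wall shear rate.

Verification, run in the test suite at desk-scale problem sizes (tube
length 2–5 cm, radius 1 cm, 100 ml/s): Hagen–Poiseuille velocity profile,
pressure drop $8\mu Q/\pi R^4$ and wall shear $4\mu Q/\pi R^3$ within 2 %
on the default mesh, with second-order grid convergence over three
refinement levels; stenotic runs (D = 0.5) at 15/30/45 ml/s demonstrate
strict monotonicity of the computed gradient in inlet flow. These flows
keep the throat Reynolds number within the laminar solver's comfort zone —
the monotonicity property, not the absolute gradient, is the claim.

## Boundary conditions

`map_inlet_profile()` reduces a velocity-encoded plane to the axisymmetric
inlet: the through-plane component is azimuthally averaged into a radial
profile, linearly interpolated onto the inlet nodes (zero outside the
measured lumen, consistent with no-slip), and rescaled by one global
factor so the discrete inlet flux equals the measured flow exactly. A
pre-scaling mismatch above 25 % raises a warning, mirroring the practical
fallback from volumetric to planar velocimetry when planes are misaligned
or aliased. In-plane components have no axisymmetric counterpart at the
inlet and are used only by the plane metrics.

`murray_split()` partitions the arch branch flow. The phrase "equally
distributed within the brachiocephalic artery as well as the left common
carotid and left subclavian arteries" admits two readings; the default
gives the brachiocephalic trunk half the total (it supplies two downstream
beds — right arm and head) and a quarter each to the other two, with the
equal-thirds reading selectable (`arch_rule = "equal"`). Below the arch
level, child flows follow Murray's law ($\propto r^3$) and terminal flows
sum to the input exactly.

## Plane metrics

Secondary flow degree is the mean in-plane speed over the mean
through-plane velocity on the lumen mask; it is undefined near zero net
flow (guarded by an epsilon of $10^{-6}$ m/s). Normalized flow
displacement is reported in two variants because the literature uses both:
the default follows the "position of the velocity maximum" wording (ties
resolved to the masked point nearest the centre, so plug flow yields 0),
and a flow-centroid variant — linear in the data and therefore unbiased
under additive noise — is selectable. Both are clipped to $[0, 1]$.

## The synthetic cohort generator

`cohort_distribution_spec()` fixes the study conditions: stenosis degree
35.1 ± 18.1 % (truncated to keep the throat open, below 95 %), BSA
1.6 ± 0.4 m², resting heart rate 72.9 ± 14.2 bpm with an exercise target
of +50 bpm achieved at 85.79 ± 10.28 %, stroke volume index 50.6 ± 6
ml/m², resting ascending flow 407 ± 87.3 ml/s, and cuff pressures matching
the cohort means. Quantities the cohort tables only constrain in aggregate
are modelling choices made once: the exercise-to-rest flow scale is
lognormal around the cohort ratio (494.4/407) with log-SD 0.13 estimated
from the per-patient ratios of the reference cohort, the
descending-to-ascending fraction is a truncated normal around 0.554, and
the aortic radius scales with body size as $12\,\mathrm{mm}\cdot
\sqrt{BSA/1.6}$. Truncated normals are sampled by rejection (exact
bounds); all draws for one patient flow through a single RNG seeded with
`seed + id`, so cohorts are reproducible patient by patient and
sub-sampling a cohort never changes earlier patients.

Measurement planes emulate velocity-encoded MRI on a 64 × 64 grid over the
lumen bounding square (discretization error of the plane metrics well
under 1 %): a blunted jet $u \propto 1-(\rho'/R)^k$ displaced by $d\cdot R$,
solid-body in-plane swirl calibrated to a target secondary flow degree,
per-component Gaussian noise (0.05 m/s at rest, 0.10 m/s under exercise —
exercise acquisitions are noisier), and optional phase wrapping into
$(-\mathrm{VENC}, \mathrm{VENC}]$ with VENC 3 m/s, raised to 4 m/s for
stenoses above 40 %. Exercise planes reuse the rest profile shape with
rescaled velocity and larger noise. The generator does **not** emulate
pulsatility, k-space physics, motion artifacts, eddy-current offsets or
segmentation error — passing parameter-recovery tests therefore shows the
metrics are correct on their idealized inputs, not that they are robust to
every MRI artifact.

## Cohort statistics

Normality is tested on the **paired differences** (the natural input of a
paired test) with Shapiro–Wilk; p ≥ 0.05 routes to the paired t-test,
otherwise to the Wilcoxon signed-rank test with zero differences dropped,
the exact distribution for up to 25 untied non-zero differences, and the
continuity-corrected normal approximation beyond. The signed-rank
implementation is cross-checked in the tests against brute-force
enumeration of all sign assignments up to n = 8. Cohort percent change is
the mean of per-patient relative changes — this convention, not the ratio
of means, reproduces the percent changes a per-patient analysis reports;
both are emitted for transparency. Threshold classification uses strict
inequality for "above 20 mmHg", and reverse crossings are counted
separately so the four categories always partition the cohort. No
multiple-testing correction is applied across the summary variables. The
routing reliability check uses n = 20 normal and n = 50 Cauchy differences
over 500 seeded replicates; at n = 20 the Shapiro–Wilk test has only
~86 % power against Cauchy tails, so the heavy-tailed arm uses the larger
pair count at which routing is reliable.

## Degenerate inputs and numerical edges

Zero inlet flow returns the exact rest state (zero velocity, uniform
pressure) without iterating. Identical rest and exercise vectors yield a
degenerate comparison with p = 1 rather than an error. Non-converged flow
fields refuse to produce wall shear or pressure gradients. The pressure
gradient is floored at zero and its P2 search is restricted to planes
downstream of the throat (for an unstenosed tube, downstream of the
inlet); it is invariant under constant pressure shifts because only
area-averaged differences enter. Cohort CSV cells that are empty stay
missing (`NA`) — zero is a legal physical value and is never used as a
missing-data sentinel.

## Known limitations

Laminar steady flow (no turbulence model, no pulsatility); axisymmetric
geometry (no arch curvature, no real branch take-offs, no secondary flow
generated by bends — the in-plane swirl of synthetic planes is imposed,
not simulated); rigid walls; first-order convection limits the sharpness
of recirculation zones; desk-scale absolute gradients understate clinical
ones because laminar jets recover pressure efficiently. The packaged
reference cohort is a transcription of published per-patient tables and
inherits their rounding (integer gradients, one-decimal flows); tests that
compare cohort summaries use tolerances matching that rounding.
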