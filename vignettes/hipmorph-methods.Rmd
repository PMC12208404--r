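---
title: "Models and methods behind hipmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hipmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hipmorph)
```

## The question the package operationalises

What would change, mechanically, if a modern human walked on an
australopithecine-shaped hip? The package answers a tightly controlled
version of that question: two musculoskeletal models that differ *only* in
hip shape (pelvis and proximal femur geometry, and therefore hip muscle
attachment sites) are driven by *identical* walking kinematics and ground
reaction forces; everything downstream of the shape change — muscle
activations resolved by a recruitment criterion, and the resulting hip
joint reaction forces — is then compared curve-by-curve over the stride.
Because the external loads are shared by construction, any difference in
the outputs is attributable to shape alone.

## Synthetic study conditions

No public mocap data ship with the package; a seeded generator produces
everything needed, which makes every downstream stage testable and every
result exactly reproducible.

**Cohort.** `generate_cohort()` draws subjects with alternating sexes
(10 subjects = 5 F + 5 M) from documented uniform anthropometry bounds
(stature 1.50–1.75 m F / 1.62–1.92 m M, BMI 19–29 kg/m²; inter-hip-centre
distance 10.2–11.4% of stature; hip-to-knee femur length 24–26% of
stature). The defaults — 10 subjects, 3 trials each — match the balanced
repeated-measures design the curve statistics require.

**Gait.** `generate_gait_trial()` poses the rigid-segment skeleton with
truncated Fourier joint-angle programs (single-harmonic ~20° hip
flexion wave; two-harmonic knee wave with stance and swing bumps; push-off
ankle wave; a 15 mm double-frequency vertical pelvis vault; small sway,
tilt, rotation waves; a 7° toe-out offset). Because the programs are
analytic, segment accelerations are available in closed form, and the
ground reaction force is *derived from the motion*: the summed plate
force equals the whole-body inertial-plus-gravitational force at every
frame, apportioned between the plates by a smooth double-support weight
(stance 62%, double support 14%) with an equal-and-opposite
braking/propulsion shear exchange (peak 0.12 body weight) that cancels in
the whole-body balance. This yields the classic two-peaked vertical
profile, nonnegative plate forces, a stride-average vertical force equal
to body weight — and, crucially, dynamic consistency: on noiseless trials
the inverse-dynamics residual force stays below 1% of body weight, so the
moments fed to the recruitment stage are trustworthy. Trial-to-trial
variability comes from two dials: multiplicative jitter on the program
amplitudes (SD 3%) and additive marker measurement noise (SD 2 mm). The
generator emulates level, straight, steady walking only: no soft-tissue
artifact, no turning, no real foot-ground contact model (feet may
approach the floor only approximately — forces come from the motion, not
from contact), and a trunk rigidly welded to the pelvis. Passing tests
therefore certify the pipeline's mechanics, not its fidelity to any real
subject.

**Hip shape.** `hip_shape_params()` encodes the contrast as four
dimensionless parameters applied at *equal inter-hip-centre distance*:
relative biacetabular breadth (1 → 1.25), femoral neck length (1 → 1.06),
iliac-blade anterior wrap (40° → 25°) and anteroposterior pelvic depth
(1 → 0.75). The australopith-like preset therefore has abductor origins
that sit lower (the ilium's height/breadth proportion falls with the
square of relative breadth — short *and* broad), markedly less anterior
(the origin fan's anterior limit is 90° minus the wrap angle), a slightly
longer neck (the neck/femur-length ratio of the fossil, scaled to equal
femur length, is only ~6% above the human value), and a compressed
inlet. The wrap angle deserves a note: purely skeletal readings of the
fossil suggest very low anterior wrap, but values below ~20° leave the
model without usable anterior abductor fibres and drive recruitment far
outside physiologic activation ranges (order 10), which no published
simulation of this morphology shows; 25° is the value at which the
variant operates in a physiologic regime while preserving a strong
contrast. Geometry and model share one parametric site map, so the mesh
landmarks and the model attachments always agree.

## Shape operations

The morphing toolbox mirrors standard geometric-morphometrics practice.
The thin-plate spline uses the 3D kernel `U(r) = r` with zero
regularization by default, so landmarks are interpolated exactly
(configurable; regularization is scaled by the mean kernel magnitude).
ICP is point-to-point with Kabsch updates and a monotone RMS trace;
because plain ICP converges only locally, the search multi-starts from
the identity plus the four proper centroid/principal-axes coarse
alignments and keeps the best final fit, which recovers arbitrary rigid
displacements of noiseless clouds to machine precision.
CPD follows the standard Gaussian-mixture non-rigid formulation with the
staged stiff-to-loose schedule (λ = 1; β = 50, 30, 10, 8 on unit-RMS
normalized clouds), each stage initialized from the last; correspondences
in the hybrid-femur pipeline are snapped to the nearest target vertex at
the end, since homologous locations are by definition points *on* the
target surface (this also makes the identity pipeline exact). Asymmetry
reduction is reflect–relabel–average: the landmark configuration is
mirrored across an estimated midsagittal plane, left/right labels
swapped, rigidly re-aligned (Kabsch) and averaged — a documented
approximation to published fossil-symmetrisation protocols whose exact
steps are not public; the mesh follows by TPS. "Evenly distributed"
control vertices use greedy farthest-point sampling started from the
point farthest from the centroid, which is deterministic without a seed.
The proximal femur region is defined by fraction of head-to-knee length
along the shaft axis (default 20%, 237 proximal / 2500 distal controls).

## The musculoskeletal model

Nine lower-body segments (pelvis, paired thigh/shank/talus/foot) plus a
lumped head-arms-trunk segment; 3-DOF ball hips, hinge knees, ankles and
subtalar joints; axes X = travel, Y = mediolateral, Z = vertical, all
angles zero in upright standing. Masses are fixed anthropometric
fractions of body mass (total exactly body mass), inertias from segment
length × radius-of-gyration approximations. The musculature is 122
straight-line elements with via points and no wrapping surfaces (a
documented limitation — wrapped paths would soften the posture dependence
of the gluteal fibre directions): 12-element gluteus medius, minimus and
maximus fans per side placed by the shape variant, plus iliopsoas,
adductors (anterior and posterior pairs), pectineus-like anterior
adductors, hamstrings, rectus femoris, vasti, gastrocnemius, soleus,
tibialis anterior, deep external rotators and tensor fasciae latae.
Maximum strengths are published order-of-magnitude values in newtons per
kilogram body mass, split equally within groups; both variants share them
exactly, so all claims are comparative. Strength is treated as
posture-independent ("instantaneous strength"), i.e. no force–length–
velocity scaling.

Moment arms use the tendon-excursion definition, −∂L/∂θ by central
difference (step 1e−5 rad), which the tests pin against closed-form
geometry (perpendicular-distance and law-of-cosines cases).

## Inverse dynamics

Marker fitting is hierarchical weighted least squares: rigid Kabsch pose
for the pelvis–trunk unit, rotation-only Procrustes for the thighs about
the known hip centres, closed-form planar Procrustes angles for the
hinges, and alternating closed-form hinge fits for the two-hinge
ankle/subtalar complex — exact on noiseless markers (the round trip test
demands 1e−6 rad). With 2 mm marker noise the documented accuracy bounds
are 0.03 rad RMS for flexion-class coordinates, 0.05 rad for axial
rotations and 0.2 rad for the weakly observed subtalar angle. Fitted
coordinates and plate forces are low-pass filtered with the same zero-lag
4th-order Butterworth (6 Hz default; signals are demeaned and
reflection-padded so startup transients act only on deviations), then
differentiated by central/second differences. Angular velocity,
acceleration and segment COM accelerations propagate analytically through
the chain, and joint loads follow by recursive Newton–Euler from the feet
upward — validated to 1e−8 relative against closed-form single- and
double-pendulum mechanics derived independently via Lagrange. Whole-body
residuals are reported at the pelvis and never corrected. The vendor-tool
parameter-identification step of the original workflow is replaced by
this per-trial least-squares fit with generator-known segment lengths — a
simplification, stated as such.

## Muscle recruitment

Each frame solves `min Σ aᵢᵖ` (default p = 3) subject to
`R diag(F) a = M`, `a ≥ 0`, over bilateral hip (3 DOF), knee and ankle
flexion. The solver is a primal-dual interior-point Newton method: the
objective Hessian is diagonal, so each iteration reduces to a DOF-sized
Schur complement; constraint rows are equilibrated to unit norm; the
barrier parameter tracks the complementarity gap to a 1e−9 relative
moment-balance tolerance. Strict convexity makes the minimiser unique
(tested by permutation-commutation). Activations above 1 are allowed and
flagged (`allow_overload_with_flag`), keeping infeasibility visible; a
hard `cap_at_1` policy is available. Frames whose demanded moment lies
outside the muscles' nonnegative span are flagged infeasible and answered
with the nonnegative least-squares match. Whether the original criterion
also normalizes by muscle volume is not stated in the sources this
package emulates; plain activation polynomials are used.

Joint reaction forces add, to the intersegmental force, each crossing
muscle's force along its joint-crossing path segment — so with all
activations zero the reaction equals the intersegmental force, and a
single active muscle shifts it by exactly its pull vector.

## Curve statistics

Curves are stride-normalized to 101 nodes, aggregated from elements to
anatomical muscles (forces sum; activations combine by strength-weighted
mean — the sources say only "combined", so this choice is switchable),
normalized by body weight, and left-side trials mirrored to pseudo-right
by flipping mediolateral components. The variant comparison uses
one-dimensional statistical parametric mapping with a *permutation*
repeated-measures ANOVA: for the two-level within-subject factor the
node-wise F reduces to the paired t² on per-subject condition-difference
curves, the family-wise threshold is the 1−α quantile of the permutation
distribution of the field maximum under within-subject whole-block label
flips (observed labelling included, so the test is exact under
exchangeability), and clusters get p-values from the maximum-extent
distribution. This replaces random-field-theory SPM deliberately:
permutation needs no smoothness estimate and targets the same inference.
Calibration is checked by Monte Carlo (500 null datasets × 1000
permutations: family-wise error 0.05 ± 0.02) and power by an injected
offset over nodes 40–60.

## Problem sizes and numerical choices

The reference design is 10 subjects × 3 trials × 2 variants at 100 Hz
(one stride ≈ 100–130 frames plus quarter-stride padding), solved
frame-wise; the full pipeline runs in minutes on one core. Tolerances
that matter: TPS exactness 1e−8 of the bounding-box diagonal; ICP
recovery 1e−6; recruitment moment balance 1e−6 of the peak moment;
noiseless whole-body residual 1% of body weight. Ties and degenerate
inputs: coplanar or duplicated TPS sources are rejected by name;
conflicting uniform-scaling targets raise an error listing the implied
factors; zero net moments return zero activations without a solve.

## What the design does and does not show

Two of the four qualitative contrasts reported for this morphology emerge
robustly from the package's parametric variant: lower gluteus maximus
activation and higher vertical hip joint reaction force on the
australopith-like hip. The other two (higher gluteus medius activation;
lower travel-direction reaction force during propulsion) do *not*
reproduce under the default synthetic conditions: with straight-line
muscle paths and a 13-group musculature, the cubic criterion responds to
the degraded abductor geometry by *substituting* toward anterior
co-contractors (pectineus-like adductors, tensor fasciae latae) rather
than by driving the medius fan harder, which simultaneously keeps medius
activation near or below the human level and adds forward-directed muscle
pull at the hip. Reproducing the substitution-resistant behaviour of the
original cadaver-derived model most likely requires its wrapped,
regionally attached muscle geometry, which is proprietary. The package
reports this honestly rather than tuning the generator to the expected
answer; the acceptance suite asserts all four orderings and the two
non-reproducing ones fail visibly.

Beyond that, all limitations of the synthetic conditions apply: the
generator's gait is smoother and more symmetric than real walking, the
trunk is rigid, strengths are generic, and absolute activation or force
levels carry no empirical weight — only within-pipeline comparisons do.
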