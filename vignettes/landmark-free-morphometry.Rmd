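---
title: "Landmark-free morphometry of bilateral bone symmetry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-free morphometry of bilateral bone symmetry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radsym)
```

## The problem

When the articular surface of a distal radius is destroyed by an
intra-articular fracture, the contralateral (mirror-image) radius is the
natural template for a patient-specific reconstruction — provided the two
sides are actually symmetric. radsym quantifies that assumption without
landmarks: instead of comparing a handful of manually placed points, it
registers the entire bone surface of one side onto the mirrored other side
with a smooth, invertible deformation, and reads the residual asymmetry off
the per-vertex deformation itself. The same machinery, pointed at a cohort
rather than a pair, estimates a mean shape (atlas) and measures how far each
individual lies from it — the population-variability side of the same
question.

## The deformation model

Deformations are generated by a control-point parameterisation of the LDDMM
(large-deformation diffeomorphic metric mapping) framework. A set of control
points $c_i \in \mathbb{R}^3$ carries momentum vectors
$\alpha_i \in \mathbb{R}^3$; together they induce the velocity field

$$v(x) = \sum_i K_{\sigma_V}(x, c_i)\,\alpha_i, \qquad
K_\sigma(x, y) = \exp(-\lVert x-y\rVert^2/\sigma^2),$$

and the deformation is the unit-time flow of $v$ while $(c, \alpha)$ evolve
under the Hamiltonian system

$$\dot c_i = \sum_j K(c_i, c_j)\,\alpha_j, \qquad
\dot \alpha_i = -\sum_j \nabla_{c_i} K(c_i, c_j)\,(\alpha_i \cdot \alpha_j),$$

whose conserved energy $H = \tfrac12 \sum_{ij} K(c_i,c_j)\,
(\alpha_i\cdot\alpha_j)$ is also the regularity term of the registration
cost. Note the kernel convention: no factor 2 in the denominator of the
exponent. Every width quoted here follows that convention; with the
alternative $2\sigma^2$ convention our $\sigma = 2$ corresponds to
$\sigma \approx 1.41$.

The flow is integrated with the midpoint (RK2) scheme over
`n_time_points - 1` uniform steps (default 10 time points). At that
resolution the Hamiltonian drifts by well under 1% over unit time, and the
endpoint agrees with a 1000-step integration to better than $10^{-4}$ mm on
the systems used in the tests; both properties are asserted in the test
suite.

## The attachment: unoriented varifolds

Surfaces are compared as varifolds. Each triangle contributes its centre
$f_p$ and area-weighted normal $n_p$, and two surfaces interact through

$$\langle A, B\rangle = \sum_{p,q}
\exp\!\big(-\lVert f_p - g_q\rVert^2/\sigma_W^2\big)\,
\frac{(n_p \cdot m_q)^2}{\lVert n_p\rVert\,\lVert m_q\rVert},$$

with $d^2(A,B) = \langle A,A\rangle - 2\langle A,B\rangle + \langle
B,B\rangle$. The squared-cosine (Cauchy–Binet) normal term makes the metric
insensitive to face orientation, so a winding flip cannot masquerade as
shape change — the unoriented choice, preferred over oriented currents for
segmentation-derived meshes whose orientation conventions may differ.

The registration cost is
$d^2(\phi(S), T)/(2\sigma_\epsilon^2) + H(\alpha)$ with
$\sigma_\epsilon = 0.0005$ mm by default. That tiny noise level makes the
data term dominate the regularity by roughly six orders of magnitude: the
fit is essentially interpolating, which is appropriate for clean
segmentation surfaces but ill-conditioned on noisy ones — raise
`noise_std` towards 0.1 mm in that regime.

### What the varifold does *not* constrain

The varifold metric sees surfaces as measures: it pins down the *shape* of
the deformed surface but not the tangential parameterisation. Registration
therefore recovers the normal component of a displacement faithfully while
the tangential component of the recovered correspondence is determined by
the optimisation path, not the data. Two consequences matter for
interpreting results. First, correspondence-based distances can exceed the
normal-projected ground truth by a tangential-sliding contribution. Second,
recovery experiments are cleanest when the simulated truth is itself
normal-directed — which is how the phantom generator injects asymmetry (see
below), and also exactly the inward/outward deviation that the signed
distance statistic reads out.

## Gradients and optimisation

Gradients of the cost with respect to the momenta (and, for free-template
atlases, the template vertices) are computed by a hand-derived reverse-mode
sweep: the varifold gradient with respect to the deformed vertices is
chained through the RK2 integrator by an adjoint recursion using
vector–Jacobian products of the Hamiltonian right-hand side. The contract —
asserted in the tests — is agreement with central finite differences to
better than $10^{-4}$ relative on small systems.

The optimiser is steepest descent with a backtracking line search: the step
halves on a cost increase and grows 1.5× after every accepted step, the
first update is capped at a control-point motion of $0.1\,\sigma_V$, and
iteration stops when the relative cost change falls below
`convergence_tol` (default $10^{-4}$) or at `max_iterations`. Accepted
steps are monotone by construction. Control points sit on a regular grid
over the padded bounding box, pruned to within two spacings of the surface,
and stay frozen during optimisation.

`control_spacing` deserves a note. Placing control points at the
deformation kernel width ($\sigma_V = 2$ mm) is the natural dense choice,
but on a full distal radius it yields thousands of control points, which is
the regime the original GPU tooling was built for. The dense-matrix
backend here is exact but benefits from coarser grids; analyses in this
package default to the dense convention while the documented examples and
the validation suite use spacings of 6–9 mm (a few hundred control points),
which resolve the smooth, centimetre-scale fields being studied.

## Rigid preprocessing

The pairwise chain mirrors the right mesh across $x = 0$ (flipping face
winding so normals stay outward), aligns each side's principal axis with
$+z$ by a single Rodrigues rotation (the sign fixed so the flared articular
end — identified as the end nearer the RS landmark — points to $+z$),
translates the lowest vertex to the origin, crops to 50 mm with an exact
clipping plane, rigidly aligns the mirrored right onto the left by Kabsch
least squares over RS, DSN and the vertex centroid, crops both to 43 mm,
and decimates to the 5295-vertex budget by quadric-error edge collapse.
Plane crops clip crossing faces with interpolated boundary vertices, so
crop lengths are exact rather than quantised to the mesh resolution. In
the final crop only $z$ is translated: a full lowest-vertex shift per side
would break the lateral frame the two sides just agreed on. The articular
subset is the set of vertices at or distal to the plane through DSN
perpendicular to the bone axis.

Atlas-mode preprocessing aligns every mesh (left sides mirrored into the
right-side chirality first) to the first subject's right mesh using RS,
DSN, DDR and the centroid. The atlas itself follows a two-pass scheme: a
deterministic atlas with the first subject's mesh as frozen template
produces corresponded deformations; their vertex-wise mean becomes the
atlas; the atlas is then re-registered to every mesh for the reported
distances and momenta. Registrations run template$\to$subject, consistent
with reading the deformation as "the atlas deformed onto this patient".

## Statistics

Per-vertex signed distances between corresponded meshes are
$\pm\lVert d_i\rVert$ with the sign of $d_i \cdot n_i$ against the source's
outward normal: positive = outward, negative = inward. Subject summaries
use $|d|$ (means in the literature's tables are positive; the sign lives in
maps and boxplots) — a `absolute = FALSE` switch exposes the raw values.
Group summaries report the unweighted mean of per-subject means; the group
SD pools all vertices of the group's subjects, a convention chosen because
the published group means are consistent with mean-of-means while no SD
rule is stated.

Momenta are flattened to one row per subject and z-scored per column
(zero-variance columns zeroed), then passed to kernel PCA with an RBF
kernel $\exp(-\gamma\lVert x - x'\rVert^2)$, $\gamma = 1/(p\,\mathrm{Var})$
by default — the usual scale-free choice where no value is prescribed; the
double-centred Gram matrix is eigendecomposed and scores follow the
$u\sqrt{\lambda}$ convention with a deterministic sign fix. Group structure
is tested per component with Shapiro–Wilk (normality), Kruskal–Wallis
(four groups) and all six pairwise Welch t-tests at $\alpha = 0.05$,
reported raw; no multiplicity correction is applied by default, mirroring
the reporting convention of the tables this reproduces, with a Holm option
available. Tests are reported for PC1 and PC2; sharing one control grid
across a cohort (built over the union bounding box of the preprocessed
meshes, whose frames are origin-anchored by construction) is what makes
momenta comparable across subjects.

## The phantom generator

No bone meshes are publicly deposited, so validation runs on seeded
phantoms that emulate the study design rather than the anatomy: a
superellipse tube with a distal flare, a styloid bump (apex = RS), a dorsal
notch (floor = DSN) and a dorsal rim point (DDR); four groups (2 sexes × 2
age bands, default 10 subjects each); per-subject smooth shape variation;
and a controllable left–right asymmetry. The phantom is stylised — it is
judged by parameter recovery and pipeline properties, never anatomical
fidelity.

Asymmetry is injected as a smooth scalar RBF field acting along outward
normals of the mirrored side (10 centres, width `asymmetry_smoothness` =
12 mm). The width is chosen for realism of the field's peak-to-mean
structure: bilateral asymmetry in the published per-patient tables has
maxima around 5-6x the subject mean, which a 12 mm field reproduces,
whereas widths near the deformation kernel scale produce isolated spikes
tens of times the mean that no bilateral bone plausibly shows; the field
remains comfortably resolvable by the sigma_V = 2 mm deformation model. The amplitude is
normalised so that the mean $|$amplitude$|$ over the *distal 43 mm* — the
region that survives cropping and is actually measured — equals the
requested `a`; normalising over the whole 60 mm pre-crop surface would make
the injected and measured quantities refer to different regions and the
comparison seed-dependent. Per-subject amplitudes default to
Uniform(0.3, 0.8) mm, the range of the published per-patient means. Random
rigid poses (rotations ≤ 30°, translations ≤ 20 mm) emulate scanner
position: large enough to exercise the alignment chain, small enough to
keep the principal-axis orientation unambiguous. Every output is a pure
function of (parameters, seed), and each pair ships its exact per-vertex
displacement field.

What the phantoms do *not* emulate: CT noise, partial-volume and
beam-hardening artefacts, segmentation variability, trabecular interiors,
or real anatomical shape statistics. A passing phantom suite therefore
demonstrates that the pipeline measures what it claims on data satisfying
its assumptions — not that those assumptions hold for any particular
scanner or reader.

## Numerical choices and degenerate inputs

* Isosurfaces are extracted by marching tetrahedra (six-tetrahedra cube
  decomposition, linear edge interpolation): a compact variant with no
  ambiguous cases, so the surface is crack-free by construction; volumes
  are padded with background so solids at the border still close.
* Voxelisation uses ray-parity along $+x$ and refuses non-watertight
  meshes.
* Decimation is quadric-error edge collapse with area-weighted quadrics,
  boundary-constraint planes (weight 10× area) so open crop boundaries do
  not shrink, lazy-deletion heap with deterministic tie-breaking.
* Kabsch alignment rejects reflections by construction (determinant
  correction) and errors on collinear configurations.
* Zero-area faces are skipped (with a warning) in varifold sums; the
  isotropic-vertex-cloud case errors in principal-axis alignment; crops
  that remove everything error rather than return empty meshes.
* Ties: `which.min`/`which.max` landmark picks and the decimation heap
  resolve ties by insertion order, keeping every generator and pipeline
  output bit-reproducible for a fixed seed.

## Problem sizes used in the validation suite

Routine checks run on deliberately small instances chosen to exercise every
code path at comfortable desk scale: phantoms of 500–900 vertices
(decimated to 220–320 for registration), control grids of 100–400 points
(spacing 7–9 mm), 10 time points, and mini-cohorts of 4–12 pairs;
statistical calibration uses 1000 score-level replicates of the null and 50
replicates of the 2-SD power setting on synthetic momenta. The full-scale
configuration (5295-vertex meshes, dense 2 mm grids) is the package
default for real analyses.

## Known limitations

* Dense kernel matrices: memory and time grow quadratically in faces and
  control points; the package targets the few-hundred-to-few-thousand
  range per mesh.
* Steepest descent converges slowly when the attachment term utterly
  dominates (the default $\sigma_\epsilon$); expect hundreds of iterations
  for tight endpoint recovery.
* Correspondence (not shape) is only weakly determined tangentially — see
  the varifold note above; statistics built on $|d|$ inherit a small
  positive bias from tangential sliding.
* The atlas's first pass inherits the first subject's topology and mesh
  resolution; a poor first subject propagates to the template.
* Landmarks still anchor the rigid stage; mis-placed RS/DSN shift the
  articular plane and the alignment, exactly as in any landmark-seeded
  pipeline.
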