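---
title: "Joint restacking and atlas mapping: model, priors, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint restacking and atlas mapping: model, priors, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stackmorph)
```

## The estimation problem

Classical histology observes a 3D brain only as a sequence of 2D sections
$J_i(x, y)$, $i = 1, \dots, n$, each independently rotated and translated by
the physical sectioning and mounting process. Restacking the sections into a
volume therefore requires estimating one in-plane rigid motion
$R_i = (\theta_i, t_i^x, t_i^y)$ per section. Without outside information
this problem is famously ill-posed: the curvature of an extended structure
is invisible in the sections, and any smoothness-driven alignment prefers a
straightened ("cylindrical") reconstruction over the true curved shape — the
*banana problem*.

`stackmorph` implements the joint estimator that resolves this: the observed
sections are modelled as noisy sections of an unknown brain
$I = I_0 \circ \varphi^{-1}$, a diffeomorphic deformation of a known atlas
$I_0$, and the rigid motions and the deformation are estimated *together*.
Writing $I^R(\cdot, z_i) = J_i \circ R_i$ for the restacked volume, the
estimator minimizes (the negation of) a MAP / penalized-likelihood
objective with four terms:

$$
E(R, v) \;=\;
\underbrace{\tfrac{1}{2}\,\rho\!\int_0^1 \lVert v_t \rVert_V^2\,dt}_{\text{deformation metric}}
\;+\;
\underbrace{\tfrac{1}{2}\sum_i \lVert D_h I^R(\cdot, z_i)\rVert_2^2}_{\text{stack smoothness}}
\;-\; \sum_i \log \pi(R_i)
\;+\; \sum_i \alpha_i \lVert I^R(\cdot, z_i) - I_0 \circ \varphi_1^{v,-1}(\cdot, z_i)\rVert_2^2 ,
$$

where $v_t$ is the time-varying velocity field generating
$\varphi$ through $\dot\varphi_t = v_t \circ \varphi_t$ (the LDDMM flow),
$D_h$ is the staggered finite difference along the cutting axis realizing
the first-order Sobolev prior, $\pi(R_i)$ are Gaussian priors on the
motions, and $\alpha_i \ge 0$ are per-section weights that allow damaged
sections to be censored ($\alpha_i = 0$). Optimization alternates an LDDMM
update of $v$ with the motions fixed ([`lddmm_descent()`]) and simultaneous
gradient sweeps over all $R_i$ with the flow fixed, both accepting only
decreases of the same objective, so the outer objective trace is
non-increasing by construction. Setting the matching weight to zero leaves
the **atlas-free** model (smoothness prior and motion priors only,
[`restack_atlas_free()`]); the full model is the **atlas-informed**
estimator ([`estimate_joint()`]).

## Priors and their parameters

**Rigid-motion prior.** Independent Gaussians: circular Gaussian on
$\theta$ (mean 0, standard deviation $\sigma_\theta$) and Gaussians on the
translations (means at the section centre, standard deviation $\sigma_c$).
The defaults are $\sigma_\theta = \pi/9$ — about 5% of the angular range —
and $\sigma_c = 7$ pixel pitches. The sources that motivate these defaults
label the pair "variances" while also describing them as standard
deviations of about 5% of each parameter's range; only the
standard-deviation reading is consistent with the 5% description, so that
is what the package adopts. With the conventional prior weight of 0.001 on
the rigid objective the distinction is immaterial to any estimate. Note
$\sigma_c$ is expressed in the *physical units of the translations*: at a
40 µm pixel pitch, pass `rigid_prior(sigma_c = 7 * 40)`.

**Stack-smoothness (Sobolev) prior.** The first-order norm penalizes the
squared z-derivative of the restacked volume, realized as forward
differences between adjacent sections on a staggered grid (`z_difference()`,
$n-1$ difference slabs for $n$ sections; the forced-zero boundary gradient
is realized by there being no term beyond the end sections). Only the
z-term enters the optimized objective: the in-plane first-derivative terms
are invariant to in-plane rigid motion of each section up to interpolation
error (verified numerically to better than 1% in the test suite), so they
would add cost without moving any argmax. The full first-order energy
including in-plane terms remains available as the diagnostic
[`h1_energy()`]. A difference term is counted only where both adjacent
sections observe the pixel; censored sections still participate in the
smoothness term by default (`censored_in_prior = TRUE`) because smoothness
is a prior on the reconstruction, not part of the likelihood — a switch is
provided because the alternative reading is also defensible.

**Deformation metric.** Velocities live in an RKHS with differential
operator $L = (1 - a^2\nabla^2)^s$, $s = 2$ by default, realized as an FFT
multiplier with the *discrete* Laplacian symbol so that the forward
operator $|\hat L|^2$ and the Green's kernel $K = (L^\dagger L)^{-1}$ are
exact mutual inverses on the grid (`apply_operator()` / `apply_kernel()`
round-trip to 1e-8; this exactness is why the multipliers are periodic on
the working grid rather than zero-padded — padding would break the inverse
pair through the intermediate crop). The printed operator
$(-\nabla^2 + 1)^2$ carries no length scale, while practical use tunes a
"kernel size"; these are reconciled by the scale-parameterized family
above with $a$ expressed in normalized image-width units (the registration
cascade default is $a = 0.05, 0.02, 0.01$). Whether the printed squared
operator means $s = 2$ or an effective $s = 4$ is ambiguous; $s$ is
exposed in `kernel_params()` with default 2, the conventional choice.

## Unit conventions and term balance

All matching and smoothness terms are physical integrals
($\int \cdot\, dx\,dy$ per section), so their relative weight depends on
the voxel size. Two conventions keep the printed weights meaningful:

* The **metric term** is taken per unit domain volume (the path energy
  divided by $|\Omega|$). The kernel scale is already expressed in
  normalized image-width units, and this normalization makes the 1.0
  (regularization) to 0.4 (matching) LDDMM ratio independent of grid size
  and units. `v_norm_sq()` itself remains the plain physical integral.
* The **simulation fixtures** emulate 40 µm isotropic sampling
  (`pitch = 40`), the sampling of the mouse-brain simulation studies this
  package's experiments are modelled on. At that pitch the per-pixel area
  weighting makes the matching term appropriately stiff relative to the
  smoothness prior; at unit spacing the two are comparable in scale, and
  the perfect-data fixed point of the joint estimator would drift by a few
  tenths of a pixel (smoothing and matching trading off), rather than the
  sub-0.1-pixel behaviour at the physical scale.

## Where the matching residual is evaluated

The per-section SSD is evaluated in each observed section's own frame,
$\lVert J_i - (I_0 \circ \varphi^{-1})(R_i^{-1}\cdot,\, z_i)\rVert^2$ — a
rigid change of variables (unit Jacobian) from the restacked form. The
difference matters discretely: resampling the *noisy* section $J_i \circ
R_i$ would let bilinear interpolation smooth the noise at fractional
offsets, lowering the noise energy there and carving spurious half-pixel
minima into the objective whose amplitude at noise $\sigma = 0.5$ exceeds
the true signal slope. In the section frame only the smooth deformed atlas
is interpolated; the noise term is constant in $R_i$ and the estimator
recovers jitter to subpixel accuracy. The smoothness term still acts on
the restacked $J_i \circ R_i$, as it is defined on the reconstruction.
The deformed atlas is taken as zero outside its frame; data masks, which
exclude missing pixels from every cost term, are transported with the
sections (nearest-neighbour) and intersected with the resampling domain.

Within the alternation, the LDDMM inner step descends the stack-frame
surrogate of the matching term (atlas deformed onto the restacked grid);
the outer loop re-evaluates the canonical section-frame objective and
accepts the velocity update only if it decreased, preserving the monotone
trace exactly.

## Discretization of the flow

A velocity field with $n_T \ge 2$ time nodes is integrated in $n_T - 1$
Euler substeps, substep $k$ using the average of the adjacent node fields;
the path energy uses trapezoidal quadrature on the same nodes, so metric
and flow share one discretization ($n_T = 1$ denotes a steady field). The
inverse map uses the semi-Lagrangian recursion
$\varphi^{-1}_{t+dt}(x) = \varphi^{-1}_t(x - dt\,v_t(x))$ with trilinear
interpolation (edge-extended for displacement fields), the forward map the
pointwise characteristic recursion. A substep displacing more than one
voxel pitch triggers a warning (CFL-style sanity check). Inside the
matching energy the deformed atlas is built by the equivalent iterated
image recursion $I_k(x) = I_{k-1}(x - dt\,v_k(x))$, and the gradient with
respect to every velocity node is the **exact adjoint** of that discrete
recursion (backpropagation through the Euler substeps and the trilinear
interpolation weights, with interpolation scatter playing the role of the
continuum $|D\varphi|\,\nabla I$ transport). This is why the analytic
gradient matches central finite differences of the discrete energy to
about 1e-3 relative error and better — the criterion the test suite
enforces — rather than the few-percent agreement typical of continuum
(Beg-style) gradients applied to a discrete energy. Descent preconditions
the gradient with the Green's kernel and uses backtracking line search
(initial step a small fraction of a voxel per unit gradient, growth 1.5 on
acceptance), so every recorded energy is an accepted decrease. Geodesic
relaxation, not geodesic shooting: the returned metric
$\int \lVert v_t\rVert_V^2\,dt$ is the path energy of the relaxation path,
and forward/backward registrations of the same pair agree in path energy
to within about 20% on smooth test pairs, a documented surrogate rather
than an exact symmetry.

## Rigid sweeps

All sections are updated simultaneously (Jacobi style) with one shared
backtracking step per sweep — the coupling through the Sobolev term is what
makes per-section line searches inconsistent — with Gauss–Seidel sweeps
available behind `sweep_mode = "gauss_seidel"` since no sweep order is
canonical. Rotation gradients are preconditioned by the mean squared
radius of the section extent so angular and translational steps move
comparable distances; the initial step is chosen so the first proposal
moves at most half a pixel. Rotation acts about the geometric centre of
the section's physical extent (the translation prior means sit at the
section centre, and centring decouples $\theta$ from $t$ as far as
possible). Convergence is declared when the relative objective change per
outer iteration falls below `tol` (default 1e-4, maximum 20 outer
iterations by default) — a criterion the package fixes since only its
existence, not its form, is conventional.

The sweeps are local. Starting from the prior means they converge
reliably for jitter within a couple of standard deviations, but a rare
far-tail draw (a few per thousand sections at σ = 6 px / 10°) can land in
a distant local minimum. [`init_motions_moments()`] provides the standard
remedy, an initial stack alignment: each section is lightly box-smoothed,
thresholded, and its intensity centroid and principal axis are matched to
the corresponding atlas section's (rotation resolved modulo π toward
zero). This starts every section within about a pixel and a few degrees
of the truth; `noise_study()` uses it, and `estimate_joint()` accepts it
through `init`.

## The synthetic data

`make_phantom()` generates curved/straight cylinders (binary, or with a
smoothstep edge over `edge_width` voxels — the soft edge keeps the
resampling error of a rigid motion below the 0.05 tolerance the tests
assert), Gaussian blobs, and a seeded "brain-like" body (ellipsoid with
3–5 interior intensity lobes and a gentle gradient) giving grayscale
contour structure without any real data. `section_phantom()` implements
the observation model: slabs are extracted, the *inverse* of each sampled
ground-truth motion is applied (so restacking with the returned truth
restores alignment, and estimates compare to truth without sign
gymnastics), optional cumulative shear of 0.25 px per section is composed
into the applied offset but excluded from the returned truth (shear
deforms the object; it is the diffeomorphic channel's job), and i.i.d.
Gaussian noise is added last. Jitter defaults are translation variance 36
(σ = 6 px) per axis and rotation σ = 10°; the rotation jitter is
elsewhere printed as "σ² = 100 in pixel units", which cannot be pixels
for an angle and is read as degrees. All generators are bit-reproducible
given their seed.

What the simulations do **not** emulate: stain texture, optical PSF,
section tearing/folding, out-of-order sections, within-plane shearing
distortion (excluded from the model by design), or cross-modality
contrast. Passing tests therefore demonstrate the estimator's statistical
behaviour under the stated observation model, not performance on real
histology.

## The packaged studies and their scales

* [`curvature_study()`] — the banana experiment: a 64×64×32 curved
  cylinder (apex deflection 8 voxels, radius 10), sectioned with moderate
  jitter (σ = 3 px, 5°; the object of study is curvature, not jitter
  recovery), reconstructed atlas-free and atlas-informed over 5 seeds.
  Expected behaviour, asserted by the acceptance tests: the atlas-free
  reconstruction retains less than half the true deflection (the
  straightening artifact), and the atlas-informed centroid-axis RMSE to
  the truth is strictly smaller than the atlas-free one on every seed.
* [`noise_study()`] — estimator statistics: a 64×64×16 elliptical
  cylinder (radii 20 and 11 voxels; the ellipse breaks the in-plane
  rotational symmetry that would make $\theta$ unidentifiable on a
  circular phantom), full jitter (σ = 6 px, 10°), additive noise
  σ = 0.5, 50 replicates (a desk-scale reduction of the 500-replicate
  protocol), the phantom itself as atlas. Since atlas and truth coincide
  the deformation update has nothing to recover and is skipped, isolating
  the rigid estimators. Expected: pooled translation RMSE and |bias|
  below one pixel and rotation RMSE below one degree, with
  RMSE² = bias² + variance holding to 1e-10 (population moments pooled
  over sections and replicates; per-section tables are also emitted since
  pooling order is a reporting choice).

Problem sizes (grids of 10³–64³ voxels, 3–20 time nodes, tens of sweeps)
are the package's desk-scale defaults: large enough that every phenomenon
of interest — straightening, recovery, monotonicity, subpixel RMSE — is
exercised, small enough to run on a laptop in minutes. All iteration
budgets are configuration, not constants.

## Degenerate inputs and edge behaviour

Constant images make the tissue-mask histogram degenerate (error);
single-slab volumes cannot form a z-difference (error); non-uniform
section spacing is rejected at construction; non-finite velocities,
motions or intensities are rejected on entry. Out-of-domain pixels after
resampling are zero in the image and zero in the mask, so they never enter
a cost term. The Jacobian determinant of every returned inverse map is
checked to be strictly positive on the interior; `random_diffeomorphism()`
errors («amplitude too large») rather than return a folded map.

## Known limitations

The LDDMM update is relaxation (Beg-style) gradient descent, not geodesic
shooting, so reported metrics are path energies of relaxation paths, upper
bounds on the geodesic metric. The two-channel (intensity + tissue-mask)
matching used on real histology is available (`use_mask_channel`) but the
monitored joint objective then tracks the intensity channel only, so the
strict monotone-trace guarantee applies to the default single-channel
configuration. Rigid estimation is local: with jitter far outside the
basin of the matching term (several object radii) the sweeps can converge
to a local minimum; the replicate harness records and bounds such
failures. Sections that are out of order or folded are outside the model;
censoring via $\alpha_i = 0$ is the supported mechanism and its detection
is left to quality control upstream.
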