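---
title: "Root growth kinematics by patch tracking: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Root growth kinematics by patch tracking: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`patchtrack` measures root growth as a flow: material points move away
from the quiescent center (QC) as the tissue between them and the QC
expands, and the spatial pattern of that expansion — not the endpoint root
length — is the phenotype. This vignette documents the model the package
implements, the assumptions behind it, the tunable parameters, the
numerical choices, and what the synthetic test bed does and does not
establish.

## The measurement model

### Patch motion

The data are pixel intensities $I(x, t)$. Endogenous structures (cell
walls, intercellular air spaces) modulate the transmitted backlight, so
intensity gradients travel with the tissue. Assuming a stationary camera
and constant illumination, a correctly tracked material patch satisfies
$D_t I = v \cdot \nabla I + \partial_t I = 0$.

Growth does not merely translate a patch: tissue expansion stretches it,
and a bending root rotates it. Both are captured to first order by a
velocity gradient around the patch center, $v(x + dx) = v(x) + \nabla v
\cdot dx$. Translation and gradient combine into a six-parameter affine
transform $T$, and the intensity-constancy residual becomes linear in $T$
through the tensor product $M = \nabla I \otimes d\tilde{x}$ of template
gradients with homogeneous patch offsets $(1, dx, dy)$.

The solver initializes $T$ to the identity and iterates: evaluate the
intensity change $D_t I$ under the current warp (sub-pixel sampling of
frame $n{+}1$), solve $dT = -D_t I \cdot M^{\dagger}$ in the least-squares
sense, update $T$. $M$ is built once per patch from the *un-warped*
template, which keeps its pseudo-inverse fixed across iterations (the
fixed-template convention). Iteration stops when $\lVert dT \rVert <
10^{-6}$ px; on well-textured patches the median is six iterations.

Two conventions make the update norm meaningful in pixels: the affine
linear part is stored as identity-plus-gradient, so the identity transform
is the zero parameter vector; and gradient entries are scaled by the disk
radius inside the norm, so a unit of gradient update counts as the pixel
displacement it causes at the patch rim.

### From patches to a velocity profile

Disks of radius 15 px are placed every 10 px of arc length along a
midline interpolated through user seed points (100 points, uniform chord
spacing, first point exactly the QC seed). For every consecutive frame
pair each disk is solved independently; its displacement, minus the QC
disk's displacement, is projected on the local midline tangent (central
difference of neighboring midline points). Referencing to the tracked QC
patch cancels whole-root translation in the frame. One (station, axial
velocity) sample is emitted per disk per frame pair; a 120-frame stack
with ~126 disks yields roughly 15,000 samples.

Between pairs the midline is advected with the translation of the nearest
tracked disk and re-resampled to uniform spacing, so stations remain
arc-length positions from the QC as the root grows; `fixed_midline = TRUE`
disables this and keeps the frame-0 midline.

### Velocity model and traits

The pooled cloud is fitted with the flexible logistic of Morris & Silk,

$$v(x) = v_f\,\bigl[1 + e^{-k (x - x_0)}\bigr]^{-1/n},$$

by Nelder–Mead least squares on $(\log v_f, \log k, x_0, \log n)$. Its
analytic derivative, scaled to % h⁻¹, is the REGR profile

$$\mathrm{REGR}(x) = 100\,\frac{v_f k}{n}\, u\,(1+u)^{-1/n - 1},
\qquad u = e^{-k(x - x_0)} .$$

Both are evaluated through a stable softplus form so extreme $k(x - x_0)$
cannot overflow. The four traits: maximum REGR at $x_0 - \ln(n)/k$
(clipped at the QC if negative); the elongation zone is where REGR exceeds
20% of its maximum, its bounds found by bracketed root finding
(`uniroot`, tolerance $10^{-9}$ mm, brackets peak $\pm\, 10/k$), the
apical bound clipped at the QC and flagged; and the average growth rate,
reported as $v_f$ exactly. Note that the area under REGR equals
$v_f - v(0)$, not $v_f$: with the default wild-type-like parameters
$v(0) \approx 3\%$ of $v_f$, so the "area under the curve" reading and
the $v_f$ reading differ by that amount. The package reports $v_f$.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `spacing` | 10 | px | arc-length interval between disk centers |
| `radius` | 15 | px | patch radius (~10 µm at 1450 px/mm); sets the spatial averaging scale of each velocity sample |
| `threshold` | 1e-6 | px | solver convergence threshold on the scaled update norm |
| `max_iter` | 50 | — | iteration cap; non-converged disks are dropped and logged |
| `sigma` | 1 | px | Gaussian pre-smoothing of the template gradient |
| `sampler` | bicubic | — | sub-pixel interpolation of the warped frame |
| `resolution` | 1450 | px/mm | acquisition scale |
| `interval` | 30 | s | frame interval |

The 30 s interval matters: it must be long enough that expansion is
measurable between frames (the fastest material moves ~1.2 px/frame at
default kinematics) yet short enough that a disk stays within roughly the
same region of the growth zone.

## Numerical choices

* **Sub-pixel sampling.** The solver evaluates the warped frame by
  Catmull–Rom bicubic interpolation. This was an empirical decision:
  on constructed affine warps of smooth textures, bilinear interpolation's
  bias limited warp recovery to several percent of the warp magnitude and
  dragged the median iteration count to 7; bicubic recovers the same warps
  to ≤ 0.5% with a median of 6 iterations. Bilinear remains available
  (`sampler = "bilinear"`).
* **Gradient operator.** Central differences of a Gaussian-smoothed
  ($\sigma = 1$ px) copy of frame $n$. Smoothing regularizes against pixel
  noise; since the template gradient only steers the iteration (the fixed
  point is set by the residual), mild smoothing does not bias the result.
* **Degenerate patches.** $M$ is solved through its SVD; a condition
  number above $10^8$ flags a textureless patch, which is dropped and
  logged, as are patches that leave the frame and disks that fail to
  converge. If the QC disk itself fails, the frame pair is skipped — there
  is no reference to measure against.
* **Midline resampling.** Equal spacing along the *input* polyline is not
  equal spacing along the polyline the resampled points themselves define,
  so the reparameterization is iterated to its fixed point (vertex motion
  < $10^{-10}$ px), making resampling idempotent and chord spacing uniform
  to well below $10^{-6}$ px.
* **Fit initialization.** $v_f$ starts at the 95th percentile of sampled
  velocities; $x_0$ where a running median first exceeds $v_f/2$; $k$ from
  the local slope there; $n = 1$. Three Nelder–Mead restarts from jittered
  starts (seeded, caller's RNG untouched) plus a polish pass; the best SSE
  wins. The loss is plain unweighted SSE. A cloud with no velocity spread
  short-circuits to a degenerate fit ($v_f \approx$ mean velocity) with a
  warning rather than an optimizer failure.

## The synthetic test bed

`render_stack()` builds a band-limited random texture (Gaussian-blurred
white noise, scale 3 px) inside a soft-edged root silhouette with a
rounded cap, on a bright background — dark features on backlight, in
$[0,1]$. Material coordinates are advected by the growth field (adaptive
`lsoda`, tolerance $10^{-9}$ mm) and each frame re-samples the material
texture at the positions a pixel maps back to, plus Gaussian read noise
(σ = 0.01). In the default geometry the mature tissue is stationary in
the camera frame and the tip advances, as for an anchored seedling; a
constant-velocity mode translates the whole image rigidly instead (the
camera-drift null case: QC-relative velocities must vanish), and an
optional constant-curvature mode bends the axis to exercise the solver's
rotation handling. Identical specs render bit-identical stacks.

**The growth field is not the raw logistic.** The flexible logistic is
strictly positive at $x = 0$, so advecting material with it makes tissue
creep *through* the QC at $v(0) \approx 2.9\%$ of $v_f$ (default truth).
The QC is by definition a fixed point of the material flow, and an
instrument that references velocities to the tracked QC patch can only
observe $v(s) - v(0)$ under such a field — whose best logistic fit
differs from the generating parameters by tens of percent in $x_0$ and
$n$ no matter how good the tracking. The generator therefore pins the
flow at the QC: for $s \ge 0$,

$$w(s) = v(s) - v(0)\,e^{-s/\delta}, \qquad \delta = 0.006\ \mathrm{mm},$$

extended odd-symmetrically ($w(-s) = -w(s)$) so root-cap material apical
of the QC moves tipward, as it does in a real root. The decay length is
about one meristematic cell; oddness makes the QC patch an exact fixed
point of the flow, so the QC reference is unbiased by symmetry. Under a
disk-averaging model of the instrument this field's best-fit parameters
sit within ~3% of the generating logistic — the residual, irreducible
cost of observing a field through 10-µm patches referenced to a
finite-sized QC patch. `quiescence = 0` restores the raw logistic field
for studying exactly this effect.

**Problem sizes.** The flagship end-to-end check runs the full default
condition — 120 frames, 1450 px/mm, ~130 disks per frame, ~15,000 velocity
samples — and recovers all four parameters and all four traits within 5%
(parameters within ~2.6%, traits within ~0.4% in practice). Unit and
property tests use shorter stacks (3–12 frames) and shorter midlines,
which exercise the same code paths at a fraction of the cost.

## What passing tests do and do not show

The generator emulates the features the tracker actually consumes:
band-limited texture contrast, smooth advection, modest read noise,
constant illumination, a single root with a clean background. It does not
emulate cell-scale morphology, illumination drift, focus changes, root
hairs crossing the midline, or neighboring roots — so a green suite
demonstrates the *algorithmic* fidelity of tracking, fitting and trait
extraction, not robustness to every acquisition artifact. On real stacks
the drop log (out-of-bounds, degenerate, non-converged counts per frame)
and the QC plot are the first things to inspect.

## Known limitations

* The analysis is one-dimensional along the midline; radial or per-cell
  variation in expansion is out of scope.
* One root per stack; no camera-motion compensation beyond the QC
  reference.
* The elongation-zone definition (20% of peak REGR) is a convention;
  absolute zone lengths shift with the cutoff, though comparisons across
  genotypes under the same cutoff remain meaningful.
* Whether to update the midline as the root grows is not uniquely
  determined by the problem; the advected-midline convention used here
  keeps stations at fixed arc lengths from the QC, and the frame-0
  alternative is provided as a flag.
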