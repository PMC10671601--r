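# patchtrack

Kinematic analysis of plant root growth from time-lapse micrographs.

Root elongation is driven by cells that leave the apical meristem and pass
through a transient phase of rapid expansion. Measuring *where* along the
root that expansion happens, and *how fast*, requires a kinematic analysis:
tracking material points as they flow away from the quiescent center (QC)
and converting their velocities into a spatial profile of local expansion
rate. `patchtrack` does this for time-lapse image stacks of a single
growing root (for example, 120 frames at 30 s intervals, 1450 px/mm), the
acquisition style used for Arabidopsis primary roots on horizontal
microscopes. It is aimed at researchers phenotyping root growth — e.g.
comparing mutants to wild type in kinematic rather than endpoint terms.

## Method

1. **Midline and disks.** The user supplies 10–12 seed points along the
   root axis (QC first, as a CSV). The package interpolates 100 evenly
   spaced midline points and places circular tracking disks at 10-px
   arc-length stations, the first exactly on the QC.

2. **Patch tracking.** Each disk's image patch is matched from frame *n*
   to frame *n* + 1 by a 6-parameter affine transform `T` — a translation
   `v` plus a velocity gradient `∇v` that lets the patch stretch and
   rotate. `T` is found by iteratively driving the material derivative of
   intensity to zero: with `M = ∇I ⊗ dx̃` formed once from the template
   patch, each iteration evaluates `D_tI = I(T·dx̃ + x, t+1) − I(x̃, t)`,
   solves `dT = −D_tI · M†` by least squares, and updates `T ← T + dT`
   until `‖dT‖ < 10⁻⁶` px (typically ≤ 6 iterations). Axial velocities are
   taken relative to the tracked QC disk, so whole-root drift cancels.

3. **Velocity profile and REGR.** The pooled (position, velocity) cloud —
   about 15,000 samples for a 120-frame stack — is fitted by Nelder–Mead
   least squares with the flexible logistic of Morris & Silk,

   v(x) = v_f · [1 + e^(−k(x−x₀))]^(−1/n),

   whose derivative (×100) is the relative elemental growth rate profile
   REGR(x) in % h⁻¹. Four traits are extracted: maximum REGR; its axial
   position `x₀ − ln(n)/k`; the elongation-zone length (where REGR exceeds
   20% of its maximum); and the average growth rate, which equals `v_f`.

A synthetic-stack generator (`synthetic_spec()` / `render_stack()`)
renders a textured, elongating root with a known flexible-logistic field
and exact ground truth, so the whole pipeline can be validated end to end.

## Worked example

```r
library(patchtrack)

syn     <- render_stack(synthetic_spec())              # 120 frames, known truth
midline <- interpolate_midline(as.matrix(syn$seeds), count = 100)
cloud   <- track_stack(syn$stack, midline)             # ~2 min on one core
fit     <- fit_flexible_logistic(cloud)
extract_traits(fit$params)
```

```
<kinematic_traits>
  max REGR:          25.029 %/h at 0.3487 mm from the QC
  elongation zone:   0.5769 mm (0.0618 to 0.6387 mm)
  avg growth rate:   0.1000 mm/h
```

The generator's truth is `v_f = 0.1` mm/h, `k = 10` mm⁻¹, `x₀ = 0.35` mm,
`n = 1`, for which the exact traits are maximum REGR `v_f·k/4 = 25` %/h at
0.35 mm, zone length `(4/k)·arccosh(√5) = 0.5774` mm and average rate
0.1 mm/h — every trait is recovered within about 1%.

For real data, the same analysis runs from the shell:

```sh
patchtrack run --stack frames/ --points seeds.csv --resolution 1450 \
               --interval 30 --out results/
```

(the `patchtrack` script installs under `exec/` in the package library;
`track`, `fit` and `simulate` subcommands expose the individual stages).
Outputs are `velocity_points.csv`, `disk_coordinates.csv`,
`fitted_velocity.csv`, `regr_profile.csv`, `traits.csv`, a QC plot of the
point cloud with fitted profiles, and a run log.

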