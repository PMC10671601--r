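# Analytic band-limited textures for solver tests: sums of random 2-D
# sinusoids can be evaluated at arbitrary (sub-pixel) coordinates, so a
# frame warped by a known affine map can be rendered exactly, with no
# interpolation error contaminating the oracle.

make_sine_texture <- function(seed, nfreq = 12, lambda = c(20, 50)) {
  set.seed(seed)
  k <- 2 * pi / runif(nfreq, lambda[1], lambda[2])
  th <- runif(nfreq, 0, 2 * pi)
  ph <- runif(nfreq, 0, 2 * pi)
  a <- runif(nfreq, 0.5, 1)
  a <- 0.25 * a / sum(a) * nfreq / 2
  function(x, y) {
    v <- 0.5
    for (i in seq_len(nfreq))
      v <- v + a[i] * sin(k[i] * (cos(th[i]) * x + sin(th[i]) * y) + ph[i])
    v
  }
}

# Rasterize a texture function on an nr x nc grid (0-based pixel coords).
rasterize <- function(tex, nr, nc) {
  outer(0:(nr - 1), 0:(nc - 1), function(y, x) tex(x, y))
}

# Render the frame that results from warping `tex` by the affine map
# d -> d + v + G d about `center`: the feature at offset d appears at
# offset (I + G) d + v in the output.
rasterize_warped <- function(tex, nr, nc, center, v, G) {
  A <- solve(diag(2) + G)  # invert to pull back pixel -> template coords
  outer(0:(nr - 1), 0:(nc - 1), function(y, x) {
    dx <- x - center[1] - v[1]
    dy <- y - center[2] - v[2]
    tex(center[1] + A[1, 1] * dx + A[1, 2] * dy,
        center[2] + A[2, 1] * dx + A[2, 2] * dy)
  })
}

# A single disk centered in a square test frame.
centered_disk <- function(center = c(50, 50), radius = 15) {
  ml <- interpolate_midline(rbind(center - c(radius, 0), center + c(radius, 0)), 5)
  d <- place_disks(ml, spacing = 4 * radius, radius = radius)[[1]]
  d$center <- c(x = center[1], y = center[2])
  d
}

# Relative warp-recovery error in the solver's pixel-comparable norm
# (translation in px, gradient entries scaled by the disk radius).
warp_rel_error <- function(result, v, G, radius = 15) {
  dv <- result$transform$translation - v
  dG <- result$transform$gradient - G
  sqrt(sum(c(dv, radius * dG)^2)) / sqrt(sum(c(v, radius * G)^2))
}

# Draw a random growth-scale warp: translation up to vmax px per axis,
# axial stretch up to gmax.
random_growth_warp <- function(vmax = 2, gmax = 0.02) {
  list(v = runif(2, -vmax, vmax), G = diag(runif(2, -gmax, gmax)))
}
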