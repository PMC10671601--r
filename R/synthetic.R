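# Synthetic time-lapse stacks of an elongating, textured root with exact
# ground-truth kinematics. Material points along the axis move under a
# prescribed flexible-logistic velocity field; a band-limited random texture
# tied to the material frame is advected accordingly and re-sampled per
# frame, so every tracking and fitting stage can be checked against truth.

#' Specification of a synthetic root stack
#'
#' Defaults emulate the acquisition conditions the package targets: 120
#' frames at 30 s intervals, 1450 px/mm, a dark root on a bright backlit
#' background, and wild-type-like kinematics (`v_f` = 0.1 mm/h, `k` = 10
#' 1/mm, `x0` = 0.35 mm, `n` = 1).
#'
#' @param truth ground-truth [logistic_params()] of the velocity field.
#' @param frames number of frames (>= 2).
#' @param interval frame interval, s.
#' @param resolution image resolution, px/mm.
#' @param root_width root diameter, px.
#' @param texture_seed RNG seed; identical specs render identical stacks.
#' @param texture_scale Gaussian blur radius of the texture, px (sets the
#'   spatial scale of the cell-wall-like intensity fluctuations).
#' @param noise_sigma per-frame additive Gaussian read noise, as a fraction
#'   of the full intensity range.
#' @param curvature optional bend radius of the root axis, px; `NULL` for a
#'   straight root. Ground-truth stations stay arc-length positions along
#'   the curved axis.
#' @param constant_velocity optional uniform velocity, mm/h: every material
#'   point (and the whole image) moves at this single speed, replacing the
#'   logistic field. Useful as the rigid-translation limit.
#' @param quiescence decay length, mm, of the quiescence taper at the QC.
#'   The flexible logistic is strictly positive at the QC, but the
#'   quiescent center is by definition a fixed point of the material flow,
#'   so for `s >= 0` the generator advects material with
#'   `w(s) = v(s) - v(0) exp(-s/quiescence)` — exactly quiescent at the QC,
#'   indistinguishable from the logistic a few cell lengths up the axis —
#'   and extends it odd-symmetrically (`w(-s) = -w(s)`) so that root-cap
#'   material apical of the QC moves tipward, as in a real root. Set to 0
#'   to advect with the raw logistic (material then creeps through the QC
#'   at `v(0)`).
#' @param midline_length arc length covered by the seeded midline, px from
#'   the QC.
#' @param qc_margin distance from the frame edge to the initial QC, px
#'   (the root tip advances into this margin as the root elongates).
#' @param tip_cap length of the rounded root cap apical of the QC, px.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(truth = logistic_params(0.1, 10, 0.35, 1),
                           frames = 120, interval = 30, resolution = 1450,
                           root_width = 180, texture_seed = 7,
                           texture_scale = 3, noise_sigma = 0.01,
                           curvature = NULL, constant_velocity = NULL,
                           quiescence = 0.006,
                           midline_length = 1250, qc_margin = 200,
                           tip_cap = 30) {
  if (frames < 2) stop_invalid_input("frames must be >= 2")
  for (p in c(interval, resolution, root_width, texture_scale,
              midline_length, qc_margin, tip_cap))
    if (p <= 0) stop_invalid_input("all physical parameters must be positive")
  if (noise_sigma < 0) stop_invalid_input("noise_sigma must be >= 0")
  if (quiescence < 0) stop_invalid_input("quiescence must be >= 0")
  structure(list(truth = truth, frames = frames, interval = interval,
                 resolution = resolution, root_width = root_width,
                 texture_seed = texture_seed, texture_scale = texture_scale,
                 noise_sigma = noise_sigma, curvature = curvature,
                 constant_velocity = constant_velocity,
                 quiescence = quiescence,
                 midline_length = midline_length, qc_margin = qc_margin,
                 tip_cap = tip_cap),
            class = "synthetic_spec")
}

# Material velocity field of the synthetic root, mm/h at station s (mm):
# the flexible logistic minus a short-range quiescence taper pinning the
# flow to zero at the QC, extended odd-symmetrically so root-cap material
# apical of the QC moves tipward (as it does in a real root). Oddness also
# makes the QC patch a true fixed point of the flow.
synthetic_velocity <- function(truth, s_mm, quiescence = 0.006,
                               constant_velocity = NULL) {
  if (!is.null(constant_velocity))
    return(rep(constant_velocity, length(s_mm)))
  if (quiescence <= 0) return(velocity_model(truth, s_mm))
  sa <- abs(s_mm)
  w <- velocity_model(truth, sa) -
    velocity_model(truth, 0) * exp(-sa / quiescence)
  sign(s_mm) * w
}

# Trajectories of material points under the velocity field: one adaptive
# lsoda solve for the whole grid of start positions, tolerance 1e-9 mm.
material_trajectories <- function(truth, start_mm, times_s,
                                  constant_velocity = NULL,
                                  quiescence = 0.006, tol = 1e-9) {
  if (!is.null(constant_velocity)) {
    return(outer(times_s, rep(constant_velocity / 3600, length(start_mm))) +
             matrix(start_mm, length(times_s), length(start_mm), byrow = TRUE))
  }
  rhs <- function(t, y, parms)
    list(synthetic_velocity(truth, y, quiescence) / 3600)
  out <- deSolve::lsoda(y = start_mm, times = times_s, func = rhs,
                        rtol = tol, atol = tol)
  unname(out[, -1, drop = FALSE])
}

#' Material displacement map of the growth field
#'
#' Integrates `dx/dt = v(x)` (velocity in mm/h, time in s) from material
#' start positions, returning the monotone map from position at time 0 to
#' position at time `t`, both in mm from the quiescent center.
#'
#' @param truth [logistic_params()] of the velocity field.
#' @param t elapsed time, s.
#' @param constant_velocity optional uniform velocity, mm/h, replacing the
#'   logistic field (then the map is an exact translation).
#' @param quiescence quiescence taper length, mm (see [synthetic_spec()]);
#'   0 integrates the raw logistic field.
#' @param tol integration tolerance, mm.
#' @return function mapping a numeric vector of start positions (mm) to
#'   positions at time `t` (mm).
#' @export
displacement_map <- function(truth, t, constant_velocity = NULL,
                             quiescence = 0, tol = 1e-9) {
  if (t < 0) stop_invalid_input("t must be >= 0")
  force(truth)
  function(x0) {
    if (t == 0) return(x0)
    material_trajectories(truth, x0, c(0, t),
                          constant_velocity = constant_velocity,
                          quiescence = quiescence, tol = tol)[2, ]
  }
}

# Axis geometry: maps arc-length coordinates (a, lateral) to camera pixels
# and back. `a` is measured along the fixed axis with a = 0 at the initial
# QC; `lat` is the signed lateral offset (px, positive toward larger rows).
axis_geometry <- function(spec, n_rows, n_cols) {
  y0 <- (n_rows - 1) / 2
  xq <- spec$qc_margin
  if (is.null(spec$curvature) || !is.finite(spec$curvature)) {
    a <- matrix(rep(0:(n_cols - 1) - xq, each = n_rows), n_rows, n_cols)
    lat <- matrix(rep(0:(n_rows - 1) - y0, n_cols), n_rows, n_cols)
    point_at <- function(arc) cbind(x = xq + arc, y = rep(y0, length(arc)))
  } else {
    rb <- spec$curvature
    # bend center below the initial QC; the axis curves toward larger rows
    dx <- matrix(rep(0:(n_cols - 1) - xq, each = n_rows), n_rows, n_cols)
    dy <- matrix(rep(0:(n_rows - 1) - (y0 + rb), n_cols), n_rows, n_cols)
    r <- sqrt(dx^2 + dy^2)
    a <- rb * atan2(dx, -dy)
    lat <- r - rb
    point_at <- function(arc) cbind(x = xq + rb * sin(arc / rb),
                                    y = y0 + rb * (1 - cos(arc / rb)))
  }
  list(a = a, lat = lat, y0 = y0, point_at = point_at)
}

# Material-frame texture: band-limited noise inside a soft-edged root mask
# (rounded cap apical of the QC), bright background. Columns index the
# material coordinate m in px (m_lo..m_hi), rows the lateral offset.
material_texture <- function(spec, n_rows, m_lo, m_hi, bg = 0.85,
                             base = 0.45, amp = 0.12) {
  ncm <- m_hi - m_lo + 1
  tex <- matrix(stats::rnorm(n_rows * ncm), n_rows, ncm)
  tex <- EBImage::gblur(tex, sigma = spec$texture_scale)
  tex <- (tex - mean(tex)) / stats::sd(tex)
  m <- m_lo:m_hi
  half <- spec$root_width / 2
  hw <- ifelse(m >= 0, half,
               half * sqrt(pmax(0, 1 - (m / spec$tip_cap)^2)))
  y0 <- (n_rows - 1) / 2
  dmat <- matrix(abs(rep(0:(n_rows - 1) - y0, ncm)), n_rows, ncm)
  hwmat <- matrix(rep(hw, each = n_rows), n_rows, ncm)
  alpha <- pmin(1, pmax(0, (hwmat - dmat) / 2 + 0.5))  # 2-px soft edge
  img <- bg * (1 - alpha) + (base + amp * tex) * alpha
  pmin(pmax(img, 0), 1)
}

#' Render a synthetic root stack with ground truth
#'
#' Builds the material texture once, integrates the material trajectories
#' of the growth field, and re-samples the texture per frame at the material
#' coordinate each pixel maps back to (bilinear interpolation), then adds
#' read noise. Under the logistic field the mature (basal) tissue is held
#' still in the camera frame, so the tip advances across the field of view
#' as a real anchored seedling's does; in `constant_velocity` mode the whole
#' image translates rigidly.
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `synthetic_stack`: `stack` (an [image_stack()]),
#'   `seeds` (midline seed points, data frame `x`, `y`, QC first),
#'   `truth` (the generating [logistic_params()]), `truth_profile`
#'   (data frame `station_mm`, `v_true_mm_h` at the standard disk stations),
#'   `tracers` (per-frame ground-truth trajectories of material points
#'   started at the stations: `frame`, `tracer_id`, `station_mm`,
#'   `v_true_mm_h`, `x`, `y`) and `spec`.
#' @export
render_stack <- function(spec) {
  res <- spec$resolution
  n_rows <- ceiling(spec$root_width + 100 +
                      if (!is.null(spec$curvature) && is.finite(spec$curvature))
                        (spec$midline_length + spec$qc_margin)^2 / (4 * spec$curvature)
                      else 0)
  n_cols <- spec$qc_margin + spec$midline_length + 40
  t_total <- (spec$frames - 1) * spec$interval
  v_anchor <- if (is.null(spec$constant_velocity)) spec$truth$v_f else 0
  drift_px <- v_anchor / 3600 * t_total * res
  if (drift_px > spec$qc_margin - spec$tip_cap - 20)
    pt_stop("patchtrack_frame_size", "root tip would leave the frame; increase qc_margin")

  m_lo <- -(spec$tip_cap + 25)
  m_hi <- spec$midline_length + 60
  m_grid_px <- seq(m_lo, m_hi, by = 2)
  times <- (0:(spec$frames - 1)) * spec$interval
  traj <- material_trajectories(spec$truth, m_grid_px / res, times,
                                constant_velocity = spec$constant_velocity,
                                quiescence = spec$quiescence)
  # every column of every frame must map back into the material grid
  # (the root extending past the basal frame edge is fine and expected)
  x_qc_t <- spec$qc_margin - v_anchor / 3600 * times * res
  if (any(traj[, ncol(traj)] * res < (n_cols - 1) - x_qc_t))
    pt_stop("patchtrack_frame_size",
            "material grid does not cover the basal frame edge; shrink the frame or extend the root")

  geom <- axis_geometry(spec, n_rows, n_cols)
  stations_px <- seq(0, spec$midline_length, by = 10)
  tracer_traj <- material_trajectories(spec$truth, stations_px / res, times,
                                       constant_velocity = spec$constant_velocity,
                                       quiescence = spec$quiescence)

  frames <- vector("list", spec$frames)
  with_seed(spec$texture_seed, {
    mt <- material_texture(spec, n_rows, m_lo, m_hi)
    for (i in seq_len(spec$frames)) {
      a_qc <- -v_anchor / 3600 * times[i] * res  # QC arc position at time t
      s_px <- geom$a - a_qc                       # station of every pixel
      m_px <- stats::approx(traj[i, ] * res, m_grid_px, xout = as.vector(s_px),
                            rule = 1)$y
      frame <- bilinear_sample(mt, x = m_px - m_lo, y = geom$y0 + as.vector(geom$lat))
      frame[is.na(frame)] <- 0.85
      frame <- matrix(frame, n_rows, n_cols)
      if (spec$noise_sigma > 0)
        frame <- frame + matrix(stats::rnorm(n_rows * n_cols, 0, spec$noise_sigma),
                                n_rows, n_cols)
      frames[[i]] <- pmin(pmax(frame, 0), 1)
    }
  })

  v_true <- function(s_mm) {
    synthetic_velocity(spec$truth, s_mm, quiescence = spec$quiescence,
                       constant_velocity = spec$constant_velocity)
  }

  seeds_arc <- seq(0, spec$midline_length, length.out = 11)
  seeds <- as.data.frame(geom$point_at(seeds_arc))

  tracers <- do.call(rbind, lapply(seq_len(spec$frames), function(i) {
    st <- tracer_traj[i, ]
    cam <- geom$point_at(st * res + (-v_anchor / 3600 * times[i] * res))
    data.frame(frame = i - 1, tracer_id = seq_along(st) - 1,
               station_mm = st, v_true_mm_h = v_true(st),
               x = cam[, 1], y = cam[, 2])
  }))

  structure(list(
    stack = image_stack(frames, interval = spec$interval, resolution = res),
    seeds = seeds,
    truth = spec$truth,
    truth_profile = data.frame(station_mm = stations_px / res,
                               v_true_mm_h = v_true(stations_px / res)),
    tracers = tracers,
    spec = spec),
    class = "synthetic_stack")
}

#' @export
print.synthetic_stack <- function(x, ...) {
  cat(sprintf("<synthetic_stack> %d frames of %dx%d px, %g s interval, %g px/mm\n",
              length(x$stack$frames), nrow(x$stack$frames[[1]]),
              ncol(x$stack$frames[[1]]), x$stack$interval, x$stack$resolution))
  invisible(x)
}
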