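# Patch tracking by iterative minimization of the intensity-constancy
# residual. Each circular patch is matched from frame n to frame n+1 by a
# 6-parameter affine transform: a translation v plus a velocity gradient
# (2x2 matrix) that lets the patch stretch and rotate as root material
# expands or the root bends.

#' Spatial intensity gradient of a frame
#'
#' Central differences of a lightly Gaussian-smoothed copy of the frame
#' (one-sided at the borders). Smoothing regularizes the gradient against
#' pixel noise; `sigma = 0` disables it.
#'
#' @param frame numeric matrix of intensities.
#' @param sigma Gaussian smoothing radius in px applied before
#'   differentiation.
#' @return list with matrices `gx` (d/dx, along columns) and `gy` (d/dy,
#'   along rows).
#' @export
intensity_gradient <- function(frame, sigma = 1) {
  if (nrow(frame) < 3 || ncol(frame) < 3)
    stop_invalid_input("frame must be at least 3x3")
  s <- smooth_frame(frame, sigma)
  nr <- nrow(s)
  nc <- ncol(s)
  gx <- s
  gx[, 2:(nc - 1)] <- (s[, 3:nc] - s[, 1:(nc - 2)]) / 2
  gx[, 1] <- s[, 2] - s[, 1]
  gx[, nc] <- s[, nc] - s[, nc - 1]
  gy <- s
  gy[2:(nr - 1), ] <- (s[3:nr, ] - s[1:(nr - 2), ]) / 2
  gy[1, ] <- s[2, ] - s[1, ]
  gy[nr, ] <- s[nr, ] - s[nr - 1, ]
  list(gx = gx, gy = gy)
}

#' Identity patch transform
#'
#' @return a `patch_transform` with zero translation and zero velocity
#'   gradient (the affine linear part applied to patch offsets is then the
#'   identity).
#' @export
identity_transform <- function() {
  structure(list(translation = c(vx = 0, vy = 0),
                 gradient = matrix(0, 2, 2)),
            class = "patch_transform")
}

# Map patch offsets (m x 2) through a transform: offset + v + G %*% offset.
apply_transform <- function(transform, offsets) {
  v <- transform$translation
  g <- transform$gradient
  cbind(offsets[, 1] + v[1] + g[1, 1] * offsets[, 1] + g[1, 2] * offsets[, 2],
        offsets[, 2] + v[2] + g[2, 1] * offsets[, 1] + g[2, 2] * offsets[, 2])
}

#' Solve for the transform matching a patch across two frames
#'
#' Finds the affine transform T (translation + velocity gradient) that warps
#' the disk's patch in `frame_n` onto `frame_n1` so the material derivative
#' of intensity vanishes. The design matrix M — the tensor product of the
#' template's spatial intensity gradient with the homogeneous patch offsets
#' (1, dx, dy) — is evaluated once on the un-warped frame-n patch; each
#' iteration then evaluates the intensity change under the current warp,
#' solves the least-squares system dT = -DtI %*% pinv(M), and adds dT to T.
#' Iteration stops when the Euclidean norm of the update (gradient entries
#' scaled by the disk radius, so the norm is in pixel units) drops below
#' `threshold`.
#'
#' @param frame_n,frame_n1 consecutive frames, numeric matrices in `[0, 1]`.
#' @param disk a disk from [place_disks()].
#' @param threshold convergence threshold on the scaled update norm, px.
#' @param max_iter iteration cap; the result is flagged unconverged beyond it.
#' @param sigma Gaussian smoothing of the template gradient, px.
#' @param grad optional precomputed [intensity_gradient()] of `frame_n`.
#' @param sampler sub-pixel interpolation used to evaluate the warped frame.
#'   Bicubic (the default) has markedly lower interpolation bias than
#'   bilinear, which both sharpens the recovered warp parameters and lets
#'   the update norm reach the 1e-6 px threshold in fewer iterations.
#' @return a `track_result`: `transform` (class `patch_transform`),
#'   `iterations`, `converged`, `final_update_norm`, and `rss` (residual sum
#'   of squares per iteration).
#' @export
solve_patch_transform <- function(frame_n, frame_n1, disk,
                                  threshold = 1e-6, max_iter = 50,
                                  sigma = 1, grad = NULL,
                                  sampler = c("bicubic", "bilinear")) {
  sampler <- match.arg(sampler)
  off <- disk$offsets
  cx <- disk$center[[1]]
  cy <- disk$center[[2]]
  tx <- cx + off[, 1]
  ty <- cy + off[, 2]

  template <- sample_image(frame_n, tx, ty, sampler)
  if (anyNA(template))
    stop_out_of_bounds("patch extends outside frame n")
  if (is.null(grad)) grad <- intensity_gradient(frame_n, sigma)
  gx <- bilinear_sample(grad$gx, tx, ty)
  gy <- bilinear_sample(grad$gy, tx, ty)
  if (anyNA(gx) || anyNA(gy))
    stop_out_of_bounds("patch gradient extends outside frame n")

  m <- cbind(gx, gy, gx * off[, 1], gx * off[, 2], gy * off[, 1], gy * off[, 2])
  sv <- svd(m)
  if (sv$d[6] <= 0 || sv$d[1] / sv$d[6] > 1e8)
    stop_degenerate_patch(sprintf(
      "patch at station %.1f px lacks texture (condition number %.3g)",
      disk$station, if (sv$d[6] > 0) sv$d[1] / sv$d[6] else Inf))
  pinv <- sv$v %*% (t(sv$u) / sv$d)  # 6 x m pseudo-inverse of M

  scale <- c(1, 1, rep(disk$radius, 4))
  theta <- numeric(6)  # (vx, vy, g11, g12, g21, g22), identity start
  rss <- numeric(0)
  update_norm <- Inf
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    wx <- tx + theta[1] + theta[3] * off[, 1] + theta[4] * off[, 2]
    wy <- ty + theta[2] + theta[5] * off[, 1] + theta[6] * off[, 2]
    warped <- sample_image(frame_n1, wx, wy, sampler)
    if (anyNA(warped))
      stop_out_of_bounds("warped patch leaves frame n+1")
    dti <- warped - template
    rss <- c(rss, sum(dti^2))
    dtheta <- -as.vector(pinv %*% dti)
    theta <- theta + dtheta
    update_norm <- sqrt(sum((dtheta * scale)^2))
    if (update_norm < threshold) break
  }

  transform <- structure(
    list(translation = c(vx = theta[1], vy = theta[2]),
         gradient = matrix(theta[3:6], 2, 2, byrow = TRUE)),
    class = "patch_transform")
  structure(list(transform = transform,
                 iterations = iter,
                 converged = update_norm < threshold,
                 final_update_norm = update_norm,
                 rss = rss),
            class = "track_result")
}

#' @export
print.patch_transform <- function(x, ...) {
  cat(sprintf("<patch_transform> v = (%.4f, %.4f) px/frame\n",
              x$translation[1], x$translation[2]))
  cat("  velocity gradient:\n")
  print(round(x$gradient, 5))
  invisible(x)
}

#' Track every disk through an image stack
#'
#' For each consecutive frame pair, fresh disks are placed at the standard
#' arc-length stations along the current midline, each disk's transform is
#' solved, and the axial velocity of its center relative to the tracked
#' quiescent-center disk is recorded as one velocity sample. The midline is
#' then advected with the tracked motion (each midline point moves with the
#' translation of the nearest tracked disk) and re-resampled to equal
#' arc-length spacing, so stations remain tied to arc-length positions from
#' the QC as the root grows; set `fixed_midline = TRUE` to keep the frame-0
#' midline throughout instead.
#'
#' Disks whose patch leaves the frame, lacks texture, or fails to converge
#' are dropped and logged; if the QC disk itself fails, the whole frame pair
#' is skipped with a warning because no QC reference exists.
#'
#' @param stack an [image_stack()].
#' @param midline midline seeded on frame 0.
#' @param spacing,radius disk layout, px (see [place_disks()]).
#' @param threshold,max_iter,sigma,sampler solver controls (see
#'   [solve_patch_transform()]).
#' @param fixed_midline keep the frame-0 midline for every frame pair.
#' @param verbose print one line per frame pair.
#' @return data frame of velocity samples with columns `disk_id`, `frame`,
#'   `station_px`, `velocity_px_frame`, `station_mm`, `velocity_mm_h`.
#'   Attributes: `drops` (data frame `frame`, `disk_id`, `reason`) and
#'   `disk_coordinates` (data frame `frame`, `disk_id`, `x`, `y`,
#'   `station_px`).
#' @export
track_stack <- function(stack, midline, spacing = 10, radius = 15,
                        threshold = 1e-6, max_iter = 50, sigma = 1,
                        sampler = "bicubic", fixed_midline = FALSE,
                        verbose = FALSE) {
  frames <- stack$frames
  n_frames <- length(frames)
  if (n_frames < 2) stop_invalid_input("stack must have at least 2 frames")

  samples <- vector("list", n_frames - 1)
  coords <- vector("list", n_frames - 1)
  drops <- list()
  current <- midline

  for (n in seq_len(n_frames - 1)) {
    disks <- place_disks(current, spacing = spacing, radius = radius)
    grad <- intensity_gradient(frames[[n]], sigma)
    translations <- matrix(NA_real_, length(disks), 2)
    for (i in seq_along(disks)) {
      res <- tryCatch(
        solve_patch_transform(frames[[n]], frames[[n + 1]], disks[[i]],
                              threshold = threshold, max_iter = max_iter,
                              sigma = sigma, grad = grad, sampler = sampler),
        patchtrack_oob_error = function(e) "out_of_bounds",
        patchtrack_degenerate_patch = function(e) "degenerate_patch")
      if (is.character(res)) {
        drops[[length(drops) + 1]] <- data.frame(frame = n - 1, disk_id = i - 1,
                                                 reason = res)
      } else if (!res$converged) {
        drops[[length(drops) + 1]] <- data.frame(frame = n - 1, disk_id = i - 1,
                                                 reason = "not_converged")
      } else {
        translations[i, ] <- res$transform$translation
      }
    }

    coords[[n]] <- data.frame(
      frame = n - 1,
      disk_id = seq_along(disks) - 1,
      x = vapply(disks, function(d) d$center[[1]], 0),
      y = vapply(disks, function(d) d$center[[2]], 0),
      station_px = vapply(disks, function(d) d$station, 0))

    if (is.na(translations[1, 1])) {
      warning(sprintf("QC disk failed to track in frame pair %d-%d; pair skipped",
                      n - 1, n))
      drops[[length(drops) + 1]] <- data.frame(frame = n - 1, disk_id = 0,
                                               reason = "qc_failed")
      next
    }

    qc_disp <- translations[1, ]
    tracked <- which(!is.na(translations[, 1]))
    vel <- vapply(tracked, function(i) {
      axial_components(translations[i, ], disks[[i]], current, qc_disp)
    }, 0)
    samples[[n]] <- data.frame(
      disk_id = tracked - 1,
      frame = n - 1,
      station_px = vapply(disks[tracked], function(d) d$station, 0),
      velocity_px_frame = vel)

    if (verbose)
      message(sprintf("frame pair %d-%d: %d/%d disks tracked",
                      n - 1, n, length(tracked), length(disks)))

    if (!fixed_midline) {
      stations <- vapply(disks[tracked], function(d) d$station, 0)
      nearest <- tracked[pmax(1, findInterval(
        current$arc_length,
        stations[-1] - diff(stations) / 2) + 1)]
      moved <- current$points + translations[nearest, , drop = FALSE]
      current <- interpolate_midline(moved, count = nrow(current$points))
    }
  }

  out <- do.call(rbind, samples[!vapply(samples, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(disk_id = integer(), frame = integer(),
                      station_px = numeric(), velocity_px_frame = numeric())
  units <- convert_units(out$station_px, out$velocity_px_frame,
                         resolution = stack$resolution,
                         interval = stack$interval)
  out$station_mm <- units$station_mm
  out$velocity_mm_h <- units$velocity_mm_h
  attr(out, "drops") <- if (length(drops)) do.call(rbind, drops) else
    data.frame(frame = integer(), disk_id = integer(), reason = character())
  attr(out, "disk_coordinates") <- do.call(rbind, coords)
  out
}

#' Convert pixel/frame measurements to millimeters and hours
#'
#' @param station_px arc-length positions from the QC, px.
#' @param velocity_px_frame axial velocities, px per frame interval.
#' @param resolution image resolution, px/mm.
#' @param interval frame interval, s.
#' @return data frame with `station_mm` and `velocity_mm_h`.
#' @examples
#' convert_units(1450, 1, resolution = 1450, interval = 30)
#' @export
convert_units <- function(station_px, velocity_px_frame,
                          resolution = 1450, interval = 30) {
  if (resolution <= 0) stop_invalid_input("resolution must be positive")
  if (interval <= 0) stop_invalid_input("interval must be positive")
  data.frame(station_mm = station_px / resolution,
             velocity_mm_h = velocity_px_frame / resolution * (3600 / interval))
}
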