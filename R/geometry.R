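# Midline and disk geometry. The midline is an arc-length-parameterized
# polyline from the quiescent center (QC) through the root axis; tracking
# disks sit on it at fixed arc-length stations.

#' Build an arc-length midline from user seed points
#'
#' Interpolates a piecewise-linear curve through the seed points and
#' resamples it into `count` points equally spaced in arc length. The first
#' seed marks the quiescent center and is returned exactly as the first
#' midline point.
#'
#' @param seed_points two-column matrix or data frame of pixel coordinates
#'   (`x` = column, `y` = row, 0-based); first row is the QC.
#' @param count number of equally spaced points to return.
#' @return an object of class `midline`: list with `points` (count x 2
#'   matrix), `arc_length` (cumulative arc length in px, starting at 0) and
#'   `total_length`.
#' @examples
#' ml <- interpolate_midline(rbind(c(0, 0), c(99, 0)), count = 100)
#' head(ml$points)
#' @export
interpolate_midline <- function(seed_points, count = 100) {
  pts <- as.matrix(seed_points)
  if (!is.numeric(pts) || ncol(pts) != 2)
    stop_invalid_input("seed points must be a two-column numeric matrix (x, y)")
  if (anyNA(pts))
    stop_invalid_input("seed points contain missing values")
  # collapse consecutive duplicates
  if (nrow(pts) > 1) {
    dup <- c(FALSE, rowSums(abs(diff(pts))) == 0)
    if (any(dup)) {
      warning("collapsing ", sum(dup), " duplicated consecutive seed point(s)")
      pts <- pts[!dup, , drop = FALSE]
    }
  }
  if (nrow(pts) < 2)
    stop_invalid_input("need at least 2 distinct seed points")
  if (count < 2)
    stop_invalid_input("count must be at least 2")
  resample_once <- function(p) {
    s <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
    target <- seq(0, s[length(s)], length.out = count)
    cbind(stats::approx(s, p[, 1], xout = target, ties = "ordered")$y,
          stats::approx(s, p[, 2], xout = target, ties = "ordered")$y)
  }
  # Iterate the reparameterization to its fixed point: points equally
  # spaced along the input polyline are not equally spaced along the
  # polyline they themselves define (chords cut corners), so one pass is
  # not idempotent. Iterating until the vertices stop moving yields
  # uniform chord spacing and makes resampling idempotent.
  out_pts <- resample_once(pts)
  for (i in 1:100) {
    new_pts <- resample_once(out_pts)
    moved <- max(abs(new_pts - out_pts))
    out_pts <- new_pts
    if (moved < 1e-10) break
  }
  # anchor the QC exactly
  out_pts[1, ] <- pts[1, ]
  seg <- sqrt(rowSums(diff(out_pts)^2))
  out <- list(points = cbind(x = out_pts[, 1], y = out_pts[, 2]),
              arc_length = c(0, cumsum(seg)),
              total_length = sum(seg))
  class(out) <- "midline"
  out
}

#' @export
print.midline <- function(x, ...) {
  cat(sprintf("<midline> %d points, total arc length %.2f px, QC at (%.1f, %.1f)\n",
              nrow(x$points), x$total_length, x$points[1, 1], x$points[1, 2]))
  invisible(x)
}

# Point on the midline polyline at arc-length position s (px from the QC).
midline_point_at <- function(midline, s) {
  cbind(stats::approx(midline$arc_length, midline$points[, 1], xout = s,
                      ties = "ordered", rule = 2)$y,
        stats::approx(midline$arc_length, midline$points[, 2], xout = s,
                      ties = "ordered", rule = 2)$y)
}

# Unit tangent at an arc-length station, from the central difference of the
# midline points bracketing the station (one-sided at the ends).
midline_tangent_at <- function(midline, station) {
  n <- nrow(midline$points)
  i <- which.min(abs(midline$arc_length - station))
  lo <- max(1, i - 1)
  hi <- min(n, i + 1)
  d <- midline$points[hi, ] - midline$points[lo, ]
  len <- sqrt(sum(d^2))
  if (len < .Machine$double.eps * 100)
    stop_geometry("degenerate midline segment: zero-length tangent")
  d / len
}

# Integer pixel offsets covering a disk: all (dx, dy) with dx^2 + dy^2 <= r^2.
disk_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  as.matrix(g[g$dx^2 + g$dy^2 <= radius^2, , drop = FALSE])
}

#' Place tracking disks along a midline
#'
#' Disks are centered on the midline at arc-length stations 0, `spacing`,
#' `2 * spacing`, ... up to the midline's total length. The first disk sits
#' exactly on the quiescent center.
#'
#' @param midline a [interpolate_midline()] result.
#' @param spacing arc-length interval between disk centers, px.
#' @param radius disk radius, px; the patch is every integer pixel offset
#'   within this radius of the center.
#' @return list of `disk` objects (fields `center`, `radius`, `station`,
#'   `offsets`).
#' @export
place_disks <- function(midline, spacing = 10, radius = 15) {
  if (spacing <= 0) stop_invalid_input("spacing must be positive")
  if (radius <= 0) stop_invalid_input("radius must be positive")
  stations <- seq(0, midline$total_length, by = spacing)
  centers <- midline_point_at(midline, stations)
  off <- disk_offsets(radius)  # shared by reference across disks
  lapply(seq_along(stations), function(i) {
    structure(list(center = c(x = centers[i, 1], y = centers[i, 2]),
                   radius = radius,
                   station = stations[i],
                   offsets = off),
              class = "disk")
  })
}

#' Axial velocity component of a tracked disk
#'
#' Projects a disk's displacement, referenced to the quiescent center's own
#' displacement, onto the local midline tangent. The sign is positive
#' pointing away from the QC, so growing roots give positive velocities.
#'
#' @param displacement 2-vector (px/frame) of the disk's tracked translation.
#' @param disk the disk (supplies the station at which to take the tangent).
#' @param midline the midline the disk was placed on.
#' @param qc_displacement 2-vector: tracked translation of the QC disk.
#' @return scalar axial velocity in px/frame.
#' @export
axial_components <- function(displacement, disk, midline,
                             qc_displacement = c(0, 0)) {
  tangent <- midline_tangent_at(midline, disk$station)
  sum((displacement - qc_displacement) * tangent)
}
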