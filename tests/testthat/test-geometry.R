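# Midline construction, disk placement and axial projection.

# Independent brute-force arc-length resampler: densify the polyline with
# tiny linear steps, then walk the cumulative length table.
brute_resample <- function(pts, count, step = 1e-3) {
  dense <- list(pts[1, , drop = FALSE])
  for (i in seq_len(nrow(pts) - 1)) {
    seg <- pts[i + 1, ] - pts[i, ]
    len <- sqrt(sum(seg^2))
    tt <- seq(step / len, 1, by = step / len)
    dense[[i + 1]] <- cbind(pts[i, 1] + tt * seg[1], pts[i, 2] + tt * seg[2])
  }
  dense <- do.call(rbind, dense)
  s <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
  target <- seq(0, s[length(s)], length.out = count)
  idx <- findInterval(target, s, all.inside = TRUE)
  dense[idx, , drop = FALSE]
}

test_that("a straight segment resamples to uniformly spaced points", {
  ml <- interpolate_midline(rbind(c(0, 0), c(99, 0)), count = 100)
  expect_equal(ml$points[, 1], 0:99, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(ml$points[, 2], rep(0, 100), ignore_attr = TRUE)
  expect_equal(ml$total_length, 99)

  # collinear interior seeds change nothing
  ml2 <- interpolate_midline(rbind(c(0, 0), c(50, 0), c(99, 0)), count = 100)
  expect_equal(ml2$points, ml$points)
})

test_that("a right-angle polyline resamples to unit arc-length gaps", {
  seeds <- rbind(c(0, 0), c(100, 0), c(100, 100))
  ml <- interpolate_midline(seeds, count = 201)
  expect_equal(nrow(ml$points), 201)
  gaps <- diff(ml$arc_length)
  expect_true(all(abs(gaps - 1) < 1e-6))
  # against the dense brute-force oracle
  oracle <- brute_resample(seeds, 201)
  expect_lt(max(abs(ml$points - oracle)), 5e-3)
  # first point is the QC seed exactly
  expect_identical(ml$points[1, ], c(x = 0, y = 0))
})

test_that("degenerate seed input is rejected or repaired", {
  expect_error(interpolate_midline(rbind(c(1, 1)), 10),
               class = "patchtrack_invalid_input")
  suppressWarnings(
    expect_error(interpolate_midline(rbind(c(1, 1), c(1, 1)), 10),
                 class = "patchtrack_invalid_input"))
  expect_warning(
    ml <- interpolate_midline(rbind(c(0, 0), c(0, 0), c(10, 0)), 11),
    "duplicated")
  expect_equal(ml$total_length, 10)
})

test_that("resampling is idempotent and preserves arc length", {
  for (rep in 1:5) {
    # smooth gently curved polylines with >= 10 seeds, as a root midline is
    t <- seq(0, 1, length.out = 12)
    seeds <- cbind(300 * t, 40 * sin(2 * pi * t / rep) + 10 * cos(3 * t + rep))
    ml1 <- interpolate_midline(seeds, 100)
    ml2 <- interpolate_midline(ml1$points, 100)
    expect_lt(max(abs(ml1$points - ml2$points)), 1e-9)
    expect_lt(abs(ml1$total_length - ml2$total_length) / ml1$total_length, 1e-3)
  }
})

test_that("disks sit at spacing-multiples of arc length from the QC", {
  ml <- interpolate_midline(rbind(c(0, 0), c(200, 0)), 100)
  disks <- place_disks(ml, spacing = 10, radius = 15)
  expect_length(disks, 21)
  expect_equal(vapply(disks, function(d) d$station, 0), seq(0, 200, 10))
  expect_equal(disks[[1]]$center, c(x = 0, y = 0))

  short <- interpolate_midline(rbind(c(0, 0), c(4, 0)), 10)
  expect_length(place_disks(short, spacing = 10, radius = 2), 1)
})

test_that("disk offsets cover exactly the integer pixels within the radius", {
  ml <- interpolate_midline(rbind(c(0, 0), c(50, 0)), 10)
  d <- place_disks(ml, spacing = 100, radius = 4.5)[[1]]
  expected <- expand.grid(dx = -4:4, dy = -4:4)
  expected <- expected[expected$dx^2 + expected$dy^2 <= 4.5^2, ]
  expect_setequal(paste(d$offsets[, 1], d$offsets[, 2]),
                  paste(expected$dx, expected$dy))
})

test_that("disk centers on a curved midline stay on the curve at equal arc gaps", {
  # quarter circle of radius 100 about the origin, densely seeded
  th <- seq(0, pi / 2, length.out = 200)
  seeds <- cbind(100 * cos(th), 100 * sin(th))
  ml <- interpolate_midline(seeds, 400)
  disks <- place_disks(ml, spacing = 10, radius = 5)
  centers <- t(vapply(disks, function(d) d$center, c(0, 0)))
  radii <- sqrt(rowSums(centers^2))
  expect_true(all(abs(radii - 100) < 0.05))
  # consecutive center-to-center arc gaps on the circle
  ang <- atan2(centers[, 2], centers[, 1])
  arc_gaps <- diff(ang) * 100
  expect_true(all(abs(abs(arc_gaps) - 10) < 1e-2))
})

test_that("axial velocity projects QC-referenced displacement onto the tangent", {
  ml <- interpolate_midline(rbind(c(0, 0), c(100, 0)), 100)
  d <- place_disks(ml, spacing = 50, radius = 5)[[2]]
  # QC disk itself: zero by construction
  expect_equal(axial_components(c(0.7, -0.3), d, ml, c(0.7, -0.3)), 0)
  # motion perpendicular to the tangent
  expect_equal(axial_components(c(0, 2), d, ml, c(0, 0)), 0)
  # unit motion along the tangent
  expect_equal(axial_components(c(1, 0), d, ml, c(0, 0)), 1)
})

test_that("axial projection is linear in the displacement", {
  th <- seq(0, pi / 3, length.out = 50)
  ml <- interpolate_midline(cbind(100 * cos(th), 100 * sin(th)), 100)
  d <- place_disks(ml, spacing = 30, radius = 5)[[2]]
  set.seed(1)
  for (i in 1:10) {
    u <- rnorm(2); w <- rnorm(2); a <- rnorm(1); qc <- rnorm(2)
    lhs <- axial_components(a * u + w, d, ml, qc)
    rhs <- a * axial_components(u, d, ml, c(0, 0)) +
      axial_components(w, d, ml, qc)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("a zero-length midline segment raises a geometry error", {
  fake <- structure(list(points = matrix(c(0, 0, 0, 0), 2, 2),
                         arc_length = c(0, 0), total_length = 0),
                    class = "midline")
  d <- structure(list(center = c(x = 0, y = 0), radius = 2, station = 0,
                      offsets = cbind(0, 0)), class = "disk")
  expect_error(axial_components(c(1, 0), d, fake, c(0, 0)),
               class = "patchtrack_geometry_error")
})
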