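# The affine intensity-constancy solver and stack-level tracking.

test_that("intensity gradients match closed forms on simple fields", {
  expect_true(all(intensity_gradient(matrix(0.5, 9, 9), sigma = 0)$gx == 0))
  expect_true(all(intensity_gradient(matrix(0.5, 9, 9), sigma = 0)$gy == 0))

  ramp <- outer(0:8, 0:8, function(y, x) x / 10)
  g <- intensity_gradient(ramp, sigma = 0)
  expect_equal(g$gx[2:8, 2:8], matrix(0.1, 7, 7))
  expect_equal(g$gy[2:8, 2:8], matrix(0, 7, 7))

  plane <- outer(0:10, 0:10, function(y, x) (2 * x + 3 * y) / 100)
  g <- intensity_gradient(plane, sigma = 0)
  expect_equal(g$gx[2:10, 2:10], matrix(0.02, 9, 9), tolerance = 1e-12)
  expect_equal(g$gy[2:10, 2:10], matrix(0.03, 9, 9), tolerance = 1e-12)
})

test_that("a tiny frame is rejected", {
  expect_error(intensity_gradient(matrix(0, 2, 2)),
               class = "patchtrack_invalid_input")
})

test_that("identical frames give the identity transform immediately", {
  f <- rasterize(make_sine_texture(3), 101, 101)
  r <- solve_patch_transform(f, f, centered_disk())
  expect_true(r$converged)
  expect_lte(r$iterations, 2)
  expect_lt(max(abs(r$transform$translation)), 1e-9)
  expect_lt(max(abs(r$transform$gradient)), 1e-9)
})

test_that("constructed warps are recovered: translation, stretch, rotation", {
  tex <- make_sine_texture(11)
  f1 <- rasterize(tex, 101, 101)
  disk <- centered_disk()

  # pure translation by (3, 0)
  f2 <- rasterize_warped(tex, 101, 101, c(50, 50), v = c(3, 0), G = matrix(0, 2, 2))
  r <- solve_patch_transform(f1, f2, disk)
  expect_lt(max(abs(r$transform$translation - c(3, 0))), 1e-2)

  # 2% stretch along x about the patch center
  f3 <- rasterize_warped(tex, 101, 101, c(50, 50), v = c(0, 0),
                         G = diag(c(0.02, 0)))
  r <- solve_patch_transform(f1, f3, disk)
  expect_lt(max(abs(r$transform$gradient - diag(c(0.02, 0)))), 2e-3)
  expect_lt(max(abs(r$transform$translation)), 2e-2)

  # 2-degree rotation about the patch center
  th <- 2 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  f4 <- rasterize_warped(tex, 101, 101, c(50, 50), v = c(0, 0), G = R - diag(2))
  r <- solve_patch_transform(f1, f4, disk)
  expect_lt(max(abs(r$transform$gradient - (R - diag(2)))), 2e-3)
})

test_that("textureless and out-of-bounds patches raise typed errors", {
  flat <- matrix(0.5, 101, 101)
  expect_error(solve_patch_transform(flat, flat, centered_disk()),
               class = "patchtrack_degenerate_patch")

  tex <- rasterize(make_sine_texture(5), 101, 101)
  edge_disk <- centered_disk(center = c(5, 50))
  expect_error(solve_patch_transform(tex, tex, edge_disk),
               class = "patchtrack_oob_error")
})

test_that("random growth-scale warps are recovered within 1% of warp magnitude", {
  set.seed(21)
  errs <- vapply(1:25, function(i) {
    tex <- make_sine_texture(400 + i)
    f1 <- rasterize(tex, 101, 101)
    w <- random_growth_warp(vmax = 3, gmax = 0.05 / 15)
    f2 <- rasterize_warped(tex, 101, 101, c(50, 50), w$v, w$G)
    r <- solve_patch_transform(f1, f2, centered_disk())
    warp_rel_error(r, w$v, w$G)
  }, 0)
  expect_lt(max(errs), 0.01)
})

test_that("patch residual is non-increasing over the final iterations", {
  set.seed(31)
  for (i in 1:5) {
    tex <- make_sine_texture(600 + i)
    f1 <- rasterize(tex, 101, 101)
    w <- random_growth_warp()
    f2 <- rasterize_warped(tex, 101, 101, c(50, 50), w$v, w$G)
    r <- solve_patch_transform(f1, f2, centered_disk())
    expect_true(r$converged)
    tail_rss <- utils::tail(r$rss, 3)
    expect_true(all(diff(tail_rss) <= 1e-12))
  }
})

test_that("tracking forward then backward cancels for small motions", {
  set.seed(41)
  for (i in 1:5) {
    tex <- make_sine_texture(700 + i)
    f1 <- rasterize(tex, 101, 101)
    v <- runif(2, -1, 1)
    f2 <- rasterize_warped(tex, 101, 101, c(50, 50), v, matrix(0, 2, 2))
    fwd <- solve_patch_transform(f1, f2, centered_disk())
    bwd <- solve_patch_transform(f2, f1, centered_disk())
    expect_lt(max(abs(fwd$transform$translation + bwd$transform$translation)),
              0.05)
  }
})

test_that("pixel/frame measurements convert to mm and mm/h", {
  u <- convert_units(1450, 0, resolution = 1450, interval = 30)
  expect_equal(u$station_mm, 1)
  expect_equal(u$velocity_mm_h, 0)
  u <- convert_units(0, 1, resolution = 1450, interval = 30)
  expect_equal(u$velocity_mm_h, (1 / 1450) * (3600 / 30), tolerance = 1e-12)
  expect_equal(u$velocity_mm_h, 0.08276, tolerance = 1e-4)
  expect_error(convert_units(1, 1, resolution = 0),
               class = "patchtrack_invalid_input")
})

test_that("a static stack yields zero axial velocity everywhere", {
  syn <- render_stack(synthetic_spec(frames = 3, constant_velocity = 0,
                                     noise_sigma = 0, midline_length = 400,
                                     qc_margin = 60))
  ml <- interpolate_midline(as.matrix(syn$seeds), 100)
  cloud <- track_stack(syn$stack, ml)
  expect_gt(nrow(cloud), 50)
  expect_lt(max(abs(cloud$velocity_px_frame)), 1e-3)
})

test_that("rigid whole-root translation gives zero QC-relative velocity", {
  # one pixel per frame of uniform motion: the QC reference must absorb it
  c_mm_h <- 3600 / (30 * 1450)
  syn <- render_stack(synthetic_spec(frames = 4, constant_velocity = c_mm_h,
                                     noise_sigma = 0, midline_length = 400,
                                     qc_margin = 60))
  ml <- interpolate_midline(as.matrix(syn$seeds), 100)
  cloud <- track_stack(syn$stack, ml)
  expect_lt(max(abs(cloud$velocity_px_frame)), 5e-3)
})

test_that("tracked velocities match the generator's field on a short stack", {
  syn <- render_stack(synthetic_spec(frames = 10, midline_length = 700,
                                     qc_margin = 80))
  ml <- interpolate_midline(as.matrix(syn$seeds), 100)
  cloud <- track_stack(syn$stack, ml)
  expect_identical(nrow(attr(cloud, "drops")), 0L)
  v_true <- approx(syn$truth_profile$station_mm, syn$truth_profile$v_true_mm_h,
                   xout = cloud$station_mm, rule = 2)$y
  rms <- sqrt(mean((cloud$velocity_mm_h - v_true)^2))
  expect_lt(rms, 0.05 * syn$truth$v_f)
  # sample bookkeeping: one sample per tracked disk per frame pair
  expect_equal(nrow(cloud),
               sum(tapply(cloud$disk_id, cloud$frame, length)))
  expect_true(all(cloud$station_px >= 0))
})

test_that("disk coordinates and drop log are reported per frame", {
  syn <- render_stack(synthetic_spec(frames = 3, midline_length = 300,
                                     qc_margin = 60, noise_sigma = 0))
  ml <- interpolate_midline(as.matrix(syn$seeds), 100)
  cloud <- track_stack(syn$stack, ml)
  coords <- attr(cloud, "disk_coordinates")
  expect_true(all(c("frame", "disk_id", "x", "y", "station_px") %in% names(coords)))
  expect_setequal(unique(coords$frame), 0:1)
  drops <- attr(cloud, "drops")
  expect_true(all(c("frame", "disk_id", "reason") %in% names(drops)))
})
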