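# Stack and seed-point I/O, the run configuration, and the end-to-end
# pipeline that binds tracking and fitting together and writes all outputs.

#' Construct an image stack
#'
#' @param frames list of numeric matrices (one per frame, intensities in
#'   `[0, 1]`, identical dimensions, acquisition order).
#' @param interval frame interval, s.
#' @param resolution image resolution, px/mm.
#' @return object of class `image_stack`.
#' @export
image_stack <- function(frames, interval = 30, resolution = 1450) {
  if (length(frames) < 1) stop_invalid_input("stack needs at least one frame")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    pt_stop("patchtrack_format_error", "frames have mixed dimensions")
  if (interval <= 0 || resolution <= 0)
    stop_invalid_input("interval and resolution must be positive")
  structure(list(frames = frames, interval = interval, resolution = resolution),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> %d frames of %dx%d px, %g s interval, %g px/mm\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              x$interval, x$resolution))
  invisible(x)
}

# A TIFF page as a [0,1] grayscale matrix; color pages are averaged.
as_gray_matrix <- function(page, file) {
  if (is.matrix(page)) return(page)
  if (length(dim(page)) == 3) return(apply(page, c(1, 2), mean))
  pt_stop("patchtrack_io_error", sprintf("unsupported TIFF layout in %s", file))
}

#' Read a time-lapse TIFF stack
#'
#' Accepts either a directory of single-page grayscale TIFF files (frames
#' in lexicographic filename order) or one multi-page TIFF. Intensities are
#' returned in `[0, 1]` (integer TIFF data are scaled by the `tiff` package
#' according to bit depth).
#'
#' @param path directory of `.tif`/`.tiff` files, or one TIFF file.
#' @param interval frame interval, s.
#' @param resolution image resolution, px/mm.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, interval = 30, resolution = 1450) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (!length(files))
      pt_stop("patchtrack_io_error", sprintf("no TIFF files in %s", path))
    frames <- lapply(files, function(f) {
      page <- tryCatch(tiff::readTIFF(f),
                       error = function(e) pt_stop("patchtrack_io_error",
                         sprintf("cannot read %s: %s", f, conditionMessage(e))))
      as_gray_matrix(page, f)
    })
  } else if (file.exists(path)) {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                      error = function(e) pt_stop("patchtrack_io_error",
                        sprintf("cannot read %s: %s", path, conditionMessage(e))))
    frames <- lapply(pages, as_gray_matrix, file = path)
  } else {
    pt_stop("patchtrack_io_error", sprintf("no such file or directory: %s", path))
  }
  image_stack(frames, interval = interval, resolution = resolution)
}

#' Write a stack as single-page TIFF files
#'
#' @param stack an [image_stack()].
#' @param dir output directory (created if needed); frames are written as
#'   `frame_000.tif`, `frame_001.tif`, ...
#' @param bits bits per sample.
#' @return invisibly, the file paths.
#' @export
write_stack <- function(stack, dir, bits = 16) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, sprintf("frame_%03d.tif", seq_along(stack$frames) - 1))
  for (i in seq_along(paths))
    tiff::writeTIFF(stack$frames[[i]], paths[i], bits.per.sample = bits)
  invisible(paths)
}

#' Read midline seed points from CSV
#'
#' Two-column CSV with header `x,y`, pixel coordinates (0-based, x =
#' column), first row the quiescent center.
#'
#' @param path CSV path.
#' @return two-column matrix of seed coordinates.
#' @export
read_seed_points <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(d)))
    pt_stop("patchtrack_io_error", "seed CSV must have columns x,y")
  as.matrix(d[, c("x", "y")])
}

#' Pipeline run configuration
#'
#' Defaults follow the acquisition setup the package targets: 10-px disk
#' spacing, 1e-6 px convergence threshold, 30 s frame interval, 1450 px/mm.
#' Every default is overridable.
#'
#' @param stack path to the TIFF stack (directory or multi-page file), or an
#'   [image_stack()] already in memory.
#' @param seed_points path to the seed CSV, or a two-column matrix.
#' @param out_dir output directory for all result files.
#' @param spacing,radius disk layout, px.
#' @param threshold,max_iter,sigma,sampler solver controls.
#' @param resolution px/mm; `interval` s.
#' @param fixed_midline keep the frame-0 midline (see [track_stack()]).
#' @param fit_seed RNG seed for the fit restarts.
#' @return object of class `run_config`.
#' @export
run_config <- function(stack, seed_points, out_dir,
                       spacing = 10, radius = 15, threshold = 1e-6,
                       max_iter = 50, sigma = 1, sampler = "bicubic",
                       resolution = 1450, interval = 30,
                       fixed_midline = FALSE, fit_seed = 1L) {
  structure(list(stack = stack, seed_points = seed_points, out_dir = out_dir,
                 spacing = spacing, radius = radius, threshold = threshold,
                 max_iter = max_iter, sigma = sigma, sampler = sampler,
                 resolution = resolution, interval = interval,
                 fixed_midline = fixed_midline, fit_seed = fit_seed),
            class = "run_config")
}

write_csv_plain <- function(d, path) {
  utils::write.csv(format(d, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
}

#' Diagnostic plot of the velocity cloud and fitted profiles
#'
#' Two panels: the (position, velocity) point cloud with the fitted
#' flexible-logistic curve, and the REGR profile with the four extracted
#' traits marked.
#'
#' @param cloud velocity samples from [track_stack()].
#' @param fit a [fit_flexible_logistic()] result.
#' @param traits an [extract_traits()] result.
#' @param path output image path (PNG).
#' @return invisibly, `path`.
#' @export
qc_plot <- function(cloud, fit, traits, path) {
  grDevices::png(path, width = 900, height = 1100, res = 110)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  xr <- range(cloud$station_mm)
  xs <- seq(xr[1], xr[2], length.out = 400)
  graphics::plot(cloud$station_mm, cloud$velocity_mm_h, pch = 16, cex = 0.2,
       col = grDevices::adjustcolor("black", 0.15),
       xlab = "position from QC (mm)", ylab = "velocity (mm/h)",
       main = "velocity profile")
  graphics::lines(xs, velocity_model(fit$params, xs), col = "red", lwd = 2)
  graphics::plot(xs, regr_profile(fit$params, xs), type = "l", col = "red", lwd = 2,
       xlab = "position from QC (mm)", ylab = "REGR (%/h)",
       main = "relative elemental growth rate")
  graphics::abline(v = c(traits$zone_apical, traits$zone_basal), lty = 3)
  graphics::points(traits$max_regr_position, traits$max_regr, pch = 19)
  invisible(path)
}

#' Run the full kinematic analysis pipeline
#'
#' Reads the stack and seed points, builds the midline, tracks every disk
#' through all frame pairs, fits the flexible logistic velocity profile,
#' extracts the kinematic traits, and writes `velocity_points.csv`,
#' `disk_coordinates.csv`, `fitted_velocity.csv`, `regr_profile.csv`,
#' `traits.csv`, `qc_plot.png` and `run_log.txt` to the output directory.
#'
#' @param config a [run_config()].
#' @param verbose print per-frame progress.
#' @return invisibly, a list with `status` (0 on success, 1 on fit
#'   failure/degeneracy), `cloud`, `fit`, `traits`, `files`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stack <- if (inherits(config$stack, "image_stack")) config$stack else
    read_stack(config$stack, interval = config$interval,
               resolution = config$resolution)
  seeds <- if (is.character(config$seed_points))
    read_seed_points(config$seed_points) else as.matrix(config$seed_points)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  midline <- interpolate_midline(seeds, count = 100)
  cloud <- track_stack(stack, midline,
                       spacing = config$spacing, radius = config$radius,
                       threshold = config$threshold, max_iter = config$max_iter,
                       sigma = config$sigma, sampler = config$sampler,
                       fixed_midline = config$fixed_midline, verbose = verbose)
  drops <- attr(cloud, "drops")

  status <- 0
  fit <- tryCatch(
    fit_flexible_logistic(cloud, seed = config$fit_seed),
    patchtrack_fit_failure = function(e) e)
  files <- file.path(config$out_dir,
                     c("velocity_points.csv", "disk_coordinates.csv",
                       "fitted_velocity.csv", "regr_profile.csv",
                       "traits.csv", "qc_plot.png", "run_log.txt"))
  names(files) <- c("velocity_points", "disk_coordinates", "fitted_velocity",
                    "regr_profile", "traits", "qc_plot", "run_log")

  write_csv_plain(cloud, files[["velocity_points"]])
  write_csv_plain(attr(cloud, "disk_coordinates"), files[["disk_coordinates"]])

  traits <- NULL
  if (inherits(fit, "condition") || fit$degenerate) {
    status <- 1
    msg <- if (inherits(fit, "condition")) conditionMessage(fit) else
      "degenerate fit: velocity cloud has no spread"
  } else {
    xr <- range(cloud$station_mm)
    xs <- seq(xr[1], xr[2], length.out = 500)
    write_csv_plain(data.frame(x_mm = xs, v_mm_h = velocity_model(fit$params, xs)),
                    files[["fitted_velocity"]])
    write_csv_plain(data.frame(x_mm = xs, regr_pct_h = regr_profile(fit$params, xs)),
                    files[["regr_profile"]])
    traits <- extract_traits(fit$params)
    write_csv_plain(data.frame(
      v_f = fit$params$v_f, k = fit$params$k, x0 = fit$params$x0,
      n = fit$params$n, max_regr_pct_h = traits$max_regr,
      max_regr_pos_mm = traits$max_regr_position,
      zone_length_mm = traits$zone_length,
      avg_rate_mm_h = traits$avg_growth_rate,
      sse = fit$sse, n_samples = fit$n_samples),
      files[["traits"]])
    qc_plot(cloud, fit, traits, files[["qc_plot"]])
    msg <- "ok"
  }

  log_lines <- c(
    sprintf("frames: %d  (%dx%d px)", length(stack$frames),
            nrow(stack$frames[[1]]), ncol(stack$frames[[1]])),
    sprintf("resolution: %g px/mm  interval: %g s", stack$resolution,
            stack$interval),
    sprintf("spacing: %g px  radius: %g px  threshold: %g  max_iter: %d",
            config$spacing, config$radius, config$threshold, config$max_iter),
    sprintf("samples: %d", nrow(cloud)),
    sprintf("dropped disks: %d", nrow(drops)),
    if (nrow(drops)) sprintf("drop frame=%d disk=%d reason=%s",
                             drops$frame, drops$disk_id, drops$reason),
    sprintf("fit: %s", msg))
  writeLines(log_lines, files[["run_log"]])

  invisible(list(status = status, cloud = cloud, fit = fit, traits = traits,
                 files = files))
}
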