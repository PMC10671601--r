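# Shared numerical helpers. Image frames are plain numeric matrices indexed
# [row, col]; user-facing coordinates are 0-based with x = column, y = row,
# sub-pixel values allowed.

#' Sample an image at sub-pixel coordinates
#'
#' Bilinear (default) or Catmull-Rom bicubic interpolation of a grayscale
#' frame at arbitrary, possibly fractional, pixel positions. Positions
#' outside the frame (or, for bicubic, within one pixel of the border)
#' return `NA`, which callers use to detect patches leaving the field of
#' view.
#'
#' @param img numeric matrix, intensities in `[0, 1]`.
#' @param x,y numeric vectors of 0-based column/row coordinates.
#' @param method `"bilinear"` or `"bicubic"`.
#' @return numeric vector of sampled intensities, `NA` where out of bounds.
#' @export
sample_image <- function(img, x, y, method = c("bicubic", "bilinear")) {
  method <- match.arg(method)
  if (method == "bilinear") bilinear_sample(img, x, y) else bicubic_sample(img, x, y)
}

bilinear_sample <- function(img, x, y) {
  nr <- nrow(img)
  nc <- ncol(img)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x) & !is.na(y) & x >= 0 & y >= 0 & x <= nc - 1 & y <= nr - 1
  if (!any(ok)) return(out)
  xs <- x[ok]
  ys <- y[ok]
  x0 <- pmin(floor(xs), nc - 2)
  y0 <- pmin(floor(ys), nr - 2)
  fx <- xs - x0
  fy <- ys - y0
  i00 <- x0 * nr + y0 + 1  # column-major linear index of img[y0+1, x0+1]
  out[ok] <- img[i00] * (1 - fx) * (1 - fy) +
    img[i00 + nr] * fx * (1 - fy) +
    img[i00 + 1] * (1 - fx) * fy +
    img[i00 + nr + 1] * fx * fy
  out
}

# Catmull-Rom kernel weights for the four taps around fractional offset f.
cubic_weights <- function(f) {
  f2 <- f * f
  f3 <- f2 * f
  cbind(-0.5 * f3 + f2 - 0.5 * f,
        1.5 * f3 - 2.5 * f2 + 1,
        -1.5 * f3 + 2 * f2 + 0.5 * f,
        0.5 * f3 - 0.5 * f2)
}

bicubic_sample <- function(img, x, y) {
  nr <- nrow(img)
  nc <- ncol(img)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x) & !is.na(y) & x >= 1 & y >= 1 & x <= nc - 3 & y <= nr - 3
  if (!any(ok)) return(out)
  xs <- x[ok]
  ys <- y[ok]
  x0 <- pmin(floor(xs), nc - 3)
  y0 <- pmin(floor(ys), nr - 3)
  wx <- cubic_weights(xs - x0)
  wy <- cubic_weights(ys - y0)
  acc <- 0
  for (j in 1:4) {
    row <- 0
    base <- (x0 + j - 2) * nr + y0  # img[y0+1 + (i-2) + 1, x0+j-2 + 1]
    for (i in 1:4) row <- row + wy[, i] * img[base + i - 1]
    acc <- acc + wx[, j] * row
  }
  out[ok] <- acc
  out
}

# Lightly smoothed copy of a frame; sigma = 0 disables smoothing.
smooth_frame <- function(frame, sigma = 1) {
  if (sigma <= 0) return(frame)
  EBImage::gblur(frame, sigma = sigma)
}

# Error conditions with machine-checkable classes -------------------------

pt_stop <- function(class, msg, ...) {
  stop(structure(class = c(class, "patchtrack_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

stop_invalid_input <- function(msg, ...) pt_stop("patchtrack_invalid_input", msg, ...)
stop_geometry <- function(msg, ...) pt_stop("patchtrack_geometry_error", msg, ...)
stop_out_of_bounds <- function(msg, ...) pt_stop("patchtrack_oob_error", msg, ...)
stop_degenerate_patch <- function(msg, ...) pt_stop("patchtrack_degenerate_patch", msg, ...)
stop_fit_failure <- function(msg, ...) pt_stop("patchtrack_fit_failure", msg, ...)

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
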