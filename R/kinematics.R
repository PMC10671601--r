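# The flexible logistic velocity profile and the kinematic traits derived
# from it. Velocity v(x) of root material at distance x from the quiescent
# center follows the four-parameter sigmoid of Morris & Silk,
#
#   v(x) = v_f * [1 + exp(-k (x - x0))]^(-1/n)
#
# with final velocity v_f (mm/h), steepness k (1/mm), reference position x0
# (mm) and asymmetry exponent n. Its spatial derivative, expressed in % per
# hour, is the relative elemental growth rate (REGR) profile whose peak and
# width describe the elongation zone.

#' Flexible logistic parameter set
#'
#' @param v_f final (plateau) velocity, mm/h; also the average root
#'   elongation rate.
#' @param k steepness of the velocity rise, 1/mm.
#' @param x0 reference position of the sigmoid, mm from the QC (the
#'   inflection for `n = 1`).
#' @param n asymmetry exponent (dimensionless); `n = 1` gives the symmetric
#'   logistic.
#' @return object of class `logistic_params`.
#' @export
logistic_params <- function(v_f, k, x0, n = 1) {
  structure(list(v_f = v_f, k = k, x0 = x0, n = n),
            class = "logistic_params")
}

#' @export
print.logistic_params <- function(x, ...) {
  cat(sprintf("<logistic_params> v_f = %.4g mm/h, k = %.4g 1/mm, x0 = %.4g mm, n = %.4g\n",
              x$v_f, x$k, x$x0, x$n))
  invisible(x)
}

# log(1 + exp(z)) without overflow
softplus <- function(z) ifelse(z > 30, z + log1p(exp(-z)), log1p(exp(z)))

#' Flexible logistic velocity profile
#'
#' Overflow-safe evaluation of the sigmoid; `v(-Inf) -> 0`,
#' `v(+Inf) -> v_f`.
#'
#' @param params a [logistic_params()].
#' @param x positions, mm from the QC.
#' @return velocities, mm/h.
#' @examples
#' velocity_model(logistic_params(0.1, 10, 0.35, 1), 0.35)  # v_f / 2
#' @export
velocity_model <- function(params, x) {
  z <- -params$k * (x - params$x0)
  params$v_f * exp(-softplus(z) / params$n)
}

#' Relative elemental growth rate profile
#'
#' Analytic derivative of [velocity_model()], reported in % per hour:
#' `REGR(x) = 100 * (v_f k / n) * u * (1 + u)^(-1/n - 1)` with
#' `u = exp(-k (x - x0))`.
#'
#' @param params a [logistic_params()].
#' @param xs positions, mm from the QC.
#' @return REGR values, % / h.
#' @export
regr_profile <- function(params, xs) {
  z <- -params$k * (xs - params$x0)  # log(u)
  100 * (params$v_f * params$k / params$n) *
    exp(z - (1 / params$n + 1) * softplus(z))
}

# Moving-median initialization for the optimizer: v_f from the upper tail of
# the sampled velocities, x0 where a moving median first crosses v_f/2, k
# from the local slope there.
initial_guess <- function(x, v) {
  v_f <- max(stats::quantile(v, 0.95, names = FALSE), 1e-8)
  ord <- order(x)
  xs <- x[ord]
  vs <- v[ord]
  win <- max(5, min(101, floor(length(xs) / 10)))
  med <- stats::runmed(vs, k = win + (win %% 2 == 0))
  above <- which(med > v_f / 2)
  x0 <- if (length(above)) xs[above[1]] else stats::median(xs)
  near <- abs(xs - x0) <= max(diff(range(xs)) / 10, 1e-6)
  slope <- if (sum(near) >= 3)
    stats::coef(stats::lm(med[near] ~ xs[near]))[2] else NA
  k <- if (is.finite(slope) && slope > 0) 4 * slope / v_f else
    10 / max(diff(range(xs)), 1e-6)
  logistic_params(v_f = v_f, k = max(k, 1e-3), x0 = x0, n = 1)
}

#' Fit the flexible logistic profile to a velocity point cloud
#'
#' Minimizes the unweighted sum of squared residuals between sampled
#' velocities and [velocity_model()] over (v_f, k, x0, n) with the
#' Nelder-Mead simplex, positive parameters log-transformed. The optimizer
#' is restarted from jittered initial guesses and the best fit kept.
#'
#' @param cloud data frame with columns `station_mm` and `velocity_mm_h`
#'   (the output of [track_stack()]), or a two-column matrix (position,
#'   velocity).
#' @param init optional [logistic_params()] starting point; by default a
#'   moving-median heuristic picks it from the cloud.
#' @param restarts number of jittered Nelder-Mead restarts.
#' @param seed RNG seed for the restart jitter (local to the fit; the
#'   caller's RNG state is untouched).
#' @return list of class `logistic_fit`: `params`, `sse`, `converged`,
#'   `degenerate`, `n_samples`, `init`.
#' @export
fit_flexible_logistic <- function(cloud, init = NULL, restarts = 3, seed = 1L) {
  if (is.matrix(cloud)) cloud <- data.frame(station_mm = cloud[, 1],
                                            velocity_mm_h = cloud[, 2])
  x <- cloud$station_mm
  v <- cloud$velocity_mm_h
  keep <- is.finite(x) & is.finite(v)
  x <- x[keep]
  v <- v[keep]
  if (length(x) < 5)
    stop_fit_failure("too few velocity samples to fit")

  if (stats::sd(v) < 1e-9 * max(1, abs(mean(v)))) {
    warning("velocity cloud has no spread; returning degenerate fit (v_f ~ mean velocity)")
    p <- logistic_params(v_f = mean(v), k = NA_real_, x0 = NA_real_, n = NA_real_)
    return(structure(list(params = p, sse = sum((v - mean(v))^2),
                          converged = FALSE, degenerate = TRUE,
                          n_samples = length(v), init = NULL),
                     class = "logistic_fit"))
  }

  if (is.null(init)) init <- initial_guess(x, v)
  sse_fn <- function(p) {
    pr <- logistic_params(exp(p[1]), exp(p[2]), p[3], exp(p[4]))
    sum((v - velocity_model(pr, x))^2)
  }
  p0 <- c(log(init$v_f), log(init$k), init$x0, log(init$n))

  best <- NULL
  with_seed(seed, {
    for (r in seq_len(max(1, restarts))) {
      start <- if (r == 1) p0 else
        p0 + c(stats::rnorm(2, 0, 0.2), stats::rnorm(1, 0, 0.05 * max(abs(p0[3]), 0.1)),
               stats::rnorm(1, 0, 0.2))
      opt <- stats::optim(start, sse_fn, method = "Nelder-Mead",
                          control = list(maxit = 10000, reltol = 1e-10))
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    if (best$convergence != 0) {
      # polish from the best simplex found so far
      opt <- stats::optim(best$par, sse_fn, method = "Nelder-Mead",
                          control = list(maxit = 10000, reltol = 1e-10))
      if (opt$value <= best$value || opt$convergence == 0) best <- opt
    }
  })
  if (best$convergence != 0)
    stop_fit_failure(sprintf("Nelder-Mead failed to converge (code %d, sse %.4g)",
                             best$convergence, best$value))
  params <- logistic_params(exp(best$par[1]), exp(best$par[2]),
                            best$par[3], exp(best$par[4]))
  structure(list(params = params, sse = best$value, converged = TRUE,
                 degenerate = FALSE, n_samples = length(v), init = init),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<logistic_fit> DEGENERATE: v_f ~ %.4g mm/h over %d samples\n",
                x$params$v_f, x$n_samples))
  } else {
    cat(sprintf("<logistic_fit> sse = %.4g over %d samples\n", x$sse, x$n_samples))
    print(x$params)
  }
  invisible(x)
}

#' Extract the four kinematic traits of the elongation zone
#'
#' From a fitted profile: maximum REGR (the peak of the REGR profile, % /h);
#' the axial position of that peak (`x0 - log(n)/k`, clipped at the QC);
#' elongation-zone length (distance between the two positions where REGR
#' falls to 20% of its maximum, found by root bracketing on each side of the
#' peak, the apical bound clipped at the QC); and average growth rate, which
#' equals `v_f` (the area under the REGR profile).
#'
#' @param params a fitted [logistic_params()].
#' @return list of class `kinematic_traits`: `max_regr` (%/h),
#'   `max_regr_position` (mm), `zone_length` (mm), `avg_growth_rate` (mm/h),
#'   plus `zone_apical`, `zone_basal` and clipping flags.
#' @examples
#' extract_traits(logistic_params(0.1, 10, 0.35, 1))
#' @export
extract_traits <- function(params) {
  if (!all(c(params$v_f, params$k, params$n) > 0))
    stop_invalid_input("extract_traits needs v_f, k, n > 0")
  peak_raw <- params$x0 - log(params$n) / params$k
  peak_clipped <- peak_raw < 0
  peak <- max(0, peak_raw)
  max_regr <- regr_profile(params, peak)
  target <- 0.2 * max_regr

  f <- function(x) regr_profile(params, x) - target
  span <- 10 / params$k
  basal <- stats::uniroot(f, c(peak, peak + span), tol = 1e-9)$root
  apical_clipped <- FALSE
  lo <- peak - span
  if (peak == 0 || f(max(lo, 0)) > 0 && peak_clipped) {
    apical <- 0
    apical_clipped <- TRUE
  } else {
    apical <- stats::uniroot(f, c(lo, peak), tol = 1e-9)$root
    if (apical < 0) {
      apical <- 0
      apical_clipped <- TRUE
    }
  }
  structure(list(max_regr = max_regr,
                 max_regr_position = peak,
                 zone_length = basal - apical,
                 avg_growth_rate = params$v_f,
                 zone_apical = apical,
                 zone_basal = basal,
                 peak_clipped = peak_clipped,
                 apical_clipped = apical_clipped),
            class = "kinematic_traits")
}

#' @export
print.kinematic_traits <- function(x, ...) {
  cat(sprintf(paste0("<kinematic_traits>\n",
                     "  max REGR:          %.3f %%/h at %.4f mm from the QC\n",
                     "  elongation zone:   %.4f mm (%.4f to %.4f mm)\n",
                     "  avg growth rate:   %.4f mm/h\n"),
              x$max_regr, x$max_regr_position, x$zone_length,
              x$zone_apical, x$zone_basal, x$avg_growth_rate))
  if (x$apical_clipped) cat("  (apical zone bound clipped at the QC)\n")
  invisible(x)
}
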