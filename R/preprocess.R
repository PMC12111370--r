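# Spectral pre-treatment: Savitzky-Golay smoothing/derivatives, asymmetric
# least squares (ALS) baseline estimation, band cropping.

# Savitzky-Golay convolution weights for one evaluation offset.
# window points at integer offsets `x`, polynomial of degree `order`,
# derivative `deriv` evaluated at offset 0.
.sg_weights <- function(x, order, deriv) {
  A <- outer(x, 0:order, `^`)
  # row of the pseudoinverse corresponding to the `deriv`-th coefficient
  C <- solve(crossprod(A), t(A))
  C[deriv + 1L, ] * factorial(deriv)
}

# Core SG engine on a numeric vector with truncated windows at the edges:
# every point is the value (or derivative) at the center of a local
# polynomial least-squares fit; near the boundaries the window is truncated
# rather than padded, so out-of-band content never leaks in.
.sg_smooth <- function(y, window, order, deriv, delta) {
  n <- length(y)
  half <- (window - 1L) %/% 2L
  w_int <- .sg_weights((-half):half, order, deriv)
  out <- numeric(n)
  if (n >= window) {
    # interior via filter
    for (i in (half + 1L):(n - half))
      out[i] <- sum(w_int * y[(i - half):(i + half)])
    edge <- c(seq_len(half), (n - half + 1L):n)
  } else edge <- seq_len(n)
  for (i in edge) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    x <- (lo:hi) - i
    ord <- min(order, length(x) - 1L)
    w <- .sg_weights(x, ord, min(deriv, ord))
    out[i] <- if (deriv > ord) 0 else sum(w * y[lo:hi])
  }
  out / delta^deriv
}

#' Savitzky--Golay smoothing and derivatives
#'
#' Local least-squares polynomial smoothing on the spectrum's uniform grid.
#' With `deriv > 0` the corresponding derivative of the local polynomial is
#' returned (per cm^-1 units), as used by the derivative-based peak search
#' of [initialize_peaks].  Boundary points are fitted on truncated windows
#' (no reflection or padding), so a cropped band is smoothed independently
#' of any out-of-band content.
#'
#' @param x a [spectrum].
#' @param window odd window size in points (default 25).
#' @param order polynomial order (default 2; must exceed `deriv`... at
#'   least equal it).
#' @param deriv derivative order (0 = smoothing).
#' @return a [spectrum] on the same grid (for `deriv > 0`, "absorbance"
#'   holds the derivative trace).
#' @examples
#' s <- spectrum_from_table("FYHHH")
#' sm <- savitzky_golay(s)
#' @export
savitzky_golay <- function(x, window = 25L, order = 2L, deriv = 0L) {
  .assert_spectrum(x)
  window <- as.integer(window); order <- as.integer(order)
  if (window %% 2L == 0L) stop("window must be odd")
  if (order >= window) stop("order must be smaller than window")
  if (deriv > order) stop("deriv must not exceed order")
  n <- length(x$wavenumber)
  if (n < window) stop(sprintf("spectrum (%d points) shorter than window (%d)", n, window))
  delta <- .grid_step(x$wavenumber)
  out <- x
  out$absorbance <- .sg_smooth(x$absorbance, window, order, deriv, delta)
  out
}

#' Asymmetric least squares baseline
#'
#' Estimates a smooth baseline under the spectrum by iterating a penalized
#' weighted least squares (Whittaker) smoother with asymmetric weights:
#' the baseline `z` minimizes `sum_i w_i (y_i - z_i)^2 + lambda sum (d2 z)^2`
#' where points above the current baseline get weight `p` and points below
#' get `1 - p`.  With small `p` the baseline hugs the underside of the
#' spectrum, leaving peaks in the corrected trace.
#'
#' Iteration stops when the relative change of the baseline falls below
#' `threshold` (or when the weight pattern stops changing); hitting
#' `max_iter` without convergence produces a warning, not an error, and the
#' last iterate is returned.
#'
#' @param x a [spectrum].
#' @param lambda smoothness penalty (default 1e6, typical for cm^-1
#'   gridded FTIR; results are stable across 1e5--1e7).
#' @param p asymmetry factor in (0, 1) (default 0.001).
#' @param threshold relative-change convergence threshold (default 0.01).
#' @param max_iter iteration cap (default 50).
#' @return list with `baseline` and `corrected` (both [spectrum]s),
#'   `iterations`, `converged`, `objective` (the penalized objective after
#'   each solve, computed with that iteration's weights) and
#'   `objective_pre` (the same objective at the previous iterate -- each
#'   solve is an exact minimizer given the weights, so
#'   `objective <= objective_pre` holds per iteration).
#' @examples
#' s <- spectrum_from_table("FYHHH")
#' s$absorbance <- s$absorbance + 0.05 + 1e-4 * (s$wavenumber - 1185)
#' bc <- als_baseline(s)
#' @export
als_baseline <- function(x, lambda = 1e6, p = 0.001, threshold = 0.01,
                         max_iter = 50L) {
  .assert_spectrum(x)
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  if (lambda <= 0) stop("lambda must be positive")
  y <- x$absorbance
  n <- length(y)
  if (n < 4L) stop("spectrum too short for baseline estimation")
  D <- Matrix::bandSparse(n - 2L, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  converged <- FALSE
  objective <- objective_pre <- numeric(0)
  obj <- function(w, z)
    sum(w * (y - z)^2) + lambda * sum(diff(z, differences = 2)^2)
  for (it in seq_len(max_iter)) {
    objective_pre[it] <- obj(w, z)   # current weights at the previous iterate
    W <- Matrix::Diagonal(n, w)
    z_new <- as.numeric(Matrix::solve(W + DtD, w * y))
    objective[it] <- obj(w, z_new)
    w_new <- ifelse(y > z_new, p, 1 - p)
    rel <- sum(abs(z_new - z)) / max(sum(abs(z_new)), .Machine$double.eps)
    z <- z_new
    if ((it > 1L && rel < threshold) || all(w_new == w)) {
      w <- w_new
      converged <- TRUE
      break
    }
    w <- w_new
  }
  if (!converged)
    warning(sprintf("ALS baseline did not converge in %d iterations", max_iter))
  baseline <- x; baseline$absorbance <- z
  corrected <- x; corrected$absorbance <- y - z
  list(baseline = baseline, corrected = corrected,
       iterations = if (converged) it else max_iter,
       converged = converged, weights = w,
       objective = objective, objective_pre = objective_pre)
}

#' Crop a spectrum to a wavenumber band
#'
#' @param x a [spectrum].
#' @param low,high band bounds in cm^-1 (defaults: the Amide III band,
#'   1185--1330).
#' @return the [spectrum] restricted to `[low, high]`.
#' @export
crop_band <- function(x, low = 1185, high = 1330) {
  .assert_spectrum(x)
  if (low > high) stop("low must not exceed high")
  keep <- x$wavenumber >= low & x$wavenumber <= high
  if (!any(keep)) stop(sprintf("band [%g, %g] does not overlap spectrum", low, high))
  out <- x
  out$wavenumber <- x$wavenumber[keep]
  out$absorbance <- x$absorbance[keep]
  out
}

#' Standard pre-treatment chain
#'
#' Savitzky--Golay smoothing, ALS baseline correction over the full
#' recorded range, then cropping to the analysis band -- the conventional
#' order for FTIR band-shape analysis.
#'
#' @param x a [spectrum].
#' @param sg_window,sg_order Savitzky--Golay parameters.
#' @param als_lambda,als_p,als_threshold,als_max_iter ALS parameters.
#' @param band length-2 crop window, cm^-1.
#' @return the corrected, cropped [spectrum]; ALS diagnostics are attached
#'   as attribute `"als"` (iterations, converged).
#' @export
preprocess_spectrum <- function(x, sg_window = 25L, sg_order = 2L,
                                als_lambda = 1e6, als_p = 0.001,
                                als_threshold = 0.01, als_max_iter = 50L,
                                band = c(1185, 1330)) {
  sm <- savitzky_golay(x, window = sg_window, order = sg_order)
  bc <- als_baseline(sm, lambda = als_lambda, p = als_p,
                     threshold = als_threshold, max_iter = als_max_iter)
  out <- crop_band(bc$corrected, band[1], band[2])
  attr(out, "als") <- list(iterations = bc$iterations,
                           converged = bc$converged)
  out
}
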