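# Box-constrained 12-Gaussian deconvolution of the Amide III band:
# derivative-based peak initialization followed by Levenberg-Marquardt
# least squares with box constraints.

#' Fit constraints for the Gaussian deconvolution
#'
#' @param center_box half-width of the allowed center excursion around the
#'   *initialized* center, cm^-1 (default 2, the conventional lock-in for
#'   Amide III sub-bands).
#' @param fwhm_box allowed FWHM range, cm^-1.  The default `c(7, 19)`
#'   covers the widths observed for Amide III sub-bands of GCF; the strict
#'   preset `c(7, 10)` used by some protocols is available via
#'   `fit_constraints(strict_fwhm = TRUE)` but truncates genuinely broad
#'   components.
#' @param strict_fwhm logical; use the strict `c(7, 10)` FWHM box.
#' @return list of class `fit_constraints`.
#' @export
fit_constraints <- function(center_box = 2, fwhm_box = c(7, 19),
                            strict_fwhm = FALSE) {
  if (strict_fwhm) fwhm_box <- c(7, 10)
  if (center_box <= 0) stop("center_box must be positive")
  if (length(fwhm_box) != 2 || fwhm_box[1] <= 0 || fwhm_box[2] <= fwhm_box[1])
    stop("fwhm_box must be an increasing positive pair")
  structure(list(center_box = center_box, fwhm_box = fwhm_box),
            class = "fit_constraints")
}

# local extrema indices of a vector (strict neighbours)
.local_minima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  which(y[2:(n - 1)] < y[1:(n - 2)] & y[2:(n - 1)] <= y[3:n]) + 1L
}
.local_maxima <- function(y) .local_minima(-y)

#' Derivative-based peak initialization
#'
#' Produces the 12 starting components for [fit_gaussians].  Candidate band
#' centers are the local minima of the Savitzky--Golay-smoothed second
#' derivative, refined to the nearest local maximum of the fourth
#' derivative (which resolves overlapped bands more sharply).  Each library
#' component takes the candidate inside its (padded) window closest to the
#' window midpoint; a window with no candidate falls back to the window
#' midpoint (overlapped neighbours often merge in the derivative traces, so
#' a missing candidate is expected, not an error).  The starting FWHM is
#' the midpoint of
#' the FWHM box and the starting area follows from the local band height
#' via the Gaussian height--area relation.
#'
#' @param x baseline-corrected [spectrum] cropped to the Amide III band.
#' @param library a [amide3_library].
#' @param constraints a [fit_constraints].
#' @param sg_window window for the derivative smoothing (points).
#' @param sg_order polynomial order for the derivative smoothing; at least
#'   4 so the fourth derivative is available (default 4).
#' @param window_pad cm^-1 by which windows are widened when matching
#'   candidates (band centers may sit marginally outside the literature
#'   windows; default 0.5).
#' @param refine_radius cm^-1 search radius for the fourth-derivative
#'   refinement of a second-derivative candidate.
#' @return data.frame with 12 rows: `index`, `assignment`, `center`,
#'   `fwhm`, `area`, `source` ("derivative" or "midpoint").
#' @export
initialize_peaks <- function(x, library = amide3_library(),
                             constraints = fit_constraints(),
                             sg_window = 25L, sg_order = 4L,
                             window_pad = 0.5, refine_radius = 2) {
  .assert_spectrum(x)
  w <- x$wavenumber
  if (length(w) < sg_window)
    stop("spectrum shorter than the derivative smoothing window")
  d2 <- savitzky_golay(x, window = sg_window, order = sg_order, deriv = 2L)$absorbance
  d4 <- savitzky_golay(x, window = sg_window, order = sg_order, deriv = 4L)$absorbance
  scale <- max(abs(x$absorbance))
  flat <- scale <= 0 || max(abs(d2)) < 1e-12 * max(scale, 1)

  cand <- numeric(0)
  if (!flat) {
    i2 <- .local_minima(d2)
    i2 <- i2[d2[i2] < 0]
    cand <- w[i2]
    # refine: snap to the nearest 4th-derivative local maximum nearby
    i4 <- .local_maxima(d4)
    i4 <- i4[d4[i4] > 0]
    if (length(i4)) {
      peaks4 <- w[i4]
      cand <- vapply(cand, function(cw) {
        d <- abs(peaks4 - cw)
        if (min(d) <= refine_radius) peaks4[which.min(d)] else cw
      }, numeric(1))
      # 4th-derivative maxima with no 2nd-derivative partner are extra
      # candidates (they flag shoulders merged in the 2nd derivative)
      extra <- peaks4[vapply(peaks4, function(pw) all(abs(cand - pw) > refine_radius),
                             logical(1))]
      cand <- sort(unique(c(cand, extra)))
    }
  }

  half_sigma <- mean(constraints$fwhm_box) * FWHM_TO_SIGMA
  init <- library[, c("index", "assignment")]
  init$center <- NA_real_; init$fwhm <- mean(constraints$fwhm_box)
  init$area <- NA_real_; init$source <- NA_character_
  for (k in seq_len(nrow(library))) {
    lo <- library$window_low[k] - window_pad
    hi <- library$window_high[k] + window_pad
    mid <- library$midpoint[k]
    inside <- cand[cand >= lo & cand <= hi]
    if (length(inside)) {
      init$center[k] <- inside[which.min(abs(inside - mid))]
      init$source[k] <- "derivative"
    } else {
      init$center[k] <- mid
      init$source[k] <- "midpoint"
    }
    height <- max(0, x$absorbance[which.min(abs(w - init$center[k]))])
    init$area[k] <- height * half_sigma * sqrt(2 * pi)
  }
  init
}

# model and Jacobian for the 36-parameter sum-of-Gaussians
.pack <- function(params) c(params$center, params$fwhm, params$area)
.unpack <- function(p) {
  m <- length(p) / 3L
  list(center = p[seq_len(m)], fwhm = p[m + seq_len(m)], area = p[2L * m + seq_len(m)])
}

.model_eval <- function(p, w) {
  q <- .unpack(p)
  y <- numeric(length(w))
  for (i in seq_along(q$center)) {
    s <- q$fwhm[i] * FWHM_TO_SIGMA
    y <- y + q$area[i] * exp(-((w - q$center[i])^2) / (2 * s^2)) / (s * sqrt(2 * pi))
  }
  y
}

.model_jac <- function(p, w) {
  q <- .unpack(p)
  m <- length(q$center)
  J <- matrix(0, length(w), 3L * m)
  for (i in seq_len(m)) {
    s <- q$fwhm[i] * FWHM_TO_SIGMA
    u <- (w - q$center[i]) / s
    core <- exp(-u^2 / 2) / (s * sqrt(2 * pi))
    g <- q$area[i] * core
    J[, i] <- g * u / s                          # d/d center
    J[, m + i] <- g * (u^2 - 1) / s * FWHM_TO_SIGMA  # d/d fwhm
    J[, 2L * m + i] <- core                      # d/d area
  }
  J
}

#' Box-constrained Levenberg--Marquardt Gaussian fit
#'
#' Fits the sum of 12 Gaussians to a baseline-corrected Amide III band by
#' Levenberg--Marquardt least squares with box constraints: each center may
#' move at most `center_box` from its initialized value, each FWHM must lie
#' in `fwhm_box`, and areas are non-negative.  Exactly 12 components are
#' always returned -- an area may reach zero but components are never
#' dropped, so fits of different samples remain component-by-component
#' comparable.
#'
#' @param x baseline-corrected [spectrum] on the Amide III band.
#' @param init 12-row initialization as from [initialize_peaks] (columns
#'   `center`, `fwhm`, `area`; `index`/`assignment` carried through).
#' @param constraints a [fit_constraints].
#' @param ftol relative chi-square convergence tolerance (default 1e-10).
#' @param max_iter iteration cap per optimizer run (default 500).
#' @param max_restarts when one or more centers converge onto a boundary of
#'   their box, the fit is restarted with those boxes re-centered on the
#'   converged values, at most this many times (default 6).  This mimics the
#'   operator practice of releasing a peak that presses against its
#'   constraint, while every individual run still respects the +/-
#'   `center_box` excursion around its starting point.  Set to 0 for a
#'   single strictly boxed run.
#' @return object of class `amide3_fit`; see [summary.amide3_fit].
#'   Components: `components` (fitted parameter data.frame with
#'   `relative_pct`), `chi2` (reduced: RSS / (N - 36)), `n_iter`,
#'   `converged`, `fitted`, `residual`, `spectrum`, `init`, `constraints`.
#' @examples
#' s <- spectrum_from_table("FOMLG")
#' fit <- fit_gaussians(s, initialize_peaks(s))
#' summary(fit)
#' @export
fit_gaussians <- function(x, init, constraints = fit_constraints(),
                          ftol = 1e-10, max_iter = 500L, max_restarts = 6L) {
  .assert_spectrum(x)
  init <- as.data.frame(init)
  if (nrow(init) != 12L) stop("initialization must have 12 components")
  w <- x$wavenumber; y <- x$absorbance
  if (length(w) <= 36L)
    stop("need more than 36 points to fit 36 parameters")
  res_fn <- function(p) .model_eval(p, w) - y
  jac_fn <- function(p) .model_jac(p, w)
  ctl <- minpack.lm::nls.lm.control(ftol = ftol, ptol = 1e-12, gtol = 0,
                                    maxiter = min(as.integer(max_iter), 1024L),
                                    maxfev = 100000L)
  centers0 <- init$center
  p0 <- .pack(init)
  n_iter_total <- 0L
  best <- NULL
  for (run in seq_len(1L + max(0L, max_restarts))) {
    lower <- c(centers0 - constraints$center_box,
               rep(constraints$fwhm_box[1], 12L), rep(0, 12L))
    upper <- c(centers0 + constraints$center_box,
               rep(constraints$fwhm_box[2], 12L), rep(Inf, 12L))
    p0 <- pmin(pmax(p0, lower), upper)
    fit <- suppressWarnings(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = res_fn, jac = jac_fn, control = ctl))
    n_iter_total <- n_iter_total + fit$niter
    if (is.null(best) || fit$deviance <= best$deviance) best <- fit
    qc <- .unpack(fit$par)$center
    at_bound <- abs(qc - (centers0 - constraints$center_box)) < 1e-8 |
      abs(qc - (centers0 + constraints$center_box)) < 1e-8
    if (!any(at_bound)) break
    centers0 <- qc      # re-center the boxes on the converged centers
    p0 <- fit$par
  }
  fit <- best
  fit$niter <- n_iter_total
  q <- .unpack(fit$par)
  comps <- data.frame(index = if (!is.null(init$index)) init$index else ROMAN12,
                      assignment = if (!is.null(init$assignment))
                        init$assignment else NA_character_,
                      center = q$center, fwhm = q$fwhm, area = q$area,
                      stringsAsFactors = FALSE)
  comps$relative_pct <- if (sum(comps$area) > 0)
    100 * comps$area / sum(comps$area) else NA_real_
  fitted <- .model_eval(fit$par, w)
  # a run cut off at maxiter while already reproducing the data to
  # numerical noise is converged for every practical purpose
  converged <- fit$info %in% 1:4 ||
    sqrt(fit$deviance / length(y)) <= 1e-7 * max(abs(y))
  if (!converged)
    warning("Gaussian fit did not converge: ", fit$message)
  structure(list(components = comps,
                 chi2 = sum((y - fitted)^2) / (length(y) - 36L),
                 n_iter = fit$niter, converged = converged,
                 message = fit$message,
                 fitted = fitted, residual = y - fitted,
                 spectrum = x, init = init, constraints = constraints),
            class = "amide3_fit")
}

#' One-call Amide III deconvolution
#'
#' [initialize_peaks] followed by [fit_gaussians].  Because the 12-Gaussian
#' least-squares surface has local minima when neighbouring bands overlap
#' strongly, the fit is run from a small set of deterministic starting
#' points and the lowest-chi-square solution is kept:
#' \enumerate{
#'   \item the derivative initialization with its areas replaced by a
#'     linear least-squares warm start (profiles fixed, areas solved and
#'     clipped at zero),
#'   \item the derivative initialization as produced by [initialize_peaks],
#'   \item an all-window-midpoint initialization.
#' }
#' A start whose fit reproduces the data to numerical noise ends the search
#' early.
#'
#' @inheritParams initialize_peaks
#' @inheritParams fit_gaussians
#' @param multistart try the alternative starting points (default `TRUE`);
#'   `FALSE` fits once from the derivative initialization.
#' @param ... passed to [initialize_peaks].
#' @return an `amide3_fit`.
#' @export
deconvolve <- function(x, library = amide3_library(),
                       constraints = fit_constraints(),
                       multistart = TRUE, ...) {
  init <- initialize_peaks(x, library = library, constraints = constraints, ...)
  starts <- list(.ls_area_start(x, init), init)
  if (multistart) {
    mid <- init
    mid$center <- library$midpoint
    mid$fwhm <- mean(constraints$fwhm_box)
    h <- vapply(mid$center, function(cc)
      max(0, x$absorbance[which.min(abs(x$wavenumber - cc))]), numeric(1))
    mid$area <- h * mid$fwhm * FWHM_TO_SIGMA * sqrt(2 * pi)
    mid$source <- "midpoint"
    starts <- c(starts, list(mid))
  }
  best <- NULL
  tol <- (1e-7 * max(abs(x$absorbance)))^2   # "perfect fit" early exit
  for (st in starts) {
    fit <- suppressWarnings(fit_gaussians(x, st, constraints = constraints))
    if (is.null(best) || fit$chi2 < best$chi2) best <- fit
    if (best$chi2 < tol) break
  }
  if (!best$converged)
    warning("Gaussian fit did not converge: ", best$message)
  best
}

#' Deconvolve the portions of one sample
#'
#' The replicate (portion) spectra of a sample are deconvolved in two
#' levels, mirroring how portioned samples are characterized in practice:
#' the portion-averaged spectrum is deconvolved first ([deconvolve],
#' multistart) to determine the sample's preliminary component parameters,
#' and each portion is then fitted with those parameters as the starting
#' point under strict boxes (no restarts).  Anchoring all portions in the
#' same solution makes the across-portion spread of each parameter reflect
#' portion variability rather than refitting ambiguity.  Independent
#' per-portion deconvolution is available with `anchor = "independent"`.
#'
#' @param spectra list of baseline-corrected [spectrum] objects (the
#'   portions), on a common grid.
#' @param library a [amide3_library].
#' @param constraints a [fit_constraints].
#' @param anchor `"average"` (default) or `"independent"`.
#' @param ... passed to [deconvolve].
#' @return list of class `amide3_portions`: `anchor_fit` (the average-
#'   spectrum fit, `NULL` for independent mode), `fits` (per-portion
#'   `amide3_fit`s), `mean` and `sd` (12 x parameter data.frames across
#'   portions).
#' @export
deconvolve_portions <- function(spectra, library = amide3_library(),
                                constraints = fit_constraints(),
                                anchor = c("average", "independent"), ...) {
  anchor <- match.arg(anchor)
  if (!length(spectra)) stop("no spectra")
  lapply(spectra, .assert_spectrum)
  if (anchor == "average") {
    avg <- spectra[[1]]
    avg$absorbance <- rowMeans(vapply(spectra, function(s) s$absorbance,
                                      numeric(length(avg$wavenumber))))
    avg$portion_id <- NA_integer_
    anchor_fit <- deconvolve(avg, library = library,
                             constraints = constraints, ...)
    fits <- lapply(spectra, function(s)
      suppressWarnings(fit_gaussians(s, anchor_fit$components,
                                     constraints = constraints,
                                     max_restarts = 0L)))
  } else {
    anchor_fit <- NULL
    fits <- lapply(spectra, function(s)
      suppressWarnings(deconvolve(s, library = library,
                                  constraints = constraints, ...)))
  }
  cols <- c("center", "fwhm", "area", "relative_pct")
  arr <- vapply(fits, function(f) as.matrix(f$components[, cols]),
                matrix(0, 12L, length(cols)))
  mk <- function(m) data.frame(index = fits[[1]]$components$index,
                               assignment = fits[[1]]$components$assignment,
                               m, stringsAsFactors = FALSE)
  structure(list(anchor_fit = anchor_fit, fits = fits,
                 mean = mk(apply(arr, 1:2, mean)),
                 sd = mk(apply(arr, 1:2, sd))),
            class = "amide3_portions")
}

#' @export
print.amide3_portions <- function(x, ...) {
  cat(sprintf("Portioned deconvolution: %d portions (%s-anchored)\n",
              length(x$fits), if (is.null(x$anchor_fit)) "independently"
              else "average"))
  tab <- x$mean
  tab$relative_sd <- x$sd$relative_pct
  print(transform(tab, center = round(center, 1), fwhm = round(fwhm, 1),
                  area = round(area, 2), relative_pct = round(relative_pct, 1),
                  relative_sd = round(relative_sd, 2)), row.names = FALSE)
  invisible(x)
}

# areas by linear least squares at fixed centers/FWHMs, clipped at zero
.ls_area_start <- function(x, init) {
  G <- vapply(seq_len(nrow(init)), function(k)
    gaussian_profile(init$center[k], init$fwhm[k], 1, x$wavenumber),
    numeric(length(x$wavenumber)))
  a <- tryCatch(stats::lm.fit(G, x$absorbance)$coefficients,
                error = function(e) init$area)
  a[!is.finite(a)] <- 0
  out <- init
  out$area <- pmax(as.numeric(a), 0)
  out
}

#' Relative secondary-structure content
#'
#' Percentage share of each component's integral intensity,
#' `100 * area_k / sum(area)`.
#'
#' @param x an `amide3_fit` or a numeric vector of areas.
#' @return named numeric vector of 12 percentages summing to 100.
#' @export
relative_content <- function(x) {
  areas <- if (inherits(x, "amide3_fit")) x$components$area else as.numeric(x)
  nm <- if (inherits(x, "amide3_fit")) x$components$index else names(x)
  if (all(areas == 0)) stop("relative content undefined: all areas are zero")
  setNames(100 * areas / sum(areas), nm)
}

#' Reduced chi-square fit criterion
#'
#' Residual sum of squares divided by the residual degrees of freedom
#' `N - n_par` (unit weights).
#'
#' @param observed,model numeric vectors on the same grid.
#' @param n_par number of fitted parameters (default 36, the 12-Gaussian
#'   model).
#' @return scalar.
#' @export
chi2 <- function(observed, model, n_par = 36L) {
  if (length(observed) != length(model))
    stop("observed and model must have the same length")
  if (length(observed) <= n_par)
    stop("no residual degrees of freedom: N <= n_par")
  sum((observed - model)^2) / (length(observed) - n_par)
}

# ---- methods -------------------------------------------------------------

#' @export
print.amide3_fit <- function(x, ...) {
  cat("Amide III deconvolution (12 Gaussian components)\n")
  cat(sprintf("  reduced chi-square: %.3g  iterations: %d  converged: %s\n",
              x$chi2, x$n_iter, x$converged))
  cat(sprintf("  dominant component: %s (%.1f%%)\n",
              x$components$index[which.max(x$components$area)],
              max(x$components$relative_pct)))
  invisible(x)
}

#' Summarize an Amide III deconvolution
#'
#' @param object an `amide3_fit`.
#' @param ... unused.
#' @return data.frame mirroring the conventional deconvolution table:
#'   component, assignment, center, area, relative percentage and FWHM.
#' @export
summary.amide3_fit <- function(object, ...) {
  out <- object$components[order(-match(object$components$index, ROMAN12)),
                           c("index", "assignment", "center", "area",
                             "relative_pct", "fwhm")]
  rownames(out) <- NULL
  structure(list(table = out, chi2 = object$chi2, n_iter = object$n_iter,
                 converged = object$converged),
            class = "summary.amide3_fit")
}

#' @export
print.summary.amide3_fit <- function(x, ...) {
  cat("Amide III deconvolution result\n")
  print(transform(x$table, center = round(center, 1), area = round(area, 2),
                  relative_pct = round(relative_pct, 1), fwhm = round(fwhm, 1)),
        row.names = FALSE)
  cat(sprintf("reduced chi-square %.3g (%s after %d iterations)\n", x$chi2,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' @export
coef.amide3_fit <- function(object, ...) {
  m <- as.matrix(object$components[, c("center", "fwhm", "area")])
  rownames(m) <- object$components$index
  m
}

#' @export
fitted.amide3_fit <- function(object, ...) object$fitted

#' @export
residuals.amide3_fit <- function(object, ...) object$residual

#' Evaluate a fitted deconvolution model
#'
#' @param object an `amide3_fit`.
#' @param newdata optional wavenumber vector (default: the fitted grid).
#' @param component optional Roman index (or vector) to evaluate single
#'   components instead of the full sum.
#' @param ... unused.
#' @return numeric vector, or a matrix (wavenumber x component) when
#'   several components are requested.
#' @export
predict.amide3_fit <- function(object, newdata = NULL, component = NULL, ...) {
  w <- if (is.null(newdata)) object$spectrum$wavenumber else as.numeric(newdata)
  cm <- object$components
  if (is.null(component))
    return(.model_eval(.pack(cm), w))
  k <- match(component, cm$index)
  if (anyNA(k)) stop("unknown component index")
  out <- sapply(k, function(i)
    gaussian_profile(cm$center[i], cm$fwhm[i], cm$area[i], w))
  if (length(k) == 1L) as.numeric(out) else out
}

#' @export
plot.amide3_fit <- function(x, show_components = TRUE, ...) {
  w <- x$spectrum$wavenumber
  plot(w, x$spectrum$absorbance, type = "l", col = "grey30",
       xlab = expression(Wavenumber~(cm^-1)), ylab = "Absorbance (arb.un.)",
       ...)
  lines(w, x$fitted, col = "red3", lwd = 2)
  if (show_components) {
    profs <- predict(x, component = x$components$index)
    matlines(w, profs, lty = 3, col = adjustcolor("steelblue", 0.8))
  }
  legend("topleft", bty = "n", lty = c(1, 1, 3), lwd = c(1, 2, 1),
         col = c("grey30", "red3", "steelblue"),
         legend = c("data", "fit", "components"))
  invisible(x)
}

#' Simulate replicate spectra from a fitted deconvolution
#'
#' Draws portion-style replicates from the generative model implied by the
#' fit: the fitted 12-Gaussian sum under multiplicative intensity scatter
#' and additive noise (the residual SD by default).
#'
#' @param object an `amide3_fit`.
#' @param nsim number of replicates.
#' @param seed optional integer seed.
#' @param portion_scale_sd multiplicative intensity SD (default 0.05).
#' @param noise_sd additive noise SD (default: residual SD of the fit).
#' @param ... unused.
#' @return list of [spectrum] objects.
#' @export
simulate.amide3_fit <- function(object, nsim = 1, seed = NULL,
                                portion_scale_sd = 0.05, noise_sd = NULL, ...) {
  if (is.null(noise_sd)) noise_sd <- stats::sd(object$residual)
  cfg <- synthetic_config(object$components[, c("center", "fwhm", "area")],
                          grid_min = min(object$spectrum$wavenumber),
                          grid_max = max(object$spectrum$wavenumber),
                          grid_step = .grid_step(object$spectrum$wavenumber),
                          baseline_coeffs = 0, noise_sd = noise_sd,
                          portion_scale_sd = portion_scale_sd,
                          n_portions = nsim,
                          seed = if (is.null(seed)) 1L else as.integer(seed))
  lapply(seq_len(nsim), function(p)
    synthesize_spectrum(cfg, p, sample_id = object$spectrum$sample_id))
}
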