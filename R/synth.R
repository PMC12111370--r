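# Synthetic Amide III spectra: the generative model the analysis assumes.
#
# A spectrum is a sum of 12 area-parameterized Gaussians plus a smooth
# polynomial baseline; portions of one sample share component parameters but
# differ by a multiplicative intensity factor and additive noise.

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

#' Area-parameterized Gaussian profile
#'
#' Evaluates `area * dnorm(grid, center, sigma)` with
#' `sigma = fwhm / (2 sqrt(2 ln 2))`, so the integral over an unbounded
#' grid equals `area` and the full width at half maximum equals `fwhm`.
#'
#' @param center band center, cm^-1.
#' @param fwhm full width at half maximum, cm^-1 (> 0).
#' @param area integral intensity (>= 0).
#' @param grid wavenumber vector.
#' @return absorbance vector, same length as `grid`.
#' @examples
#' g <- seq(1200, 1280, 0.5)
#' y <- gaussian_profile(1240, 13.1, 1, g)
#' # numerical area recovers the parameter
#' sum(diff(g) * (head(y, -1) + tail(y, -1)) / 2)
#' @export
gaussian_profile <- function(center, fwhm, area, grid) {
  if (length(grid) == 0L) stop("empty grid")
  if (!is.finite(fwhm) || fwhm <= 0) stop("fwhm must be positive")
  if (!is.finite(area) || area < 0) stop("area must be non-negative")
  sigma <- fwhm * FWHM_TO_SIGMA
  area * exp(-((grid - center)^2) / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
}

# sum of 12 components given a parameter data.frame (center/fwhm/area cols)
.gaussian_sum <- function(params, grid) {
  y <- numeric(length(grid))
  for (i in seq_len(nrow(params)))
    y <- y + gaussian_profile(params$center[i], params$fwhm[i],
                              params$area[i], grid)
  y
}

#' Configuration for the synthetic spectrum generator
#'
#' Bundles the generative parameters: component set, wavenumber grid,
#' baseline polynomial, portion-to-portion variability and noise.
#'
#' Defaults emulate the acquisition this model was developed for: the Amide
#' III band sampled on a 1185--1330 cm^-1 grid at 0.5 cm^-1 (finer than the
#' nominal 4 cm^-1 instrument resolution, as needed for stable derivative
#' initialization), a gently sloping linear baseline, a ~5% multiplicative
#' intensity spread between the ten portions of one sample, and additive
#' noise at 0.5% of the peak maximum.
#'
#' @param components data.frame with columns `center`, `fwhm`, `area` (12
#'   rows; e.g. from [reference_parameters]).
#' @param grid_min,grid_max,grid_step wavenumber grid, cm^-1.
#' @param baseline_coeffs polynomial coefficients (intercept first) in
#'   absorbance units; evaluated in `(wavenumber - grid_min)` to keep
#'   magnitudes interpretable.
#' @param noise_sd additive Gaussian noise SD; if `NULL` (default) it is set
#'   to 0.5% of the noiseless peak maximum.
#' @param portion_scale_sd SD of the per-portion multiplicative intensity
#'   factor (drawn from N(1, sd^2)).
#' @param n_portions portions (replicate spectra) per sample.
#' @param seed integer seed controlling all randomness of the generator.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(components,
                             grid_min = 1185, grid_max = 1330, grid_step = 0.5,
                             baseline_coeffs = c(0.02, 2e-4),
                             noise_sd = NULL,
                             portion_scale_sd = 0.05,
                             n_portions = 10L,
                             seed = 1L) {
  components <- as.data.frame(components)
  need <- c("center", "fwhm", "area")
  if (!all(need %in% names(components)))
    stop("components needs columns center, fwhm, area")
  if (nrow(components) != 12L)
    stop("exactly 12 components required, got ", nrow(components))
  if (any(components$fwhm <= 0)) stop("fwhm must be positive")
  if (any(components$area < 0)) stop("area must be non-negative")
  if (grid_step <= 0) stop("grid_step must be positive")
  if (grid_min >= grid_max) stop("grid_min must be below grid_max")
  if (n_portions < 1L) stop("n_portions must be >= 1")
  if (portion_scale_sd < 0) stop("portion_scale_sd must be >= 0")
  grid <- seq(grid_min, grid_max, by = grid_step)
  if (min(components$center) < grid_min || max(components$center) > grid_max)
    stop("grid does not cover all component centers")
  if (is.null(noise_sd)) {
    peak <- max(.gaussian_sum(components, grid))
    noise_sd <- 0.005 * peak
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(components = components[, need],
                 grid = grid, grid_step = grid_step,
                 baseline_coeffs = as.numeric(baseline_coeffs),
                 noise_sd = noise_sd, portion_scale_sd = portion_scale_sd,
                 n_portions = as.integer(n_portions), seed = as.integer(seed)),
            class = "synthetic_config")
}

.baseline_eval <- function(coeffs, grid) {
  x <- grid - grid[1]
  y <- numeric(length(grid))
  for (k in seq_along(coeffs)) y <- y + coeffs[k] * x^(k - 1)
  y
}

#' Synthesize one portion spectrum
#'
#' Draws `absorbance = scale * sum of 12 Gaussians + baseline + noise`,
#' where the multiplicative `scale` is drawn once per portion from
#' N(1, portion_scale_sd^2).  The random stream is keyed on
#' `(config$seed, portion)`, so the same configuration and portion always
#' reproduce the identical trace, independently of how many other portions
#' were generated before.
#'
#' @param config a [synthetic_config].
#' @param portion portion number (1-based).
#' @param sample_id label attached to the output.
#' @return a [spectrum].
#' @export
synthesize_spectrum <- function(config, portion = 1L, sample_id = "synthetic") {
  if (!inherits(config, "synthetic_config")) stop("expected a synthetic_config")
  portion <- as.integer(portion)
  if (portion < 1L) stop("portion must be >= 1")
  pure <- .gaussian_sum(config$components, config$grid)
  base <- .baseline_eval(config$baseline_coeffs, config$grid)
  # independent, reproducible sub-stream per portion
  rs <- .portion_stream(config$seed, portion)
  scale <- if (config$portion_scale_sd > 0)
    1 + rs$norm(1) * config$portion_scale_sd else 1
  noise <- if (config$noise_sd > 0)
    rs$norm(length(config$grid)) * config$noise_sd else 0
  spectrum(config$grid, scale * pure + base + noise,
           sample_id = sample_id, portion_id = portion)
}

# Small deterministic RNG sub-stream: re-seeds R's RNG locally from a
# (seed, key) pair without disturbing the caller's RNG state.
.portion_stream <- function(seed, key) {
  sub <- (as.numeric(seed) * 7919 + as.numeric(key) * 104729) %% 2147483647
  env <- new.env()
  env$state <- NULL
  list(norm = function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    if (is.null(env$state)) set.seed(as.integer(sub))
    else assign(".Random.seed", env$state, envir = globalenv())
    out <- rnorm(n)
    env$state <- get(".Random.seed", globalenv())
    out
  })
}

#' Noiseless reference spectrum from the published parameter table
#'
#' Builds the pure 12-Gaussian Amide III band of one of the four tabulated
#' samples (no baseline, no noise), taking the printed integral-intensity
#' percentages as areas in arbitrary units.
#'
#' @param sample_id one of `"FYHHH"`, `"FOCHH"`, `"FOCMC"`, `"FOMLG"`.
#' @param grid wavenumber vector (default 1185--1330 at 0.5 cm^-1).
#' @return a [spectrum] with `portion_id = NA`.
#' @examples
#' s <- spectrum_from_table("FOMLG")
#' plot(s)
#' @export
spectrum_from_table <- function(sample_id,
                                grid = seq(1185, 1330, by = 0.5)) {
  ref <- reference_parameters()
  if (!sample_id %in% unique(ref$sample_id))
    stop("unknown sample_id: ", sample_id)
  params <- ref[ref$sample_id == sample_id, ]
  spectrum(grid, .gaussian_sum(params, grid), sample_id = sample_id)
}

#' Generate a synthetic cohort
#'
#' Emulates the screening dataset: for each participant in `roster`, a
#' participant-specific component set is drawn by perturbing a base
#' parameter set within the library windows, then `n_portions` replicate
#' spectra are synthesized with portion-level intensity variability and
#' noise.  Optional factor-linked effects (e.g. a caries-linked shift of one
#' component's share) can be injected to create known structure.
#'
#' Perturbation model per participant: each center is jittered around the
#' base position by Gaussian noise of SD `center_jitter` and clipped to its
#' library window; each FWHM and area is jittered by independent Gaussian
#' relative noise (`param_jitter`).  Setting both jitters to zero makes all
#' participants share the base parameters exactly (useful for studying a
#' single injected effect).
#'
#' @param roster data.frame as from [cohort_roster].
#' @param base data.frame of 12 base components (`center`, `fwhm`, `area`);
#'   default the FYHHH reference set.
#' @param n_portions portions per participant (default 10).
#' @param param_jitter relative SD of FWHM/area jitter between participants.
#' @param center_jitter SD (cm^-1) of the center jitter between
#'   participants (default 0.5).
#' @param effects optional list of effects, each a list with fields
#'   `factor` (roster column), `level`, `component` (Roman index) and
#'   `shift` (additive change of that component's area, in the same units
#'   as the base areas, i.e. percentage points when areas sum to 100).
#' @param seed integer seed.
#' @param ... further arguments passed to [synthetic_config] (grid,
#'   baseline, noise_sd, portion_scale_sd).
#' @return list with `spectra` (list of [spectrum], participants x
#'   portions), `factors` (the roster) and `params` (named list of the
#'   participant-level component parameter data.frames actually drawn).
#' @examples
#' coh <- generate_cohort(cohort_roster()[1:3, ], n_portions = 2, seed = 7)
#' length(coh$spectra)
#' @export
generate_cohort <- function(roster, base = NULL, n_portions = 10L,
                            param_jitter = 0.05, center_jitter = 0.5,
                            effects = NULL, seed = 1L, ...) {
  .validate_factor_codes(roster)
  if (is.null(base)) base <- reference_parameters("FYHHH")
  lib <- amide3_library()
  spectra <- list()
  params_list <- list()
  for (i in seq_len(nrow(roster))) {
    rs <- .portion_stream(seed, 1000L + i)
    params <- base[, c("center", "fwhm", "area")]
    params$center <- pmin(pmax(base$center + center_jitter * rs$norm(12),
                               lib$window_low), lib$window_high)
    params$fwhm <- pmax(7, base$fwhm * (1 + param_jitter * rs$norm(12)))
    params$area <- pmax(0, base$area * (1 + param_jitter * rs$norm(12)))
    if (!is.null(effects)) {
      for (ef in effects) {
        if (roster[[ef$factor]][i] == ef$level) {
          k <- match(ef$component, ROMAN12)
          params$area[k] <- max(0, params$area[k] + ef$shift)
        }
      }
    }
    cfg <- synthetic_config(params, seed = seed + 13L * i,
                            n_portions = n_portions, ...)
    for (p in seq_len(n_portions)) {
      spectra[[length(spectra) + 1L]] <-
        synthesize_spectrum(cfg, p, sample_id = roster$subject[i])
    }
    params_list[[roster$subject[i]]] <- params
  }
  list(spectra = spectra, factors = roster, params = params_list)
}
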