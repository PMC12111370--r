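# shared fixtures: grids, phantoms and summary-exact vectors

amide3_grid <- function(step = 0.5) seq(1185, 1330, by = step)

trapz <- function(x, y) sum((head(y, -1) + tail(y, -1)) * diff(x)) / 2

# a vector with exactly the requested mean and (sample) sd
vector_with_summary <- function(mean, sd, n) {
  z <- as.numeric(scale(seq_len(n)))
  mean + sd * z
}

# noiseless phantom: polynomial baseline + one Gaussian
phantom_spectrum <- function(center = 1250, fwhm = 12, area = 1,
                             base_coef = c(0.05, 2e-4), grid = amide3_grid()) {
  y <- base_coef[1] + base_coef[2] * (grid - grid[1]) +
    gaussian_profile(center, fwhm, area, grid)
  spectrum(grid, y, sample_id = "phantom")
}

# the four reference sample ids
REF_SAMPLES <- c("FYHHH", "FOCHH", "FOCMC", "FOMLG")
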