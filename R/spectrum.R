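# Spectrum container and CSV input/output.

#' Construct a spectrum
#'
#' A spectrum is a wavenumber/absorbance pair with sample and portion
#' identity.  Wavenumbers are canonicalized to strictly ascending order at
#' construction (instrument exports are often descending).
#'
#' @param wavenumber numeric vector, cm^-1.
#' @param absorbance numeric vector, arbitrary units, same length.
#' @param sample_id,portion_id identity labels.
#' @return object of class `spectrum`: list with fields `wavenumber`,
#'   `absorbance`, `sample_id`, `portion_id`.
#' @examples
#' s <- spectrum(seq(1200, 1300, 2), rnorm(51), "demo", 1L)
#' print(s)
#' @export
spectrum <- function(wavenumber, absorbance, sample_id = NA_character_,
                     portion_id = NA_integer_) {
  wavenumber <- as.numeric(wavenumber)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumber) != length(absorbance))
    stop("wavenumber and absorbance must have the same length")
  if (length(wavenumber) == 0L) stop("empty spectrum")
  if (!all(is.finite(wavenumber)) || !all(is.finite(absorbance)))
    stop("spectrum contains non-finite values")
  if (anyDuplicated(wavenumber))
    stop("duplicate wavenumbers in spectrum")
  ord <- order(wavenumber)
  out <- structure(
    list(wavenumber = wavenumber[ord], absorbance = absorbance[ord],
         sample_id = as.character(sample_id),
         portion_id = portion_id),
    class = "spectrum")
  out
}

is_spectrum <- function(x) inherits(x, "spectrum")

.assert_spectrum <- function(x) {
  if (!is_spectrum(x)) stop("expected a 'spectrum' object")
  invisible(x)
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("FTIR spectrum '%s'%s: %d points, %.1f-%.1f cm^-1\n",
              x$sample_id,
              if (!is.na(x$portion_id)) sprintf(" portion %s", x$portion_id) else "",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}

#' @export
as.data.frame.spectrum <- function(x, ...) {
  data.frame(wavenumber = x$wavenumber, absorbance = x$absorbance)
}

#' @export
plot.spectrum <- function(x, ..., xlab = expression(Wavenumber~(cm^-1)),
                          ylab = "Absorbance (arb.un.)", type = "l") {
  plot(x$wavenumber, x$absorbance, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

# grid step of a (uniform) spectrum; tolerates tiny float jitter
.grid_step <- function(w) {
  d <- diff(w)
  if (length(d) == 0L) return(NA_real_)
  if (max(d) - min(d) > 1e-6 * max(abs(d)))
    warning("wavenumber grid is not uniform; using median step")
  median(d)
}

#' Read a spectrum from a two-column CSV file
#'
#' Expects columns wavenumber, absorbance (header optional; non-numeric
#' first line is treated as a header).  Descending wavenumber order is
#' canonicalized to ascending.  Sample and portion identity are taken from
#' a `<sample>_<portion>.csv` filename pattern when present.
#'
#' @param path file path.
#' @return a [spectrum].
#' @seealso [write_spectrum]
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- {
    fields <- strsplit(first, ",", fixed = TRUE)[[1]]
    suppressWarnings(any(is.na(as.numeric(fields[1:min(2, length(fields))]))))
  }
  dat <- utils::read.csv(path, header = has_header,
                         col.names = c("wavenumber", "absorbance"),
                         colClasses = "character")
  w <- suppressWarnings(as.numeric(dat$wavenumber))
  a <- suppressWarnings(as.numeric(dat$absorbance))
  bad <- which(is.na(w) | is.na(a))
  if (length(bad))
    stop(sprintf("non-numeric value in %s at data line %d", path, bad[1]))
  if (anyDuplicated(w)) {
    dup <- w[duplicated(w)][1]
    stop(sprintf("duplicate wavenumber %.6g in %s (line %d)", dup, path,
                 which(w == dup)[2]))
  }
  base <- sub("\\.[^.]+$", "", basename(path))
  parts <- strsplit(base, "_", fixed = TRUE)[[1]]
  sample_id <- parts[1]
  portion_id <- if (length(parts) > 1)
    suppressWarnings(as.integer(parts[length(parts)])) else NA_integer_
  spectrum(w, a, sample_id = sample_id, portion_id = portion_id)
}

#' Write a spectrum as a two-column CSV file
#'
#' @param x a [spectrum].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(x, path) {
  .assert_spectrum(x)
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

# trapezoid integral
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
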