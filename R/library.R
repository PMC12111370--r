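# Component library for the Amide III band and the published reference
# parameter sets used throughout the package and its test-suite.

ROMAN12 <- c("I", "II", "III", "IV", "V", "VI",
             "VII", "VIII", "IX", "X", "XI", "XII")

STRUCTURE_CLASSES <- c("beta-sheet", "random coil", "beta-turn", "alpha-helix")

#' Amide III twelve-component library
#'
#' The fixed decomposition model for the Amide III band: twelve Gaussian
#' components, each confined to a literature wavenumber window and assigned
#' to a protein secondary-structure class.  Components I--V are beta-sheet,
#' VI--VII random coil, VIII--IX beta-turn and X--XII alpha-helix.
#'
#' The window bounds are literature consensus ranges for the sub-band
#' positions; measured band centers occasionally fall a fraction of a
#' wavenumber outside them, which is why the peak-matching step of
#' [initialize_peaks] admits candidates within `window_pad` of a window.
#'
#' @param fwhm_box numeric length-2, allowed full width at half maximum
#'   (cm^-1) for every component.  The default `c(7, 19)` accommodates the
#'   widths observed in practice; the strict `c(7, 10)` preset used by some
#'   deconvolution protocols can be requested instead (see
#'   [fit_constraints]).
#' @return A data.frame of class `component_library` with one row per
#'   component: `index` (Roman numeral, I at the low-wavenumber end),
#'   `assignment` (structure class), `window_low`, `window_high` and
#'   `midpoint` (cm^-1), plus the `fwhm_box` attribute.
#' @examples
#' amide3_library()
#' @export
amide3_library <- function(fwhm_box = c(7, 19)) {
  stopifnot(length(fwhm_box) == 2, fwhm_box[1] > 0, fwhm_box[2] > fwhm_box[1])
  lib <- data.frame(
    index = ROMAN12,
    assignment = c(rep("beta-sheet", 5), rep("random coil", 2),
                   rep("beta-turn", 2), rep("alpha-helix", 3)),
    window_low  = c(1194.5, 1203.5, 1214.0, 1224.5, 1238.5, 1251.0,
                    1261.5, 1270.0, 1283.0, 1298.0, 1308.8, 1317.0),
    window_high = c(1196.5, 1206.0, 1218.0, 1230.0, 1242.0, 1254.0,
                    1264.0, 1273.0, 1285.0, 1299.0, 1311.0, 1318.5),
    stringsAsFactors = FALSE
  )
  lib$midpoint <- (lib$window_low + lib$window_high) / 2
  attr(lib, "fwhm_box") <- fwhm_box
  class(lib) <- c("component_library", "data.frame")
  lib
}

#' Published Amide III deconvolution parameters for four reference samples
#'
#' Fitted Gaussian parameters (band center, integral-intensity share and
#' FWHM, each with its across-portion spread) for the Amide III band of four
#' GCF samples spanning healthy, caries and periodontitis conditions.  The
#' intensity shares are percentages summing to ~100 per sample and are used
#' directly as areas when synthesizing reference spectra
#' ([spectrum_from_table]): downstream analysis only ever uses relative
#' content, so the absolute scale is immaterial.
#'
#' @param sample_id one of `"FYHHH"`, `"FOCHH"`, `"FOCMC"`, `"FOMLG"`, or
#'   `NULL` (default) for all four.
#' @return A data.frame with columns `sample_id`, `index`, `assignment`,
#'   `center`, `center_sd`, `area`, `area_sd`, `fwhm`, `fwhm_sd` ordered
#'   component I to XII within sample.
#' @examples
#' head(reference_parameters("FOMLG"))
#' @export
reference_parameters <- function(sample_id = NULL) {
  ref <- .reference_table()
  if (!is.null(sample_id)) {
    sample_id <- match.arg(sample_id, unique(ref$sample_id))
    ref <- ref[ref$sample_id == sample_id, , drop = FALSE]
    rownames(ref) <- NULL
  }
  ref
}

# Values are stored component XII down to I per sample (the order the
# deconvolution is conventionally tabulated in) and re-sorted I..XII.
.reference_table <- function() {
  col <- function(sample_id, center, center_sd, area, area_sd, fwhm, fwhm_sd) {
    data.frame(sample_id = sample_id, index = rev(ROMAN12),
               center = center, center_sd = center_sd,
               area = area, area_sd = area_sd,
               fwhm = fwhm, fwhm_sd = fwhm_sd,
               stringsAsFactors = FALSE)
  }
  ref <- rbind(
    col("FYHHH",
        center = c(1317.3, 1309.2, 1299.0, 1285.0, 1273.0, 1264.2,
                   1253.9, 1242.1, 1230.0, 1218.1, 1205.3, 1195.0),
        center_sd = c(0.7, 0.6, 0.7, 0.9, 0.8, 0.7, 0.8, 0.9, 0.7, 0.9, 0.8, 0.9),
        area = c(3.7, 3.4, 2.1, 2.2, 4.2, 9.3, 21.9, 21.0, 16.8, 10.8, 4.3, 0.3),
        area_sd = c(0.60, 0.30, 0.30, 0.30, 0.60, 1.51, 2.72, 2.12, 0.91, 0.60, 0.30, 0.30),
        fwhm = c(7.4, 14.3, 15.7, 16.0, 16.0, 16.0, 13.3, 13.1, 14.0, 12.7, 11.1, 11.0),
        fwhm_sd = c(0.5, 0.4, 0.5, 0.6, 0.5, 0.4, 0.5, 0.5, 0.6, 0.5, 0.6, 0.7)),
    col("FOCHH",
        center = c(1318.4, 1310.9, 1298.1, 1283.9, 1270.8, 1261.5,
                   1251.0, 1239.5, 1226.2, 1215.0, 1203.4, 1194.5),
        center_sd = c(0.9, 0.9, 0.6, 1.0, 0.9, 0.7, 1.0, 0.6, 0.8, 1.0, 1.0, 0.7),
        area = c(3.8, 4.0, 2.5, 3.1, 4.5, 8.0, 13.4, 28.4, 19.0, 9.1, 3.7, 0.6),
        area_sd = c(0.35, 1.05, 0.35, 0.35, 0.70, 1.74, 1.39, 2.09, 1.39, 0.35, 0.35, 0.35),
        fwhm = c(9.2, 13.7, 15.3, 16.8, 18.0, 15.4, 14.2, 13.9, 15.2, 14.0, 11.3, 9.8),
        fwhm_sd = c(0.3, 0.5, 0.6, 0.5, 0.5, 0.5, 0.7, 0.4, 0.5, 0.3, 0.7, 0.5)),
    col("FOCMC",
        center = c(1317.0, 1308.8, 1298.0, 1284.0, 1273.0, 1262.0,
                   1251.5, 1240.0, 1228.4, 1218.0, 1206.0, 1196.0),
        center_sd = c(0.9, 0.7, 0.7, 0.6, 0.6, 0.8, 0.6, 1.1, 0.7, 0.6, 0.9, 0.8),
        area = c(1.4, 3.0, 4.6, 4.5, 4.6, 10.6, 12.8, 26.4, 14.6, 12.5, 4.9, 0.3),
        area_sd = c(0.15, 0.31, 0.76, 0.61, 0.76, 1.22, 1.53, 3.06, 1.22, 0.61, 0.31, 0.15),
        fwhm = c(8.0, 15.0, 16.0, 15.5, 18.0, 15.6, 16.3, 14.8, 16.0, 16.0, 12.9, 10.5),
        fwhm_sd = c(0.4, 0.3, 0.3, 0.7, 0.6, 0.6, 0.6, 0.3, 0.6, 0.5, 0.4, 0.6)),
    col("FOMLG",
        center = c(1317.5, 1309.8, 1298.6, 1283.0, 1269.9, 1261.8,
                   1251.0, 1238.5, 1224.7, 1213.8, 1203.5, 1196.4),
        center_sd = c(0.8, 0.8, 0.6, 1.1, 0.6, 0.9, 0.9, 0.7, 0.6, 0.8, 1.1, 0.8),
        area = c(3.6, 3.5, 2.1, 1.6, 4.5, 6.0, 17.8, 30.2, 19.9, 7.2, 3.1, 0.5),
        area_sd = c(0.68, 0.34, 0.34, 0.34, 0.68, 0.68, 1.36, 1.70, 1.36, 0.68, 0.34, 0.34),
        fwhm = c(8.1, 13.0, 13.9, 16.5, 18.0, 16.4, 13.0, 13.4, 14.3, 14.2, 10.4, 9.6),
        fwhm_sd = c(0.4, 0.6, 0.6, 0.4, 0.5, 0.6, 0.7, 0.5, 0.6, 0.4, 0.3, 0.5))
  )
  lib <- amide3_library()
  ref$assignment <- lib$assignment[match(ref$index, lib$index)]
  ref <- ref[order(match(ref$sample_id, c("FYHHH", "FOCHH", "FOCMC", "FOMLG")),
                   match(ref$index, ROMAN12)), ]
  rownames(ref) <- NULL
  ref[, c("sample_id", "index", "assignment", "center", "center_sd",
          "area", "area_sd", "fwhm", "fwhm_sd")]
}

#' Study cohort roster
#'
#' The 17-participant cohort used for screening.  Each participant carries a
#' five-letter code whose positions encode gender (F/M), age group (Y
#' younger / O older), caries status (H healthy, C initial, M multiple),
#' periodontal status (H healthy, L mild periodontitis, M moderate
#' periodontitis) and comorbidity (H healthy, G gastrointestinal,
#' C oncological, M multiple pathologies).  Codes are not unique (several
#' participants share a clinical profile), so a unique `subject` id is added.
#'
#' @return data.frame with columns `subject`, `participant_id`, `gender`,
#'   `age`, `caries`, `periodontal`, `comorbidity`.
#' @examples
#' table(cohort_roster()$caries)
#' @export
cohort_roster <- function() {
  ids <- c("FYHHH", "FYCHH", "FYCHH", "FOCHH", "MYCLG", "MOCLH", "FOCMC",
           "FYCHG", "MYCLH", "FYCHM", "FOMLG", "MOMLG", "FOMHC", "FOMLM",
           "FOMLG", "FYMLM", "FYCHH")
  subject <- make.unique(ids, sep = "_")
  out <- data.frame(
    subject = subject,
    participant_id = ids,
    gender      = substr(ids, 1, 1),
    age         = substr(ids, 2, 2),
    caries      = substr(ids, 3, 3),
    periodontal = substr(ids, 4, 4),
    comorbidity = substr(ids, 5, 5),
    stringsAsFactors = FALSE
  )
  .validate_factor_codes(out)
  out
}

.validate_factor_codes <- function(factors) {
  chk <- list(gender = c("F", "M"), age = c("Y", "O"),
              caries = c("H", "C", "M"), periodontal = c("H", "L", "M"),
              comorbidity = c("H", "G", "C", "M"))
  for (nm in names(chk)) {
    bad <- setdiff(unique(factors[[nm]]), chk[[nm]])
    if (length(bad))
      stop(sprintf("invalid %s code(s): %s", nm, paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}

#' @export
print.component_library <- function(x, ...) {
  cat("Amide III component library (12 Gaussian components)\n")
  cat(sprintf("FWHM box: %.1f-%.1f cm^-1\n\n", attr(x, "fwhm_box")[1],
              attr(x, "fwhm_box")[2]))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
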