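# Aggregation of fitted components into secondary-structure class totals.

#' Secondary-structure class totals
#'
#' Sums fitted integral intensities and relative percentages over the four
#' structure classes (components I--V beta-sheet, VI--VII random coil,
#' VIII--IX beta-turn, X--XII alpha-helix).
#'
#' @param x an `amide3_fit`, or a data.frame with columns `assignment`,
#'   `area` (and optionally `relative_pct`).
#' @return data.frame with one row per class: `assignment`, `area_total`,
#'   `pct_total`.
#' @examples
#' fit <- deconvolve(spectrum_from_table("FYHHH"))
#' class_totals(fit)
#' @export
class_totals <- function(x) {
  comps <- if (inherits(x, "amide3_fit")) x$components else as.data.frame(x)
  if (!all(c("assignment", "area") %in% names(comps)))
    stop("need columns assignment and area")
  bad <- setdiff(unique(comps$assignment), STRUCTURE_CLASSES)
  if (length(bad))
    stop("unknown assignment label(s): ", paste(bad, collapse = ", "))
  if (is.null(comps$relative_pct)) {
    tot <- sum(comps$area)
    comps$relative_pct <- if (tot > 0) 100 * comps$area / tot else NA_real_
  }
  out <- data.frame(assignment = STRUCTURE_CLASSES, stringsAsFactors = FALSE)
  out$area_total <- vapply(out$assignment, function(cl)
    sum(comps$area[comps$assignment == cl]), numeric(1))
  out$pct_total <- vapply(out$assignment, function(cl)
    sum(comps$relative_pct[comps$assignment == cl]), numeric(1))
  rownames(out) <- NULL
  out
}
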