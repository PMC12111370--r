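# Stage-2 pairwise comparison of deconvolution outputs: two-sample t-tests
# from summary statistics with Bonferroni correction.

#' Two-sample t-test from summary statistics
#'
#' Welch (default) or pooled-variance two-sample t-test computed from
#' means, standard deviations and sizes, with a two-sided p-value and a
#' confidence interval for the mean difference -- numerically identical to
#' running `t.test` on raw vectors with those summaries.
#'
#' Degenerate input (both SDs zero): equal means are reported as
#' no-difference (`t = NA`, `p = 1`); unequal means as an exact difference
#' (`t = +/-Inf`, `p = 0`).
#'
#' @param mean_x,sd_x,n_x summary of the first sample (`n_x >= 2`).
#' @param mean_y,sd_y,n_y summary of the second sample.
#' @param var_equal pool the variances (default `FALSE`, Welch).
#' @param conf_level confidence level (default 0.95).
#' @return list of class `tsum_test`: `statistic` (t), `df`, `p.value`,
#'   `conf.int`, `estimate` (mean difference x - y), `method`.
#' @examples
#' tsum_test(10, 2, 10, 12, 2, 10, var_equal = TRUE)
#' @export
tsum_test <- function(mean_x, sd_x, n_x, mean_y, sd_y, n_y,
                      var_equal = FALSE, conf_level = 0.95) {
  if (n_x < 2 || n_y < 2) stop("each sample needs n >= 2")
  if (sd_x < 0 || sd_y < 0) stop("standard deviations must be >= 0")
  diff <- mean_x - mean_y
  if (sd_x == 0 && sd_y == 0) {
    if (diff == 0) {
      out <- list(statistic = NA_real_, df = n_x + n_y - 2, p.value = 1,
                  conf.int = c(0, 0), estimate = 0,
                  method = "degenerate (no variance, no difference)")
    } else {
      out <- list(statistic = sign(diff) * Inf, df = n_x + n_y - 2,
                  p.value = 0, conf.int = c(diff, diff), estimate = diff,
                  method = "degenerate (no variance)")
    }
    class(out) <- "tsum_test"
    return(out)
  }
  if (var_equal) {
    df <- n_x + n_y - 2
    sp2 <- ((n_x - 1) * sd_x^2 + (n_y - 1) * sd_y^2) / df
    se <- sqrt(sp2 * (1 / n_x + 1 / n_y))
    method <- "pooled-variance two-sample t-test from summaries"
  } else {
    vx <- sd_x^2 / n_x; vy <- sd_y^2 / n_y
    se <- sqrt(vx + vy)
    df <- (vx + vy)^2 / (vx^2 / (n_x - 1) + vy^2 / (n_y - 1))
    method <- "Welch two-sample t-test from summaries"
  }
  t <- diff / se
  p <- 2 * pt(-abs(t), df)
  half <- qt(1 - (1 - conf_level) / 2, df) * se
  out <- list(statistic = t, df = df, p.value = p,
              conf.int = c(diff - half, diff + half), estimate = diff,
              method = method)
  class(out) <- "tsum_test"
  out
}

#' @export
print.tsum_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("t = %.4g, df = %.4g, p = %.4g\n", x$statistic, x$df, x$p.value))
  cat(sprintf("mean difference %.4g, CI [%.4g, %.4g]\n", x$estimate,
              x$conf.int[1], x$conf.int[2]))
  invisible(x)
}

# per-portion component measures from portioned results, a list of fits,
# or a plain matrix of areas
.portion_matrix <- function(res, measure) {
  if (inherits(res, "amide3_portions")) res <- res$fits
  if (is.matrix(res)) {
    if (ncol(res) != 12L) stop("portion matrix must have 12 columns")
    m <- res
    if (measure == "relative_pct") m <- t(apply(m, 1, function(a) 100 * a / sum(a)))
    colnames(m) <- ROMAN12
    return(m)
  }
  if (is.list(res) && all(vapply(res, inherits, logical(1), "amide3_fit"))) {
    idx <- res[[1]]$components$index
    for (r in res)
      if (!identical(r$components$index, idx))
        stop("portion fits use different component libraries")
    col <- if (measure == "area") "area" else "relative_pct"
    m <- do.call(rbind, lapply(res, function(r) r$components[[col]]))
    colnames(m) <- idx
    return(m)
  }
  stop("expected a list of amide3_fit objects or a portions x 12 area matrix")
}

#' Pairwise comparison of two samples' deconvolution results
#'
#' For every component (I--XII) and measure (integral intensity and/or
#' relative percentage), summarizes the per-portion values of each sample
#' (mean, SD, n), applies [tsum_test] and flags Bonferroni-significant
#' differences.
#'
#' The Bonferroni family size is `m = n_comparisons * 12 components *
#' number of measures` under the default `family = "run"` policy, where
#' `n_comparisons` is the number of sample pairs in the analysis run (1 if
#' this is the only comparison).  `family = "per_comparison"` corrects only
#' over this pair's own tests.
#'
#' @param res_a,res_b per-portion deconvolution results for the two
#'   samples: `amide3_portions` objects (see [deconvolve_portions]), lists
#'   of `amide3_fit` objects, or portions x 12 matrices of component areas.
#' @param alpha family-wise significance level (default 0.05).
#' @param measures subset of `c("area", "relative_pct")`.
#' @param var_equal pooled-variance t (default `FALSE`, Welch).
#' @param family Bonferroni family policy (see Details).
#' @param n_comparisons number of sample pairs in the run (used by
#'   `family = "run"`).
#' @return data.frame of class `group_comparison`: `component`, `measure`,
#'   `mean_a`, `sd_a`, `mean_b`, `sd_b`, `diff` (a - b), `t`, `df`,
#'   `p_raw`, `p_adj` (`min(1, m * p_raw)`), `significant`; attributes
#'   `m`, `alpha`.
#' @examples
#' a <- matrix(rnorm(120, rep(reference_parameters("FYHHH")$area, each = 10),
#'                   0.3), 10, 12)
#' b <- matrix(rnorm(120, rep(reference_parameters("FOMLG")$area, each = 10),
#'                   0.3), 10, 12)
#' compare_samples(a, b)
#' @export
compare_samples <- function(res_a, res_b, alpha = 0.05,
                            measures = c("area", "relative_pct"),
                            var_equal = FALSE,
                            family = c("run", "per_comparison"),
                            n_comparisons = 1L) {
  family <- match.arg(family)
  measures <- match.arg(measures, several.ok = TRUE)
  m_family <- 12L * length(measures) *
    (if (family == "run") as.integer(n_comparisons) else 1L)
  rows <- NULL
  for (ms in measures) {
    A <- .portion_matrix(res_a, ms)
    B <- .portion_matrix(res_b, ms)
    if (nrow(A) < 2L || nrow(B) < 2L) stop("need >= 2 portions per sample")
    for (k in seq_len(12L)) {
      tt <- tsum_test(mean(A[, k]), sd(A[, k]), nrow(A),
                      mean(B[, k]), sd(B[, k]), nrow(B),
                      var_equal = var_equal)
      rows <- rbind(rows, data.frame(
        component = ROMAN12[k], measure = ms,
        mean_a = mean(A[, k]), sd_a = sd(A[, k]),
        mean_b = mean(B[, k]), sd_b = sd(B[, k]),
        diff = tt$estimate, t = tt$statistic, df = tt$df,
        p_raw = tt$p.value, stringsAsFactors = FALSE))
    }
  }
  rows$p_adj <- pmin(1, m_family * rows$p_raw)
  rows$significant <- rows$p_adj < alpha
  attr(rows, "m") <- m_family
  attr(rows, "alpha") <- alpha
  class(rows) <- c("group_comparison", "data.frame")
  rows
}

#' @export
print.group_comparison <- function(x, significant_only = TRUE, ...) {
  cat(sprintf("Pairwise comparison (Bonferroni family m = %d, alpha = %g)\n",
              attr(x, "m"), attr(x, "alpha")))
  y <- as.data.frame(x)
  if (significant_only) {
    y <- y[y$significant, , drop = FALSE]
    if (!nrow(y)) {
      cat("no significant differences\n")
      return(invisible(x))
    }
    cat("significant differences only:\n")
  }
  print(transform(y, diff = round(diff, 3), t = round(t, 2),
                  df = round(df, 1), p_raw = signif(p_raw, 3),
                  p_adj = signif(p_adj, 3)), row.names = FALSE)
  invisible(x)
}

#' Compare all sample pairs of a deconvolution set
#'
#' Runs [compare_samples] on every pair of samples, with the Bonferroni
#' family sized over the whole run (pairs x components x measures).
#'
#' @param results named list: per sample, the per-portion results accepted
#'   by [compare_samples].
#' @param pairs optional 2-column matrix/data.frame of sample names;
#'   default all unordered pairs.
#' @param ... passed to [compare_samples].
#' @return named list of `group_comparison` tables ("A_vs_B").
#' @export
compare_pairs <- function(results, pairs = NULL, ...) {
  nms <- names(results)
  if (is.null(nms)) stop("results must be a named list")
  if (is.null(pairs)) {
    pairs <- t(utils::combn(nms, 2))
  } else {
    pairs <- as.matrix(pairs)
  }
  out <- lapply(seq_len(nrow(pairs)), function(i)
    compare_samples(results[[pairs[i, 1]]], results[[pairs[i, 2]]],
                    n_comparisons = nrow(pairs), ...))
  names(out) <- paste(pairs[, 1], pairs[, 2], sep = "_vs_")
  out
}
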