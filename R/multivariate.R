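# Stage-1 screening: PCA of the spectral matrix and statistical description
# of the principal components by categorical clinical factors.

#' Assemble a spectral matrix
#'
#' Arranges spectra into the samples x wavenumbers matrix used for PCA:
#' one row per sample (portions averaged, the default) or one row per
#' portion, restricted to the analysis band.
#'
#' @param spectra list of [spectrum] objects on a common grid.
#' @param band length-2 wavenumber window (default the Amide III band).
#' @param average_portions average the portions of each sample into one row
#'   (default `TRUE`).
#' @param factors optional data.frame of per-sample metadata with a column
#'   matching the sample ids (`subject` or `sample_id`); carried through
#'   aligned to the rows.
#' @return list of class `spectral_matrix`: `x` (matrix, rownames = sample
#'   or sample.portion ids), `wavenumber`, `sample_id`, `factors`.
#' @export
build_matrix <- function(spectra, band = c(1185, 1330),
                         average_portions = TRUE, factors = NULL) {
  if (!length(spectra)) stop("no spectra")
  spectra <- lapply(spectra, function(s) crop_band(s, band[1], band[2]))
  w <- spectra[[1]]$wavenumber
  same <- vapply(spectra, function(s)
    length(s$wavenumber) == length(w) && all(abs(s$wavenumber - w) < 1e-8),
    logical(1))
  if (!all(same)) stop("spectra are not on a common wavenumber grid")
  ids <- vapply(spectra, function(s) s$sample_id, character(1))
  X <- do.call(rbind, lapply(spectra, function(s) s$absorbance))
  if (average_portions) {
    groups <- unique(ids)
    X <- do.call(rbind, lapply(groups, function(g)
      colMeans(X[ids == g, , drop = FALSE])))
    rownames(X) <- groups
    row_id <- groups
  } else {
    portions <- vapply(spectra, function(s)
      as.character(s$portion_id), character(1))
    rownames(X) <- make.unique(paste(ids, portions, sep = "."))
    row_id <- ids
  }
  colnames(X) <- sprintf("%.6g", w)
  if (!is.null(factors)) {
    key <- intersect(c("subject", "sample_id", "participant_id"), names(factors))
    if (!length(key)) stop("factors must carry a subject/sample_id column")
    m <- match(row_id, factors[[key[1]]])
    if (anyNA(m)) stop("factors do not cover all samples")
    factors <- factors[m, , drop = FALSE]
    rownames(factors) <- NULL
  }
  structure(list(x = X, wavenumber = w, sample_id = row_id, factors = factors),
            class = "spectral_matrix")
}

#' Principal component analysis of a spectral matrix
#'
#' Singular-value decomposition of the centered (and, by default,
#' unit-variance scaled) matrix.  Scaling to unit variance makes the
#' eigenvalues correlation-matrix eigenvalues, the scale on which the
#' Kaiser criterion is defined.
#'
#' @param x a `spectral_matrix` or a plain numeric matrix (rows = samples).
#' @param scale_unit scale columns to unit variance (default `TRUE`).
#' @return object of class `amide3_pca`: `eigenvalues`, `explained_pct`,
#'   `cumulative_pct`, `scores` (samples x PCs, centered), `loadings`
#'   (variables x PCs), `center`, `scale`, `scaled`, `dropped`
#'   (zero-variance columns removed before scaling), `factors`.
#' @examples
#' m <- matrix(rnorm(40), 8, 5)
#' p <- run_pca(m)
#' sum(p$explained_pct)
#' @export
run_pca <- function(x, scale_unit = TRUE) {
  factors <- NULL
  if (inherits(x, "spectral_matrix")) { factors <- x$factors; x <- x$x }
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows for PCA")
  dropped <- character(0)
  if (scale_unit) {
    v <- apply(x, 2, var)
    zero <- v <= .Machine$double.eps * max(v, 1)
    if (any(zero)) {
      dropped <- colnames(x)[zero]
      warning(sprintf("dropping %d zero-variance column(s) before scaling",
                      sum(zero)))
      x <- x[, !zero, drop = FALSE]
    }
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = scale_unit)
  eig <- pc$sdev^2
  structure(list(eigenvalues = eig,
                 explained_pct = 100 * eig / sum(eig),
                 cumulative_pct = cumsum(100 * eig / sum(eig)),
                 scores = pc$x, loadings = pc$rotation,
                 center = pc$center,
                 scale = if (scale_unit) pc$scale else NULL,
                 scaled = scale_unit, dropped = dropped,
                 factors = factors),
            class = "amide3_pca")
}

#' @export
print.amide3_pca <- function(x, n = 5L, ...) {
  k <- min(n, length(x$eigenvalues))
  cat(sprintf("PCA of a %d x %d spectral matrix (%s)\n", nrow(x$scores),
              nrow(x$loadings), if (x$scaled) "correlation" else "covariance"))
  print(round(data.frame(PC = seq_len(k), eigenvalue = x$eigenvalues[1:k],
                         explained_pct = x$explained_pct[1:k],
                         cumulative_pct = x$cumulative_pct[1:k]), 3),
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.amide3_pca <- function(object, ...) {
  data.frame(PC = seq_along(object$eigenvalues),
             eigenvalue = object$eigenvalues,
             explained_pct = object$explained_pct,
             cumulative_pct = object$cumulative_pct)
}

#' @export
plot.amide3_pca <- function(x, type = c("scree", "scores"), n_pcs = 2, ...) {
  type <- match.arg(type)
  if (type == "scree") {
    k <- seq_along(x$eigenvalues)
    plot(k, x$explained_pct, type = "b", xlab = "Principal component",
         ylab = "Explained variance (%)", ...)
  } else {
    plot(x$scores[, 1], x$scores[, 2],
         xlab = sprintf("PC1 (%.1f%%)", x$explained_pct[1]),
         ylab = sprintf("PC2 (%.1f%%)", x$explained_pct[2]), ...)
  }
  invisible(x)
}

#' Project new spectra onto fitted principal components
#'
#' @param object an `amide3_pca`.
#' @param newdata matrix (rows = samples) on the same variable set.
#' @param ... unused.
#' @return score matrix.
#' @export
predict.amide3_pca <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  x <- sweep(newdata, 2, object$center)
  if (object$scaled) x <- sweep(x, 2, object$scale, "/")
  x %*% object$loadings
}

#' Kaiser component retention
#'
#' Number of correlation-matrix eigenvalues exceeding 1.
#'
#' @param eigenvalues numeric vector (from [run_pca] with
#'   `scale_unit = TRUE`).
#' @param scale_unit flag stating the scale of the supplied eigenvalues; a
#'   warning is raised when they are covariance eigenvalues, where the
#'   criterion is not defined.
#' @return integer count; 0 (with a warning suggesting the elbow rule)
#'   when no eigenvalue exceeds 1.
#' @export
kaiser_retain <- function(eigenvalues, scale_unit = TRUE) {
  if (!scale_unit)
    warning("Kaiser criterion applies to correlation-matrix eigenvalues")
  k <- sum(eigenvalues > 1)
  if (k == 0L)
    warning("no eigenvalue exceeds 1; fall back to the elbow rule")
  as.integer(k)
}

#' Elbow-rule component retention
#'
#' Retains components up to the sharpest proportional drop in explained
#' variance (the scree-plot elbow).
#'
#' @param explained_pct explained-variance percentages, decreasing.
#' @return integer count.
#' @export
elbow_retain <- function(explained_pct) {
  if (length(explained_pct) < 2L) return(length(explained_pct))
  rel_drop <- -diff(explained_pct) / head(explained_pct, -1L)
  which.max(rel_drop)
}

#' Describe principal components by categorical factors
#'
#' For every (PC, factor) pair, a one-way ANOVA of the scores on the factor
#' (F statistic, R^2 = between-group / total sum of squares, p-value), and
#' for every factor level the estimate (level mean score minus grand mean)
#' with a t-test of that contrast against the ANOVA residual variance --
#' the construction that remains defined even for single-observation
#' levels.
#'
#' @param pca an `amide3_pca` (or a score matrix).
#' @param factors data.frame of categorical variables aligned with the
#'   score rows; non-factor id columns (`subject`, `sample_id`,
#'   `participant_id`) are ignored.
#' @param n_pcs how many leading PCs to describe (default: Kaiser count,
#'   minimum 2).
#' @return object of class `factor_association`: `anova` (pc, factor, F,
#'   r2, p) and `levels` (pc, factor, level, n, estimate, t, p).
#' @export
describe_dimension <- function(pca, factors, n_pcs = NULL) {
  scores <- if (inherits(pca, "amide3_pca")) pca$scores else as.matrix(pca)
  if (is.null(factors) && inherits(pca, "amide3_pca")) factors <- pca$factors
  factors <- as.data.frame(factors)
  factors <- factors[, setdiff(names(factors),
                               c("subject", "sample_id", "participant_id")),
                     drop = FALSE]
  if (nrow(factors) != nrow(scores))
    stop("factors and scores have different numbers of rows")
  if (is.null(n_pcs)) {
    n_pcs <- if (inherits(pca, "amide3_pca"))
      max(2L, suppressWarnings(kaiser_retain(pca$eigenvalues, pca$scaled)))
    else ncol(scores)
    n_pcs <- min(n_pcs, ncol(scores))
  }
  an <- NULL; lv <- NULL
  for (pc in seq_len(n_pcs)) {
    y <- scores[, pc]
    for (fn in names(factors)) {
      f <- factor(factors[[fn]])
      if (nlevels(f) < 2L) {
        warning(sprintf("factor %s has a single level; skipped", fn))
        next
      }
      fit <- lm(y ~ f)
      a <- anova(fit)
      ss_b <- a$`Sum Sq`[1]; ss_tot <- sum(a$`Sum Sq`)
      an <- rbind(an, data.frame(pc = pc, factor = fn,
                                 F = a$`F value`[1], r2 = ss_b / ss_tot,
                                 p = a$`Pr(>F)`[1], stringsAsFactors = FALSE))
      # level contrasts: mean(level) - grand mean, SE from residual variance
      s2 <- sum(residuals(fit)^2) / fit$df.residual
      N <- length(y)
      for (l in levels(f)) {
        n_l <- sum(f == l)
        est <- mean(y[f == l]) - mean(y)
        se <- sqrt(s2 * (1 / n_l - 1 / N))
        tt <- if (se > 0) est / se else NA_real_
        pv <- if (is.na(tt)) NA_real_ else 2 * pt(-abs(tt), fit$df.residual)
        lv <- rbind(lv, data.frame(pc = pc, factor = fn, level = l, n = n_l,
                                   estimate = est, t = tt, p = pv,
                                   stringsAsFactors = FALSE))
      }
    }
  }
  structure(list(anova = an, levels = lv, n_pcs = n_pcs),
            class = "factor_association")
}

#' @export
print.factor_association <- function(x, alpha = 0.05, ...) {
  cat(sprintf("Dimension description over %d PCs\n\nANOVA (PC ~ factor):\n",
              x$n_pcs))
  print(transform(x$anova, F = round(F, 2), r2 = round(r2, 3),
                  p = signif(p, 3)), row.names = FALSE)
  sig <- x$levels[!is.na(x$levels$p) & x$levels$p < alpha, ]
  if (nrow(sig)) {
    cat(sprintf("\nLevel contrasts with p < %.3g:\n", alpha))
    print(transform(sig, estimate = round(estimate, 2), t = round(t, 2),
                    p = signif(p, 3)), row.names = FALSE)
  }
  invisible(x)
}

#' v-test of a quantitative variable against factor levels
#'
#' Standardized deviation of each level's mean from the overall mean:
#' `v = (mean_level - mean) / sqrt((s2 / n_level) * (N - n_level) / (N - 1))`
#' with `s2` the overall (population, 1/N) variance.  Under the null that
#' the level is a random draw of its size, v is approximately standard
#' normal; the sign gives the direction of the deviation.
#'
#' @param values numeric vector (e.g. integral intensity at one
#'   wavenumber, or a PC score).
#' @param labels factor-level labels, same length.
#' @return data.frame: `level`, `n`, `mean`, `v`, `p` (two-sided normal).
#' @examples
#' v_test(c(1, 2, 3, 4), c("a", "a", "b", "b"))
#' @export
v_test <- function(values, labels) {
  values <- as.numeric(values)
  if (length(values) != length(labels)) stop("length mismatch")
  N <- length(values)
  if (N < 2L) stop("need at least two observations")
  gm <- mean(values)
  s2 <- sum((values - gm)^2) / N
  if (s2 <= 0) stop("v-test undefined: zero overall variance")
  f <- factor(labels)
  out <- do.call(rbind, lapply(levels(f), function(l) {
    n_l <- sum(f == l)
    ml <- mean(values[f == l])
    if (n_l == N) {
      v <- 0
    } else {
      v <- (ml - gm) / sqrt((s2 / n_l) * (N - n_l) / (N - 1))
    }
    data.frame(level = l, n = n_l, mean = ml, v = v,
               p = 2 * pnorm(-abs(v)), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Euclidean distances between factor-level barycenters in PC space
#'
#' For each factor: the barycenter of scores per level, its Euclidean
#' distance from the overall center in the first `n_pcs` dimensions (the
#' per-level statistic conventionally tabulated), and the full
#' level-by-level distance matrix.
#'
#' @param pca an `amide3_pca` (or score matrix).
#' @param factors data.frame of categorical variables aligned with rows;
#'   defaults to the factors carried by the `spectral_matrix`.
#' @param n_pcs dimensions retained (default 2).
#' @return object of class `distance_table`: a list per factor with
#'   `center_distance` (named vector) and `pairwise` (matrix); empty
#'   levels are skipped.
#' @export
level_distances <- function(pca, factors = NULL, n_pcs = 2L) {
  scores <- if (inherits(pca, "amide3_pca")) pca$scores else as.matrix(pca)
  if (is.null(factors) && inherits(pca, "amide3_pca")) factors <- pca$factors
  factors <- as.data.frame(factors)
  factors <- factors[, setdiff(names(factors),
                               c("subject", "sample_id", "participant_id")),
                     drop = FALSE]
  if (n_pcs > ncol(scores)) stop("n_pcs exceeds available components")
  S <- scores[, seq_len(n_pcs), drop = FALSE]
  center <- colMeans(S)
  out <- lapply(names(factors), function(fn) {
    f <- factor(factors[[fn]])
    lv <- levels(f)[table(f)[levels(f)] > 0]
    bary <- do.call(rbind, lapply(lv, function(l)
      colMeans(S[f == l, , drop = FALSE])))
    rownames(bary) <- lv
    d0 <- sqrt(rowSums(sweep(bary, 2, center)^2))
    pw <- as.matrix(dist(bary))
    list(center_distance = setNames(d0, lv), pairwise = pw)
  })
  names(out) <- names(factors)
  structure(out, class = "distance_table", n_pcs = n_pcs)
}

#' @export
print.distance_table <- function(x, ...) {
  cat(sprintf("Level barycenter distances in the first %d PCs\n",
              attr(x, "n_pcs")))
  for (fn in names(x)) {
    cat(sprintf("\n%s (distance to overall center):\n", fn))
    print(round(x[[fn]]$center_distance, 2))
  }
  invisible(x)
}
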