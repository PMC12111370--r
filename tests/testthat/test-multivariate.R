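# PCA screening, dimension description, v-test, level distances

test_that("spectral matrix has the cohort geometry", {
  roster <- cohort_roster()
  coh <- generate_cohort(roster, n_portions = 10, seed = 4)
  m_avg <- build_matrix(coh$spectra, factors = roster)
  expect_equal(dim(m_avg$x), c(17L, 291L))   # 1185-1330 at 0.5 cm^-1
  m_all <- build_matrix(coh$spectra, average_portions = FALSE)
  expect_equal(nrow(m_all$x), 170L)
  # averaging really averages
  expect_equal(m_avg$x[1, ], colMeans(m_all$x[1:10, ]), tolerance = 1e-12)
  # inconsistent grids are rejected
  bad <- c(coh$spectra[1:3],
           list(spectrum(seq(1185, 1330, 1), rep(1, 146), "odd")))
  expect_error(build_matrix(bad), "common")
})

test_that("PCA satisfies its algebraic identities", {
  set.seed(10)
  X <- matrix(rnorm(20), 5, 4)
  p <- run_pca(X, scale_unit = FALSE)
  expect_equal(sum(p$explained_pct), 100, tolerance = 1e-9)
  expect_true(all(diff(p$eigenvalues) <= 1e-12) && all(p$eigenvalues >= -1e-12))
  expect_equal(colSums(p$scores^2), p$eigenvalues * (nrow(X) - 1),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(colMeans(p$scores), rep(0, ncol(p$scores)),
               tolerance = 1e-9, ignore_attr = TRUE)
  # full-rank reconstruction
  rec <- p$scores %*% t(p$loadings)
  rec <- sweep(rec, 2, p$center, "+")
  expect_equal(unname(rec), unname(X), tolerance = 1e-8)
})

test_that("two perfectly correlated variables give eigenvalues (2, 0)", {
  x <- rnorm(30)
  p <- run_pca(cbind(a = x, b = 2 * x + 1), scale_unit = TRUE)
  expect_equal(p$eigenvalues, c(2, 0), tolerance = 1e-9)
})

test_that("zero-variance columns are dropped with a warning when scaling", {
  X <- cbind(rnorm(10), rep(1, 10), rnorm(10))
  expect_warning(p <- run_pca(X, scale_unit = TRUE), "zero-variance")
  expect_equal(nrow(p$loadings), 2L)
})

test_that("Kaiser retention counts correlation eigenvalues above one", {
  expect_equal(kaiser_retain(c(2.1, 0.9, 0.5)), 1L)
  expect_equal(kaiser_retain(c(2.1, 1.2, 0.5)), 2L)
  expect_warning(k0 <- kaiser_retain(c(0.9, 0.6)), "elbow")
  expect_equal(k0, 0L)
  expect_warning(kaiser_retain(c(3, 1), scale_unit = FALSE), "correlation")
  # independent equal-variance variables retain about half the components
  set.seed(77)
  X <- matrix(rnorm(200 * 10), 200, 10)
  k <- kaiser_retain(run_pca(X)$eigenvalues)
  expect_gte(k, 3L); expect_lte(k, 7L)
  expect_equal(elbow_retain(c(60, 30, 5, 3, 2)), 2L)
})

test_that("dimension description matches a brute-force correlation ratio", {
  set.seed(5)
  f <- rep(c("a", "b", "c"), times = c(6, 5, 4))
  y <- rnorm(15) + (f == "b") * 2
  scores <- cbind(PC1 = y)
  da <- describe_dimension(scores, data.frame(g = f), n_pcs = 1)
  # oracle: eta^2 from group means
  gm <- tapply(y, f, mean); n_g <- table(f)
  ss_b <- sum(n_g * (gm - mean(y))^2)
  eta2 <- ss_b / sum((y - mean(y))^2)
  expect_equal(da$anova$r2, eta2, tolerance = 1e-12)
  # oracle: F/p from aov
  a <- summary(aov(y ~ factor(f)))[[1]]
  expect_equal(da$anova$F, a$`F value`[1], tolerance = 1e-12)
  expect_equal(da$anova$p, a$`Pr(>F)`[1], tolerance = 1e-12)
  # level estimates sum to zero (weighted by level size)
  lv <- da$levels
  expect_equal(sum(lv$estimate * lv$n), 0, tolerance = 1e-9)
})

test_that("a perfectly separating binary factor gives R^2 = 1", {
  scores <- cbind(PC1 = c(1, 1, 1, 5, 5, 5))
  f <- data.frame(g = c("x", "x", "x", "y", "y", "y"))
  da <- suppressWarnings(describe_dimension(scores, f, n_pcs = 1))
  expect_equal(da$anova$r2, 1, tolerance = 1e-12)
})

test_that("R^2 vanishes and p is calibrated under independence", {
  set.seed(8)
  r2 <- p <- numeric(40)
  for (i in 1:40) {
    scores <- cbind(PC1 = rnorm(60))
    f <- data.frame(g = sample(c("a", "b", "c"), 60, replace = TRUE))
    da <- describe_dimension(scores, f, n_pcs = 1)
    r2[i] <- da$anova$r2; p[i] <- da$anova$p
  }
  expect_lt(mean(r2), 0.10)
  expect_gt(mean(p), 0.3); expect_lt(mean(p), 0.7)
})

test_that("singleton levels still receive an estimate and p-value", {
  scores <- cbind(PC1 = c(0.1, -0.2, 0.3, -0.1, 12))
  f <- data.frame(g = c("h", "h", "h", "h", "solo"))
  da <- describe_dimension(scores, f, n_pcs = 1)
  solo <- da$levels[da$levels$level == "solo", ]
  expect_true(is.finite(solo$estimate) && is.finite(solo$p))
  expect_gt(solo$estimate, 9)
  expect_lt(solo$p, 0.05)
})

test_that("v-test matches its closed form and a permutation oracle", {
  # hand-checked case: values 1..4, level = {3,4}
  vt <- v_test(c(1, 2, 3, 4), c("o", "o", "l", "l"))
  v_l <- vt$v[vt$level == "l"]
  expect_equal(v_l, (3.5 - 2.5) / sqrt((1.25 / 2) * (2 / 3)), tolerance = 1e-12)
  expect_equal(v_l, 1.549193, tolerance = 1e-6)
  # the whole sample deviates by nothing
  expect_equal(v_test(rnorm(5), rep("all", 5))$v, 0)
  expect_error(v_test(rep(1, 6), rep(c("a", "b"), 3)), "variance")
  # permutation z-score agrees in sign and approximate magnitude
  set.seed(12)
  x <- rnorm(40); lab <- rep(c("a", "b"), each = 20)
  x[lab == "b"] <- x[lab == "b"] + 0.8
  v <- v_test(x, lab)$v[2]
  obs <- mean(x[lab == "b"])
  perm <- replicate(2000, mean(sample(x, 20)))
  z <- (obs - mean(perm)) / sd(perm)
  expect_equal(sign(v), sign(z))
  expect_lt(abs(v - z), 0.5)
})

test_that("level distances reproduce plane geometry and metric axioms", {
  scores <- rbind(c(0, 0), c(3, 4))
  dt <- level_distances(scores, data.frame(g = c("p", "q")), n_pcs = 2)
  expect_equal(dt$g$pairwise["p", "q"], 5)
  expect_equal(unname(dt$g$center_distance), c(2.5, 2.5))
  # coincident members collapse onto the shared barycenter
  sc2 <- rbind(c(1, 2), c(1, 2), c(4, 6))
  dt2 <- level_distances(sc2, data.frame(g = c("a", "a", "b")), n_pcs = 2)
  expect_equal(dt2$g$pairwise["a", "b"], 5)
  # symmetry + triangle inequality on random data
  set.seed(9)
  sc <- matrix(rnorm(60), 20, 3)
  f <- data.frame(g = sample(letters[1:4], 20, replace = TRUE))
  pw <- level_distances(sc, f, n_pcs = 3)$g$pairwise
  expect_equal(pw, t(pw))
  expect_true(all(diag(pw) == 0))
  for (i in 1:4) for (j in 1:4) for (k in 1:4)
    expect_lte(pw[i, j], pw[i, k] + pw[k, j] + 1e-12)
  expect_error(level_distances(sc, f, n_pcs = 5), "exceeds")
})

test_that("a dominant structured factor concentrates variance in 2 PCs", {
  # two spectral archetypes plus small noise: rank-~1 dominant signal
  set.seed(14)
  a <- spectrum_from_table("FYHHH")$absorbance
  b <- spectrum_from_table("FOMLG")$absorbance
  X <- rbind(t(replicate(8, a + rnorm(length(a), 0, 0.01))),
             t(replicate(8, b + rnorm(length(b), 0, 0.01))))
  p <- run_pca(X, scale_unit = FALSE)
  expect_gt(p$cumulative_pct[2], 90)
})
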