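test_that("spearman handles perfect, reversed and hand-computed cases", {
  expect_equal(spearman(1:6, (1:6)^3)$rho, 1)
  expect_equal(spearman(1:6, rev(1:6))$rho, -1)
  s <- spearman(c(1, 2, 3), c(2, 1, 3))
  expect_equal(s$rho, 0.5, tolerance = 1e-12)
  # all 3! = 6 rank permutations have |rho| >= 0.5: exact p = 1
  expect_equal(s$p, 1)
  expect_identical(s$method, "exact")
  expect_warning(sc <- spearman(c(1, 1, 1, 1), 1:4), "constant")
  expect_true(is.na(sc$rho))
  expect_error(spearman(1:2, 2:1), "at least 3")
})

test_that("exact p-values equal explicit permutation enumeration, with and without ties", {
  set.seed(80)
  cases <- list(
    list(x = c(3, 1, 4, 1, 5), y = c(9, 2, 6, 5, 3)),       # tie in x
    list(x = rnorm(6), y = rnorm(6)),
    list(x = c(1, 2, 2, 3, 3, 4), y = rnorm(6)),            # ties
    list(x = rnorm(7), y = rnorm(7)),
    list(x = rnorm(8), y = c(1, 1, rnorm(6)))               # tie in y
  )
  for (cs in cases) {
    got <- spearman(cs$x, cs$y)
    expect_equal(got$p, spearman_brute_p(cs$x, cs$y), tolerance = 1e-12)
  }
})

test_that("spearman agrees with the reference implementation", {
  set.seed(81)
  for (rep in 1:5) {
    x <- rnorm(9); y <- rnorm(9)
    got <- spearman(x, y)
    ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
    # for untied n < 10, cor.test's exact p is also enumeration-based
    expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  }
  x <- rnorm(30); y <- x + rnorm(30, 0, 0.8)
  got <- spearman(x, y)
  expect_equal(got$rho,
               stats::cor(x, y, method = "spearman"), tolerance = 1e-12)
  expect_identical(got$method, "t-approximation")
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(82)
  x <- rnorm(15); y <- rnorm(15)
  base <- spearman(x, y)
  expect_equal(spearman(exp(x), y)$rho, base$rho, tolerance = 1e-12)
  expect_equal(spearman(x, 3 * y - 100)$rho, base$rho, tolerance = 1e-12)
  expect_equal(spearman(qnorm(pnorm(x)), y^3 * 0 + rank(y))$rho,
               spearman(x, rank(y))$rho, tolerance = 1e-12)
})

test_that("array correlation matrices match per-pair recomputation", {
  set.seed(83)
  folds <- matrix(2^rnorm(10 * 3), 10, 3,
                  dimnames = list(sprintf("g%02d", 1:10),
                                  c("a1", "a2", "a3")))
  fm <- make_folds(folds, c("case", "case", "control"))
  cm <- correlation_matrix(fm)
  expect_equal(unname(diag(cm$rho)), rep(1, 3))
  expect_equal(cm$rho, t(cm$rho), tolerance = 1e-15)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(cm$rho[i, j],
                 spearman(folds[, i], folds[, j])$rho, tolerance = 1e-12)
  }
  # duplicated array gives off-diagonal 1
  dup <- cbind(folds, a4 = folds[, 1])
  cm2 <- correlation_matrix(make_folds(dup, c("case", "case", "control",
                                              "control")))
  expect_equal(cm2$rho["a1", "a4"], 1)
  # insufficient shared genes -> missing entry
  sparse <- folds
  sparse[3:10, 1] <- NA
  sparse[1:2, 2] <- NA
  cm3 <- correlation_matrix(make_folds(sparse, c("case", "case",
                                                 "control")))
  expect_true(is.na(cm3$rho["a1", "a2"]))
})

test_that("svd imputation is exact on complete input and recovers rank-1 structure", {
  set.seed(84)
  full <- matrix(rnorm(30), 5, 6)
  out <- svd_impute(full)
  expect_identical(out[, ], full)
  expect_identical(attr(out, "iterations"), 0L)

  u <- c(1, 2, 3, 4, 5); v <- c(2, 1, 4, 0.5, 3, 1.5)
  r1 <- outer(u, v)
  masked <- r1
  masked[2, 3] <- NA
  imp <- svd_impute(masked, k = 1, tol = 1e-9, max_iter = 500)
  expect_lt(abs(imp[2, 3] - r1[2, 3]), 1e-6)
  # observed entries never modified
  idx <- which(is.na(masked))
  expect_identical(imp[-idx], r1[-idx])

  # imputed-entry change decays monotonically on this fixture
  deltas <- attr(imp, "delta_history")
  expect_true(all(diff(deltas) <= 1e-12))

  bad <- masked
  bad[2, ] <- NA
  expect_error(svd_impute(bad), "row")
})

test_that("PCA wraps prcomp with sane variance fractions and orthonormal loadings", {
  set.seed(85)
  x <- matrix(rnorm(20 * 12), 20, 12,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%d", 1:12)))
  fit <- pca_expression(x)
  expect_equal(sum(fit$variance_fraction), 1, tolerance = 1e-12)
  ltl <- crossprod(fit$loadings)
  expect_equal(ltl, diag(ncol(fit$loadings)), tolerance = 1e-10,
               ignore_attr = TRUE)
  # diagonal point cloud: PC1 dominates
  t_ <- rnorm(50, sd = 2)
  cloud <- rbind(g1 = t_ + rnorm(50, 0, 0.02),
                 g2 = t_ + rnorm(50, 0, 0.02))
  fit2 <- pca_expression(cloud)
  expect_gt(fit2$variance_fraction[1], 0.95)
  expect_error(pca_expression(matrix(1, 3, 4)), "rank 0")
  expect_error(pca_expression(matrix(c(NA, rnorm(7)), 2, 4)), "missing")
})

test_that("delta-delta-Ct conversion matches hand computations", {
  expect_equal(ddct(20, 15, 22, 17), 1)   # ddCt = 0
  expect_equal(ddct(21, 15, 22, 16), 1)
  expect_equal(ddct(24, 18, 25, 18), 2)   # one cycle below calibrator
  expect_equal(ddct(25, 20, 28, 21), 4)   # (25-20) - (28-21) = -2 -> 4
  expect_error(ddct(NA, 1, 1, 1), "finite")
  # vectorized over samples
  expect_equal(ddct(c(25, 24), c(20, 18), 28, 21),
               c(4, 2^(-(6 - 7))))
})

test_that("transcript-score correlations identify monotone relationships", {
  set.seed(86)
  sc <- data.frame(sample_id = sprintf("s%02d", 1:20),
                   dataset_id = "D1", disease_label = "disease",
                   group = "case",
                   ifn_score = 2^rnorm(20), stringsAsFactors = FALSE)
  tm <- cbind(mono = sc$ifn_score^2 + 1,
              noise = rnorm(20))
  rownames(tm) <- sc$sample_id
  res <- transcript_score_correlation(sc, tm)
  expect_equal(res$rho[res$transcript == "mono"], 1)
  expect_lt(abs(res$rho[res$transcript == "noise"]), 0.7)
  rownames(tm) <- paste0("x", rownames(tm))
  expect_error(transcript_score_correlation(sc, tm), "shared")
})
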