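make_two_channel <- function(fg1, fg2, bg1 = NULL, bg2 = NULL) {
  dn <- dimnames(fg1)
  channels <- list(ch1 = fg1, ch2 = fg2)
  if (!is.null(bg1)) channels$bg1 <- bg1
  if (!is.null(bg2)) channels$bg2 <- bg2
  probe_matrix(log2(fg1 / fg2), space = "log2", channels = channels,
               platform_id = "2ch")
}

test_that("filter_probes applies the inclusive signal-over-background rule", {
  dn <- list(c("p1", "p2", "p3"), c("s1", "s2"))
  fg1 <- matrix(c(150, 100, 400, 150, 100, 400), 3, 2, dimnames = dn)
  fg2 <- matrix(100, 3, 2, dimnames = dn)
  bg1 <- matrix(100, 3, 2, dimnames = dn)
  bg2 <- matrix(100, 3, 2, dimnames = dn)
  pm <- make_two_channel(fg1, fg2, bg1, bg2)
  # p1: foreground exactly 1.5x background in channel 1 -> retained (>=)
  # p2: below threshold in both channels everywhere -> removed
  # p3: well above -> retained
  out <- filter_probes(pm, background_ratio = 1.5, adequacy_fraction = 0.8)
  expect_identical(rownames(out$values), c("p1", "p3"))
  expect_identical(attr(out, "n_removed"), 1L)
})

test_that("filter_probes enforces the adequacy fraction and masks bad values", {
  n_samp <- 100L
  dn <- list(c("p79", "p80", "pall"), sprintf("s%03d", 1:n_samp))
  vals <- matrix(1, 3, n_samp, dimnames = dn)
  ok <- matrix(TRUE, 3, n_samp, dimnames = dn)
  ok["p79", 1:21] <- FALSE  # adequate in 79% of samples
  ok["p80", 1:20] <- FALSE  # adequate in exactly 80%
  pm <- probe_matrix(vals, space = "linear", adequate = ok)
  out <- filter_probes(pm, adequacy_fraction = 0.8)
  expect_identical(rownames(out$values), c("p80", "pall"))
  # inadequate individual values are set to missing
  expect_true(all(is.na(out$values["p80", 1:20])))
  expect_false(anyNA(out$values["pall", ]))

  # identity when everything is adequate
  pm_all <- probe_matrix(vals, space = "linear",
                         adequate = matrix(TRUE, 3, n_samp, dimnames = dn))
  expect_equal(filter_probes(pm_all)$values, vals)

  # no channel data and no flags -> explicit error
  bare <- probe_matrix(vals, space = "linear")
  expect_error(filter_probes(bare), "neither channel")
})

test_that("lowess normalization removes a planted intensity trend", {
  set.seed(7)
  n <- 400L
  dn <- list(sprintf("p%03d", 1:n), "s1")
  a <- runif(n, 6, 14)                       # intensity
  m <- 0.8 + 0.25 * a + rnorm(n, 0, 0.05)    # planted linear dye bias
  ch1 <- matrix(2^(a + m / 2), dimnames = dn)
  ch2 <- matrix(2^(a - m / 2), dimnames = dn)
  pm <- make_two_channel(ch1, ch2)
  out <- lowess_normalize(pm, span = 0.4)
  fit <- stats::lm(out$values[, 1] ~ a)
  expect_lt(abs(stats::coef(fit)[2]), 0.01)
  expect_lt(abs(mean(out$values[, 1])), 0.02)
  expect_identical(out$space, "log2")
})

test_that("lowess normalization is exact on trend-free arrays and odd under channel swap", {
  set.seed(8)
  n <- 300L
  dn <- list(sprintf("p%03d", 1:n), "s1")
  a <- runif(n, 6, 14)
  ch1 <- matrix(2^a, dimnames = dn)
  ch2 <- matrix(2^a, dimnames = dn)   # M identically zero
  out <- lowess_normalize(make_two_channel(ch1, ch2))
  expect_equal(unname(out$values[, 1]), rep(0, n), tolerance = 1e-12)

  ch2b <- matrix(2^(a + rnorm(n, 0, 0.4)), dimnames = dn)
  fwd <- lowess_normalize(make_two_channel(ch1, ch2b))
  rev_ <- lowess_normalize(make_two_channel(ch2b, ch1))
  expect_equal(fwd$values, -rev_$values, tolerance = 1e-8)

  expect_error(lowess_normalize(make_two_channel(ch1[1:10, , drop = FALSE],
                                                 ch2[1:10, , drop = FALSE])),
               "underdetermined")
})

test_that("collapse_probes averages in linear space and excludes multi-gene probes", {
  dn <- list(c("p1", "p2", "p3", "p4", "p5"), c("s1", "s2"))
  vals <- matrix(c(2, 4, 1, 8, 5,
                   2, 4, 1, 8, 5), 5, 2, dimnames = dn)
  ann <- data.frame(probe_id = c("p1", "p2", "p3", "p4", "p5"),
                    gene_ids = c("gA", "gA", "gB", "gB", "gA,gB"),
                    stringsAsFactors = FALSE)
  pm <- probe_matrix(vals, space = "linear")
  gm <- collapse_probes(pm, ann)
  # gA: linear mean of {2, 4} = 3
  expect_equal(unname(2^gm["gA", "s1"]), 3, tolerance = 1e-12)
  # p5 maps to two genes and contributes to neither
  expect_identical(attr(gm, "n_multi_gene"), 1L)
  expect_equal(unname(2^gm["gB", "s1"]), mean(c(1, 8)), tolerance = 1e-12)

  # log2-space input: values {1, 3} -> linear {2, 8} -> mean 5 -> log2(5)
  pm2 <- probe_matrix(matrix(c(1, 3), 2, 1,
                             dimnames = list(c("q1", "q2"), "s1")),
                      space = "log2")
  ann2 <- data.frame(probe_id = c("q1", "q2"), gene_ids = "gX",
                     stringsAsFactors = FALSE)
  gm2 <- collapse_probes(pm2, ann2)
  expect_equal(unname(gm2["gX", 1]), log2(5), tolerance = 1e-12)

  # missing probe values are ignored in the mean
  pm3 <- probe_matrix(matrix(c(2, NA), 2, 1,
                             dimnames = list(c("q1", "q2"), "s1")),
                      space = "linear")
  gm3 <- collapse_probes(pm3, ann2)
  expect_equal(unname(2^gm3["gX", 1]), 2, tolerance = 1e-12)

  # one-to-one annotation is the identity up to space conversion
  ann_11 <- data.frame(probe_id = rownames(vals)[1:4],
                       gene_ids = paste0("g", 1:4),
                       stringsAsFactors = FALSE)
  gm4 <- collapse_probes(probe_matrix(vals[1:4, , drop = FALSE],
                                      space = "linear"), ann_11)
  expect_equal(unname(2^gm4[paste0("g", 1:4), ]), unname(vals[1:4, ]),
               tolerance = 1e-12)

  expect_error(collapse_probes(pm, data.frame(probe_id = "zz",
                                              gene_ids = "g",
                                              stringsAsFactors = FALSE)),
               "no overlap")
})

test_that("control_normalize divides by the control mean and keeps controls at mean fold 1", {
  gm <- matrix(c(8, 3, 2, 4,
                 2, 3, 2, 4), 2, 4, byrow = TRUE,
               dimnames = list(c("gA", "gB"),
                               c("case1", "case2", "ctl1", "ctl2")))
  attr(gm, "space") <- "linear"
  man <- make_manifest(colnames(gm), c("case", "case", "control", "control"))
  fm <- control_normalize(gm, man, space = "linear")
  # control values {2, 4}: mean 3; case value 8 -> fold 8/3; case 3 -> 1
  expect_equal(unname(fm$folds["gA", "case1"]), 8 / 3, tolerance = 1e-12)
  expect_equal(unname(fm$folds["gA", "case2"]), 1, tolerance = 1e-12)
  ctrl <- fm$manifest$group == "control"
  expect_equal(unname(rowMeans(fm$folds[, ctrl])), c(1, 1),
               tolerance = 1e-12)
  # manifests without controls are rejected upstream
  man_bad <- man; man_bad$group <- rep("case", 4)
  expect_error(control_normalize(gm, man_bad, space = "linear"),
               "control")
})

test_that("control_normalize drops genes without usable control data", {
  gm <- matrix(c(4, NA, NA,
                 4, 2, NA,
                 4, 2, 6), 3, 3, byrow = TRUE,
               dimnames = list(c("g_none", "g_partial", "g_full"),
                               c("case1", "ctl1", "ctl2")))
  man <- make_manifest(colnames(gm), c("case", "control", "control"))
  fm <- suppressMessages(control_normalize(gm, man, space = "linear"))
  expect_identical(rownames(fm$folds), c("g_partial", "g_full"))
  # partial control coverage: mean over the available control values
  expect_equal(unname(fm$folds["g_partial", "case1"]), 2, tolerance = 1e-12)
})

test_that("comparison matrix is the sorted gene intersection, order-invariant", {
  mk <- function(genes, dataset) {
    m <- matrix(seq_len(2 * length(genes)) + 0.5, length(genes), 2,
                dimnames = list(genes, paste0(dataset, c("_a", "_b"))))
    make_folds(m, c("case", "control"), dataset)
  }
  d1 <- mk(c("A", "B", "C"), "D1")
  d2 <- mk(c("B", "C", "D"), "D2")
  merged <- build_comparison_matrix(list(d1, d2))
  expect_identical(rownames(merged$folds), c("B", "C"))
  expect_identical(merged$dataset, "comparison")
  merged_rev <- build_comparison_matrix(list(d2, d1))
  expect_identical(rownames(merged_rev$folds), rownames(merged$folds))
  expect_equal(merged_rev$folds[, colnames(merged$folds)], merged$folds,
               tolerance = 1e-15)

  expect_error(build_comparison_matrix(list(mk(c("A"), "D1"),
                                            mk(c("B"), "D2"))),
               "no genes shared")

  # random-subset triple intersection against an exhaustive set oracle
  set.seed(13)
  universe <- sprintf("G%03d", 1:100)
  subs <- lapply(1:3, function(i) sort(sample(universe, 50)))
  ds <- lapply(1:3, function(i) mk(subs[[i]], paste0("R", i)))
  got <- rownames(build_comparison_matrix(ds)$folds)
  oracle <- sort(Reduce(intersect, subs))
  expect_identical(got, oracle)
  expect_lte(length(got), min(lengths(subs)))
})
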