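stim_fixture <- function(seed = 55, ...) {
  simulate_stimulation_study(n_studies = 3, n_genes = 400,
                             n_responsive = 30, n_pairs = 4,
                             noise_sd = 0.4, seed = seed, ...)
}

test_that("signature derivation recovers responsive genes and records stage counts", {
  stim <- stim_fixture()
  sig <- derive_core_signature(stim$experiments, fdr = 0.05,
                               n_perm = 100, seed = 2)
  truth <- stim$truth$responsive_genes
  recall <- mean(truth %in% sig$gene_id)
  precision <- mean(sig$gene_id %in% truth)
  expect_gte(recall, 0.85)
  expect_gte(precision, 0.85)
  counts <- attr(sig, "counts")
  expect_true(counts[["significant"]] >= counts[["min_fold"]])
  expect_true(counts[["min_fold"]] >= counts[["comparison"]])
  # descending fold order with identifier tie-break
  expect_true(all(diff(sig$mean_fold) <= 0))
  expect_true(all(sig$mean_fold >= 2))
})

test_that("per-study baseline shifts do not change the derived signature", {
  stim <- stim_fixture()
  sig <- derive_core_signature(stim$experiments, fdr = 0.05,
                               n_perm = 100, seed = 2)
  shifted <- stim_fixture(study_shifts = c(5, 0, -3))
  sig_shift <- derive_core_signature(shifted$experiments, fdr = 0.05,
                                     n_perm = 100, seed = 2)
  expect_identical(sig$gene_id, sig_shift$gene_id)
  expect_equal(sig$mean_fold, sig_shift$mean_fold, tolerance = 1e-9)

  # adding a per-gene constant to one study is removed by mean-centering
  # and cancels in the per-study fold ratio
  stim2 <- stim_fixture()
  e1 <- stim2$experiments[[1]]
  e1$matrix <- e1$matrix + stats::rnorm(nrow(e1$matrix))
  stim2$experiments[[1]] <- e1
  sig_pg <- derive_core_signature(stim2$experiments, fdr = 0.05,
                                  n_perm = 100, seed = 2)
  expect_identical(sig_pg$gene_id, sig$gene_id)
})

test_that("the comparison-gene intersection stage excludes off-platform genes", {
  stim <- stim_fixture()
  sig_all <- derive_core_signature(stim$experiments, fdr = 0.05,
                                   n_perm = 100, seed = 2)
  drop <- sig_all$gene_id[1:5]
  comparison <- setdiff(rownames(stim$experiments[[1]]$matrix), drop)
  sig_cut <- derive_core_signature(stim$experiments,
                                   comparison_genes = comparison,
                                   fdr = 0.05, n_perm = 100, seed = 2)
  expect_false(any(drop %in% sig_cut$gene_id))
  expect_identical(sort(sig_cut$gene_id),
                   sort(setdiff(sig_all$gene_id, drop)))
  counts <- attr(sig_cut, "counts")
  expect_identical(unname(counts[["comparison"]]),
                   length(sig_all$gene_id) - 5L)
})

test_that("select_top_n sorts by fold with identifier tie-break", {
  sig <- derive_signature_fixture()  # gC/gA at fold 8, gB 4, gD 2.5
  expect_identical(select_top_n(sig, 2), c("gA", "gC"))
  expect_identical(select_top_n(sig, 10), c("gA", "gC", "gB", "gD"))
  # brute-force sort-and-slice oracle on a random hand-built list
  set.seed(40)
  genes <- sprintf("h%02d", 1:10)
  folds <- sample(c(2, 4, 4, 8), 10, replace = TRUE) + 0
  sig2 <- ifnscore:::new_core_signature(genes, folds,
                                        counts = c(significant = NA,
                                                   min_fold = NA,
                                                   comparison = NA))
  oracle <- genes[order(-folds, genes)][1:3]
  expect_identical(select_top_n(sig2, 3), oracle)
  expect_error(select_top_n(sig2[0, ], 3))
})

test_that("IFN scores are medians in linear space with documented conventions", {
  folds <- matrix(1, 25, 3,
                  dimnames = list(sprintf("g%02d", 1:25),
                                  c("null", "high", "partial")))
  folds[, "high"] <- 4
  folds[, "partial"] <- NA
  folds[1:3, "partial"] <- c(1, 2, 8)
  fm <- make_folds(folds, c("control", "case", "case"))
  sc <- ifn_score(fm, rownames(folds), min_coverage = 0.6)
  expect_equal(sc$ifn_score[sc$sample_id == "null"], 1)
  expect_equal(sc$ifn_score[sc$sample_id == "high"], 4)
  # available folds {1, 2, 8}: median 2; coverage 3/25 flagged
  expect_equal(sc$ifn_score[sc$sample_id == "partial"], 2)
  expect_identical(sc$n_genes_used[sc$sample_id == "partial"], 3L)
  expect_true(sc$low_coverage[sc$sample_id == "partial"])
  expect_false(any(sc$low_coverage[sc$sample_id != "partial"]))
  expect_error(ifn_score(fm, c("absent1", "absent2")), "none")
})

test_that("scores are scale-equivariant and blind to non-scoring genes", {
  set.seed(41)
  folds <- matrix(2^rnorm(50 * 4), 50, 4,
                  dimnames = list(sprintf("g%02d", 1:50),
                                  sprintf("s%d", 1:4)))
  fm <- make_folds(folds, c("control", "control", "case", "case"))
  genes <- rownames(folds)[1:25]
  base <- ifn_score(fm, genes)
  scaled <- folds
  scaled[, "s3"] <- scaled[, "s3"] * 7
  expect_equal(ifn_score(make_folds(scaled, c("control", "control",
                                              "case", "case")),
                         genes)$ifn_score,
               base$ifn_score * c(1, 1, 7, 1), tolerance = 1e-12)
  shuffled <- folds
  shuffled[26:50, ] <- folds[sample(26:50), ]
  expect_equal(ifn_score(make_folds(shuffled, c("control", "control",
                                                "case", "case")),
                         genes)$ifn_score,
               base$ifn_score, tolerance = 1e-15)
})

test_that("score summaries report mean and SEM per group", {
  sc <- data.frame(sample_id = sprintf("s%d", 1:5),
                   dataset_id = c("A", "A", "B", "C", "C"),
                   disease_label = "disease", group = "case",
                   ifn_score = c(2, 4, 7, 3, 3),
                   stringsAsFactors = FALSE)
  s <- summarize_scores(sc, by = "dataset_id")
  # scores {2, 4}: mean 3, sd sqrt(2), SEM sqrt(2)/sqrt(2) = 1
  expect_equal(s$mean[s$group == "A"], 3)
  expect_equal(s$sem[s$group == "A"], 1)
  expect_true(is.na(s$sem[s$group == "B"]))
  expect_equal(s$sem[s$group == "C"], 0)
  expect_error(summarize_scores(sc[0, ], by = "dataset_id"), "no rows")
})

test_that("compact and full signature scores are concordant on latent-driven cohorts", {
  spec <- cohort_spec(n_datasets = 1, n_genes = 500, n_signature = 60,
                      modules = list(), seed = 99)
  coh <- simulate_disease_cohort(spec)
  folds <- suppressMessages(harmonize_cohort(coh))$comparison
  sig_genes <- intersect(coh$truth$signature_genes, rownames(folds$folds))
  sig <- ifnscore:::new_core_signature(
    sig_genes, seq(8, 2, length.out = length(sig_genes)),
    counts = c(significant = NA, min_fold = NA, comparison = NA))
  conc <- score_concordance(folds, sig, n_small = 25)
  expect_gte(conc$rho, 0.9)
  expect_equal(score_concordance(folds, sig, n_small = 25,
                                 n_full = 25)$rho, 1)
})
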