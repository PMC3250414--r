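#' In vitro interferon stimulation experiment
#'
#' Container for one pre/post stimulation dataset: a gene x sample log2
#' expression matrix with a paired design labelling each sample `pre` or
#' `post`.
#'
#' @param matrix Gene x sample numeric matrix, log2 space.
#' @param design Character vector (`"pre"`/`"post"`), one per column.
#' @param dataset_id Dataset label.
#' @param cell_type Responder cell type (e.g. keratinocyte, fibroblast).
#' @param ifn_type One of `"alpha"`, `"beta"`, `"gamma"`, `"other"`.
#' @return Object of class `stimulation_experiment`.
#' @export
stimulation_experiment <- function(matrix, design, dataset_id,
                                   cell_type = NA_character_,
                                   ifn_type = c("alpha", "beta", "gamma",
                                                "other")) {
  ifn_type <- match.arg(ifn_type)
  stopifnot(is.matrix(matrix), length(design) == ncol(matrix))
  if (!all(design %in% c("pre", "post"))) {
    stop("design labels must be 'pre' or 'post'")
  }
  if (!any(design == "pre") || !any(design == "post")) {
    stop("both pre and post groups must be non-empty")
  }
  if (is.null(rownames(matrix))) stop("matrix must have gene rownames")
  structure(list(matrix = matrix, design = design, dataset_id = dataset_id,
                 cell_type = cell_type, ifn_type = ifn_type),
            class = "stimulation_experiment")
}

#' @export
print.stimulation_experiment <- function(x, ...) {
  cat("stimulation_experiment [", x$dataset_id, "]: ", nrow(x$matrix),
      " genes; ", sum(x$design == "pre"), " pre / ",
      sum(x$design == "post"), " post; IFN-", x$ifn_type,
      " on ", x$cell_type, "\n", sep = "")
  invisible(x)
}

new_core_signature <- function(genes, mean_fold, counts, provenance = NULL) {
  ord <- order(-mean_fold, genes)
  df <- data.frame(rank = seq_along(genes), gene_id = genes[ord],
                   mean_fold = mean_fold[ord], stringsAsFactors = FALSE)
  structure(df, class = c("core_signature", "data.frame"),
            counts = counts, provenance = provenance)
}

#' @export
print.core_signature <- function(x, ...) {
  counts <- attr(x, "counts")
  cat("core IFN signature:", nrow(x), "genes\n")
  if (!is.null(counts) && !all(is.na(counts))) {
    cat("  derivation counts: significant =", counts[["significant"]],
        "-> fold filter =", counts[["min_fold"]],
        "-> comparison-set intersect =", counts[["comparison"]], "\n")
  }
  if (nrow(x) > 0) {
    top <- utils::head(as.data.frame(x), 5L)
    cat("  top genes:\n")
    print(top, row.names = FALSE)
  }
  invisible(x)
}

#' Derive the core IFN signature from pooled stimulation experiments
#'
#' Pools in vitro interferon stimulation datasets and extracts a consensus
#' list of IFN-inducible genes:
#' 1. within each study, log2 values are mean-centered per gene across that
#'    study's samples (removing study-specific baselines);
#' 2. studies are restricted to their shared genes and column-concatenated;
#' 3. a SAM two-class analysis (pre vs post) with permutation FDR is run on
#'    the combined matrix;
#' 4. significant genes with average linear fold change (post over pre,
#'    per-study ratios of class means averaged with equal study weights) of
#'    at least `min_fold` are retained;
#' 5. the result is intersected with `comparison_genes` (the cross-platform
#'    comparison-matrix gene set), if provided.
#'
#' Gene counts after stages 3, 4 and 5 are recorded on the result. The
#' signature is ordered by descending mean fold change, ties broken by gene
#' identifier.
#'
#' @param experiments List of two or more [stimulation_experiment()]s with
#'   overlapping gene coverage.
#' @param comparison_genes Optional character vector restricting the final
#'   signature to genes measurable on all platforms.
#' @param fdr Target FDR for the SAM stage (default 0.05).
#' @param min_fold Minimum average linear fold change (default 2).
#' @param n_perm,s0,seed Passed to [sam_fdr()].
#' @return A `core_signature` object: a data.frame (`rank`, `gene_id`,
#'   `mean_fold`) with attributes `counts` and `provenance`.
#' @export
derive_core_signature <- function(experiments, comparison_genes = NULL,
                                  fdr = 0.05, min_fold = 2,
                                  n_perm = 1000L, s0 = NULL, seed = NULL) {
  stopifnot(is.list(experiments), length(experiments) >= 2L, min_fold >= 1)
  for (e in experiments) stopifnot(inherits(e, "stimulation_experiment"))
  shared <- Reduce(intersect, lapply(experiments,
                                     function(e) rownames(e$matrix)))
  if (length(shared) == 0L) stop("no genes shared across studies")
  shared <- sort(shared)
  centered <- lapply(experiments, function(e) {
    m <- e$matrix[shared, , drop = FALSE]
    m - rowMeans(m)
  })
  combined <- do.call(cbind, centered)
  design <- factor(unlist(lapply(experiments, `[[`, "design")),
                   levels = c("pre", "post"))
  fit <- sam_fdr(combined, design, fdr = fdr, n_perm = n_perm, s0 = s0,
                 seed = seed, space = "log2")
  sig_genes <- fit$table$gene[fit$table$significant %in% TRUE]
  n_sig <- length(sig_genes)

  # equal-weight average across studies of the per-study post/pre ratio of
  # linear-space class means (computed on the uncentered data; per-gene
  # centering cancels in the ratio anyway)
  ratios <- vapply(experiments, function(e) {
    m <- 2^e$matrix[shared, , drop = FALSE]
    rowMeans(m[, e$design == "post", drop = FALSE]) /
      rowMeans(m[, e$design == "pre", drop = FALSE])
  }, numeric(length(shared)))
  mean_fold <- rowMeans(ratios)
  names(mean_fold) <- shared

  keep <- intersect(sig_genes, shared[mean_fold >= min_fold])
  n_fold <- length(keep)
  if (!is.null(comparison_genes)) {
    keep <- intersect(keep, comparison_genes)
  }
  n_final <- length(keep)
  new_core_signature(keep, unname(mean_fold[keep]),
                     counts = c(significant = n_sig, min_fold = n_fold,
                                comparison = n_final),
                     provenance = vapply(experiments, `[[`, "",
                                         "dataset_id"))
}

#' Select the top-N most strongly induced signature genes
#'
#' Returns the first `min(n, |signature|)` genes in descending mean-fold
#' order, ties broken by gene identifier ascending. The original analyses
#' use the top 25 as a static scoring list.
#'
#' @param signature A `core_signature`.
#' @param n Number of genes (default 25).
#' @return Character vector of gene identifiers.
#' @export
select_top_n <- function(signature, n = 25L) {
  stopifnot(inherits(signature, "core_signature"), n >= 1)
  if (nrow(signature) == 0L) stop("empty signature")
  ord <- order(-signature$mean_fold, signature$gene_id)
  utils::head(signature$gene_id[ord], n)
}

#' Per-sample IFN score
#'
#' The IFN score of a sample is the median, in linear space, of its fold
#' changes (relative to the dataset's internal healthy controls) over the
#' scoring gene list. Missing values are ignored; with an even number of
#' available genes the median is the arithmetic mean of the two central
#' values. Samples covering fewer than `min_coverage` of the scoring genes
#' are still scored but flagged.
#'
#' @param folds A [fold_matrix()] (linear space).
#' @param score_genes Character vector of scoring genes (e.g. from
#'   [select_top_n()]).
#' @param min_coverage Minimum fraction of scoring genes that must be
#'   non-missing for an unflagged score (default 0.6).
#' @return Object of class `ifn_scores`: data.frame with columns
#'   `sample_id`, `dataset_id`, `disease_label`, `group`, `ifn_score`,
#'   `n_genes_used`, `low_coverage`.
#' @export
ifn_score <- function(folds, score_genes, min_coverage = 0.6) {
  stopifnot(inherits(folds, "fold_matrix"))
  present <- intersect(score_genes, rownames(folds$folds))
  if (length(present) == 0L) {
    stop("none of the scoring genes are present in the fold matrix")
  }
  sub <- folds$folds[present, , drop = FALSE]
  score <- apply(sub, 2L, stats::median, na.rm = TRUE)
  n_used <- as.integer(colSums(!is.na(sub)))
  out <- data.frame(sample_id = colnames(sub),
                    dataset_id = folds$manifest$dataset_id,
                    disease_label = folds$manifest$disease_label,
                    group = folds$manifest$group,
                    ifn_score = unname(score),
                    n_genes_used = unname(n_used),
                    low_coverage = unname(n_used <
                                          min_coverage * length(score_genes)),
                    stringsAsFactors = FALSE)
  structure(out, class = c("ifn_scores", "data.frame"),
            score_genes = score_genes)
}

#' @export
print.ifn_scores <- function(x, ...) {
  cat("IFN scores for", nrow(x), "samples (",
      length(attr(x, "score_genes")), "scoring genes )\n")
  print(as.data.frame(utils::head(x, 10L)), row.names = FALSE)
  if (nrow(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' @export
plot.ifn_scores <- function(x, by = c("dataset_id", "disease_label"), ...) {
  by <- match.arg(by)
  s <- summarize_scores(x, by = by)
  bp <- graphics::barplot(s$mean, names.arg = s$group, las = 2,
                          ylab = "mean IFN score", ...)
  sem <- ifelse(is.na(s$sem), 0, s$sem)
  graphics::arrows(bp, s$mean - sem, bp, s$mean + sem,
                   angle = 90, code = 3, length = 0.04)
  invisible(s)
}

#' Summarize IFN scores by dataset or disease
#'
#' @param scores An `ifn_scores` data.frame.
#' @param by Grouping column: `"dataset_id"` or `"disease_label"`.
#' @param cases_only If `TRUE` (default), summarize case samples only, the
#'   convention for reporting per-disease signature strength.
#' @return data.frame with columns `group`, `n`, `mean`, `sem` (SEM is the
#'   sample standard deviation over sqrt(n); `NA` for single-sample groups).
#' @export
summarize_scores <- function(scores, by = c("dataset_id", "disease_label"),
                             cases_only = TRUE) {
  by <- match.arg(by)
  stopifnot(is.data.frame(scores), by %in% colnames(scores))
  if (cases_only && "group" %in% colnames(scores)) {
    scores <- scores[scores$group == "case", , drop = FALSE]
  }
  if (nrow(scores) == 0L) stop("no rows to summarize")
  groups <- split(scores$ifn_score, scores[[by]])
  out <- data.frame(group = names(groups),
                    n = lengths(groups),
                    mean = vapply(groups, mean, 0),
                    sem = vapply(groups, function(v) {
                      if (length(v) < 2L) NA_real_
                      else stats::sd(v) / sqrt(length(v))
                    }, 0),
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Concordance between compact and full signature scores
#'
#' Computes per-sample IFN scores with the top `n_small` signature genes and
#' with the full signature (or its top `n_full`), and returns their Spearman
#' rank correlation across samples.
#'
#' @param folds A [fold_matrix()].
#' @param signature A `core_signature`.
#' @param n_small Size of the compact list (default 25).
#' @param n_full Size of the full list (default: the whole signature).
#' @return List with `rho`, `p`, `n` (see [spearman()]).
#' @export
score_concordance <- function(folds, signature, n_small = 25L,
                              n_full = NULL) {
  stopifnot(inherits(folds, "fold_matrix"),
            inherits(signature, "core_signature"))
  if (ncol(folds$folds) < 3L) stop("need at least 3 samples")
  if (is.null(n_full)) n_full <- nrow(signature)
  small <- ifn_score(folds, select_top_n(signature, n_small))
  full <- ifn_score(folds, select_top_n(signature, n_full))
  spearman(small$ifn_score, full$ifn_score)
}
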