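#' Changed genes on a single array
#'
#' Splits a sample's linear fold-change vector into induced
#' (`fold >= min_fold`) and repressed (`fold <= 1/min_fold`) gene sets.
#' Thresholds are inclusive and the two sets are disjoint for
#' `min_fold > 1`. Missing folds belong to neither set.
#'
#' @param folds Named numeric vector of positive linear fold changes.
#' @param min_fold Fold-change threshold (default 2).
#' @return List with character vectors `induced` and `repressed`.
#' @export
array_changed_genes <- function(folds, min_fold = 2) {
  stopifnot(min_fold >= 1, !is.null(names(folds)))
  if (any(folds <= 0, na.rm = TRUE)) stop("folds must be positive (linear)")
  list(induced = names(folds)[which(folds >= min_fold)],
       repressed = names(folds)[which(folds <= 1 / min_fold)])
}

#' Hypergeometric enrichment p-value (upper tail)
#'
#' Probability of observing `k` or more hits when drawing `n` genes without
#' replacement from a universe of `N` genes of which `K` belong to the set:
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#'
#' @param k Observed hits, `0 <= k <= min(K, n)`.
#' @param K Gene-set size within the universe.
#' @param n Number of changed genes drawn.
#' @param N Universe size.
#' @return The upper-tail probability (vectorized over its arguments).
#' @export
hypergeom_p <- function(k, K, n, N) {
  args <- cbind(k, K, n, N)
  k <- args[, 1L]; K <- args[, 2L]; n <- args[, 3L]; N <- args[, 4L]
  if (any(k < 0 | K < 0 | n < 0 | N < 0 | K > N | n > N | k > pmin(K, n))) {
    stop("inconsistent hypergeometric counts")
  }
  as.vector(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}

#' Per-array hypergeometric gene-set module map
#'
#' For every array (sample) and gene set, tests whether the set is
#' over-represented among that array's induced genes and, separately, among
#' its repressed genes (at least `min_fold` change), using the
#' hypergeometric upper tail over the universe of genes present in the fold
#' matrix. P-values are Benjamini-Hochberg adjusted across gene sets within
#' each array and direction; a call is made when the adjusted value is at
#' most `alpha`. If a set passes in both directions on one array (possible
#' when it straddles induced and repressed genes) the direction with the
#' smaller adjusted p-value wins. Gene sets are reported only when called on
#' at least `min_arrays` arrays. The display value for a call is the mean
#' log2 fold change of the set's changed genes on that array.
#'
#' @param folds A [fold_matrix()] (linear space).
#' @param sets Named list of gene-identifier vectors (e.g. [read_gmt()]).
#' @param min_fold Fold-change threshold defining changed genes (default 2).
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @param min_arrays Minimum number of arrays on which a set must be called
#'   to be reported (default 4).
#' @param min_set_size,max_set_fraction Sets smaller than `min_set_size`
#'   (default 5) or larger than `max_set_fraction` of the universe (default
#'   0.5) after intersection with the universe are skipped.
#' @return Object of class `module_map`: list with `table` (long-form
#'   data.frame: `set`, `array`, `direction`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   `mean_hit_expression`, `called`), `calls` (set x array character matrix
#'   of `"induced"`/`"repressed"`/`"none"`), `display` (set x array matrix
#'   of mean hit log2 folds for reported sets), `n_arrays_enriched`,
#'   `reported`, and the parameters.
#' @export
module_map <- function(folds, sets, min_fold = 2, alpha = 0.05,
                       min_arrays = 4L, min_set_size = 5L,
                       max_set_fraction = 0.5) {
  stopifnot(inherits(folds, "fold_matrix"), is.list(sets),
            !is.null(names(sets)))
  universe <- rownames(folds$folds)
  N <- length(universe)
  sets_u <- lapply(sets, intersect, universe)
  sizes <- lengths(sets_u)
  keep <- sizes >= min_set_size & sizes <= max_set_fraction * N
  sets_u <- sets_u[keep]
  if (length(sets_u) == 0L) {
    stop("no gene sets overlap the fold-matrix universe at usable sizes")
  }
  arrays <- colnames(folds$folds)
  rows <- vector("list", length(arrays))
  for (a in seq_along(arrays)) {
    fv <- folds$folds[, a]
    names(fv) <- universe
    changed <- array_changed_genes(fv, min_fold)
    per_dir <- lapply(c(induced = "induced", repressed = "repressed"),
                      function(dir) {
      ch <- changed[[dir]]
      n <- length(ch)
      k <- vapply(sets_u, function(s) length(intersect(s, ch)), 0L)
      p <- hypergeom_p(k, lengths(sets_u), n, N)
      q <- stats::p.adjust(p, method = "BH")
      mhe <- vapply(sets_u, function(s) {
        hits <- intersect(s, ch)
        if (length(hits) == 0L) NA_real_
        else mean(log2(fv[hits]), na.rm = TRUE)
      }, 0)
      data.frame(set = names(sets_u), array = arrays[a], direction = dir,
                 k = k, K = lengths(sets_u), n = n, N = N, p = p, q = q,
                 mean_hit_expression = mhe,
                 called = q <= alpha & k > 0L,
                 stringsAsFactors = FALSE, row.names = NULL)
    })
    both <- rbind(per_dir$induced, per_dir$repressed)
    # direction separation: keep at most one call per set per array
    dual <- intersect(per_dir$induced$set[per_dir$induced$called],
                      per_dir$repressed$set[per_dir$repressed$called])
    for (s in dual) {
      qi <- per_dir$induced$q[per_dir$induced$set == s]
      qr <- per_dir$repressed$q[per_dir$repressed$set == s]
      drop_dir <- if (qi <= qr) "repressed" else "induced"
      both$called[both$set == s & both$direction == drop_dir] <- FALSE
    }
    rows[[a]] <- both
  }
  tab <- do.call(rbind, rows)
  calls <- matrix("none", length(sets_u), length(arrays),
                  dimnames = list(names(sets_u), arrays))
  called_rows <- tab[tab$called, , drop = FALSE]
  calls[cbind(called_rows$set, called_rows$array)] <- called_rows$direction
  n_arrays_enriched <- rowSums(calls != "none")
  reported <- n_arrays_enriched >= min_arrays
  display <- matrix(NA_real_, length(sets_u), length(arrays),
                    dimnames = list(names(sets_u), arrays))
  disp_rows <- called_rows[reported[called_rows$set], , drop = FALSE]
  display[cbind(disp_rows$set, disp_rows$array)] <-
    disp_rows$mean_hit_expression
  structure(list(table = tab, calls = calls, display = display,
                 n_arrays_enriched = n_arrays_enriched, reported = reported,
                 params = list(min_fold = min_fold, alpha = alpha,
                               min_arrays = min_arrays,
                               min_set_size = min_set_size,
                               max_set_fraction = max_set_fraction)),
            class = "module_map")
}

#' @export
print.module_map <- function(x, ...) {
  cat("module map:", nrow(x$calls), "gene sets x", ncol(x$calls),
      "arrays\n")
  cat("  reported sets (called on >=", x$params$min_arrays, "arrays):",
      sum(x$reported), "\n")
  if (any(x$reported)) {
    for (s in names(which(x$reported))) {
      cat("   ", s, "-", x$n_arrays_enriched[[s]], "arrays\n")
    }
  }
  invisible(x)
}

#' Write a module map as TSV
#'
#' Writes the long-form enrichment table and the set x array display matrix.
#'
#' @param mm A `module_map`.
#' @param prefix Output path prefix; writes `<prefix>_table.tsv` and
#'   `<prefix>_display.tsv`.
#' @export
write_module_map <- function(mm, prefix) {
  stopifnot(inherits(mm, "module_map"))
  tab <- mm$table
  tab$reported <- mm$reported[tab$set]
  utils::write.table(tab, paste0(prefix, "_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  write_expression_matrix(mm$display, paste0(prefix, "_display.tsv"),
                          id_column = "set")
  invisible(prefix)
}
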