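#' Spearman rank correlation with exact small-sample p-values
#'
#' Computes the Spearman coefficient as the Pearson correlation of average
#' ranks (ties receive average ranks). For `n <= 10` the two-sided p-value
#' is exact, from the full permutation distribution of the rank inner
#' product (computed by exact dynamic programming over all `n!`
#' permutations); for larger `n` the usual t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` is used.
#'
#' @param x,y Numeric vectors; pairwise-complete observations are used and
#'   at least 3 are required.
#' @return List with `rho`, `p`, `n` and `method` (`"exact"` or
#'   `"t-approximation"`). A constant input yields `rho = NA` with a
#'   warning.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 10L) {
    p <- spearman_exact_p(rx, ry)
    method <- "exact"
  } else {
    den <- max(1 - rho^2, 0)
    if (den == 0) {
      p <- 0
    } else {
      tt <- rho * sqrt((n - 2) / den)
      p <- 2 * stats::pt(-abs(tt), df = n - 2)
    }
    method <- "t-approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

# Exact two-sided permutation p-value for the Spearman coefficient.
# rho is a fixed increasing affine function of S = sum(rx * ry[perm]), so
# P(|rho*| >= |rho_obs|) = P(|S* - c| >= |S_obs - c|) with c = n*mx*my.
# Doubled average ranks are integers, so the distribution of S (on the
# doubled scale) is tabulated exactly by a bitmask DP over assignments.
spearman_exact_p <- function(rx, ry) {
  n <- length(rx)
  stopifnot(n <= 12L)
  rx2 <- as.integer(round(2 * rx))
  ry2 <- as.integer(round(2 * ry))
  max_s <- sum(sort(rx2) * sort(ry2))
  full <- bitwShiftL(1L, n) - 1L
  pop <- vapply(0:full, function(m) {
    sum(bitwAnd(m, bitwShiftL(1L, 0:(n - 1L))) > 0L)
  }, 0L)
  counts <- vector("list", full + 1L)
  counts[[1L]] <- c(1, rep(0, max_s))
  for (m in order(pop)[-(full + 1L)]) {
    mask <- m - 1L  # order() gives 1-based positions over 0:full
    cm <- counts[[mask + 1L]]
    if (is.null(cm)) next
    i <- pop[mask + 1L] + 1L  # next x position to assign
    for (j in 0:(n - 1L)) {
      bit <- bitwShiftL(1L, j)
      if (bitwAnd(mask, bit) > 0L) next
      tgt <- mask + bit
      shift <- rx2[i] * ry2[j + 1L]
      tv <- counts[[tgt + 1L]]
      if (is.null(tv)) tv <- numeric(max_s + 1L)
      idx <- (shift + 1L):(max_s + 1L)
      tv[idx] <- tv[idx] + cm[seq_len(max_s + 1L - shift)]
      counts[[tgt + 1L]] <- tv
    }
    counts[mask + 1L] <- list(NULL)  # clear the slot without shrinking
  }
  dist <- counts[[full + 1L]]
  s_vals <- which(dist > 0) - 1L
  cnts <- dist[dist > 0]
  centre <- n * mean(rx2) * mean(ry2)
  s_obs <- sum(rx2 * ry2)
  hit <- abs(s_vals - centre) >= abs(s_obs - centre) - 1e-9
  sum(cnts[hit]) / sum(cnts)
}

#' Pairwise Spearman correlation matrix between arrays
#'
#' Computes the array x array Spearman correlation matrix over a gene
#' subset (e.g. a disease module or the core IFN signature), using
#' pairwise-complete observations. Pairs sharing fewer than 3 non-missing
#' genes are reported as missing.
#'
#' @param folds A [fold_matrix()].
#' @param genes Optional gene subset; default all genes.
#' @return Object of class `correlation_matrix`: list with `rho` (symmetric
#'   matrix, unit diagonal), `n_shared` (pairwise non-missing counts) and
#'   `cohorts` (per-array dataset labels).
#' @export
correlation_matrix <- function(folds, genes = NULL) {
  stopifnot(inherits(folds, "fold_matrix"))
  if (ncol(folds$folds) < 2L) stop("need at least 2 arrays")
  sub <- folds$folds
  if (!is.null(genes)) {
    genes <- intersect(genes, rownames(sub))
    if (length(genes) == 0L) stop("gene subset does not overlap the matrix")
    sub <- sub[genes, , drop = FALSE]
  }
  rho <- suppressWarnings(stats::cor(sub, method = "spearman",
                                     use = "pairwise.complete.obs"))
  n_shared <- crossprod(!is.na(sub))
  rho[n_shared < 3L] <- NA_real_
  diag(rho) <- 1
  structure(list(rho = rho, n_shared = n_shared,
                 cohorts = stats::setNames(folds$manifest$dataset_id,
                                           folds$manifest$sample_id)),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("correlation_matrix:", nrow(x$rho), "arrays,",
      length(unique(x$cohorts)), "cohort(s)\n")
  off <- x$rho[upper.tri(x$rho)]
  cat(sprintf("  off-diagonal rho: median %.3f [%.3f, %.3f]\n",
              stats::median(off, na.rm = TRUE),
              min(off, na.rm = TRUE), max(off, na.rm = TRUE)))
  invisible(x)
}

#' Iterative SVD imputation of missing values
#'
#' svdImpute-style scheme: missing entries are initialized with row means,
#' then repeatedly replaced by the corresponding entries of the rank-`k`
#' truncated SVD reconstruction of the filled matrix, until the relative
#' change of the imputed entries falls below `tol` or `max_iter` is reached.
#' Observed entries are never modified.
#'
#' @param x Numeric matrix with missing values; every row and column must
#'   have at least one observed entry.
#' @param k Reconstruction rank. Default: the number of components capturing
#'   at least 90% of the variance of the complete rows, capped at 10.
#' @param max_iter Maximum number of iterations (default 100).
#' @param tol Relative-change convergence tolerance (default 1e-5).
#' @return The completed matrix with attributes `iterations`, `converged`
#'   and `delta_history` (per-iteration relative change of the imputed
#'   entries). A warning is issued on non-convergence.
#' @export
svd_impute <- function(x, k = NULL, max_iter = 100L, tol = 1e-5) {
  stopifnot(is.matrix(x))
  miss <- is.na(x)
  if (!any(miss)) {
    attr(x, "iterations") <- 0L
    attr(x, "converged") <- TRUE
    attr(x, "delta_history") <- numeric(0)
    return(x)
  }
  if (any(rowSums(!miss) == 0L)) stop("a row has no observed values")
  if (any(colSums(!miss) == 0L)) stop("a column has no observed values")
  if (is.null(k)) k <- choose_impute_rank(x, miss)
  k <- as.integer(max(1L, min(k, nrow(x), ncol(x))))
  filled <- x
  rm_ <- rowMeans(x, na.rm = TRUE)
  filled[miss] <- rm_[row(x)[miss]]
  prev <- filled[miss]
  deltas <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    sv <- svd(filled, nu = k, nv = k)
    recon <- sv$u %*% (sv$d[seq_len(k)] * t(sv$v))
    filled[miss] <- recon[miss]
    cur <- filled[miss]
    delta <- sqrt(sum((cur - prev)^2)) /
      max(sqrt(sum(prev^2)), .Machine$double.eps)
    deltas <- c(deltas, delta)
    prev <- cur
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("svd_impute did not converge in ", max_iter, " iterations ",
            "(last relative change ", signif(deltas[length(deltas)], 3), ")")
  }
  out <- x
  out[miss] <- filled[miss]
  attr(out, "iterations") <- it
  attr(out, "converged") <- converged
  attr(out, "delta_history") <- deltas
  out
}

choose_impute_rank <- function(x, miss, var_target = 0.9, cap = 10L) {
  complete <- x[rowSums(miss) == 0L, , drop = FALSE]
  basis <- if (nrow(complete) >= 2L) {
    complete
  } else {
    filled <- x
    rm_ <- rowMeans(x, na.rm = TRUE)
    filled[miss] <- rm_[row(x)[miss]]
    filled
  }
  d2 <- svd(scale(t(basis), center = TRUE, scale = FALSE), nu = 0,
            nv = 0)$d^2
  if (sum(d2) == 0) return(1L)
  k <- which(cumsum(d2) / sum(d2) >= var_target)[1L]
  min(max(k, 1L), cap)
}

#' Principal components analysis of an expression matrix
#'
#' SVD-based PCA of a complete (post-imputation) gene x sample matrix with
#' samples as observations and genes as variables; columns (genes) are
#' centered by default and not scaled, mirroring `prcomp` defaults.
#'
#' @param x Complete numeric gene x sample matrix (log2 fold changes by
#'   default convention).
#' @param center,scale. Passed to [stats::prcomp()].
#' @return Object of class `ifn_pca`: list with `scores` (samples x
#'   components), `loadings` (genes x components), `variance_fraction`, and
#'   the underlying `prcomp` fit.
#' @export
pca_expression <- function(x, center = TRUE, scale. = FALSE) {
  stopifnot(is.matrix(x), ncol(x) >= 2L)
  if (anyNA(x)) stop("matrix has missing values; impute first (svd_impute)")
  obs <- t(x)
  v <- apply(obs, 2L, stats::var)
  if (all(v == 0)) stop("matrix has rank 0 after centering")
  if (scale. && any(v == 0)) {
    obs <- obs[, v > 0, drop = FALSE]
  }
  pr <- stats::prcomp(obs, center = center, scale. = scale.)
  vf <- pr$sdev^2 / sum(pr$sdev^2)
  structure(list(scores = pr$x, loadings = pr$rotation,
                 variance_fraction = vf, prcomp = pr),
            class = "ifn_pca")
}

#' @export
print.ifn_pca <- function(x, ...) {
  cat("PCA:", nrow(x$scores), "samples,", nrow(x$loadings), "genes\n")
  k <- min(5L, length(x$variance_fraction))
  cat("  variance fractions:",
      paste(sprintf("PC%d %.1f%%", seq_len(k),
                    100 * x$variance_fraction[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.ifn_pca <- function(x, components = c(1L, 2L), col = 1, pch = 19,
                         ...) {
  vf <- 100 * x$variance_fraction[components]
  plot(x$scores[, components[1L]], x$scores[, components[2L]],
       xlab = sprintf("PC%d (%.1f%%)", components[1L], vf[1L]),
       ylab = sprintf("PC%d (%.1f%%)", components[2L], vf[2L]),
       col = col, pch = pch, ...)
  invisible(x)
}

#' Relative abundance by the delta-delta-Ct method
#'
#' `2^-ddCt` with `ddCt = (target_ct - reference_ct) -
#' (calibrator_target_ct - calibrator_reference_ct)`: qPCR threshold cycles
#' of the target gene are normalized to a reference gene (e.g. GAPDH) and to
#' a calibrator sample.
#'
#' @param target_ct,reference_ct Threshold cycles for the target and
#'   reference gene in the sample of interest.
#' @param calibrator_target_ct,calibrator_reference_ct The same for the
#'   calibrator sample.
#' @return Relative abundance (vectorized).
#' @export
ddct <- function(target_ct, reference_ct, calibrator_target_ct,
                 calibrator_reference_ct) {
  args <- cbind(target_ct, reference_ct, calibrator_target_ct,
                calibrator_reference_ct)
  if (any(!is.finite(args))) stop("Ct values must be finite")
  ddct_val <- (args[, 1L] - args[, 2L]) - (args[, 3L] - args[, 4L])
  as.vector(2^(-ddct_val))
}

#' Correlate transcript abundances with the IFN score
#'
#' For each transcript (column of `transcripts`), computes the Spearman
#' correlation of its relative abundance with the per-sample IFN score
#' across the samples shared by both tables.
#'
#' @param scores An `ifn_scores` data.frame (see [ifn_score()]).
#' @param transcripts Numeric matrix or data.frame of per-sample relative
#'   abundances, one column per transcript, with sample identifiers as
#'   rownames.
#' @return data.frame with columns `transcript`, `rho`, `p`, `n`.
#' @export
transcript_score_correlation <- function(scores, transcripts) {
  stopifnot(is.data.frame(scores), "ifn_score" %in% colnames(scores))
  tm <- as.matrix(transcripts)
  if (is.null(rownames(tm))) stop("transcripts must have sample rownames")
  shared <- intersect(scores$sample_id, rownames(tm))
  if (length(shared) == 0L) stop("no shared samples between tables")
  if (length(shared) < 3L) stop("need at least 3 shared samples")
  sc <- scores$ifn_score[match(shared, scores$sample_id)]
  out <- lapply(colnames(tm), function(tr) {
    r <- spearman(tm[shared, tr], sc)
    data.frame(transcript = tr, rho = r$rho, p = r$p, n = r$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
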