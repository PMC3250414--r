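#' SAM-style moderated difference statistic
#'
#' Computes, per gene, `d = (mean2 - mean1) / (s + s0)` where `s` is the
#' pooled (equal-variance) standard error of the difference of class means
#' and `s0` is a variance-stabilizing fudge factor. Genes with zero variance
#' in both classes and `s0 = 0` have undefined `d` and are reported as
#' missing with a warning.
#'
#' @param x Numeric gene x sample matrix (typically log2 values).
#' @param classes Vector of two class labels, one per column of `x`. The
#'   statistic is oriented as second level minus first level (levels in
#'   factor order).
#' @param s0 Fudge factor, `>= 0`.
#' @return Numeric vector of d statistics (one per gene), with attributes
#'   `numerator` (difference of class means) and `se` (pooled standard
#'   error).
#' @export
sam_statistic <- function(x, classes, s0 = 0) {
  parts <- sam_parts(x, classes)
  stopifnot(s0 >= 0)
  d <- parts$r / (parts$s + s0)
  undef <- parts$s == 0 & s0 == 0
  if (any(undef, na.rm = TRUE)) {
    warning(sum(undef, na.rm = TRUE),
            " gene(s) with zero variance and s0 = 0: d undefined")
    d[undef] <- NA_real_
  }
  attr(d, "numerator") <- parts$r
  attr(d, "se") <- parts$s
  d
}

# Numerator r (mean2 - mean1) and pooled SE s for each gene, computed over
# the samples observed (non-missing) for that gene. Genes with fewer than
# two observed samples in either class get NA statistics.
sam_parts <- function(x, classes) {
  stopifnot(is.matrix(x), length(classes) == ncol(x))
  classes <- as.factor(classes)
  if (nlevels(classes) != 2L) stop("exactly two classes required")
  i1 <- which(classes == levels(classes)[1L])
  i2 <- which(classes == levels(classes)[2L])
  if (length(i1) < 2L || length(i2) < 2L) {
    stop("at least 2 samples per class required for variance estimation")
  }
  obs <- !is.na(x)
  n1 <- rowSums(obs[, i1, drop = FALSE])
  n2 <- rowSums(obs[, i2, drop = FALSE])
  m1 <- rowMeans(x[, i1, drop = FALSE], na.rm = TRUE)
  m2 <- rowMeans(x[, i2, drop = FALSE], na.rm = TRUE)
  ss1 <- rowSums((x[, i1, drop = FALSE] - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((x[, i2, drop = FALSE] - m2)^2, na.rm = TRUE)
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  r <- m2 - m1
  few <- n1 < 2L | n2 < 2L
  if (any(few)) {
    r[few] <- NA_real_
    s[few] <- NA_real_
  }
  list(r = r, s = s, n1 = length(i1), n2 = length(i2),
       levels = levels(classes), i1 = i1, i2 = i2)
}

#' Choose the SAM fudge factor s0
#'
#' Evaluates candidate values of `s0` at the percentiles 0, 5, ..., 100 of
#' the per-gene pooled standard errors and picks the candidate minimizing the
#' coefficient of variation of the median absolute deviation of `d` across
#' bins of `s`. If the standard-error distribution is degenerate (all equal)
#' the ordering of `d` does not depend on `s0` and 0 is returned with a
#' warning.
#'
#' @inheritParams sam_statistic
#' @param override If non-`NULL`, returned as-is (configuration passthrough).
#' @param n_bins Number of quantile bins of `s` used to assess spread
#'   stability (default 20, reduced for small gene counts).
#' @return The chosen `s0` (scalar, `>= 0`).
#' @export
choose_s0 <- function(x, classes, override = NULL, n_bins = 20L) {
  if (!is.null(override)) {
    stopifnot(is.numeric(override), override >= 0)
    return(override)
  }
  parts <- sam_parts(x, classes)
  if (nrow(x) < 10L) stop("at least 10 genes required to choose s0")
  ok <- which(!is.na(parts$s))
  s <- parts$s[ok]
  r <- parts$r[ok]
  if (length(s) < 10L ||
      max(s) - min(s) < .Machine$double.eps * max(1, max(s))) {
    warning("degenerate standard-error distribution; s0 = 0")
    return(0)
  }
  cands <- unique(stats::quantile(s, probs = seq(0, 1, by = 0.05),
                                  names = FALSE))
  n_bins <- max(2L, min(n_bins, floor(length(s) / 5)))
  bins <- cut(rank(s, ties.method = "first"), breaks = n_bins,
              labels = FALSE)
  cv <- vapply(cands, function(a) {
    d <- r / (s + a)
    mads <- vapply(split(d, bins), stats::mad, 0, na.rm = TRUE)
    m <- mean(mads)
    if (m == 0) Inf else stats::sd(mads) / m
  }, 0)
  cands[which.min(cv)]
}

#' Permutation-based SAM differential expression
#'
#' Two-class SAM: computes the moderated d statistic, builds a permutation
#' null by relabelling samples (exhaustively when the number of distinct
#' label assignments does not exceed `n_perm`), estimates the expected number
#' of false calls at each symmetric |d| threshold as the median permuted
#' exceedance count scaled by an estimate of the true-null proportion pi0
#' (from the fraction of observed d falling in the central 50% of the
#' permuted distribution), and selects the smallest threshold whose
#' estimated FDR does not exceed the target.
#'
#' Per-gene q-values are the minimum estimated FDR over all thresholds at or
#' below the gene's |d|. Ties in |d| at the selected threshold are called
#' significant. The mean fold change is the ratio of linear-space class
#' means (second class over first).
#'
#' @inheritParams sam_statistic
#' @param fdr Target false discovery rate in (0, 1]; a target of 1 calls
#'   every gene with a defined d.
#' @param n_perm Number of label permutations (default 1000).
#' @param s0 Fudge factor; `NULL` (default) selects it via [choose_s0()].
#' @param seed Optional integer seed for the permutation draw.
#' @param space Space of `x` for the fold-change computation: `"log2"`
#'   (default; folds use `2^x`) or `"linear"`.
#' @return Object of class `sam_fit`: a list with `table` (data.frame with
#'   columns `gene`, `d`, `mean_fold`, `q_value`, `significant`,
#'   `direction`), the selected `threshold`, `pi0`, `s0`, `n_perm`,
#'   `exhaustive` flag, class `levels`, and the `fdr` target.
#' @export
sam_fdr <- function(x, classes, fdr = 0.05, n_perm = 1000L, s0 = NULL,
                    seed = NULL, space = c("log2", "linear")) {
  space <- match.arg(space)
  stopifnot(fdr > 0, fdr <= 1, n_perm >= 1)
  parts <- sam_parts(x, classes)
  n <- ncol(x)
  n2 <- length(parts$i2)
  if (length(parts$i1) == 1L && n2 == 1L) {
    stop("both classes of size 1: no permutation null available")
  }
  if (is.null(s0)) s0 <- choose_s0(x, classes)
  d <- parts$r / (parts$s + s0)
  undef <- !is.na(parts$s) & parts$s == 0 & s0 == 0
  if (any(undef)) {
    warning(sum(undef), " gene(s) with undefined d excluded")
    d[undef] <- NA_real_
  }

  n_distinct <- choose(n, n2)
  exhaustive <- n_distinct <= n_perm
  if (exhaustive) {
    assign2 <- utils::combn(n, n2)
  } else {
    if (!is.null(seed)) {
      old_seed <- get0(".Random.seed", envir = globalenv())
      on.exit(if (!is.null(old_seed))
        assign(".Random.seed", old_seed, envir = globalenv()))
      set.seed(seed)
    }
    assign2 <- replicate(n_perm, sample.int(n, n2))
  }
  B <- ncol(assign2)
  # indicator matrices (samples x permutations) for class-2 membership
  ind2 <- matrix(0, n, B)
  ind2[cbind(as.vector(assign2), rep(seq_len(B), each = n2))] <- 1
  ind1 <- 1 - ind2
  obs <- !is.na(x)
  x0 <- x
  x0[!obs] <- 0
  # per-gene per-permutation observed counts, means and sums of squares
  n1p <- obs %*% ind1
  n2p <- obs %*% ind2
  m1p <- (x0 %*% ind1) / n1p
  m2p <- (x0 %*% ind2) / n2p
  ss1 <- (x0^2 %*% ind1) - n1p * m1p^2
  ss2 <- (x0^2 %*% ind2) - n2p * m2p^2
  ss1[ss1 < 0] <- 0
  ss2[ss2 < 0] <- 0
  sp <- sqrt((1 / n1p + 1 / n2p) * (ss1 + ss2) / (n1p + n2p - 2))
  dp <- (m2p - m1p) / (sp + s0)
  dp[sp == 0 & s0 == 0] <- NA
  dp[n1p < 2 | n2p < 2] <- NA

  # pi0 from the central 50% of the permuted distribution
  qq <- stats::quantile(dp, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  pi0 <- min(1, mean(d >= qq[1L] & d <= qq[2L], na.rm = TRUE) / 0.5)
  if (!is.finite(pi0)) pi0 <- 1

  ok <- which(!is.na(d))
  absd <- abs(d[ok])
  ord <- order(absd, decreasing = TRUE)
  thresholds <- absd[ord]
  adp <- abs(dp)
  # expected false calls at each threshold: median over permutations of the
  # per-permutation exceedance count #{|d*| >= t}, computed via binary
  # search on each sorted permutation column
  exceed <- vapply(seq_len(B), function(b) {
    s <- sort(adp[, b])  # drops NAs
    length(s) - findInterval(thresholds, s, left.open = TRUE)
  }, numeric(length(thresholds)))
  if (is.null(dim(exceed))) exceed <- matrix(exceed, nrow = 1L)
  false_at <- apply(exceed, 1L, stats::median)
  called_at <- seq_along(thresholds)
  fdr_at <- pmin(1, pi0 * false_at / called_at)
  # q for gene ranked i: min FDR over thresholds at or below its |d|
  q_sorted <- rev(cummin(rev(fdr_at)))
  q <- rep(NA_real_, length(d))
  q[ok[ord]] <- q_sorted

  hit <- which(fdr_at <= fdr)
  threshold <- if (length(hit)) unname(thresholds[max(hit)]) else Inf
  significant <- !is.na(d) & abs(d) >= threshold

  lin <- if (space == "log2") 2^x else x
  mf <- rowMeans(lin[, parts$i2, drop = FALSE], na.rm = TRUE) /
        rowMeans(lin[, parts$i1, drop = FALSE], na.rm = TRUE)
  direction <- ifelse(is.na(d), NA_character_,
                      ifelse(d >= 0, "up", "down"))
  genes <- rownames(x)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(x)))
  tab <- data.frame(gene = genes, d = as.vector(d), mean_fold = mf,
                    q_value = q, significant = significant,
                    direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, threshold = threshold, pi0 = pi0, s0 = s0,
                 n_perm = B, exhaustive = exhaustive,
                 levels = parts$levels, fdr = fdr),
            class = "sam_fit")
}

#' @export
print.sam_fit <- function(x, ...) {
  cat("SAM two-class fit (", x$levels[2L], " vs ", x$levels[1L], ")\n",
      sep = "")
  cat("  genes:", nrow(x$table),
      " permutations:", x$n_perm,
      if (x$exhaustive) "(exhaustive)" else "", "\n")
  cat(sprintf("  s0 = %.4g, pi0 = %.3f, |d| threshold = %.4g (FDR target %g)\n",
              x$s0, x$pi0, x$threshold, x$fdr))
  cat("  significant:", sum(x$table$significant, na.rm = TRUE), "genes\n")
  invisible(x)
}

#' @export
summary.sam_fit <- function(object, ...) {
  sig <- object$table[object$table$significant, ]
  out <- list(n_significant = nrow(sig),
              n_up = sum(sig$direction == "up"),
              n_down = sum(sig$direction == "down"),
              threshold = object$threshold, pi0 = object$pi0,
              s0 = object$s0, fdr = object$fdr)
  class(out) <- "summary.sam_fit"
  out
}

#' @export
print.summary.sam_fit <- function(x, ...) {
  cat("significant genes:", x$n_significant,
      "(", x$n_up, "up /", x$n_down, "down ) at FDR target", x$fdr, "\n")
  invisible(x)
}

#' Derive a disease gene module from a fold-change matrix
#'
#' Runs SAM (case vs control, per the manifest carried by the fold matrix)
#' and retains significant genes whose mean fold change (ratio of class
#' means, case over control) is at least `min_fold` or at most
#' `1/min_fold`, partitioned into up- and down-regulated lists.
#'
#' @param folds A [fold_matrix()] containing both cases and controls.
#' @param fdr Target FDR (default 0.05; the stricter 0.043 used in parts of
#'   the original analyses is a documented alternative).
#' @param min_fold Minimum mean linear fold change (default 2); the
#'   threshold is strict at the boundary in neither direction (`>=` and
#'   `<=` of the reciprocal).
#' @param n_perm,s0,seed Passed to [sam_fdr()].
#' @return Object of class `disease_module`: list with data.frames `up` and
#'   `down` (columns `gene`, `mean_fold`, `d`, `q_value`), the full
#'   `sam_fit`, and `counts` (significant / up / down).
#' @export
derive_disease_module <- function(folds, fdr = 0.05, min_fold = 2,
                                  n_perm = 1000L, s0 = NULL, seed = NULL) {
  stopifnot(inherits(folds, "fold_matrix"), min_fold >= 1)
  classes <- factor(folds$manifest$group, levels = c("control", "case"))
  fit <- sam_fdr(log2(folds$folds), classes, fdr = fdr, n_perm = n_perm,
                 s0 = s0, seed = seed, space = "log2")
  tab <- fit$table
  pass <- tab$significant &
    (tab$mean_fold >= min_fold | tab$mean_fold <= 1 / min_fold)
  pass[is.na(pass)] <- FALSE
  cols <- c("gene", "mean_fold", "d", "q_value")
  up <- tab[pass & tab$mean_fold >= min_fold, cols]
  down <- tab[pass & tab$mean_fold <= 1 / min_fold, cols]
  up <- up[order(-up$mean_fold, up$gene), ]
  down <- down[order(down$mean_fold, down$gene), ]
  rownames(up) <- rownames(down) <- NULL
  structure(list(up = up, down = down, fit = fit,
                 counts = c(significant = sum(tab$significant, na.rm = TRUE),
                            module = nrow(up) + nrow(down),
                            up = nrow(up), down = nrow(down)),
                 min_fold = min_fold, fdr = fdr),
            class = "disease_module")
}

#' @export
print.disease_module <- function(x, ...) {
  cat("disease module (FDR target ", x$fdr, ", min fold ", x$min_fold,
      "):\n", sep = "")
  cat("  SAM-significant genes:", x$counts[["significant"]], "\n")
  cat("  module genes:", x$counts[["module"]],
      "(", x$counts[["up"]], "up /", x$counts[["down"]], "down )\n")
  invisible(x)
}
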