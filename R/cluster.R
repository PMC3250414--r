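#' Uncentered correlation similarity
#'
#' The Cluster-3.0 "uncentered" metric:
#' `sum(x*y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))` — the cosine similarity,
#' i.e. a correlation computed with both means assumed zero. Only
#' pairwise-complete entries are used. Undefined (zero-norm vector) results
#' are reported as missing with a warning.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Similarity in `[-1, 1]`, or `NA` when undefined.
#' @export
uncentered_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) {
    warning("no pairwise-complete observations")
    return(NA_real_)
  }
  x <- x[ok]; y <- y[ok]
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    warning("zero-norm vector: uncentered correlation undefined")
    return(NA_real_)
  }
  sum(x * y) / (nx * ny)
}

# Leaf x leaf similarity matrix for the chosen metric. Rows of x are leaves.
similarity_matrix <- function(x, metric = c("uncentered", "centered",
                                            "euclidean")) {
  metric <- match.arg(metric)
  if (metric == "euclidean") {
    return(-as.matrix(stats::dist(x)))
  }
  if (metric == "centered") {
    return(suppressWarnings(stats::cor(t(x),
                                       use = "pairwise.complete.obs")))
  }
  n <- nrow(x)
  if (!anyNA(x)) {
    nrm <- sqrt(rowSums(x^2))
    s <- tcrossprod(x) / outer(nrm, nrm)
    s[nrm == 0, ] <- NA_real_
    s[, nrm == 0] <- NA_real_
    return(s)
  }
  s <- matrix(NA_real_, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n)) {
    s[i, i] <- 1
    for (j in seq_len(i - 1L)) {
      s[i, j] <- s[j, i] <-
        suppressWarnings(uncentered_correlation(x[i, ], x[j, ]))
    }
  }
  s
}

#' Average-linkage hierarchical clustering on a similarity metric
#'
#' Agglomerative UPGMA clustering operating on similarities (not distances),
#' following the semantics of the Cluster 3.0 program: at each step the pair
#' of clusters with the highest average cross-pair similarity is merged.
#' Ties are broken deterministically by merging the pair whose sorted pair
#' of smallest member leaf indices is lexicographically smallest. Exported
#' merge heights are `1 - similarity`.
#'
#' @param x Numeric matrix; leaves are rows when `axis = "genes"`, columns
#'   when `axis = "samples"`. Alternatively a precomputed symmetric
#'   similarity matrix may be supplied with `metric = "precomputed"`.
#' @param metric Similarity metric: `"uncentered"` correlation (default),
#'   `"centered"` (Pearson) correlation, `"euclidean"` (negated distance),
#'   or `"precomputed"`.
#' @param axis Which margin of `x` holds the leaves.
#' @return Object of class `cluster_tree`: list with `merge` (hclust-style,
#'   negative entries are leaves), `similarity` (at each merge), `height`
#'   (`1 - similarity`), `order`, `labels`, `axis`, `metric`.
#' @export
average_linkage <- function(x, metric = c("uncentered", "centered",
                                          "euclidean", "precomputed"),
                            axis = c("genes", "samples")) {
  metric <- match.arg(metric)
  axis <- match.arg(axis)
  if (metric == "precomputed") {
    stopifnot(is.matrix(x), nrow(x) == ncol(x))
    sim <- x
  } else {
    if (axis == "samples") x <- t(x)
    sim <- similarity_matrix(x, metric)
  }
  n <- nrow(sim)
  if (n < 2L) stop("need at least 2 leaves")
  labels <- rownames(sim)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  off_missing <- is.na(sim) & !diag(TRUE, n)
  bad <- which(rowSums(off_missing) == n - 1L)
  if (length(bad)) {
    stop("leaf ", labels[bad[1L]], " has no defined similarity to any ",
         "other leaf")
  }
  S <- sim
  S[is.na(S)] <- -Inf
  diag(S) <- -Inf

  active <- rep(TRUE, n)
  size <- rep(1L, n)
  minleaf <- seq_len(n)    # smallest original leaf index in each cluster
  node <- -seq_len(n)      # hclust code of each active cluster
  merge <- matrix(0L, n - 1L, 2L)
  simil <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- S[idx, idx, drop = FALSE]
    mx <- max(sub)
    cand <- which(sub == mx, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    keys <- cbind(pmin(minleaf[idx[cand[, 1L]]], minleaf[idx[cand[, 2L]]]),
                  pmax(minleaf[idx[cand[, 1L]]], minleaf[idx[cand[, 2L]]]))
    pick <- order(keys[, 1L], keys[, 2L])[1L]
    i <- idx[cand[pick, 1L]]
    j <- idx[cand[pick, 2L]]
    if (minleaf[j] < minleaf[i]) { tmp <- i; i <- j; j <- tmp }
    merge[step, ] <- c(node[i], node[j])
    simil[step] <- mx
    # average-linkage update into slot i
    others <- setdiff(idx, c(i, j))
    if (length(others)) {
      S[i, others] <- S[others, i] <-
        (size[i] * S[i, others] + size[j] * S[j, others]) /
        (size[i] + size[j])
    }
    size[i] <- size[i] + size[j]
    minleaf[i] <- min(minleaf[i], minleaf[j])
    node[i] <- step
    active[j] <- FALSE
    S[j, ] <- S[, j] <- -Inf
  }
  unpack <- function(k) {
    if (k < 0L) -k else c(unpack(merge[k, 1L]), unpack(merge[k, 2L]))
  }
  structure(list(merge = merge, similarity = simil,
                 height = 1 - simil, order = unpack(n - 1L),
                 labels = labels, axis = axis, metric = metric),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat("cluster_tree:", length(x$labels), "leaves (", x$axis,
      "),", x$metric, "similarity, average linkage\n")
  cat(sprintf("  merge similarities: first %.4f, last %.4f\n",
              x$similarity[1L], x$similarity[length(x$similarity)]))
  invisible(x)
}

#' Convert a cluster_tree to an hclust object
#'
#' Heights are `1 - similarity`; tiny non-monotonicities from floating-point
#' averaging are flattened so the object plots cleanly.
#'
#' @param x A `cluster_tree`.
#' @param ... Ignored.
#' @return An object of class `hclust`.
#' @exportS3Method stats::as.hclust
as.hclust.cluster_tree <- function(x, ...) {
  structure(list(merge = x$merge, height = cummax(x$height),
                 order = x$order, labels = x$labels,
                 method = "average", call = match.call(),
                 dist.method = x$metric),
            class = "hclust")
}

#' @export
plot.cluster_tree <- function(x, ...) {
  plot(stats::as.hclust(x), ...)
  invisible(x)
}

#' Export a clustering in Java TreeView format
#'
#' Writes a CDT file (clustered data table, rows in leaf order) and a GTR
#' (gene tree) or ATR (array tree) file with `GENE<i>X`/`ARRY<i>X` leaf
#' identifiers, `NODE<k>X` internal nodes, and merge similarities as node
#' correlation values.
#'
#' @param tree A `cluster_tree`.
#' @param x The matrix that was clustered (leaves on the axis recorded in
#'   the tree).
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_treeview <- function(tree, x, prefix) {
  stopifnot(inherits(tree, "cluster_tree"))
  if (tree$axis == "samples") x <- t(x)
  if (!identical(rownames(x), tree$labels)) {
    x <- x[tree$labels, , drop = FALSE]
  }
  leaf_tag <- if (tree$axis == "genes") "GENE" else "ARRY"
  n <- length(tree$labels)
  code <- function(k) {
    if (k < 0L) paste0(leaf_tag, -k - 1L, "X") else paste0("NODE", k, "X")
  }
  tre <- data.frame(
    NODEID = paste0("NODE", seq_len(n - 1L), "X"),
    LEFT = vapply(tree$merge[, 1L], code, ""),
    RIGHT = vapply(tree$merge[, 2L], code, ""),
    CORRELATION = tree$similarity, stringsAsFactors = FALSE)
  tre_path <- paste0(prefix, if (tree$axis == "genes") ".gtr" else ".atr")
  utils::write.table(tre, tre_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  ord <- tree$order
  cdt <- data.frame(GID = paste0(leaf_tag, ord - 1L, "X"),
                    NAME = tree$labels[ord], GWEIGHT = 1,
                    x[ord, , drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE)
  cdt_path <- paste0(prefix, ".cdt")
  utils::write.table(cdt, cdt_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(c(cdt_path, tre_path))
}
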