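# Shared fixture builders and independent brute-force oracles.

make_manifest <- function(sample_ids, groups, dataset = "D1",
                          disease = "disease") {
  data.frame(sample_id = sample_ids, dataset_id = dataset,
             group = groups,
             disease_label = ifelse(groups == "case", disease, "healthy"),
             tissue = "skin", platform_id = paste0("pf_", dataset),
             stringsAsFactors = FALSE)
}

make_folds <- function(folds, groups, dataset = "D1") {
  fold_matrix(folds, make_manifest(colnames(folds), groups, dataset))
}

# all n! permutations of 1..n as an (n!, n) matrix, built iteratively
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[p], nrow(p)))
  }))
}

# exact two-sided Spearman permutation p by explicit enumeration
spearman_brute_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(rx)
  perms <- all_perms(n)
  rho_obs <- stats::cor(rx, ry)
  rhos <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
  mean(abs(rhos) >= abs(rho_obs) - 1e-9)
}

# hypergeometric upper tail by enumerating all C(N, n) draws
hyper_enum_draws <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # items 1..K are the set members
  mean(hits >= k)
}

# hypergeometric upper tail by direct summation of choose products
hyper_enum_sum <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# brute-force UPGMA on a similarity matrix: cluster-cluster similarity is
# recomputed from scratch as the mean over all cross pairs of the original
# matrix; same deterministic tie-break as the implementation
upgma_oracle <- function(sim) {
  n <- nrow(sim)
  clusters <- as.list(seq_len(n))
  merges <- list()
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        s <- mean(sim[clusters[[i]], clusters[[j]]])
        key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        if (is.null(best) || s > best$s + 1e-12 ||
            (abs(s - best$s) <= 1e-12 &&
             (key[1L] < best$key[1L] ||
              (key[1L] == best$key[1L] && key[2L] < best$key[2L])))) {
          best <- list(i = i, j = j, s = s, key = key)
        }
      }
    }
    merges[[length(merges) + 1L]] <-
      list(members = sort(c(clusters[[best$i]], clusters[[best$j]])),
           similarity = best$s)
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  merges
}

# member sets at each merge of a cluster_tree, for comparison with the oracle
tree_merge_members <- function(tree) {
  n <- length(tree$labels)
  members <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    get_m <- function(code) {
      if (code < 0L) -code else members[[code]]
    }
    members[[k]] <- sort(c(get_m(tree$merge[k, 1L]),
                           get_m(tree$merge[k, 2L])))
  }
  members
}

# exhaustive SAM oracle for small two-class designs: enumerates every
# distinct label assignment and follows the documented FDR estimator
# step by step with scalar loops
sam_brute <- function(x, classes, s0, fdr) {
  cl <- as.factor(classes)
  i1 <- which(cl == levels(cl)[1L]); i2 <- which(cl == levels(cl)[2L])
  n <- ncol(x); n1 <- length(i1); n2 <- length(i2)
  dstat <- function(idx2) {
    idx1 <- setdiff(seq_len(n), idx2)
    vapply(seq_len(nrow(x)), function(g) {
      a <- x[g, idx1]; b <- x[g, idx2]
      s <- sqrt((1 / length(a) + 1 / length(b)) *
                (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
                (n - 2))
      (mean(b) - mean(a)) / (s + s0)
    }, 0)
  }
  d <- dstat(i2)
  assigns <- utils::combn(n, n2)
  dp <- apply(assigns, 2L, dstat)
  qs <- stats::quantile(dp, c(0.25, 0.75), names = FALSE)
  pi0 <- min(1, mean(d >= qs[1L] & d <= qs[2L]) / 0.5)
  ord <- order(abs(d), decreasing = TRUE)
  thresholds <- abs(d)[ord]
  fdr_at <- vapply(seq_along(thresholds), function(i) {
    t <- thresholds[i]
    false <- stats::median(apply(dp, 2L, function(col) sum(abs(col) >= t)))
    min(1, pi0 * false / i)
  }, 0)
  q <- rep(NA_real_, length(d))
  q[ord] <- rev(cummin(rev(fdr_at)))
  hit <- which(fdr_at <= fdr)
  threshold <- if (length(hit)) thresholds[max(hit)] else Inf
  list(d = d, q = q, pi0 = pi0, threshold = threshold,
       significant = abs(d) >= threshold)
}

withr_tempfile <- function() {
  path <- tempfile(fileext = ".tsv")
  path
}

annotation_list_for_test <- function(annotation) {
  ifnscore:::annotation_list(annotation)
}

# tiny hand-built signature for io round-trips
derive_signature_fixture <- function() {
  ifnscore:::new_core_signature(
    genes = c("gC", "gA", "gB", "gD"),
    mean_fold = c(8, 8, 4, 2.5),
    counts = c(significant = 10L, min_fold = 6L, comparison = 4L))
}

# exact two-sided Spearman permutation p at n = 10 by chunked enumeration:
# fix the y-index of position 1, enumerate the 9! arrangements of the rest
spearman_brute_p10 <- function(x, y) {
  stopifnot(length(x) == 10L)
  rx <- rank(x); ry <- rank(y)
  p9 <- all_perms(9L)
  s_obs <- sum(rx * ry)
  centre <- 10 * mean(rx) * mean(ry)
  cnt <- 0
  for (i in 1:10) {
    rest <- (1:10)[-i]
    ry_mat <- matrix(ry[rest[p9]], nrow(p9))
    s <- rx[1] * ry[i] + as.vector(ry_mat %*% rx[2:10])
    cnt <- cnt + sum(abs(s - centre) >= abs(s_obs - centre) - 1e-9)
  }
  cnt / (10 * nrow(p9))
}
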