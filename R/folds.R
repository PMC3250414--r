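#' Gene-level fold-change matrix relative to internal controls
#'
#' The universal currency of the pipeline: gene x sample linear fold changes
#' relative to the arithmetic mean of each dataset's own healthy-control
#' samples, carrying the sample manifest alongside.
#'
#' @param folds Numeric gene x sample matrix of positive linear fold changes
#'   (missing allowed).
#' @param manifest Manifest data.frame (see [read_manifest()]) with one row
#'   per column of `folds`, in column order.
#' @param dataset Dataset label (`"comparison"` for merged matrices).
#' @return Object of class `fold_matrix`.
#' @export
fold_matrix <- function(folds, manifest, dataset = NULL) {
  stopifnot(is.matrix(folds))
  if (is.null(rownames(folds)) || is.null(colnames(folds))) {
    stop("folds must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(folds))) stop("duplicate gene ids")
  if (any(folds <= 0, na.rm = TRUE)) {
    stop("fold changes must be positive (linear space)")
  }
  manifest <- validate_manifest(manifest)
  if (!identical(colnames(folds), manifest$sample_id)) {
    manifest <- manifest[match(colnames(folds), manifest$sample_id), ]
    if (anyNA(manifest$sample_id)) {
      stop("manifest does not cover all samples in the fold matrix")
    }
  }
  if (is.null(dataset)) {
    dataset <- if (length(unique(manifest$dataset_id)) == 1L)
      manifest$dataset_id[1L] else "comparison"
  }
  structure(list(folds = folds, manifest = manifest, dataset = dataset),
            class = "fold_matrix")
}

#' @export
print.fold_matrix <- function(x, ...) {
  cat("fold_matrix [", x$dataset, "]: ", nrow(x$folds), " genes x ",
      ncol(x$folds), " samples (",
      sum(x$manifest$group == "case"), " case / ",
      sum(x$manifest$group == "control"), " control)\n", sep = "")
  invisible(x)
}

#' @export
dim.fold_matrix <- function(x) dim(x$folds)

#' Normalize a gene-level matrix to its internal control samples
#'
#' Converts a gene x sample expression matrix to linear fold changes
#' relative to the arithmetic mean (in linear space) of the dataset's
#' control samples: `fold(g, s) = linear(g, s) / mean_controls(linear(g, .))`.
#' Control samples themselves are normalized the same way, so each retained
#' gene has mean fold exactly 1 over controls. Genes whose control mean is
#' missing or non-positive are dropped (a count is reported).
#'
#' @param gm Gene x sample numeric matrix; log2 space by default (set the
#'   `space` attribute or the `space` argument to `"linear"` otherwise).
#' @param manifest Manifest covering `gm`'s samples; must describe a single
#'   dataset with at least one control.
#' @param space Measurement space of `gm`; defaults to its `space` attribute
#'   or `"log2"`.
#' @return A [fold_matrix()].
#' @export
control_normalize <- function(gm, manifest,
                              space = attr(gm, "space", exact = TRUE)) {
  stopifnot(is.matrix(gm))
  if (is.null(space)) space <- "log2"
  space <- match.arg(space, c("linear", "log2"))
  manifest <- validate_manifest(manifest)
  manifest <- manifest[match(colnames(gm), manifest$sample_id), ]
  if (anyNA(manifest$sample_id)) {
    stop("manifest does not cover all samples in the matrix")
  }
  if (length(unique(manifest$dataset_id)) != 1L) {
    stop("control_normalize expects a single dataset; got: ",
         paste(unique(manifest$dataset_id), collapse = ", "))
  }
  ctrl <- manifest$group == "control"
  if (!any(ctrl)) stop("dataset has zero control samples")
  lin <- if (space == "log2") 2^gm else gm
  # mean over the available (non-missing) control values; a gene is dropped
  # only when no control value is observed or the mean is non-positive
  ctrl_mean <- rowMeans(lin[, ctrl, drop = FALSE], na.rm = TRUE)
  keep <- is.finite(ctrl_mean) & ctrl_mean > 0
  if (sum(!keep) > 0) {
    message(sum(!keep), " gene(s) dropped: missing or non-positive ",
            "control mean")
  }
  folds <- lin[keep, , drop = FALSE] / ctrl_mean[keep]
  fold_matrix(folds, manifest)
}

#' Merge datasets into a cross-platform comparison matrix
#'
#' Restricts all datasets to the genes shared by every platform and
#' concatenates their samples, retaining dataset provenance in the merged
#' manifest. Gene order is deterministic (sorted by identifier).
#'
#' @param datasets List of two or more [fold_matrix()] objects in a common
#'   gene namespace.
#' @return A merged `fold_matrix` (dataset label `"comparison"`).
#' @export
build_comparison_matrix <- function(datasets) {
  stopifnot(is.list(datasets), length(datasets) >= 2L)
  for (d in datasets) stopifnot(inherits(d, "fold_matrix"))
  shared <- sort(Reduce(intersect, lapply(datasets,
                                          function(d) rownames(d$folds))))
  if (length(shared) == 0L) {
    stop("no genes shared by all datasets")
  }
  all_samples <- unlist(lapply(datasets, function(d) colnames(d$folds)))
  if (anyDuplicated(all_samples)) {
    stop("duplicate sample ids across datasets: ",
         paste(unique(all_samples[duplicated(all_samples)]), collapse = ", "))
  }
  folds <- do.call(cbind, lapply(datasets,
                                 function(d) d$folds[shared, , drop = FALSE]))
  manifest <- do.call(rbind, lapply(datasets, function(d) d$manifest))
  fold_matrix(folds, manifest, dataset = "comparison")
}
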