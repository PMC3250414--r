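#' Probe-level expression matrix
#'
#' Container for raw probe x sample values together with the measurement
#' space (`linear` or `log2`) and, for two-channel arrays, the per-channel
#' foreground/background signals needed for adequacy filtering and LOWESS
#' normalization.
#'
#' @param values Numeric probe x sample matrix (rownames = probe ids,
#'   colnames = sample ids); may contain `NA`.
#' @param space Either `"linear"` (all non-missing values must be positive)
#'   or `"log2"`.
#' @param channels Optional named list with foreground matrices `ch1`, `ch2`
#'   and (optionally) background matrices `bg1`, `bg2`, all with the same
#'   dimensions as `values`.
#' @param platform_id Platform label.
#' @param adequate Optional logical matrix of per-value adequacy flags, used
#'   by [filter_probes()] when raw channel data are unavailable.
#' @return Object of class `probe_matrix`.
#' @export
probe_matrix <- function(values, space = c("linear", "log2"),
                         channels = NULL, platform_id = NA_character_,
                         adequate = NULL) {
  space <- match.arg(space)
  stopifnot(is.matrix(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have probe rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate probe ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (space == "linear" && any(values <= 0, na.rm = TRUE)) {
    stop("linear-space values must be positive")
  }
  if (!is.null(channels)) {
    if (!all(c("ch1", "ch2") %in% names(channels))) {
      stop("channels must contain matrices ch1 and ch2")
    }
    for (nm in names(channels)) {
      if (!identical(dim(channels[[nm]]), dim(values))) {
        stop("channel matrix ", nm, " does not match values dimensions")
      }
    }
  }
  if (!is.null(adequate) && !identical(dim(adequate), dim(values))) {
    stop("adequate flags do not match values dimensions")
  }
  structure(list(values = values, space = space, channels = channels,
                 platform_id = platform_id, adequate = adequate),
            class = "probe_matrix")
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat("probe_matrix:", nrow(x$values), "probes x", ncol(x$values),
      "samples;", x$space, "space")
  if (!is.null(x$channels)) cat("; two-channel")
  if (!is.na(x$platform_id)) cat("; platform", x$platform_id)
  cat("\n")
  nm <- sum(is.na(x$values))
  if (nm > 0) cat("  missing values:", nm, "\n")
  invisible(x)
}

#' @export
dim.probe_matrix <- function(x) dim(x$values)

#' Filter probes by hybridization signal over background
#'
#' Retains probes whose signal is technically adequate — foreground at least
#' `background_ratio` times the local background in at least one channel — in
#' at least `adequacy_fraction` of samples. Inadequate individual values are
#' set to missing. Both thresholds are inclusive. When the probe matrix does
#' not carry channel/background data, a precomputed `adequate` flag matrix is
#' used instead; if neither is available, an error names the problem.
#'
#' @param pm A [probe_matrix()] with channel + background data or `adequate`
#'   flags.
#' @param background_ratio Minimum foreground/background ratio (default 1.5).
#' @param adequacy_fraction Minimum fraction of samples in which the probe
#'   must be adequate (default 0.8); must lie in (0, 1].
#' @return A filtered `probe_matrix`.
#' @export
filter_probes <- function(pm, background_ratio = 1.5,
                          adequacy_fraction = 0.8) {
  stopifnot(inherits(pm, "probe_matrix"))
  if (!(adequacy_fraction > 0 && adequacy_fraction <= 1)) {
    stop("adequacy_fraction must lie in (0, 1]")
  }
  ch <- pm$channels
  if (!is.null(ch) && all(c("bg1", "bg2") %in% names(ch))) {
    ok <- (ch$ch1 >= background_ratio * ch$bg1) |
          (ch$ch2 >= background_ratio * ch$bg2)
    ok[is.na(ok)] <- FALSE
  } else if (!is.null(pm$adequate)) {
    ok <- pm$adequate
    ok[is.na(ok)] <- FALSE
  } else {
    stop("background filtering requested but probe matrix '",
         pm$platform_id, "' carries neither channel/background data nor ",
         "adequacy flags")
  }
  frac <- rowMeans(ok)
  keep <- frac >= adequacy_fraction
  values <- pm$values
  values[!ok] <- NA_real_
  values <- values[keep, , drop = FALSE]
  channels <- pm$channels
  if (!is.null(channels)) {
    channels <- lapply(channels, function(m) m[keep, , drop = FALSE])
  }
  adequate <- if (is.null(pm$adequate)) NULL else
    pm$adequate[keep, , drop = FALSE]
  out <- probe_matrix(values, space = pm$space, channels = channels,
                      platform_id = pm$platform_id, adequate = adequate)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Intensity-dependent (LOWESS) normalization of two-channel arrays
#'
#' For each array, fits a locally weighted regression of
#' M = log2(ch1/ch2) on A = (1/2) log2(ch1 * ch2) and subtracts the fitted
#' trend, removing intensity-dependent dye bias. Uses tricube-weighted local
#' linear regression with 3 robustness iterations; the smoother fraction is
#' the `span` parameter.
#'
#' @param pm A two-channel [probe_matrix()].
#' @param span LOWESS smoother span in (0, 1]; default 0.4.
#' @param min_probes Minimum number of usable probes per array below which
#'   the fit is considered underdetermined (default 30).
#' @return A `probe_matrix` of normalized log2 ratios (space `"log2"`).
#' @export
lowess_normalize <- function(pm, span = 0.4, min_probes = 30L) {
  stopifnot(inherits(pm, "probe_matrix"))
  if (is.null(pm$channels)) {
    stop("lowess_normalize requires two-channel signal data")
  }
  if (!(span > 0 && span <= 1)) stop("span must lie in (0, 1]")
  ch1 <- pm$channels$ch1
  ch2 <- pm$channels$ch2
  out <- matrix(NA_real_, nrow(ch1), ncol(ch1), dimnames = dimnames(ch1))
  for (j in seq_len(ncol(ch1))) {
    ok <- which(is.finite(ch1[, j]) & is.finite(ch2[, j]) &
                ch1[, j] > 0 & ch2[, j] > 0)
    if (length(ok) < min_probes) {
      stop("array ", colnames(ch1)[j], " has only ", length(ok),
           " usable probes (minimum ", min_probes, "); fit underdetermined")
    }
    m <- log2(ch1[ok, j] / ch2[ok, j])
    a <- 0.5 * log2(ch1[ok, j] * ch2[ok, j])
    fit <- stats::lowess(a, m, f = span, iter = 3)
    trend <- stats::approx(fit$x, fit$y, xout = a, rule = 2, ties = mean)$y
    out[ok, j] <- m - trend
  }
  probe_matrix(out, space = "log2", platform_id = pm$platform_id)
}

#' Collapse probes to genes by linear-space averaging
#'
#' Probes annotated to more than one gene are excluded; probes with no
#' annotation are dropped (a count is reported). For each gene, the
#' per-sample value is the arithmetic mean of its probes' values in linear
#' space, returned in log2 space. Missing probe values are ignored in the
#' mean.
#'
#' @param pm A [probe_matrix()] (linear or log2 space).
#' @param annotation Annotation data.frame with columns `probe_id` and
#'   `gene_ids` (comma-separated for multi-gene probes), as from
#'   [read_probe_annotation()].
#' @return Gene x sample numeric matrix in log2 space, genes sorted by
#'   identifier, with attributes `space = "log2"`, `n_multi_gene` and
#'   `n_unannotated`.
#' @export
collapse_probes <- function(pm, annotation) {
  stopifnot(inherits(pm, "probe_matrix"))
  ann <- annotation_list(annotation)
  probes <- rownames(pm$values)
  known <- intersect(probes, names(ann))
  if (length(known) == 0L) {
    stop("no overlap between probe matrix and annotation")
  }
  genes_per_probe <- ann[known]
  n_genes <- lengths(genes_per_probe)
  multi <- known[n_genes > 1L]
  none <- c(setdiff(probes, names(ann)), known[n_genes == 0L])
  usable <- known[n_genes == 1L]
  if (length(none)) {
    message(length(none), " unannotated probe(s) dropped")
  }
  if (length(usable) == 0L) {
    stop("no single-gene probes remain after annotation filtering")
  }
  gene <- vapply(genes_per_probe[usable], `[[`, "", 1L)
  lin <- pm$values[usable, , drop = FALSE]
  if (pm$space == "log2") lin <- 2^lin
  obs <- !is.na(lin)
  lin0 <- lin
  lin0[!obs] <- 0
  sums <- rowsum(lin0, gene)
  counts <- rowsum(obs + 0, gene)
  means <- sums / counts
  means[counts == 0] <- NA_real_
  out <- log2(means[order(rownames(means)), , drop = FALSE])
  attr(out, "space") <- "log2"
  attr(out, "n_multi_gene") <- length(multi)
  attr(out, "n_unannotated") <- length(none)
  out
}
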