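#' Read an expression matrix from TSV or GCT
#'
#' Reads a probe- or gene-level expression matrix. Plain tab-separated files
#' must have the row identifier in the first column and sample identifiers in
#' the header row. Files whose first line is `#1.2` are parsed as GCT 1.2
#' (versioned header, dimensions line, `Name`/`Description` columns). Missing
#' values are encoded as `NA`.
#'
#' @param path Path to a tab-separated or GCT file.
#' @return Numeric matrix with row identifiers as rownames and sample
#'   identifiers as colnames.
#' @seealso [write_expression_matrix()], [read_gct()]
#' @export
read_expression_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  if (identical(trimws(first), "#1.2")) {
    return(read_gct(path))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = "NA")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate row identifiers in ", path)
  }
  if (anyDuplicated(colnames(df)[-1L])) {
    stop("duplicate sample identifiers in ", path)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write an expression matrix as TSV
#'
#' @param x Numeric matrix with rownames (identifiers) and colnames (samples).
#' @param path Output path.
#' @param id_column Header name of the identifier column.
#' @export
write_expression_matrix <- function(x, path, id_column = "id") {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname read_expression_matrix
#' @export
read_gct <- function(path) {
  lines <- readLines(path)
  if (!identical(trimws(lines[1L]), "#1.2")) {
    stop("not a GCT 1.2 file: ", path)
  }
  dims <- as.integer(strsplit(lines[2L], "\t")[[1L]][1:2])
  df <- utils::read.delim(text = paste(lines[-(1:2)], collapse = "\n"),
                          header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  if (nrow(df) != dims[1L] || ncol(df) - 2L != dims[2L]) {
    stop("GCT dimensions line does not match table in ", path)
  }
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate row identifiers in ", path)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write an expression matrix in GCT 1.2 format
#'
#' @inheritParams write_expression_matrix
#' @param description Optional per-row description column (defaults to the
#'   row identifiers).
#' @export
write_gct <- function(x, path, description = NULL) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  if (is.null(description)) description <- rownames(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(x), ncol(x), sep = "\t")), con)
  df <- data.frame(Name = rownames(x), Description = description, x,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a sample manifest
#'
#' A manifest is a tab-separated table with columns `sample_id`, `dataset_id`,
#' `group` (one of `case`/`control`), `disease_label`, `tissue` and
#' `platform_id`. Every dataset must contain at least one control sample and
#' sample identifiers must be unique within a dataset.
#'
#' @param path Path to the manifest TSV.
#' @return A validated data.frame.
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  validate_manifest(df)
}

#' @rdname read_manifest
#' @param manifest A data.frame to validate in place.
#' @export
validate_manifest <- function(manifest) {
  required <- c("sample_id", "dataset_id", "group", "disease_label",
                "tissue", "platform_id")
  missing_cols <- setdiff(required, colnames(manifest))
  if (length(missing_cols)) {
    stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  bad_group <- setdiff(unique(manifest$group), c("case", "control"))
  if (length(bad_group)) {
    stop("manifest group labels must be 'case' or 'control'; found: ",
         paste(bad_group, collapse = ", "))
  }
  for (d in unique(manifest$dataset_id)) {
    rows <- manifest[manifest$dataset_id == d, ]
    if (anyDuplicated(rows$sample_id)) {
      stop("duplicate sample_id within dataset ", d)
    }
    if (!any(rows$group == "control")) {
      stop("dataset ", d, " has no control samples")
    }
  }
  manifest
}

#' Read a probe-to-gene annotation table
#'
#' Tab-separated table with columns `probe_id` and `gene_ids`, the latter
#' comma-separated for probes matching multiple genes. Multi-gene mappings are
#' preserved here (they are excluded later, by [collapse_probes()], not at
#' parse time).
#'
#' @param path Path to the annotation TSV.
#' @return data.frame with columns `probe_id`, `gene_ids`.
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("probe_id", "gene_ids") %in% colnames(df))) {
    stop("annotation must have columns probe_id and gene_ids")
  }
  if (anyDuplicated(df$probe_id)) stop("duplicate probe_id in annotation")
  df
}

#' @rdname read_probe_annotation
#' @param annotation Annotation data.frame (as from [read_probe_annotation()]).
#' @param file Output path.
#' @export
write_probe_annotation <- function(annotation, file) {
  utils::write.table(annotation[, c("probe_id", "gene_ids")], file,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

# Split comma-separated gene_ids into a named list of character vectors.
annotation_list <- function(annotation) {
  genes <- strsplit(annotation$gene_ids, ",", fixed = TRUE)
  genes <- lapply(genes, function(g) unique(g[nzchar(trimws(g))]))
  names(genes) <- annotation$probe_id
  genes
}

#' Read and write gene-set collections in GMT format
#'
#' GMT files have one gene set per line: set name, description, then
#' tab-separated gene identifiers.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of gene identifiers.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicate set names in ", path)
  if (any(lengths(sets) == 0L)) stop("empty gene set in ", path)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param description Optional per-set description (defaults to set names).
#' @export
write_gmt <- function(sets, path, description = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(description)) description <- names(sets)
  lines <- mapply(function(nm, desc, genes) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, names(sets), description, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read and write core-signature files
#'
#' Signature files are TSV with columns `rank`, `gene_id`, `mean_fold`
#' (linear-space mean fold change across the contributing in vitro studies,
#' descending).
#'
#' @param path Path to the signature TSV.
#' @return A `core_signature` object (see [derive_core_signature()]).
#' @export
read_signature <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "mean_fold") %in% colnames(df))) {
    stop("signature file must have columns gene_id and mean_fold")
  }
  new_core_signature(df$gene_id, df$mean_fold,
                     counts = c(significant = NA_integer_,
                                min_fold = NA_integer_,
                                comparison = NA_integer_),
                     provenance = attr(df, "provenance"))
}

#' @rdname read_signature
#' @param signature A `core_signature` object.
#' @param file Output path.
#' @export
write_signature <- function(signature, file) {
  stopifnot(inherits(signature, "core_signature"))
  utils::write.table(as.data.frame(signature), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}
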