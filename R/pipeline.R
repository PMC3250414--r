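pipeline_stage_names <- c("simulate", "harmonize", "diffexpr", "signature",
                          "score", "module_map", "cluster", "pca")

pipeline_defaults <- function() {
  list(
    seed = NULL,
    out_dir = NULL,
    stages = list(simulate = TRUE, harmonize = TRUE, diffexpr = TRUE,
                  signature = TRUE, score = TRUE, module_map = FALSE,
                  cluster = FALSE, pca = FALSE),
    params = list(
      cohort = list(),
      stimulation = list(),
      sam = list(fdr = 0.05, min_fold = 2, n_perm = 200L),
      signature = list(fdr = 0.05, min_fold = 2, n_perm = 200L),
      score = list(top_n = 25L, min_coverage = 0.6),
      module_map = list(min_fold = 2, alpha = 0.05, min_arrays = 4L,
                        n_random_sets = 20L, random_set_size = 50L),
      pca = list(rank = NULL)
    )
  )
}

#' Build and validate a pipeline configuration
#'
#' Merges user settings over the pipeline defaults and validates the result
#' against the configuration schema before any stage runs; unknown keys are
#' rejected. Stage parameters mirror the corresponding function defaults
#' except for permutation counts, which default to 200 for pipeline runs.
#'
#' @param seed Integer master seed; all stage randomness is derived from it
#'   deterministically.
#' @param out_dir Output directory (created if absent).
#' @param stages Named list of logical stage toggles; see
#'   [run_pipeline()] for the stage graph.
#' @param params Named list of per-stage parameter overrides
#'   (`cohort`, `stimulation`, `sam`, `signature`, `score`, `module_map`,
#'   `pca`).
#' @return Validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, out_dir, stages = list(),
                            params = list()) {
  cfg <- pipeline_defaults()
  cfg$seed <- seed
  cfg$out_dir <- out_dir
  unknown <- setdiff(names(stages), pipeline_stage_names)
  if (length(unknown)) {
    stop("unknown stage toggle(s): ", paste(unknown, collapse = ", "))
  }
  for (nm in names(stages)) cfg$stages[[nm]] <- isTRUE(stages[[nm]])
  unknown <- setdiff(names(params), names(cfg$params))
  if (length(unknown)) {
    stop("unknown parameter group(s): ", paste(unknown, collapse = ", "))
  }
  for (grp in names(params)) {
    if (grp %in% c("cohort", "stimulation")) {
      cfg$params[[grp]] <- params[[grp]]
      next
    }
    unknown <- setdiff(names(params[[grp]]), names(cfg$params[[grp]]))
    if (length(unknown)) {
      stop("unknown key(s) in params$", grp, ": ",
           paste(unknown, collapse = ", "))
    }
    for (nm in names(params[[grp]])) {
      cfg$params[[grp]][[nm]] <- params[[grp]][[nm]]
    }
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L) {
    stop("seed must be a single number")
  }
  if (!is.character(cfg$out_dir) || length(cfg$out_dir) != 1L) {
    stop("out_dir must be a single path")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file may contain the keys `seed`, `out_dir`, `stages` and `params`
#' (same schema as [pipeline_config()]); anything else is rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(raw), c("seed", "out_dir", "stages", "params"))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  pipeline_config(seed = raw$seed, out_dir = raw$out_dir,
                  stages = if (is.null(raw$stages)) list() else raw$stages,
                  params = if (is.null(raw$params)) list() else raw$params)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the enabled stages in dependency order, mirroring the analysis
#' chain: `simulate` (synthetic cohort + stimulation studies) ->
#' `harmonize` (probe collapse, control normalization, comparison matrix)
#' -> `diffexpr` (disease module from dataset 1) and `signature` (core IFN
#' signature from the stimulation studies, restricted to comparison-matrix
#' genes) -> `score` (per-sample IFN scores and per-dataset summaries) ->
#' optional `module_map`, `cluster` and `pca`. Each stage draws its
#' randomness from a seed derived deterministically from the master seed,
#' so identical configurations yield byte-identical outputs. An enabled
#' stage whose upstream is disabled raises an error naming the dependency.
#'
#' @param config A `pipeline_config` (or arguments forwarded to
#'   [pipeline_config()] via `...`).
#' @param ... Used to build a config when `config` is missing.
#' @return Invisibly, the run manifest: effective configuration, stages
#'   executed, and every output file with its md5 checksum. Also written to
#'   `run_manifest.json` in the output directory.
#' @export
run_pipeline <- function(config = NULL, ...) {
  if (is.null(config)) config <- pipeline_config(...)
  stopifnot(inherits(config, "pipeline_config"))
  st <- config$stages
  need <- function(stage, deps) {
    on_ <- vapply(deps, function(d) isTRUE(st[[d]]), TRUE)
    if (isTRUE(st[[stage]]) && !all(on_)) {
      stop("stage '", stage, "' requires upstream stage(s): ",
           paste(deps[!on_], collapse = ", "))
    }
  }
  need("harmonize", "simulate")
  need("diffexpr", "harmonize")
  need("signature", c("simulate", "harmonize"))
  need("score", c("harmonize", "signature"))
  need("module_map", c("simulate", "harmonize"))
  need("cluster", c("harmonize", "signature"))
  need("pca", c("harmonize", "signature"))

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  stages_run <- character(0)
  emit <- function(path) files <<- c(files, path)
  out <- function(name) file.path(config$out_dir, name)
  seed <- as.integer(config$seed)
  stage_seed <- function(i) seed + i

  cohort <- NULL; stim <- NULL; harm <- NULL
  signature <- NULL; scores <- NULL

  if (isTRUE(st$simulate)) {
    stages_run <- c(stages_run, "simulate")
    spec <- do.call(cohort_spec,
                    c(config$params$cohort, list(seed = stage_seed(1L))))
    cohort <- simulate_disease_cohort(spec)
    # the stimulation studies respond on the cohort's planted signature
    # genes, so the derived signature is informative for the cohort
    stim_args <- config$params$stimulation
    stim_args$n_genes <- NULL
    stim_args$n_responsive <- NULL
    stim <- do.call(simulate_stimulation_study,
                    c(stim_args,
                      list(gene_ids = cohort$truth$gene_universe,
                           responsive_genes =
                             cohort$truth$signature_genes,
                           seed = stage_seed(2L))))
    manifest_all <- do.call(rbind,
                            lapply(cohort$datasets, `[[`, "manifest"))
    utils::write.table(manifest_all, out("manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit(out("manifest.tsv"))
    for (nm in names(cohort$datasets)) {
      d <- cohort$datasets[[nm]]
      write_expression_matrix(d$probes$values,
                              out(paste0("probes_", nm, ".tsv")),
                              id_column = "probe_id")
      emit(out(paste0("probes_", nm, ".tsv")))
      write_probe_annotation(d$annotation,
                             out(paste0("annotation_", nm, ".tsv")))
      emit(out(paste0("annotation_", nm, ".tsv")))
    }
    for (e in stim$experiments) {
      p <- out(paste0("stimulation_", e$dataset_id, ".tsv"))
      write_expression_matrix(e$matrix, p, id_column = "gene_id")
      emit(p)
    }
    truth_out <- cohort$truth
    truth_out$spec <- unclass(truth_out$spec)
    truth_out$stimulation <- stim$truth
    jsonlite::write_json(truth_out, out("ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
    emit(out("ground_truth.json"))
  }

  if (isTRUE(st$harmonize)) {
    stages_run <- c(stages_run, "harmonize")
    harm <- harmonize_cohort(cohort)
    for (nm in names(harm$per_dataset)) {
      p <- out(paste0("folds_", nm, ".tsv"))
      write_expression_matrix(harm$per_dataset[[nm]]$folds, p,
                              id_column = "gene_id")
      emit(p)
    }
    write_expression_matrix(harm$comparison$folds, out("comparison.tsv"),
                            id_column = "gene_id")
    emit(out("comparison.tsv"))
  }

  if (isTRUE(st$diffexpr)) {
    stages_run <- c(stages_run, "diffexpr")
    pr <- config$params$sam
    module <- derive_disease_module(harm$per_dataset[[1L]],
                                    fdr = pr$fdr, min_fold = pr$min_fold,
                                    n_perm = pr$n_perm,
                                    seed = stage_seed(3L))
    mod_tab <- rbind(
      if (nrow(module$up)) cbind(direction = "up", module$up),
      if (nrow(module$down)) cbind(direction = "down", module$down))
    if (is.null(mod_tab)) {
      mod_tab <- data.frame(direction = character(0), gene = character(0),
                            mean_fold = numeric(0), d = numeric(0),
                            q_value = numeric(0))
    }
    utils::write.table(mod_tab, out("disease_module.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit(out("disease_module.tsv"))
  }

  if (isTRUE(st$signature)) {
    stages_run <- c(stages_run, "signature")
    pr <- config$params$signature
    signature <- derive_core_signature(
      stim$experiments,
      comparison_genes = rownames(harm$comparison$folds),
      fdr = pr$fdr, min_fold = pr$min_fold, n_perm = pr$n_perm,
      seed = stage_seed(4L))
    write_signature(signature, out("signature.tsv"))
    emit(out("signature.tsv"))
  }

  if (isTRUE(st$score)) {
    stages_run <- c(stages_run, "score")
    pr <- config$params$score
    top <- select_top_n(signature, pr$top_n)
    scores <- ifn_score(harm$comparison, top,
                        min_coverage = pr$min_coverage)
    utils::write.table(as.data.frame(scores), out("scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(out("scores.tsv"))
    utils::write.table(summarize_scores(scores, by = "dataset_id"),
                       out("score_summary.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit(out("score_summary.tsv"))
  }

  if (isTRUE(st$module_map)) {
    stages_run <- c(stages_run, "module_map")
    pr <- config$params$module_map
    withr_seed(stage_seed(5L))
    genes <- rownames(harm$comparison$folds)
    sets <- cohort$truth$module_genes
    names(sets) <- paste0("planted_", names(sets))
    sets$planted_signature <- cohort$truth$signature_genes
    for (i in seq_len(pr$n_random_sets)) {
      sets[[sprintf("random_%02d", i)]] <- sample(genes,
                                                  pr$random_set_size)
    }
    write_gmt(sets, out("gene_sets.gmt"))
    emit(out("gene_sets.gmt"))
    mm <- module_map(harm$comparison, sets, min_fold = pr$min_fold,
                     alpha = pr$alpha, min_arrays = pr$min_arrays)
    write_module_map(mm, out("module_map"))
    emit(out("module_map_table.tsv"))
    emit(out("module_map_display.tsv"))
  }

  if (isTRUE(st$cluster)) {
    stages_run <- c(stages_run, "cluster")
    sig_genes <- intersect(signature$gene_id,
                           rownames(harm$comparison$folds))
    mat <- log2(harm$comparison$folds[sig_genes, , drop = FALSE])
    tree <- average_linkage(mat, metric = "uncentered", axis = "genes")
    paths <- write_treeview(tree, mat, out("cluster_signature"))
    for (p in paths) emit(p)
  }

  if (isTRUE(st$pca)) {
    stages_run <- c(stages_run, "pca")
    sig_genes <- intersect(signature$gene_id,
                           rownames(harm$comparison$folds))
    mat <- log2(harm$comparison$folds[sig_genes, , drop = FALSE])
    if (anyNA(mat)) {
      mat <- svd_impute(mat, k = config$params$pca$rank)
    }
    fit <- pca_expression(mat)
    pcs <- data.frame(sample_id = rownames(fit$scores),
                      fit$scores[, seq_len(min(5L, ncol(fit$scores))),
                                 drop = FALSE],
                      check.names = FALSE)
    utils::write.table(pcs, out("pca_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit(out("pca_scores.tsv"))
    utils::write.table(
      data.frame(component = seq_along(fit$variance_fraction),
                 variance_fraction = fit$variance_fraction),
      out("pca_variance.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    emit(out("pca_variance.tsv"))
  }

  manifest <- list(
    package = "ifnscore",
    version = as.character(utils::packageVersion("ifnscore")),
    seed = seed,
    stages_run = stages_run,
    config = unclass(config),
    files = lapply(stats::setNames(files, basename(files)), function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, out("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
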