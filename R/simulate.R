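#' Specification for a synthetic multi-dataset disease cohort
#'
#' Collects the parameters of the synthetic-cohort generator and validates
#' them, reporting every violation at once. The defaults describe the
#' reference simulation conditions used throughout the package's validation:
#' three datasets of 10 cases and 10 controls over a 3000-gene universe; a
#' latent per-sample interferon-activity factor (log-normal with median 2
#' and log-scale sigma 0.75 for cases, exactly 0 for controls) driving 120
#' planted signature genes at 1 log2 unit per activity unit; an additional
#' up-regulated disease module (100 genes, 2.5-fold) and a down-regulated
#' module (50 genes, 0.4-fold); gene-level noise sd 0.5 (log2); 1-3 probes
#' per gene with 2% of probes annotated to two genes; 2% missing values.
#'
#' @param n_datasets Number of datasets (platforms).
#' @param n_cases,n_controls Samples per dataset.
#' @param n_genes Size of the gene universe.
#' @param coverage Fraction of the universe measured by each platform
#'   (genes are sampled independently per platform when `< 1`).
#' @param n_signature Number of planted IFN-responsive genes.
#' @param signature_slope Effect slope in log2 units per activity unit.
#' @param activity_meanlog,activity_sdlog Log-normal parameters of the
#'   latent case activity.
#' @param modules List of planted module specs, each `list(size=, fold=)`
#'   (linear fold in cases vs controls).
#' @param noise_sd Gene-level Gaussian noise sd in log2 units (must be
#'   positive; use a tiny value to approach the noise-free limit).
#' @param probe_multiplicity Integer vector of possible probes-per-gene
#'   counts (sampled uniformly).
#' @param probe_affinity_sd Per-probe constant affinity offset sd (log2).
#' @param probe_noise_sd Probe-level measurement noise sd (log2).
#' @param multi_gene_rate Fraction of probes annotated to a second gene.
#' @param missing_rate Completely-at-random missingness rate in `[0, 1)`.
#' @param baseline_mean,baseline_sd Per-gene baseline log2 expression.
#' @param seed Mandatory integer seed.
#' @return Validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_datasets = 3L, n_cases = 10L, n_controls = 10L,
                        n_genes = 3000L, coverage = 1.0,
                        n_signature = 120L, signature_slope = 1.0,
                        activity_meanlog = log(2), activity_sdlog = 0.75,
                        modules = list(up = list(size = 100L, fold = 2.5),
                                       down = list(size = 50L, fold = 0.4)),
                        noise_sd = 0.5,
                        probe_multiplicity = 1:3,
                        probe_affinity_sd = 0.3, probe_noise_sd = 0.1,
                        multi_gene_rate = 0.02, missing_rate = 0.02,
                        baseline_mean = 7, baseline_sd = 1,
                        seed) {
  spec <- list(n_datasets = n_datasets, n_cases = n_cases,
               n_controls = n_controls, n_genes = n_genes,
               coverage = coverage, n_signature = n_signature,
               signature_slope = signature_slope,
               activity_meanlog = activity_meanlog,
               activity_sdlog = activity_sdlog, modules = modules,
               noise_sd = noise_sd,
               probe_multiplicity = probe_multiplicity,
               probe_affinity_sd = probe_affinity_sd,
               probe_noise_sd = probe_noise_sd,
               multi_gene_rate = multi_gene_rate,
               missing_rate = missing_rate,
               baseline_mean = baseline_mean, baseline_sd = baseline_sd,
               seed = if (missing(seed)) NULL else seed)
  problems <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(n_datasets >= 1, "n_datasets must be >= 1")
  chk(n_cases >= 1 && n_controls >= 1, "sample counts must be >= 1")
  chk(n_genes >= 1, "n_genes must be >= 1")
  chk(coverage > 0 && coverage <= 1, "coverage must lie in (0, 1]")
  chk(n_signature >= 1 && n_signature <= n_genes,
      "n_signature must lie in [1, n_genes]")
  chk(noise_sd > 0, "noise_sd must be > 0")
  chk(missing_rate >= 0 && missing_rate < 1,
      "missing_rate must lie in [0, 1)")
  chk(all(vapply(modules, function(m)
        is.numeric(m$size) && m$size >= 1 && is.numeric(m$fold) &&
        m$fold > 0, TRUE)),
      "each module needs size >= 1 and fold > 0")
  total_planted <- n_signature +
    sum(vapply(modules, function(m) m$size, 0))
  chk(total_planted <= n_genes,
      "planted gene sets exceed the gene universe")
  chk(!is.null(spec$seed) && is.numeric(spec$seed),
      "seed is mandatory")
  if (length(problems)) {
    stop("invalid cohort spec:\n  ",
         paste(problems, collapse = "\n  "))
  }
  structure(spec, class = "cohort_spec")
}

#' Simulate a multi-platform disease cohort with known ground truth
#'
#' Generates, per dataset, a probe-level expression matrix (log2 space), a
#' sample manifest and a probe annotation table, following the generative
#' model: log2 expression = per-gene platform baseline + signature effect
#' (`slope * activity`, cases only, planted signature genes only) + planted
#' module effects (cases only) + Gaussian noise; probes add a constant
#' affinity offset and probe-level noise; a configurable fraction of probes
#' is annotated to two genes (these are excluded downstream); values are
#' masked completely at random. Output is deterministic given the spec's
#' seed.
#'
#' @param spec A [cohort_spec()].
#' @return List with `datasets` (each: `probes` as [probe_matrix()],
#'   `manifest`, `annotation`) and `truth` (per-sample latent `activity`,
#'   `signature_genes`, `module_genes`, `differential_genes`, the spec).
#' @export
simulate_disease_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr_seed(spec$seed)
  genes <- sprintf("G%05d", seq_len(spec$n_genes))
  signature_genes <- sort(sample(genes, spec$n_signature))
  pool <- setdiff(genes, signature_genes)
  module_genes <- list()
  for (nm in names(spec$modules)) {
    module_genes[[nm]] <- sort(sample(pool, spec$modules[[nm]]$size))
    pool <- setdiff(pool, module_genes[[nm]])
  }
  datasets <- vector("list", spec$n_datasets)
  names(datasets) <- sprintf("DS%d", seq_len(spec$n_datasets))
  activity_rows <- list()
  for (d in seq_len(spec$n_datasets)) {
    ds_id <- names(datasets)[d]
    covered <- if (spec$coverage < 1) {
      sort(sample(genes, round(spec$coverage * spec$n_genes)))
    } else genes
    n_s <- spec$n_cases + spec$n_controls
    sample_ids <- sprintf("%s_S%02d", ds_id, seq_len(n_s))
    group <- c(rep("case", spec$n_cases), rep("control", spec$n_controls))
    activity <- c(stats::rlnorm(spec$n_cases, spec$activity_meanlog,
                                spec$activity_sdlog),
                  rep(0, spec$n_controls))
    baseline <- stats::rnorm(length(covered), spec$baseline_mean,
                             spec$baseline_sd)
    expr <- matrix(baseline, length(covered), n_s,
                   dimnames = list(covered, sample_ids))
    sig_here <- intersect(covered, signature_genes)
    expr[sig_here, ] <- expr[sig_here, ] +
      spec$signature_slope * rep(activity, each = length(sig_here))
    for (nm in names(module_genes)) {
      mg <- intersect(covered, module_genes[[nm]])
      is_case <- group == "case"
      expr[mg, is_case] <- expr[mg, is_case] +
        log2(spec$modules[[nm]]$fold)
    }
    expr <- expr + matrix(stats::rnorm(length(expr), 0, spec$noise_sd),
                          nrow(expr))
    # probe layer: 1..k probes per gene, constant affinity offsets
    mult <- sample(spec$probe_multiplicity, length(covered), replace = TRUE)
    gene_of_probe <- rep(covered, mult)
    probe_ids <- sprintf("%s_P%05d", ds_id, seq_along(gene_of_probe))
    affinity <- stats::rnorm(length(probe_ids), 0, spec$probe_affinity_sd)
    probes <- expr[gene_of_probe, , drop = FALSE] + affinity
    if (spec$probe_noise_sd > 0) {
      probes <- probes + matrix(stats::rnorm(length(probes), 0,
                                             spec$probe_noise_sd),
                                nrow(probes))
    }
    rownames(probes) <- probe_ids
    gene_ids <- gene_of_probe
    if (spec$multi_gene_rate > 0 && length(probe_ids) >= 2L) {
      n_multi <- round(spec$multi_gene_rate * length(probe_ids))
      if (n_multi > 0) {
        multi_idx <- sample(seq_along(probe_ids), n_multi)
        second <- vapply(gene_of_probe[multi_idx], function(g) {
          sample(setdiff(covered, g), 1L)
        }, "")
        gene_ids[multi_idx] <- paste(gene_of_probe[multi_idx], second,
                                     sep = ",")
      }
    }
    if (spec$missing_rate > 0) {
      mask <- stats::runif(length(probes)) < spec$missing_rate
      probes[mask] <- NA_real_
    }
    manifest <- data.frame(sample_id = sample_ids, dataset_id = ds_id,
                           group = group, disease_label =
                             ifelse(group == "case", "disease", "healthy"),
                           tissue = "skin",
                           platform_id = sprintf("platform_%d", d),
                           stringsAsFactors = FALSE)
    annotation <- data.frame(probe_id = probe_ids, gene_ids = gene_ids,
                             stringsAsFactors = FALSE)
    datasets[[d]] <- list(
      probes = probe_matrix(probes, space = "log2",
                            platform_id = manifest$platform_id[1L]),
      manifest = manifest, annotation = annotation)
    activity_rows[[d]] <- data.frame(sample_id = sample_ids,
                                     dataset_id = ds_id,
                                     activity = activity,
                                     stringsAsFactors = FALSE)
  }
  truth <- list(activity = do.call(rbind, activity_rows),
                gene_universe = genes,
                signature_genes = signature_genes,
                module_genes = module_genes,
                differential_genes = sort(c(signature_genes,
                                            unlist(module_genes,
                                                   use.names = FALSE))),
                spec = spec)
  list(datasets = datasets, truth = truth)
}

#' Harmonize a simulated cohort to fold matrices
#'
#' Convenience wrapper running the standard harmonization chain
#' ([collapse_probes()] then [control_normalize()]) on every dataset of a
#' simulated cohort and, when more than one dataset is present, building the
#' cross-platform comparison matrix.
#'
#' @param cohort Result of [simulate_disease_cohort()].
#' @return List with `per_dataset` (list of [fold_matrix()]) and
#'   `comparison` (merged `fold_matrix`, or the single dataset).
#' @export
harmonize_cohort <- function(cohort) {
  per_dataset <- lapply(cohort$datasets, function(d) {
    gm <- suppressMessages(collapse_probes(d$probes, d$annotation))
    suppressMessages(control_normalize(gm, d$manifest))
  })
  comparison <- if (length(per_dataset) >= 2L) {
    build_comparison_matrix(per_dataset)
  } else {
    per_dataset[[1L]]
  }
  list(per_dataset = per_dataset, comparison = comparison)
}

#' Simulate paired in vitro IFN stimulation studies
#'
#' Generates `n_studies` pre/post stimulation experiments over a common gene
#' universe. Responsive genes receive per-study effects drawn uniformly from
#' `effect_range` (log2 units); each study has its own per-gene baseline,
#' and an optional constant per-study shift exercises the mean-centering
#' step of signature derivation.
#'
#' @param n_studies Number of studies (default 4).
#' @param cell_types Cycled across studies.
#' @param n_genes Gene universe size (default 3000).
#' @param n_responsive Number of planted IFN-responsive genes (default 150).
#' @param effect_range Range of per-study log2 effects (default 1.5-3).
#' @param n_pairs Pre/post pairs per study (default 4).
#' @param noise_sd Gaussian noise sd in log2 units (default 0.5).
#' @param study_shifts Optional numeric vector (length `n_studies`) of
#'   constant log2 shifts added to entire studies.
#' @param responsive_fraction Fraction of the responsive set active in each
#'   study (default 1; lower values emulate cell-type-specific response).
#' @param gene_ids Optional explicit gene universe (overrides `n_genes`),
#'   e.g. the universe of a simulated disease cohort.
#' @param responsive_genes Optional explicit responsive set (overrides
#'   `n_responsive`); must be a subset of the universe. Lets stimulation
#'   studies share their IFN-responsive genes with a cohort's planted
#'   signature, mirroring the biology the pipeline assumes.
#' @param seed Integer seed (mandatory).
#' @return List with `experiments` (list of [stimulation_experiment()]) and
#'   `truth` (`responsive_genes`, per-study effect tables).
#' @export
simulate_stimulation_study <- function(n_studies = 4L,
                                       cell_types = c("keratinocyte",
                                                      "fibroblast",
                                                      "endothelial",
                                                      "macrophage"),
                                       n_genes = 3000L,
                                       n_responsive = 150L,
                                       effect_range = c(1.5, 3),
                                       n_pairs = 4L, noise_sd = 0.5,
                                       study_shifts = NULL,
                                       responsive_fraction = 1,
                                       gene_ids = NULL,
                                       responsive_genes = NULL,
                                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(all(effect_range > 0), n_pairs >= 2)
  withr_seed(seed)
  if (is.null(study_shifts)) study_shifts <- rep(0, n_studies)
  stopifnot(length(study_shifts) == n_studies)
  genes <- if (is.null(gene_ids)) {
    sprintf("G%05d", seq_len(n_genes))
  } else {
    gene_ids
  }
  n_genes <- length(genes)
  responsive <- if (is.null(responsive_genes)) {
    stopifnot(n_responsive >= 1, n_responsive <= n_genes)
    sort(sample(genes, n_responsive))
  } else {
    stopifnot(all(responsive_genes %in% genes))
    sort(responsive_genes)
  }
  n_responsive <- length(responsive)
  ifn_types <- rep(c("alpha", "gamma", "beta", "other"),
                   length.out = n_studies)
  experiments <- vector("list", n_studies)
  effects <- vector("list", n_studies)
  for (s in seq_len(n_studies)) {
    ds_id <- sprintf("STIM%d", s)
    active <- if (responsive_fraction < 1) {
      sort(sample(responsive, round(responsive_fraction * n_responsive)))
    } else responsive
    eff <- stats::setNames(stats::runif(length(active), effect_range[1L],
                                        effect_range[2L]), active)
    baseline <- stats::rnorm(n_genes, 7, 1)
    n_s <- 2L * n_pairs
    sample_ids <- sprintf("%s_%s%02d", ds_id,
                          rep(c("pre", "post"), each = n_pairs),
                          rep(seq_len(n_pairs), 2L))
    design <- rep(c("pre", "post"), each = n_pairs)
    m <- matrix(baseline, n_genes, n_s,
                dimnames = list(genes, sample_ids))
    m[active, design == "post"] <- m[active, design == "post"] + eff
    m <- m + matrix(stats::rnorm(length(m), 0, noise_sd), n_genes)
    m <- m + study_shifts[s]
    experiments[[s]] <- stimulation_experiment(
      m, design, dataset_id = ds_id,
      cell_type = cell_types[(s - 1L) %% length(cell_types) + 1L],
      ifn_type = ifn_types[s])
    effects[[s]] <- data.frame(dataset_id = ds_id, gene = active,
                               effect_log2 = unname(eff),
                               stringsAsFactors = FALSE)
  }
  list(experiments = experiments,
       truth = list(responsive_genes = responsive,
                    effects = do.call(rbind, effects)))
}

#' Simulate a qPCR panel linked to latent IFN activity
#'
#' Generates threshold-cycle (Ct) tables for a set of transcripts whose
#' expression tracks the latent activity with transcript-specific link
#' coefficients: `target Ct = baseline - link * activity + noise`; the
#' reference gene has constant mean Ct. Calibrator samples have activity 0.
#'
#' @param activity Named numeric vector of per-sample latent activities.
#' @param transcripts data.frame with columns `name` and `link` (Ct units
#'   per activity unit; finite).
#' @param baseline_ct Mean target Ct at zero activity (default 30).
#' @param reference_ct Mean reference-gene Ct (default 20).
#' @param ct_noise Gaussian Ct noise sd (default 0.5).
#' @param n_calibrators Number of zero-activity calibrator samples
#'   (default 4).
#' @param seed Integer seed (mandatory).
#' @return data.frame with columns `sample_id`, `transcript`, `target_ct`,
#'   `reference_ct`, `is_calibrator`.
#' @export
simulate_qpcr <- function(activity, transcripts, baseline_ct = 30,
                          reference_ct = 20, ct_noise = 0.5,
                          n_calibrators = 4L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(!is.null(names(activity)), is.data.frame(transcripts),
            all(c("name", "link") %in% colnames(transcripts)),
            all(is.finite(transcripts$link)))
  withr_seed(seed)
  cal_ids <- sprintf("CAL%02d", seq_len(n_calibrators))
  all_act <- c(activity, stats::setNames(rep(0, n_calibrators), cal_ids))
  is_cal <- c(rep(FALSE, length(activity)), rep(TRUE, n_calibrators))
  rows <- lapply(seq_len(nrow(transcripts)), function(i) {
    tr <- transcripts$name[i]
    link <- transcripts$link[i]
    data.frame(sample_id = names(all_act), transcript = tr,
               target_ct = baseline_ct - link * all_act +
                 stats::rnorm(length(all_act), 0, ct_noise),
               reference_ct = reference_ct +
                 stats::rnorm(length(all_act), 0, ct_noise),
               is_calibrator = is_cal, stringsAsFactors = FALSE,
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Convert a qPCR Ct table to relative abundances
#'
#' Applies [ddct()] per transcript, using the mean target and reference Ct
#' of the calibrator samples as the calibrator values.
#'
#' @param ct_table As produced by [simulate_qpcr()].
#' @return Sample x transcript matrix of relative abundances (calibrator
#'   rows excluded).
#' @export
qpcr_relative_abundance <- function(ct_table) {
  stopifnot(all(c("sample_id", "transcript", "target_ct", "reference_ct",
                  "is_calibrator") %in% colnames(ct_table)))
  if (!any(ct_table$is_calibrator)) stop("no calibrator samples present")
  split_tr <- split(ct_table, ct_table$transcript)
  samples <- unique(ct_table$sample_id[!ct_table$is_calibrator])
  out <- matrix(NA_real_, length(samples), length(split_tr),
                dimnames = list(samples, names(split_tr)))
  for (tr in names(split_tr)) {
    df <- split_tr[[tr]]
    cal <- df[df$is_calibrator, ]
    smp <- df[!df$is_calibrator, ]
    out[smp$sample_id, tr] <- ddct(smp$target_ct, smp$reference_ct,
                                   mean(cal$target_ct),
                                   mean(cal$reference_ct))
  }
  out
}

# all generator randomness flows from one explicit seed
withr_seed <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  set.seed(as.integer(seed))
}
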