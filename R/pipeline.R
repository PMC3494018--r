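#' Run the full targeted-panel workflow
#'
#' Executes the complete analysis on either a simulated cohort or files on
#' disk: (1) load or simulate the raw Ct matrix, metadata and axis panels;
#' (2) mask failed reactions; (3) supervised normalization; (4) axis PC1
#' scoring; (5) variance components of the leading PCs with a permutation
#' null; (6) all pairwise group contrasts; (7) axis-2 vs BMI association
#' with group and BMI-band strata plus the joint BMI + lifestyle fit within
#' the Indian samples. Every intermediate is written to `outdir` so each
#' stage can be interrogated, with a `#`-prefixed provenance header (package
#' version, seed, config hash) on each CSV and a JSON run manifest.
#'
#' @param outdir output directory (created if needed).
#' @param cohort a `Cohort` from [generate_cohort()]; if `NULL`, one is
#'   simulated from `config`.
#' @param config a [cohort_config()] used when `cohort` is `NULL`.
#' @param matrix_path,metadata_path,panel_path alternatively, read inputs
#'   from these files (all three required together).
#' @param platform platform of `matrix_path` data.
#' @param seed RNG seed for simulation and the permutation null.
#' @param k_pcs leading PCs for variance components (default 5).
#' @param n_perm label permutations (default 1000; minimum 100).
#' @param nlp_threshold volcano significance cut-off (default 2).
#' @param bmi_band BMI band boundary for stratified association (default 25).
#' @param k_mad outlier-sample threshold (default 3).
#' @param ct_max failed-reaction Ct cut-off (default 28).
#' @return (invisibly) list with `cohort`, `normalized`, `norm_report`,
#'   `axes`, `varcomp`, `contrasts`, `association`, `joint`, `manifest`.
#' @export
run_pipeline <- function(outdir, cohort = NULL, config = cohort_config(),
                         matrix_path = NULL, metadata_path = NULL,
                         panel_path = NULL, platform = "ct", seed = NULL,
                         k_pcs = 5, n_perm = 1000, nlp_threshold = 2,
                         bmi_band = 25, k_mad = 3, ct_max = 28) {
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timings <- c()
  tick <- function(stage) {
    timings[[stage]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
  }

  if (!is.null(matrix_path)) {
    if (is.null(metadata_path) || is.null(panel_path)) {
      stop("matrix_path requires metadata_path and panel_path", call. = FALSE)
    }
    m <- read_expression_table(matrix_path, platform = platform)
    samples <- read_sample_table(metadata_path)
    panel <- read_axis_panels(panel_path)
    cohort <- NULL
  } else {
    if (is.null(cohort)) {
      if (!is.null(seed)) config$seed <- seed
      cohort <- generate_cohort(config)
    }
    m <- cohort$ct
    samples <- cohort$samples
    panel <- cohort$panel
  }
  prov <- c(tool = paste0("bitaxes ",
                          as.character(utils::packageVersion("bitaxes"))),
            seed = ifelse(is.null(seed), "unset", seed),
            config_hash = substr(config_hash(list(k_pcs, n_perm,
                                                  nlp_threshold, bmi_band,
                                                  k_mad, ct_max)), 1, 12))
  write_expression_table(m, file.path(outdir, "raw_matrix.csv"), prov)
  write_expression_table(as.data.frame(samples),
                         file.path(outdir, "sample_table.csv"), prov)
  write_axis_panels(panel, file.path(outdir, "axis_panels.json"))
  tick("load")

  if (em_platform(m) == "ct") m <- mask_failed_ct(m, ct_max = ct_max)
  norm <- normalize_pipeline(m, samples, k_mad = k_mad,
                             adjust_rin = em_platform(m) == "ct")
  write_expression_table(norm$matrix,
                         file.path(outdir, "normalized_matrix.csv"), prov)
  jsonlite::write_json(
    list(samples_removed = norm$report$samples_removed,
         probes_removed = norm$report$probes_removed,
         stage_log = norm$report$stage_log),
    file.path(outdir, "normalization_report.json"), auto_unbox = TRUE,
    pretty = TRUE, digits = NA)
  tick("normalize")

  axes <- score_all_axes(norm$matrix, panel)
  write_expression_table(
    data.frame(sample_id = rownames(axes$scores), axes$scores),
    file.path(outdir, "axis_scores.csv"), prov)
  write_expression_table(axes$summary,
                         file.path(outdir, "axis_summary.csv"), prov)
  write_expression_table(
    data.frame(axis = rownames(axes$axis_cor), axes$axis_cor),
    file.path(outdir, "axis_correlation.csv"), prov)
  tick("axes")

  vc <- varcomp_report(norm$matrix, samples, k = k_pcs, n_perm = n_perm,
                       seed = seed)
  write_expression_table(vc$pc_table, file.path(outdir, "pc_table.csv"), prov)
  jsonlite::write_json(
    list(eigen_share = vc$eigen_share, weighted_ve = vc$weighted_ve,
         raw_ve = vc$raw_ve,
         permutation = list(
           n_perm = vc$permutation$n_perm,
           null_quantiles = as.data.frame(vc$permutation$null_quantiles),
           empirical_p = vc$permutation$empirical_p)),
    file.path(outdir, "varcomp_report.json"), auto_unbox = TRUE,
    pretty = TRUE, digits = NA)
  tick("varcomp")

  present <- levels(droplevels(samples$type[samples$sample_id %in%
                                              rownames(norm$matrix)]))
  contrasts <- list()
  for (i in seq_along(present)) {
    for (j in seq_along(present)) {
      if (i < j) {
        key <- paste(present[i], "vs", present[j], sep = "_")
        contrasts[[key]] <- pairwise_contrast(
          norm$matrix, samples, present[i], present[j],
          nlp_threshold = nlp_threshold)
      }
    }
  }
  de_tab <- do.call(rbind, lapply(contrasts, function(x) x))
  write_expression_table(de_tab, file.path(outdir, "contrasts.csv"), prov)
  tick("differential")

  assoc <- joint <- NULL
  ax2 <- "axis_2"
  if (ax2 %in% colnames(axes$scores)) {
    assoc <- regress_axis_on_covariate(axes$scores[, ax2], samples, "bmi",
                                       group_factor = "type",
                                       band_boundary = bmi_band, axis_id = 2)
    write_expression_table(assoc, file.path(outdir, "association.csv"), prov)
    indian <- samples$ethnicity[match(rownames(axes$scores),
                                      samples$sample_id)] == "indian"
    joint <- tryCatch(
      joint_fit(axes$scores[, ax2], samples, "bmi", "lifestyle",
                subset = rownames(axes$scores)[indian]),
      error = function(e) NULL)
  }
  tick("associate")

  manifest <- list(
    provenance = as.list(prov),
    n_samples_in = nrow(m), n_samples_analyzed = nrow(norm$matrix),
    samples_removed = nrow(norm$report$samples_removed),
    probes_removed = nrow(norm$report$probes_removed),
    n_probes_analyzed = ncol(norm$matrix),
    stage_seconds = as.list(timings))
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(cohort = cohort, normalized = norm$matrix,
                 norm_report = norm$report, axes = axes, varcomp = vc,
                 contrasts = contrasts, association = assoc, joint = joint,
                 manifest = manifest))
}

config_hash <- function(x) {
  # small deterministic checksum of the serialized run options; provenance only
  bytes <- as.integer(serialize(x, NULL, ascii = TRUE))
  sprintf("%08x", sum(bytes * (seq_along(bytes) %% 97 + 1)) %% 2^31)
}
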