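#' Read a pipeline run configuration
#'
#' YAML configuration with sections `inputs` (`manifest`, `variants`,
#' `dialect`, optional `pgx_rules`, `reference_counts`), `thresholds`
#' (`min_qual`, `min_depth`, `min_gq`, `max_pop_af`), `classifier`
#' (`delta_threshold`, `gmaf_cutoff`, `cadd_cutoff`, `alpha`,
#' `p_adjust_method`), `out_dir`, and `seed`. Every threshold defaults to
#' the pipeline's standard value, so a minimal config names only the input
#' paths.
#'
#' @param path YAML file path.
#' @return A named list of class `panelvar_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config not found: %s", path), class = "panelvar_io_error")
  }
  raw <- yaml::read_yaml(path)
  run_config(
    manifest = raw$inputs$manifest,
    variants = raw$inputs$variants,
    dialect = raw$inputs$dialect %||% "annotated_tsv",
    pgx_rules = raw$inputs$pgx_rules,
    reference_counts = raw$inputs$reference_counts,
    thresholds = do.call(filter_thresholds, raw$thresholds %||% list()),
    delta_threshold = raw$classifier$delta_threshold %||% 0.1,
    gmaf_cutoff = raw$classifier$gmaf_cutoff %||% 0.01,
    cadd_cutoff = raw$classifier$cadd_cutoff %||% 20,
    alpha = raw$classifier$alpha %||% 0.01,
    p_adjust_method = raw$classifier$p_adjust_method %||% "bonferroni",
    out_dir = raw$out_dir,
    seed = raw$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_run_config
#' @param manifest,variants,dialect,pgx_rules,reference_counts Input paths
#'   (or in-memory tibbles for `manifest`/`variants`).
#' @param thresholds A [filter_thresholds] object.
#' @param delta_threshold,gmaf_cutoff,cadd_cutoff,alpha,p_adjust_method
#'   Classifier and statistics settings.
#' @param out_dir Optional report directory.
#' @param seed Integer seed (used only when simulating inputs).
#' @export
run_config <- function(manifest = NULL, variants = NULL,
                       dialect = "annotated_tsv", pgx_rules = NULL,
                       reference_counts = NULL,
                       thresholds = filter_thresholds(),
                       delta_threshold = 0.1, gmaf_cutoff = 0.01,
                       cadd_cutoff = 20, alpha = 0.01,
                       p_adjust_method = "bonferroni",
                       out_dir = NULL, seed = 1L) {
  stopifnot(delta_threshold >= 0, alpha > 0, alpha < 1)
  for (p in c(
    if (is.character(manifest)) manifest, if (is.character(variants)) variants,
    pgx_rules, reference_counts
  )) {
    if (!is.null(p) && !file.exists(p)) {
      abort(sprintf("configured input does not exist: %s", p),
        class = "panelvar_configuration_error"
      )
    }
  }
  structure(
    list(
      manifest = manifest, variants = variants, dialect = dialect,
      pgx_rules = pgx_rules, reference_counts = reference_counts,
      thresholds = thresholds, delta_threshold = delta_threshold,
      gmaf_cutoff = gmaf_cutoff, cadd_cutoff = cadd_cutoff, alpha = alpha,
      p_adjust_method = p_adjust_method, out_dir = out_dir,
      seed = as.integer(seed)
    ),
    class = "panelvar_run_config"
  )
}

stage_log <- function(stage, n_in, n_kept, n_removed) {
  inform(sprintf(
    "[%s] rows_in = %d, retained = %d, removed = %d",
    stage, n_in, n_kept, n_removed
  ))
}

#' Run the full interpretation pipeline
#'
#' Stages run in a fixed order: quality filter (QUAL/DP/GQ), rarity split
#' (population AF), somatic/germline classification by the blast-fraction
#' rule, consequence and conservation annotation, clonal ordering,
#' germline prioritization, cohort statistics (recurrence, burden,
#' co-occurrence), and the pharmacogenomic lookup (which runs on the
#' QC-passing set *before* rarity filtering). Row-count conservation is
#' logged at every stage. When `out_dir` is configured, the classified
#' table, JSON summary, and text report are written there.
#'
#' @param config A [run_config]; `manifest`/`variants` may be paths or
#'   tibbles. When both are `NULL` a synthetic cohort is simulated with
#'   `sim_config(seed = config$seed)`.
#' @return A list with `summary` (a `panelvar_summary`), `qc`, `split`
#'   (filter partitions), `ratio` (nonsyn/syn comparison when reference
#'   counts were configured, else cohort-only), and `files` (paths written,
#'   or `NULL`).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "panelvar_run_config"))
  if (is.null(config$manifest) && is.null(config$variants)) {
    sim <- simulate_cohort(sim_config(seed = config$seed))
    manifest <- sim$manifest
    variants <- sim$variants
  } else {
    manifest <- if (is.data.frame(config$manifest)) {
      config$manifest
    } else {
      read_manifest(config$manifest)
    }
    variants <- if (is.data.frame(config$variants)) {
      config$variants
    } else {
      read_variants(config$variants, dialect = config$dialect)
    }
  }

  qc <- apply_qc_filter(variants, config$thresholds)
  stage_log("qc_filter", nrow(variants), nrow(qc$retained), nrow(qc$removed))

  split <- apply_popaf_filter(qc$retained, config$thresholds)
  stage_log("popaf_filter", nrow(qc$retained), nrow(split$rare), nrow(split$common))

  classified <- classify_origin(split$rare, manifest)
  classified$silence <- classify_silence(
    classified$functional_impact, classified$genomic_region
  )
  classified$conservation_bin <- bin_conservation(classified$phylop)
  stage_log(
    "classify_origin", nrow(split$rare),
    sum(classified$origin == "somatic"), sum(classified$origin == "germline")
  )

  prioritized <- prioritize_germline(
    filter(classified, .data$origin == "germline"),
    gmaf_cutoff = config$gmaf_cutoff, cadd_cutoff = config$cadd_cutoff
  )
  assignments <- assign_clones(
    filter(classified, .data$origin == "somatic", .data$silence == "non_silent"),
    delta_threshold = config$delta_threshold
  )
  pgx_rules <- if (is.null(config$pgx_rules)) {
    read_pgx_rules()
  } else {
    read_pgx_rules(config$pgx_rules)
  }
  summary <- summarize_cohort(
    classified, manifest,
    prioritized = prioritized, assignments = assignments,
    qc_variants = qc$retained, pgx_rules = pgx_rules,
    alpha = config$alpha, p_adjust_method = config$p_adjust_method
  )
  ratio <- nonsyn_syn_ratio(
    summarize_regions(qc$retained),
    reference = config$reference_counts
  )

  files <- NULL
  if (!is.null(config$out_dir)) {
    files <- write_report(summary, config$out_dir)
  }
  list(summary = summary, qc = qc, split = split, ratio = ratio, files = files)
}
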