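#' Multi-evidence germline prioritization cascade
#'
#' A germline variant is brought forward when it passes the global
#' minor-allele-frequency gate and at least one line of evidence marks it as
#' potentially detrimental: ClinVar pathogenic/likely-pathogenic
#' significance, a protein-truncating (stop-gain/stop-loss) consequence, a
#' splice-site consequence, a frameshift indel, or a missense change called
#' deleterious by SIFT *and* damaging by PolyPhen2. A high CADD score is
#' reported as supporting evidence but never gates the verdict.
#'
#' @param variants Germline-classified variant tibble.
#' @param gmaf_cutoff GMAF gate: the variant's maximum population AF
#'   (gnomAD, 1000 Genomes; missing treated as 0) must be below this.
#' @param cadd_cutoff CADD phred score at or above which `cadd_high` is set.
#' @param polyphen2_damaging Which PolyPhen2 classes count as damaging.
#' @return The input tibble plus logical evidence columns
#'   (`clinvar_pathogenic`, `protein_truncating`, `splice_disrupting`,
#'   `frameshift`, `missense_deleterious`, `cadd_high`, `gmaf_pass`),
#'   `verdict` (`"prioritized"`/`"not_prioritized"`), and `note`
#'   (`"missing-evidence"` for missense variants lacking both predictor
#'   calls).
#' @export
prioritize_germline <- function(variants, gmaf_cutoff = 0.01, cadd_cutoff = 20,
                                polyphen2_damaging = c(
                                  "probably_damaging",
                                  "possibly_damaging"
                                )) {
  stopifnot(gmaf_cutoff >= 0, gmaf_cutoff <= 1)
  polyphen2_damaging <- match.arg(polyphen2_damaging,
    choices = polyphen2_levels(), several.ok = TRUE
  )
  gmaf <- pmax(
    ifelse(is.na(variants$af_gnomad), 0, variants$af_gnomad),
    ifelse(is.na(variants$af_1000g), 0, variants$af_1000g)
  )
  is_missense <- !is.na(variants$functional_impact) &
    variants$functional_impact == "nonsynonymous_snv"
  out <- variants %>%
    mutate(
      gmaf_pass = .env$gmaf < .env$gmaf_cutoff,
      clinvar_pathogenic = !is.na(.data$clinvar_class) &
        .data$clinvar_class %in% c("pathogenic", "likely_pathogenic"),
      protein_truncating = !is.na(.data$functional_impact) &
        .data$functional_impact %in% c("stopgain", "stoploss"),
      splice_disrupting = (!is.na(.data$functional_impact) &
        .data$functional_impact == "splicing") |
        (!is.na(.data$genomic_region) & .data$genomic_region == "splicing"),
      frameshift = !is.na(.data$functional_impact) &
        .data$functional_impact %in% c("frameshift_insertion", "frameshift_deletion"),
      missense_deleterious = .env$is_missense &
        !is.na(.data$sift_class) & .data$sift_class == "deleterious" &
        !is.na(.data$polyphen2_class) &
        .data$polyphen2_class %in% .env$polyphen2_damaging,
      cadd_high = !is.na(.data$cadd_phred) & .data$cadd_phred >= .env$cadd_cutoff,
      note = ifelse(
        .env$is_missense & is.na(.data$sift_class) & is.na(.data$polyphen2_class),
        "missing-evidence", NA_character_
      ),
      verdict = ifelse(
        .data$gmaf_pass & (.data$clinvar_pathogenic | .data$protein_truncating |
          .data$splice_disrupting | .data$frameshift | .data$missense_deleterious),
        "prioritized", "not_prioritized"
      )
    )
  out
}

#' Recurrent and independently re-mutated genes among prioritized variants
#'
#' Two views of recurrence: the *recurrent* list groups identical events
#' (same gene and protein change) seen in at least `min_cases` distinct
#' cases; the *independent-events* list reports genes hit by at least
#' `min_cases` distinct variants (different protein changes) in distinct
#' cases — genes repeatedly but non-identically mutated.
#'
#' @param prioritized Output of [prioritize_germline], or any variant tibble
#'   with `gene`, `hgvs_p`, `case_id` (rows with `verdict` present are
#'   restricted to `"prioritized"`).
#' @param min_cases Minimum number of distinct cases.
#' @return A list with tibbles `recurrent` (`gene`, `hgvs_p`, `n_cases`,
#'   `case_ids`) and `independent_events` (`gene`, `n_variants`, `n_cases`,
#'   `case_ids`).
#' @export
detect_recurrent_germline <- function(prioritized, min_cases = 2) {
  if ("verdict" %in% names(prioritized)) {
    prioritized <- filter(prioritized, .data$verdict == "prioritized")
  }
  key <- prioritized %>%
    distinct(.data$gene, .data$hgvs_p, .data$case_id)
  recurrent <- key %>%
    group_by(.data$gene, .data$hgvs_p) %>%
    summarise(
      n_cases = n_distinct(.data$case_id),
      case_ids = paste(sort(unique(.data$case_id)), collapse = ","),
      .groups = "drop"
    ) %>%
    filter(.data$n_cases >= .env$min_cases) %>%
    arrange(dplyr::desc(.data$n_cases), .data$gene)
  independent <- key %>%
    group_by(.data$gene) %>%
    summarise(
      n_variants = n_distinct(.data$hgvs_p),
      n_cases = n_distinct(.data$case_id),
      case_ids = paste(sort(unique(.data$case_id)), collapse = ","),
      .groups = "drop"
    ) %>%
    filter(.data$n_variants >= .env$min_cases, .data$n_cases >= .env$min_cases) %>%
    arrange(dplyr::desc(.data$n_variants), .data$gene)
  list(recurrent = recurrent, independent_events = independent)
}
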