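#' Classify variant origin by the blast-fraction rule
#'
#' Tumor-only specimens lack a matched normal, so somatic status is inferred
#' from the variant allele fraction alone: in a specimen whose tumor content
#' is `blast_percent / 100`, a clonal heterozygous somatic variant is
#' expected at half that fraction, while germline variants sit at 0.5 (het)
#' or 1.0 (hom). A variant is therefore called somatic when
#' `vaf < 0.5 * blast_percent / 100` (strict inequality), germline
#' otherwise.
#'
#' Two caveat flags are attached rather than silently ignored:
#' `x_hemizygous` marks X-linked variants in male cases, where a hemizygous
#' somatic variant has doubled VAF and may be misrouted to germline; and
#' `untestable` marks variants in cases whose blast percentage puts the
#' threshold below read-count resolution (`threshold < 3 / depth`), where
#' the rule cannot separate the classes.
#'
#' @param variants QC-passing, rare variant tibble (must carry `vaf` and
#'   `depth`).
#' @param manifest Cohort manifest tibble with `case_id`, `sex`,
#'   `blast_percent`.
#' @return The variant tibble with added columns `somatic_threshold`,
#'   `origin` (`"somatic"`/`"germline"`), and `caveat` (`NA`, or
#'   `"x_hemizygous"`, `"untestable"`, or both joined by `"+"`).
#' @export
classify_origin <- function(variants, manifest) {
  unknown <- setdiff(variants$case_id, manifest$case_id)
  if (length(unknown) > 0) {
    abort(sprintf(
      "cases absent from manifest, variants unclassifiable: %s",
      paste(unique(unknown), collapse = ", ")
    ), class = "panelvar_classification_error")
  }
  if (anyNA(manifest$blast_percent)) {
    abort("blast_percent missing for some manifest cases",
      class = "panelvar_classification_error"
    )
  }
  if (any(is.na(variants$vaf) | variants$depth <= 0)) {
    abort("classification needs vaf and positive depth on every record",
      class = "panelvar_classification_error"
    )
  }
  x_genes <- panel_genes() %>%
    filter(.data$chrom == "chrX") %>%
    pull(.data$gene)
  out <- variants %>%
    left_join(
      manifest %>% select("case_id", "sex", "blast_percent"),
      by = "case_id"
    ) %>%
    mutate(
      somatic_threshold = 0.5 * .data$blast_percent / 100,
      origin = ifelse(.data$vaf < .data$somatic_threshold, "somatic", "germline"),
      caveat_x = .data$sex == "male" &
        (.data$chrom == "chrX" | .data$gene %in% x_genes),
      caveat_untestable = .data$somatic_threshold < 3 / .data$depth,
      caveat = dplyr::case_when(
        .data$caveat_x & .data$caveat_untestable ~ "x_hemizygous+untestable",
        .data$caveat_x ~ "x_hemizygous",
        .data$caveat_untestable ~ "untestable",
        TRUE ~ NA_character_
      )
    ) %>%
    select(-"caveat_x", -"caveat_untestable", -"sex", -"blast_percent")
  out
}

#' Order co-existing somatic mutations into founding clone and subclone
#'
#' When a case carries two or more non-silent somatic mutations, their VAF
#' spread hints at clonal architecture: the highest-VAF mutation defines the
#' founding clone, and a lower-VAF mutation is placed in the same clone when
#' its VAF sits within `delta_threshold` of the maximum, in a subclone
#' otherwise. The reasoning is ordinal — no mixture model or cancer-cell
#' fraction estimation is attempted.
#'
#' @param variants Non-silent somatic variants, across one or more cases
#'   (must carry `case_id`, `vaf`, and ideally `gene`/`hgvs_p` for
#'   readability).
#' @param delta_threshold Maximum VAF gap to the case maximum for
#'   founding-clone co-membership.
#' @return A tibble with one row per variant in cases having >= 2 qualifying
#'   variants: `case_id`, `gene`, `hgvs_p`, `vaf`, `rank` (1 = highest VAF),
#'   `clone_label` (`"founding"`/`"subclone"`), `delta_vaf` (gap to the
#'   previous rank, `NA` for rank 1). Cases with fewer than 2 variants are
#'   omitted.
#' @export
assign_clones <- function(variants, delta_threshold = 0.1) {
  stopifnot(delta_threshold >= 0)
  for (col in c("gene", "hgvs_p")) {
    if (!col %in% names(variants)) variants[[col]] <- NA_character_
  }
  eligible <- variants %>%
    group_by(.data$case_id) %>%
    filter(n() >= 2)
  if (nrow(eligible) == 0) {
    return(tibble(
      case_id = character(0), gene = character(0), hgvs_p = character(0),
      vaf = numeric(0), rank = integer(0), clone_label = character(0),
      delta_vaf = numeric(0)
    ))
  }
  eligible %>%
    arrange(dplyr::desc(.data$vaf), .by_group = TRUE) %>%
    mutate(
      rank = row_number(),
      clone_label = ifelse(max(.data$vaf) - .data$vaf <= .env$delta_threshold,
        "founding", "subclone"
      ),
      delta_vaf = c(NA_real_, -diff(.data$vaf))
    ) %>%
    ungroup() %>%
    select("case_id", "gene", "hgvs_p", "vaf", "rank", "clone_label", "delta_vaf")
}
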