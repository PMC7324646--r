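#' Tabulate variants by genomic region and functional impact
#'
#' The machine-readable twin of a panel study's region/impact summary table:
#' every variant increments exactly one region counter, and exonic or
#' splicing variants additionally increment exactly one functional-impact
#' counter.
#'
#' @param variants Annotated variant tibble.
#' @return A list of class `panelvar_region_impact` with tibbles `regions`
#'   (`genomic_region`, `n`) and `impacts` (`functional_impact`, `n`), plus
#'   `total` and `coding_total`.
#' @export
summarize_regions <- function(variants) {
  check_tokens(variants$genomic_region, genomic_regions(), "genomic_region",
    allow_na = FALSE
  )
  regions <- tibble(genomic_region = genomic_regions()) %>%
    left_join(count(variants, .data$genomic_region), by = "genomic_region") %>%
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
  coding <- variants %>%
    filter(.data$genomic_region %in% c("exonic", "splicing"))
  check_tokens(coding$functional_impact,
    setdiff(functional_impacts(), "not_applicable"),
    "functional_impact (coding)",
    allow_na = FALSE
  )
  impacts <- tibble(
    functional_impact = setdiff(functional_impacts(), "not_applicable")
  ) %>%
    left_join(count(coding, .data$functional_impact), by = "functional_impact") %>%
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
  structure(
    list(
      regions = regions, impacts = impacts,
      total = nrow(variants), coding_total = nrow(coding)
    ),
    class = "panelvar_region_impact"
  )
}

#' Partition variants into silent and non-silent
#'
#' Non-silent events are those expected to alter the protein or its
#' splicing: missense (nonsynonymous SNV), stop-gain/stop-loss, frameshift
#' insertions/deletions, and splice-site variants. Everything else —
#' synonymous, UTR, intronic, upstream/downstream, and in-frame
#' (non-frameshift) indels — is silent. In-frame indels do alter protein
#' sequence; set `nonframeshift_is_nonsilent = TRUE` to move them, the
#' default keeps them silent.
#'
#' @param functional_impact,genomic_region Character vectors (recycled
#'   together).
#' @param nonframeshift_is_nonsilent Treat in-frame indels as non-silent.
#' @return Character vector of `"silent"`/`"non_silent"`.
#' @export
classify_silence <- function(functional_impact, genomic_region,
                             nonframeshift_is_nonsilent = FALSE) {
  check_tokens(functional_impact, functional_impacts(), "functional_impact")
  check_tokens(genomic_region, genomic_regions(), "genomic_region")
  nonsilent_impacts <- c(
    "nonsynonymous_snv", "stopgain", "stoploss", "splicing",
    "frameshift_insertion", "frameshift_deletion"
  )
  if (nonframeshift_is_nonsilent) {
    nonsilent_impacts <- c(
      nonsilent_impacts,
      "nonframeshift_insertion", "nonframeshift_deletion"
    )
  }
  ifelse(
    (!is.na(functional_impact) & functional_impact %in% nonsilent_impacts) |
      (!is.na(genomic_region) & genomic_region == "splicing"),
    "non_silent", "silent"
  )
}

#' Nonsynonymous/synonymous ratio with optional reference comparison
#'
#' The ratio of nonsynonymous to synonymous coding SNVs; elevation over a
#' matched healthy reference suggests positive selection on (or elevated
#' mutation of) nonsynonymous sites.
#'
#' @param counts A [summarize_regions] result, or a variant tibble, or a
#'   named vector/list with `nonsynonymous_snv` and `synonymous_snv` counts.
#' @param reference Optional reference counts: a two-element named
#'   vector/list (`nonsyn`, `syn`) or a path to a TSV with those columns.
#' @return A tibble with `cohort_nonsyn`, `cohort_syn`, `cohort_ratio`
#'   (2 decimals; `NA` when syn = 0) and, when a reference is supplied,
#'   `reference_nonsyn`, `reference_syn`, `reference_ratio`.
#' @export
nonsyn_syn_ratio <- function(counts, reference = NULL) {
  extract <- function(x) {
    if (inherits(x, "panelvar_region_impact")) {
      imp <- setNames(x$impacts$n, x$impacts$functional_impact)
      c(nonsyn = unname(imp["nonsynonymous_snv"]), syn = unname(imp["synonymous_snv"]))
    } else if (is.data.frame(x) && all(c("nonsyn", "syn") %in% names(x))) {
      c(nonsyn = sum(x$nonsyn), syn = sum(x$syn))
    } else if (is.data.frame(x)) {
      c(
        nonsyn = sum(x$functional_impact == "nonsynonymous_snv", na.rm = TRUE),
        syn = sum(x$functional_impact == "synonymous_snv", na.rm = TRUE)
      )
    } else {
      x <- unlist(x)
      nm <- names(x)
      nonsyn <- if ("nonsyn" %in% nm) x[["nonsyn"]] else x[["nonsynonymous_snv"]]
      syn <- if ("syn" %in% nm) x[["syn"]] else x[["synonymous_snv"]]
      c(nonsyn = nonsyn, syn = syn)
    }
  }
  cohort <- extract(counts)
  ratio <- function(p) if (p[["syn"]] == 0) NA_real_ else round(p[["nonsyn"]] / p[["syn"]], 2)
  out <- tibble(
    cohort_nonsyn = cohort[["nonsyn"]], cohort_syn = cohort[["syn"]],
    cohort_ratio = ratio(cohort)
  )
  if (!is.null(reference)) {
    if (is.character(reference) && length(reference) == 1) {
      reference <- readr::read_tsv(reference, col_types = readr::cols(), progress = FALSE)
    }
    ref <- extract(reference)
    out$reference_nonsyn <- ref[["nonsyn"]]
    out$reference_syn <- ref[["syn"]]
    out$reference_ratio <- ratio(ref)
  }
  out
}

#' Bin PhyloP conservation scores
#'
#' Scores above 4 mark highly conserved sites, scores in `[1, 4]`
#' moderately conserved, scores below 1 non-conserved; missing scores stay
#' missing.
#'
#' @param phylop Numeric vector (NA for missing).
#' @return Character vector over
#'   `{"high", "moderate", "non_conserved", NA}`.
#' @export
bin_conservation <- function(phylop) {
  dplyr::case_when(
    is.na(phylop) ~ NA_character_,
    phylop > 4 ~ "high",
    phylop >= 1 ~ "moderate",
    TRUE ~ "non_conserved"
  )
}

#' Render the region/impact count table as text
#'
#' Splicing is its own region token internally, but for rendering it is
#' folded into the exonic subtotal so region counts stay comparable with
#' conventional region tables (a footnote records the fold).
#'
#' @param ri A [summarize_regions] result.
#' @return Character vector of report lines.
#' @export
render_region_table <- function(ri) {
  stopifnot(inherits(ri, "panelvar_region_impact"))
  regions <- ri$regions
  exonic_n <- sum(regions$n[regions$genomic_region %in% c("exonic", "splicing")])
  display <- regions %>% filter(.data$genomic_region != "splicing")
  display$n[display$genomic_region == "exonic"] <- exonic_n
  pretty_impact <- c(
    nonsynonymous_snv = "Non-synonymous", synonymous_snv = "Synonymous",
    stopgain = "Stop-gain", stoploss = "Stop-loss", splicing = "Splicing",
    frameshift_insertion = "Frameshift insertion",
    frameshift_deletion = "Frameshift deletion",
    nonframeshift_insertion = "Non-frameshift insertion",
    nonframeshift_deletion = "Non-frameshift deletion"
  )
  c(
    "Genomic region\tNo. of variants",
    sprintf("%s\t%d", tools::toTitleCase(display$genomic_region), display$n),
    sprintf("Total\t%d", ri$total),
    "Functional impact\tNo. of variants",
    sprintf("%s\t%d", pretty_impact[ri$impacts$functional_impact], ri$impacts$n),
    "# splicing-region variants are folded into the exonic subtotal above"
  )
}
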