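#' Filter thresholds for staged variant QC
#'
#' Defaults follow the tumor-only panel workflow this package implements:
#' sites are removed when QUAL < 50, DP < 20, or GQ < 20 (strict
#' less-than, so a record sitting exactly on a threshold is kept), and
#' variants with a population allele frequency of 1% or more in either
#' gnomAD or the 1000 Genomes Project are routed to the common pool
#' (removal is `>=`, so AF exactly 1% counts as common).
#'
#' @param min_qual Minimum site quality (QUAL).
#' @param min_depth Minimum read depth (DP).
#' @param min_gq Minimum genotype quality (GQ).
#' @param max_pop_af Population-AF cutoff for the rarity filter.
#' @return A list of class `panelvar_thresholds`.
#' @export
filter_thresholds <- function(min_qual = 50, min_depth = 20L, min_gq = 20,
                              max_pop_af = 0.01) {
  stopifnot(
    min_qual >= 0, min_depth >= 0, min_gq >= 0,
    max_pop_af >= 0, max_pop_af <= 1
  )
  structure(
    list(
      min_qual = min_qual, min_depth = as.integer(min_depth),
      min_gq = min_gq, max_pop_af = max_pop_af
    ),
    class = "panelvar_thresholds"
  )
}

#' Site/genotype quality filter
#'
#' Partitions variants into a retained set (QUAL, DP, and GQ all at or above
#' their thresholds) and a removed set. The removed set carries a
#' `failed_condition` column naming which leg(s) failed.
#'
#' @param variants A variant tibble.
#' @param thresholds A [filter_thresholds] object.
#' @return A list with tibbles `retained` and `removed`.
#' @export
apply_qc_filter <- function(variants, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "panelvar_thresholds"))
  fail_qual <- variants$qual < thresholds$min_qual
  fail_dp <- variants$depth < thresholds$min_depth
  fail_gq <- variants$genotype_quality < thresholds$min_gq
  keep <- !(fail_qual | fail_dp | fail_gq)
  removed <- variants[!keep, , drop = FALSE]
  if (nrow(removed) > 0) {
    removed$failed_condition <- apply(
      cbind(
        ifelse(fail_qual[!keep], "QUAL", NA),
        ifelse(fail_dp[!keep], "DP", NA),
        ifelse(fail_gq[!keep], "GQ", NA)
      ),
      1, function(x) paste(x[!is.na(x)], collapse = "+")
    )
  } else {
    removed$failed_condition <- character(0)
  }
  list(retained = variants[keep, , drop = FALSE], removed = removed)
}

#' Population-allele-frequency rarity filter
#'
#' A QC-passing variant is routed to the common pool when its allele
#' frequency in *either* gnomAD or the 1000 Genomes Project reaches
#' `max_pop_af`; a missing frequency is treated as rare (absence from the
#' population databases is evidence of rarity, not commonness). Common
#' variants are not discarded: they bypass somatic/germline interpretation
#' but stay visible to the pharmacogenomic lookup, which deliberately
#' concerns common polymorphisms.
#'
#' @inheritParams apply_qc_filter
#' @return A list with tibbles `rare` and `common`.
#' @export
apply_popaf_filter <- function(variants, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "panelvar_thresholds"))
  common <- (!is.na(variants$af_gnomad) & variants$af_gnomad >= thresholds$max_pop_af) |
    (!is.na(variants$af_1000g) & variants$af_1000g >= thresholds$max_pop_af)
  list(
    rare = variants[!common, , drop = FALSE],
    common = variants[common, , drop = FALSE]
  )
}
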