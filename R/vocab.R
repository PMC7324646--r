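#' Controlled vocabularies used across the pipeline
#'
#' The pipeline consumes ANNOVAR-style annotation categories. These helpers
#' return the allowed tokens so callers can validate their own tables before
#' handing them to the classifier.
#'
#' @return A character vector of allowed tokens.
#' @name vocab
NULL

#' @rdname vocab
#' @export
genomic_regions <- function() {
  c("exonic", "splicing", "intronic", "upstream", "downstream", "UTR5", "UTR3")
}

#' @rdname vocab
#' @export
functional_impacts <- function() {
  c(
    "nonsynonymous_snv", "synonymous_snv", "stopgain", "stoploss", "splicing",
    "frameshift_insertion", "frameshift_deletion",
    "nonframeshift_insertion", "nonframeshift_deletion", "not_applicable"
  )
}

#' @rdname vocab
#' @export
genotype_levels <- function() c("het", "hom_alt", "hemi", "other")

#' @rdname vocab
#' @export
sift_levels <- function() c("deleterious", "tolerated")

#' @rdname vocab
#' @export
polyphen2_levels <- function() c("probably_damaging", "possibly_damaging", "benign")

#' @rdname vocab
#' @export
clinvar_levels <- function() c("pathogenic", "likely_pathogenic", "vus", "benign_like")

# Columns a fully annotated variant table carries. `vaf` is always recomputed
# from alt_depth/depth; an upstream AF field is never trusted.
variant_columns <- function() {
  c(
    "case_id", "chrom", "pos", "ref", "alt", "qual", "depth", "alt_depth",
    "genotype_quality", "genotype", "vaf",
    "gene", "genomic_region", "functional_impact", "hgvs_p",
    "af_gnomad", "af_1000g", "sift_class", "polyphen2_class",
    "cadd_phred", "phylop", "clinvar_class", "cosmic_id", "rsid",
    "transcripts_affected", "transcripts_total"
  )
}

check_tokens <- function(x, allowed, what, allow_na = TRUE) {
  bad <- setdiff(unique(x[!is.na(x)]), allowed)
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid %s token(s): %s; allowed: %s",
      what, paste(bad, collapse = ", "), paste(allowed, collapse = ", ")
    ), class = "panelvar_validation_error")
  }
  if (!allow_na && anyNA(x)) {
    abort(sprintf("missing values not allowed in %s", what),
      class = "panelvar_validation_error"
    )
  }
  invisible(x)
}

validate_variants <- function(variants) {
  stopifnot(is.data.frame(variants))
  missing_cols <- setdiff(variant_columns(), names(variants))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "variant table lacks column(s): %s",
      paste(missing_cols, collapse = ", ")
    ), class = "panelvar_configuration_error")
  }
  check_tokens(variants$genomic_region, genomic_regions(), "genomic_region")
  check_tokens(variants$functional_impact, functional_impacts(), "functional_impact")
  check_tokens(variants$genotype, genotype_levels(), "genotype")
  if (any(variants$alt_depth > variants$depth, na.rm = TRUE)) {
    abort("alt_depth exceeds depth", class = "panelvar_validation_error")
  }
  bad_impact <- !is.na(variants$genomic_region) &
    !(variants$genomic_region %in% c("exonic", "splicing")) &
    !is.na(variants$functional_impact) &
    variants$functional_impact != "not_applicable"
  if (any(bad_impact)) {
    abort("functional_impact must be not_applicable outside exonic/splicing regions",
      class = "panelvar_validation_error"
    )
  }
  invisible(variants)
}
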