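# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles deliberately use plain loops / base R so they share no code
# with the implementation they check.

make_random_filter_records <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    case_id = sample(sprintf("C%02d", 1:10), n, replace = TRUE),
    qual = round(runif(n, 0, 120), 1),
    depth = sample(0:80, n, replace = TRUE),
    genotype_quality = round(runif(n, 0, 99)),
    af_gnomad = ifelse(runif(n) < 0.3, NA_real_, runif(n, 0, 0.05)),
    af_1000g = ifelse(runif(n) < 0.5, NA_real_, runif(n, 0, 0.05))
  )
}

oracle_qc_keep <- function(records, thr) {
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    keep[i] <- !(r$qual < thr$min_qual) &&
      !(r$depth < thr$min_depth) &&
      !(r$genotype_quality < thr$min_gq)
  }
  keep
}

oracle_popaf_common <- function(records, thr) {
  common <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    g <- !is.na(r$af_gnomad) && r$af_gnomad >= thr$max_pop_af
    k <- !is.na(r$af_1000g) && r$af_1000g >= thr$max_pop_af
    common[i] <- g || k
  }
  common
}

oracle_prioritize <- function(v, gmaf_cutoff = 0.01) {
  verdict <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    r <- v[i, ]
    gmaf <- max(
      ifelse(is.na(r$af_gnomad), 0, r$af_gnomad),
      ifelse(is.na(r$af_1000g), 0, r$af_1000g)
    )
    clinvar <- !is.na(r$clinvar_class) &&
      r$clinvar_class %in% c("pathogenic", "likely_pathogenic")
    trunc <- !is.na(r$functional_impact) &&
      r$functional_impact %in% c("stopgain", "stoploss")
    splice <- (!is.na(r$functional_impact) && r$functional_impact == "splicing") ||
      (!is.na(r$genomic_region) && r$genomic_region == "splicing")
    fs <- !is.na(r$functional_impact) &&
      r$functional_impact %in% c("frameshift_insertion", "frameshift_deletion")
    mis <- !is.na(r$functional_impact) &&
      r$functional_impact == "nonsynonymous_snv" &&
      !is.na(r$sift_class) && r$sift_class == "deleterious" &&
      !is.na(r$polyphen2_class) &&
      r$polyphen2_class %in% c("probably_damaging", "possibly_damaging")
    verdict[i] <- if (gmaf < gmaf_cutoff && (clinvar || trunc || splice || fs || mis)) {
      "prioritized"
    } else {
      "not_prioritized"
    }
  }
  verdict
}

# A minimal classified-variant table: `blank_rows(n)` gives n valid rows that
# individual tests then overwrite column-wise.
blank_rows <- function(n) {
  tibble::tibble(
    case_id = "C01", chrom = "chr1", pos = seq_len(n), ref = "A", alt = "G",
    qual = 1000, depth = 5000L, alt_depth = 500L, genotype_quality = 99,
    genotype = "het", vaf = 0.1, gene = "TET2", genomic_region = "exonic",
    functional_impact = "nonsynonymous_snv", hgvs_p = NA_character_,
    af_gnomad = NA_real_, af_1000g = NA_real_, sift_class = NA_character_,
    polyphen2_class = NA_character_, cadd_phred = NA_real_,
    phylop = NA_real_, clinvar_class = NA_character_,
    cosmic_id = NA_character_, rsid = NA_character_,
    transcripts_affected = 1L, transcripts_total = 1L
  )
}

# The somatic landscape encoded category-by-category as enumerated for the
# cohort this package's worked example mirrors: 23 non-silent (18 missense,
# 2 stop-gain, 1 splice, 2 frameshift deletions) and 15 silent events.
enumerated_somatic_categories <- function() {
  tibble::tibble(
    functional_impact = c(
      rep("nonsynonymous_snv", 18), rep("stopgain", 2), "splicing",
      rep("frameshift_deletion", 2),
      rep("synonymous_snv", 2), rep("not_applicable", 10),
      rep("nonframeshift_insertion", 2), "nonframeshift_deletion"
    ),
    genomic_region = c(
      rep("exonic", 20), "splicing", rep("exonic", 2),
      rep("exonic", 2), rep("downstream", 2), "UTR3", rep("intronic", 7),
      rep("exonic", 3)
    )
  )
}

# Cohort with configurable planted high-burden cases for the burden test.
make_burden_cohort <- function(n_cases = 26, planted = character(0),
                               planted_n = 12, background_mean = 1.5, seed = 1) {
  set.seed(seed)
  genes <- panelvar::panel_genes()$gene
  manifest <- tibble::tibble(
    case_id = sprintf("B%02d", seq_len(n_cases)),
    sex = "female", blast_percent = 60, karyotype_note = NA_character_
  )
  manifest$case_id[seq_along(planted)] <- planted
  rows <- list()
  for (i in seq_len(n_cases)) {
    k <- if (manifest$case_id[i] %in% planted) {
      planted_n
    } else {
      stats::rpois(1, background_mean)
    }
    if (k > 0) {
      r <- blank_rows(k)
      r$case_id <- manifest$case_id[i]
      r$gene <- sample(genes, k, replace = FALSE)
      r$origin <- "somatic"
      rows[[length(rows) + 1]] <- r
    }
  }
  list(manifest = manifest, classified = dplyr::bind_rows(rows))
}
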