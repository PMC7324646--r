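#' Worked-example cohort
#'
#' A small, fully synthetic 26-case worked example whose headline numbers
#' mirror a published ultra-deep 54-gene myeloid-panel cohort: 38 somatic
#' mutations (23 non-silent, 1.46 per case), 18 prioritized germline
#' variants across 15 cases, recurrent events (a nonsynonymous SNV recurring
#' in 4 cases in CDKN2A, in 3 cases each in STAG2 and BCORL1, two-case
#' germline recurrences in GATA2 and NPM1, three independent WT1 germline
#' hits), BCOR hit in 4 distinct cases counting somatic plus germline
#' events, a 9/8/6/3 both/somatic-only/germline-only/neither co-occurrence
#' split (23 of 26 cases with any non-silent event), and a TP53 rs1042522
#' risk genotype in 19 of 26 cases. Case identifiers, variant positions, and
#' read supports are invented; only the category structure and counts are
#' meaningful.
#'
#' These objects let the documentation, tests, and the acceptance script run
#' the whole cohort-statistics stack on known inputs without any sequencing
#' data.
#'
#' @return `worked_example_cohort()`: a list with `manifest` (26 cases),
#'   `classified` (56 origin-labelled variants: 38 somatic + 18 germline),
#'   and `pgx_variants` (QC-passing rs1042522 calls for the lookup).
#' @name worked_example
NULL

example_case_ids <- function() sprintf("AM%02d", 1:26)

blank_variant_row <- function(n) {
  tibble(
    case_id = NA_character_, chrom = "chr1", pos = seq_len(n),
    ref = "A", alt = "G",
    qual = 1000, depth = 5000L, alt_depth = 500L,
    genotype_quality = 99, genotype = "het", vaf = 0.1,
    gene = NA_character_, genomic_region = "exonic",
    functional_impact = "nonsynonymous_snv", hgvs_p = NA_character_,
    af_gnomad = NA_real_, af_1000g = NA_real_,
    sift_class = NA_character_, polyphen2_class = NA_character_,
    cadd_phred = NA_real_, phylop = NA_real_,
    clinvar_class = NA_character_, cosmic_id = NA_character_,
    rsid = NA_character_,
    transcripts_affected = 1L, transcripts_total = 1L
  )
}

#' @rdname worked_example
#' @export
worked_example_cohort <- function() {
  manifest <- tibble(
    case_id = example_case_ids(),
    sex = rep(c("male", "female"), length.out = 26),
    blast_percent = round(seq(40, 90, length.out = 26), 1),
    karyotype_note = NA_character_
  )

  # 23 non-silent somatic events: 18 nonsynonymous SNVs, 2 stop-gains,
  # 1 splice-site SNV, 2 frameshift deletions, over 17 distinct cases.
  ns <- tibble(
    case_id = c(
      "AM01", "AM01", "AM02", "AM02", "AM03", "AM03", "AM04", "AM04",
      "AM05", "AM05", "AM06", "AM06", "AM07", "AM08", "AM09", "AM10",
      "AM11", "AM12", "AM13", "AM14", "AM15", "AM16", "AM17"
    ),
    gene = c(
      "BCOR", "RAD21", "STAG2", "CDKN2A", "BCOR", "KIT", "STAG2", "CDKN2A",
      "BCOR", "KIT", "STAG2", "CDKN2A", "CDKN2A", "SRSF2", "CBL", "BCORL1",
      "BCORL1", "BCORL1", "NRAS", "CUX1", "DNMT3A", "RUNX1", "CSF3R"
    ),
    hgvs_p = c(
      "p.V1675G", "p.R478X", "p.L526F", "p.R90C", "p.V1649I", "p.D419fs",
      "p.L526F", "p.R90C", "p.P1398Q", "p.R420fs", "p.L526F", "p.R90C",
      "p.R90C", "p.Q88X", NA, "p.A400V", "p.A400V", "p.A400V", "p.G12S",
      "p.L509V", "p.R730C", "p.R80H", "p.T618I"
    ),
    genomic_region = c(
      rep("exonic", 14), "splicing", rep("exonic", 8)
    ),
    functional_impact = c(
      "nonsynonymous_snv", "stopgain", "nonsynonymous_snv", "nonsynonymous_snv",
      "nonsynonymous_snv", "frameshift_deletion", "nonsynonymous_snv",
      "nonsynonymous_snv", "nonsynonymous_snv", "frameshift_deletion",
      "nonsynonymous_snv", "nonsynonymous_snv", "nonsynonymous_snv",
      "stopgain", "splicing", "nonsynonymous_snv", "nonsynonymous_snv",
      "nonsynonymous_snv", "nonsynonymous_snv", "nonsynonymous_snv",
      "nonsynonymous_snv", "nonsynonymous_snv", "nonsynonymous_snv"
    ),
    vaf = c(
      0.167, 0.12, 0.102, 0.084, 0.135, 0.418, 0.111, 0.09, 0.15, 0.42,
      0.105, 0.105, 0.093, 0.214, 0.203, 0.08, 0.097, 0.106, 0.11,
      0.366, 0.112, 0.25, 0.108
    )
  )
  # 15 silent somatic events: 2 synonymous, 2 downstream, 1 UTR3, 7 intronic,
  # 2 non-frameshift insertions, 1 non-frameshift deletion.
  sil <- tibble(
    case_id = sprintf("AM%02d", c(1:7, 9, 11, 13, 15, 17, 19, 21, 23)),
    gene = c(
      "TET2", "ASXL1", "JAK2", "MPL", "SF3B1", "U2AF1", "SMC3", "IDH1",
      "IDH2", "GNAS", "SETBP1", "PTPN11", "CEBPA", "ETV6", "FLT3"
    ),
    hgvs_p = NA_character_,
    genomic_region = c(
      "exonic", "exonic", "downstream", "downstream", "UTR3",
      rep("intronic", 7), "exonic", "exonic", "exonic"
    ),
    functional_impact = c(
      "synonymous_snv", "synonymous_snv", rep("not_applicable", 10),
      "nonframeshift_insertion", "nonframeshift_insertion",
      "nonframeshift_deletion"
    ),
    vaf = round(seq(0.05, 0.2, length.out = 15), 3)
  )
  somatic <- bind_rows(ns, sil)
  somatic_rows <- blank_variant_row(nrow(somatic))
  for (col in names(somatic)) somatic_rows[[col]] <- somatic[[col]]
  fs <- somatic_rows$functional_impact %in%
    c("frameshift_deletion", "nonframeshift_deletion")
  somatic_rows$ref[fs] <- "ATG"
  ins <- somatic_rows$functional_impact == "nonframeshift_insertion"
  somatic_rows$alt[ins] <- "GTCA"
  somatic_rows$origin <- "somatic"

  # 18 prioritized germline variants over 15 cases (AM09-AM23): 13 missense
  # (SIFT deleterious + PolyPhen2 damaging), 1 stop-gain, 1 splice-site,
  # 3 frameshift insertions; GATA2 and NPM1 events recur in two cases each,
  # WT1 is hit by three distinct variants in three cases.
  germ <- tibble(
    case_id = c(
      "AM09", "AM10", "AM11", "AM12", "AM13", "AM14", "AM15", "AM16",
      "AM17", "AM18", "AM19", "AM20", "AM21", "AM22", "AM23",
      "AM09", "AM10", "AM11"
    ),
    gene = c(
      "GATA2", "GATA2", "NPM1", "NPM1", "WT1", "WT1", "WT1", "BCOR",
      "PHF6", "CALR", "ABL1", "KRAS", "PTEN", "SMC1A", "ZRSR2",
      "ETV6", "RUNX1", "TET2"
    ),
    hgvs_p = c(
      "p.T358P", "p.T358P", "p.L258fs", "p.L258fs", "p.R441X", "p.D396N",
      "p.A382T", "p.S1582G", NA, "p.K385fs", "p.E255K", "p.G60D",
      "p.R130Q", "p.R96W", "p.S447P", "p.P214L", "p.L472F", "p.I1873T"
    ),
    genomic_region = c(
      rep("exonic", 8), "splicing", rep("exonic", 9)
    ),
    functional_impact = c(
      "nonsynonymous_snv", "nonsynonymous_snv", "frameshift_insertion",
      "frameshift_insertion", "stopgain", "nonsynonymous_snv",
      "nonsynonymous_snv", "nonsynonymous_snv", "splicing",
      "frameshift_insertion", rep("nonsynonymous_snv", 8)
    ),
    vaf = round(seq(0.46, 0.54, length.out = 18), 3)
  )
  germ_rows <- blank_variant_row(nrow(germ))
  for (col in names(germ)) germ_rows[[col]] <- germ[[col]]
  missense <- germ_rows$functional_impact == "nonsynonymous_snv"
  germ_rows$sift_class[missense] <- "deleterious"
  germ_rows$polyphen2_class[missense] <- "probably_damaging"
  germ_rows$clinvar_class[c(5, 3)] <- "pathogenic"
  germ_rows$cadd_phred <- 25
  germ_rows$alt[germ_rows$functional_impact == "frameshift_insertion"] <- "AGT"
  germ_rows$origin <- "germline"

  classified <- bind_rows(somatic_rows, germ_rows)
  classified$pos <- seq_len(nrow(classified)) * 101L
  classified$silence <- classify_silence(
    classified$functional_impact, classified$genomic_region
  )

  # rs1042522 (TP53, ref G, alt C): 7 cases homozygous reference (no call),
  # 12 heterozygous, 7 homozygous alternate -> 19/26 carry GG or GC.
  het_cases <- example_case_ids()[8:19]
  hom_cases <- example_case_ids()[20:26]
  pgx <- blank_variant_row(length(het_cases) + length(hom_cases))
  pgx$case_id <- c(het_cases, hom_cases)
  pgx$gene <- "TP53"
  pgx$ref <- "G"
  pgx$alt <- "C"
  pgx$rsid <- "rs1042522"
  pgx$genotype <- c(
    rep("het", length(het_cases)),
    rep("hom_alt", length(hom_cases))
  )
  pgx$af_gnomad <- 0.54

  list(manifest = manifest, classified = classified, pgx_variants = pgx)
}

#' @rdname worked_example
#' @return `worked_example_region_counts()`: region and functional-impact
#'   count tables for a 293-variant post-QC cohort (the region counts sum to
#'   the cohort total; the functional counts give a nonsyn/syn ratio of
#'   1.16).
#' @export
worked_example_region_counts <- function() {
  list(
    regions = tibble(
      genomic_region = c(
        "exonic", "intronic", "upstream", "downstream", "UTR5", "UTR3"
      ),
      n = c(146L, 133L, 0L, 3L, 2L, 9L)
    ),
    impacts = tibble(
      functional_impact = c(
        "nonsynonymous_snv", "synonymous_snv", "stopgain", "splicing",
        "frameshift_insertion", "frameshift_deletion",
        "nonframeshift_insertion", "nonframeshift_deletion"
      ),
      n = c(71L, 61L, 3L, 2L, 3L, 2L, 2L, 3L)
    ),
    total = 293L
  )
}

#' @rdname worked_example
#' @return `worked_example_clonal_vafs()`: the seven co-mutated cases used
#'   to illustrate founding-clone/subclone ordering, with the assignment the
#'   default VAF-gap threshold should reproduce in `expected_clone`.
#' @export
worked_example_clonal_vafs <- function() {
  tibble(
    case_id = c(
      "AM01", "AM01", "AM03", "AM03", "AM03", "AM16", "AM16",
      "AM19", "AM19", "AM23", "AM23", "AM25", "AM25", "AM26", "AM26"
    ),
    gene = c(
      "RUNX1", "CBL", "KIT", "KIT", "BCOR", "DNMT3A", "STAG2",
      "CUX1", "STAG2", "CDKN2A", "RUNX1", "CSF3R", "BCORL1",
      "SRSF2", "BCORL1"
    ),
    hgvs_p = c(
      "p.R80H", "c.1096-2", "p.D419fs", "p.R420fs", "p.V1649I",
      "p.R730C", "p.L526F", "p.L509V", "p.L526F", "p.R90C", "p.N434K",
      "p.T618I", "p.A400V", "p.Q88X", "p.A400V"
    ),
    vaf = c(
      0.25, 0.203, 0.418, 0.42, 0.135, 0.112, 0.102,
      0.366, 0.126, 0.214, 0.159, 0.108, 0.097, 0.214, 0.08
    ),
    expected_clone = c(
      "founding", "founding", "founding", "founding", "subclone",
      "founding", "founding", "founding", "subclone", "founding",
      "founding", "founding", "founding", "founding", "subclone"
    )
  )
}
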