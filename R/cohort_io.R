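#' Read a cohort manifest
#'
#' The manifest lists one row per cohort member with the clinical fields the
#' tumor-only classifier needs: a unique case identifier, sex, and the
#' percentage of circulating blast cells (the proxy for tumor fraction in a
#' peripheral-blood specimen). An optional `karyotype_note` column is carried
#' through verbatim.
#'
#' @param path Path to a tab-separated file with header columns `case_id`,
#'   `sex`, `blast_percent` (and optionally `karyotype_note`).
#' @return A tibble with columns `case_id`, `sex` (`male`/`female`/`unknown`),
#'   `blast_percent` (0-100), `karyotype_note`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("manifest not found: %s", path), class = "panelvar_io_error")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  required <- c("case_id", "sex", "blast_percent")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "manifest lacks required column(s): %s",
      paste(missing_cols, collapse = ", ")
    ), class = "panelvar_configuration_error")
  }
  if (!"karyotype_note" %in% names(raw)) raw$karyotype_note <- NA_character_
  raw <- mutate(raw, across(all_of(c("case_id", "sex", "blast_percent")), trimws))
  if (any(raw$blast_percent == "")) {
    abort("manifest rows with blank blast_percent are not allowed",
      class = "panelvar_validation_error"
    )
  }
  out <- tibble(
    case_id = raw$case_id,
    sex = tolower(raw$sex),
    blast_percent = suppressWarnings(as.numeric(raw$blast_percent)),
    karyotype_note = raw$karyotype_note
  )
  check_tokens(out$sex, c("male", "female", "unknown"), "sex", allow_na = FALSE)
  if (anyNA(out$blast_percent) ||
    any(out$blast_percent < 0 | out$blast_percent > 100)) {
    abort("blast_percent must be numeric in [0, 100]",
      class = "panelvar_validation_error"
    )
  }
  if (anyDuplicated(out$case_id) > 0) {
    abort(sprintf(
      "duplicate case_id in manifest: %s",
      paste(unique(out$case_id[duplicated(out$case_id)]), collapse = ", ")
    ), class = "panelvar_validation_error")
  }
  out
}

#' Read per-case variant calls with annotations
#'
#' Two dialects are supported. `"annotated_tsv"` is a flat table carrying the
#' call fields (`qual`, `depth`, `alt_depth`, `genotype_quality`, `genotype`)
#' together with ANNOVAR-style annotation columns; `"."` marks a missing
#' value. `"vcf"` is a VCF 4.2 file whose FORMAT block carries `GT:DP:AD:GQ`
#' and whose INFO block may carry the same annotations (keys `GENE`, `REGION`,
#' `IMPACT`, `HGVSP`, `AF_GNOMAD`, `AF_1000G`, `SIFT`, `PP2`, `CADD`,
#' `PHYLOP`, `CLINVAR`, `COSMIC`, `RSID`, `TRA`, `TRT`); absent keys become
#' missing values. The sample column name is taken as the case id unless the
#' INFO key `CASE` overrides it.
#'
#' The variant allele fraction is always recomputed as `alt_depth / depth`
#' from the AD field; any caller-supplied AF value is ignored. Multi-allelic
#' VCF records are split into one row per alternate allele. Records with zero
#' depth are skipped with a warning rather than failing the whole file.
#'
#' @param path Input file path.
#' @param dialect `"annotated_tsv"` or `"vcf"`.
#' @return A tibble with one row per (case, variant, alt allele); columns as
#'   in [variant_columns]; missing annotations are `NA`.
#' @export
read_variants <- function(path, dialect = c("annotated_tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("variant file not found: %s", path), class = "panelvar_io_error")
  }
  out <- switch(dialect,
    annotated_tsv = read_variants_tsv(path),
    vcf = read_variants_vcf(path)
  )
  zero <- !is.na(out$depth) & out$depth == 0
  if (any(zero)) {
    warn(sprintf("skipping %d record(s) with zero depth", sum(zero)))
    out <- out[!zero, , drop = FALSE]
  }
  out$vaf <- out$alt_depth / out$depth
  if (any(out$vaf < 0 | out$vaf > 1, na.rm = TRUE)) {
    abort("derived VAF outside [0, 1]", class = "panelvar_validation_error")
  }
  validate_variants(out)
  out
}

read_variants_tsv <- function(path) {
  raw <- readr::read_tsv(path, na = ".", progress = FALSE,
    col_types = readr::cols(
      case_id = readr::col_character(), chrom = readr::col_character(),
      pos = readr::col_integer(), ref = readr::col_character(),
      alt = readr::col_character(), qual = readr::col_double(),
      depth = readr::col_integer(), alt_depth = readr::col_integer(),
      genotype_quality = readr::col_double(), genotype = readr::col_character(),
      gene = readr::col_character(), genomic_region = readr::col_character(),
      functional_impact = readr::col_character(), hgvs_p = readr::col_character(),
      af_gnomad = readr::col_double(), af_1000g = readr::col_double(),
      sift_class = readr::col_character(), polyphen2_class = readr::col_character(),
      cadd_phred = readr::col_double(), phylop = readr::col_double(),
      clinvar_class = readr::col_character(), cosmic_id = readr::col_character(),
      rsid = readr::col_character(),
      transcripts_affected = readr::col_integer(),
      transcripts_total = readr::col_integer(),
      .default = readr::col_skip()
    )
  )
  needed <- setdiff(variant_columns(), "vaf")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "annotated TSV lacks column(s): %s",
      paste(missing_cols, collapse = ", ")
    ), class = "panelvar_configuration_error")
  }
  as_tibble(raw[, needed])
}

# INFO annotation keys and the variant-table columns they populate.
vcf_info_map <- function() {
  c(
    GENE = "gene", REGION = "genomic_region", IMPACT = "functional_impact",
    HGVSP = "hgvs_p", AF_GNOMAD = "af_gnomad", AF_1000G = "af_1000g",
    SIFT = "sift_class", PP2 = "polyphen2_class", CADD = "cadd_phred",
    PHYLOP = "phylop", CLINVAR = "clinvar_class", COSMIC = "cosmic_id",
    RSID = "rsid", TRA = "transcripts_affected", TRT = "transcripts_total"
  )
}

read_variants_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    abort("VCF contains no records", class = "panelvar_io_error")
  }
  fmt_keys <- strsplit(vcf@gt[, "FORMAT"], ":", fixed = TRUE)
  need_fmt <- c("GT", "DP", "AD", "GQ")
  for (k in need_fmt) {
    if (!all(vapply(fmt_keys, function(x) k %in% x, logical(1)))) {
      abort(sprintf("VCF FORMAT must carry %s on every record", k),
        class = "panelvar_configuration_error"
      )
    }
  }
  sample_id <- colnames(vcf@gt)[2]
  gt <- vcfR::extract.gt(vcf, element = "GT")[, 1]
  dp <- as.integer(vcfR::extract.gt(vcf, element = "DP")[, 1])
  ad <- vcfR::extract.gt(vcf, element = "AD")[, 1]
  gq <- as.numeric(vcfR::extract.gt(vcf, element = "GQ")[, 1])
  info <- vcf@fix[, "INFO"]

  rows <- purrr::map(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    ad_i <- as.integer(strsplit(ad[i], ",", fixed = TRUE)[[1]])
    kv <- parse_info(info[i])
    case_id <- if ("CASE" %in% names(kv)) kv[["CASE"]] else sample_id
    purrr::map(seq_along(alts), function(a) {
      alt_reads <- if (length(ad_i) >= a + 1) ad_i[a + 1] else NA_integer_
      list(
        case_id = case_id, chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[a],
        qual = as.numeric(fix$QUAL[i]), depth = dp[i], alt_depth = alt_reads,
        genotype_quality = gq[i], genotype = genotype_from_gt(gt[i]),
        annotations = kv
      )
    })
  })
  rows <- purrr::flatten(rows)

  ann_cols <- vcf_info_map()
  base <- tibble(
    case_id = purrr::map_chr(rows, "case_id"),
    chrom = purrr::map_chr(rows, "chrom"),
    pos = purrr::map_int(rows, "pos"),
    ref = purrr::map_chr(rows, "ref"),
    alt = purrr::map_chr(rows, "alt"),
    qual = purrr::map_dbl(rows, "qual"),
    depth = purrr::map_int(rows, "depth"),
    alt_depth = purrr::map_int(rows, "alt_depth"),
    genotype_quality = purrr::map_dbl(rows, "genotype_quality"),
    genotype = purrr::map_chr(rows, "genotype")
  )
  for (key in names(ann_cols)) {
    vals <- purrr::map_chr(rows, function(r) {
      kv <- r$annotations
      if (key %in% names(kv)) kv[[key]] else NA_character_
    })
    col <- ann_cols[[key]]
    base[[col]] <- if (col %in% c("af_gnomad", "af_1000g", "cadd_phred", "phylop")) {
      as.numeric(vals)
    } else if (col %in% c("transcripts_affected", "transcripts_total")) {
      as.integer(vals)
    } else {
      vals
    }
  }
  base$vaf <- NA_real_
  base[, variant_columns()]
}

parse_info <- function(info) {
  if (is.na(info) || info == "." || info == "") {
    return(character(0))
  }
  parts <- strsplit(info, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- vapply(kv, function(x) if (length(x) > 1) x[2] else "", character(1))
  names(vals) <- vapply(kv, `[[`, character(1), 1)
  vals[vals != ""]
}

genotype_from_gt <- function(gt) {
  if (is.na(gt)) return("other")
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (length(alleles) == 1 && alleles != "0" && alleles != ".") return("hemi")
  if (length(alleles) == 2) {
    if (all(alleles == alleles[1]) && alleles[1] != "0" && alleles[1] != ".") {
      return("hom_alt")
    }
    if (any(alleles == "0") && any(alleles != "0" & alleles != ".")) return("het")
  }
  "other"
}

#' Write the classified-variant table and cohort report
#'
#' Emits three files into `out_dir`: `classified_variants.tsv` (one row per
#' classified variant, missing values as `"."`), `cohort_summary.json`
#' (machine-readable summary), and `cohort_report.txt` (a human-readable
#' rendering of the region/impact count table plus headline rates).
#'
#' @param summary A [summarize_cohort] result (class `panelvar_summary`).
#' @param out_dir Output directory; created if absent.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(summary, out_dir) {
  stopifnot(inherits(summary, "panelvar_summary"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, mode = 2) != 0) {
    abort(sprintf("cannot write to directory: %s", out_dir), class = "panelvar_io_error")
  }
  tsv_path <- file.path(out_dir, "classified_variants.tsv")
  json_path <- file.path(out_dir, "cohort_summary.json")
  txt_path <- file.path(out_dir, "cohort_report.txt")

  write_classified_tsv(summary$classified, tsv_path)
  jsonlite::write_json(summary_to_list(summary), json_path,
    auto_unbox = TRUE, digits = NA, null = "null", na = "null", pretty = TRUE
  )
  writeLines(render_report_text(summary), txt_path)
  invisible(c(tsv_path, json_path, txt_path))
}

write_classified_tsv <- function(classified, path) {
  out <- classified
  for (col in names(out)) {
    if (is.logical(out[[col]])) out[[col]] <- as.character(out[[col]])
  }
  readr::write_tsv(out, path, na = ".", progress = FALSE)
}

#' Write a variant table in the annotated-TSV dialect
#'
#' The inverse of `read_variants(..., dialect = "annotated_tsv")`: missing
#' values become `"."` and the derived `vaf` column is written for human
#' readers but ignored on re-read.
#'
#' @param variants A variant tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_variants_tsv <- function(variants, path) {
  readr::write_tsv(variants[, variant_columns()], path, na = ".", progress = FALSE)
  invisible(path)
}

#' Write a variant table as VCF 4.2
#'
#' Emits one multi-sample-free VCF per cohort: each record carries the case id
#' in the INFO key `CASE`, call quality in QUAL, read support in the
#' `GT:DP:AD:GQ` FORMAT block, and annotations in INFO keys (see
#' [read_variants]).
#'
#' @param variants A variant tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_variants_vcf <- function(variants, path) {
  ann_cols <- vcf_info_map()
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=panelvar",
    "##INFO=<ID=CASE,Number=1,Type=String,Description=\"Case identifier\">",
    sprintf(
      "##INFO=<ID=%s,Number=1,Type=String,Description=\"%s\">",
      names(ann_cols), unname(ann_cols)
    ),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE"
  )
  fmt_num <- function(x) ifelse(is.na(x), ".", format(x, scientific = FALSE, trim = TRUE))
  gt_code <- c(het = "0/1", hom_alt = "1/1", hemi = "1", other = "./.")
  info <- vapply(seq_len(nrow(variants)), function(i) {
    kv <- c(CASE = variants$case_id[i])
    for (key in names(ann_cols)) {
      val <- variants[[ann_cols[[key]]]][i]
      if (!is.na(val)) kv[[key]] <- as.character(val)
    }
    paste(sprintf("%s=%s", names(kv), unname(kv)), collapse = ";")
  }, character(1))
  sample_field <- sprintf(
    "%s:%d:%d,%d:%s",
    gt_code[variants$genotype],
    variants$depth, variants$depth - variants$alt_depth, variants$alt_depth,
    fmt_num(round(variants$genotype_quality))
  )
  body <- sprintf(
    "%s\t%d\t%s\t%s\t%s\t%s\t.\t%s\tGT:DP:AD:GQ\t%s",
    variants$chrom, variants$pos,
    ifelse(is.na(variants$rsid), ".", variants$rsid),
    variants$ref, variants$alt, fmt_num(variants$qual), info, sample_field
  )
  writeLines(c(header, body), path)
  invisible(path)
}
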