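#' Simulation configuration for a synthetic panel cohort
#'
#' Builds the configuration object consumed by [simulate_cohort]. The
#' defaults emulate the study conditions the pipeline was designed around: a
#' 26-case myeloid-neoplasm cohort sequenced on a 54-gene amplicon panel at
#' roughly 5000x coding depth, with ~80 called variants per case of which
#' about 1.5 are somatic. Depth is drawn log-normal (amplicon panels are
#' heavy-tailed); per-case germline and somatic counts are Poisson; read
#' support at a site is Binomial(depth, expected VAF).
#'
#' @param n_cases Number of cohort members.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config.
#' @param depth_mean Mean sequencing depth at a variant site.
#' @param depth_dispersion Log-normal `sdlog` for depth.
#' @param blast_percent_range Range (percent, 0-100) from which each case's
#'   circulating-blast percentage is drawn uniformly.
#' @param germline_per_case_mean,somatic_per_case_mean Poisson means for
#'   per-case variant counts.
#' @param subclone_probability Probability that a somatic variant belongs to a
#'   subclone rather than the founding clone.
#' @param subclone_ccf_range Range of cancer-cell fractions for subclonal
#'   variants (founding-clone variants have CCF 1).
#' @param impact_category_weights Named numeric vector of sampling weights
#'   over functional-impact categories for exonic variants; must sum to 1.
#' @param fraction_male Fraction of male cases (X-linked genes become
#'   hemizygous in males).
#' @param fraction_common_germline Fraction of germline variants drawn as
#'   common polymorphisms (population AF above 1%), so both branches of the
#'   rarity filter are exercised.
#' @param tumor_purity Fraction of the counted blast percentage that
#'   actually contributes leukemic DNA to the specimen. Circulating-blast
#'   counts overestimate the leukemic DNA fraction (the specimen also
#'   carries non-blast leukocytes, and the morphological count has error),
#'   so a clonal somatic variant's expected VAF sits strictly below the
#'   classifier threshold of half the blast fraction rather than exactly on
#'   it; 0.9 keeps that margin several binomial standard deviations wide at
#'   5000x depth.
#' @return A list of class `panelvar_sim_config`.
#' @export
sim_config <- function(n_cases = 26,
                       seed = 1L,
                       depth_mean = 5000,
                       depth_dispersion = 0.3,
                       blast_percent_range = c(30, 90),
                       germline_per_case_mean = 78.5,
                       somatic_per_case_mean = 1.46,
                       subclone_probability = 0.3,
                       subclone_ccf_range = c(0.2, 0.6),
                       impact_category_weights = default_impact_weights(),
                       fraction_male = 15 / 26,
                       fraction_common_germline = 0.85,
                       tumor_purity = 0.9) {
  stopifnot(
    n_cases >= 1, depth_mean > 0, depth_dispersion >= 0,
    length(blast_percent_range) == 2,
    blast_percent_range[1] <= blast_percent_range[2],
    blast_percent_range[1] >= 0, blast_percent_range[2] <= 100,
    germline_per_case_mean >= 0, somatic_per_case_mean >= 0,
    subclone_probability >= 0, subclone_probability <= 1,
    length(subclone_ccf_range) == 2,
    subclone_ccf_range[1] <= subclone_ccf_range[2],
    subclone_ccf_range[1] > 0, subclone_ccf_range[2] < 1,
    fraction_male >= 0, fraction_male <= 1,
    fraction_common_germline >= 0, fraction_common_germline <= 1,
    tumor_purity > 0, tumor_purity <= 1
  )
  w <- impact_category_weights
  if (is.null(names(w)) || !all(names(w) %in% functional_impacts())) {
    abort("impact_category_weights must be named by functional impact tokens",
      class = "panelvar_validation_error"
    )
  }
  if (abs(sum(w) - 1) > 1e-8) {
    abort("impact_category_weights must sum to 1", class = "panelvar_validation_error")
  }
  structure(
    list(
      n_cases = as.integer(n_cases), seed = as.integer(seed),
      depth_mean = depth_mean, depth_dispersion = depth_dispersion,
      blast_percent_range = blast_percent_range,
      germline_per_case_mean = germline_per_case_mean,
      somatic_per_case_mean = somatic_per_case_mean,
      subclone_probability = subclone_probability,
      subclone_ccf_range = subclone_ccf_range,
      impact_category_weights = w,
      fraction_male = fraction_male,
      fraction_common_germline = fraction_common_germline,
      tumor_purity = tumor_purity
    ),
    class = "panelvar_sim_config"
  )
}

# Functional-impact sampling weights for exonic/splicing variants, proportional
# to the cohort-wide functional distribution the generator emulates
# (71 nonsyn : 61 syn : 3 stopgain : 2 splicing : 3 fs-ins : 2 fs-del :
#  2 nfs-ins : 3 nfs-del).
default_impact_weights <- function() {
  counts <- c(
    nonsynonymous_snv = 71, synonymous_snv = 61, stopgain = 3, splicing = 2,
    frameshift_insertion = 3, frameshift_deletion = 2,
    nonframeshift_insertion = 2, nonframeshift_deletion = 3
  )
  counts / sum(counts)
}

# Genomic-region sampling weights (exonic 146 : intronic 133 : downstream 3 :
# UTR5 2 : UTR3 9; upstream kept tiny but nonzero so the token is exercised).
default_region_weights <- function() {
  w <- c(
    exonic = 146, intronic = 133, upstream = 0.5, downstream = 3,
    UTR5 = 2, UTR3 = 9
  )
  w / sum(w)
}

#' Bundled 54-gene myeloid panel description
#'
#' @return A tibble with columns `gene`, `coverage`
#'   (`complete_exons`/`hotspots`), `chrom`. Chromosome assignments are used
#'   only to mark X-linked genes; simulated positions are synthetic integers,
#'   not genome coordinates.
#' @export
panel_genes <- function() {
  path <- system.file("extdata", "panel_genes.tsv", package = "panelvar")
  readr::read_tsv(path, col_types = "ccc", progress = FALSE)
}

#' Expected variant allele fraction under the tumor-only model
#'
#' For a diploid locus, a germline heterozygote sits at VAF 0.5 and a
#' homozygote at 1.0. A heterozygous somatic variant carried by a clone with
#' cancer-cell fraction `ccf` in a specimen whose tumor content is
#' `blast_fraction` has expectation `0.5 * blast_fraction * ccf`; hemizygous
#' loci (X-linked in males) double both germline-het and somatic
#' expectations.
#'
#' @param origin `"somatic"` or `"germline"`.
#' @param genotype `"het"` or `"hom_alt"` (ignored for hemizygous loci).
#' @param blast_fraction Tumor fraction of the specimen in `[0, 1]` (blast
#'   percentage / 100). Required for somatic variants.
#' @param ccf Cancer-cell fraction in `(0, 1]` of the clone carrying a
#'   somatic variant; must be `NULL` for germline variants.
#' @param hemizygous Logical; single-copy locus.
#' @return Expected VAF in `[0, 1]`.
#' @export
expected_vaf <- function(origin, genotype = "het", blast_fraction = NULL,
                         ccf = NULL, hemizygous = FALSE) {
  origin <- match.arg(origin, c("somatic", "germline"))
  genotype <- match.arg(genotype, c("het", "hom_alt"))
  if (origin == "germline") {
    if (!is.null(ccf)) {
      abort("ccf applies only to somatic variants", class = "panelvar_validation_error")
    }
    if (genotype == "hom_alt" || hemizygous) {
      return(1.0)
    }
    return(0.5)
  }
  if (is.null(blast_fraction) || is.na(blast_fraction) ||
    blast_fraction < 0 || blast_fraction > 1) {
    abort("blast_fraction must be in [0, 1]", class = "panelvar_validation_error")
  }
  if (is.null(ccf) || is.na(ccf) || ccf <= 0 || ccf > 1) {
    abort("ccf must be in (0, 1]", class = "panelvar_validation_error")
  }
  if (hemizygous) blast_fraction * ccf else 0.5 * blast_fraction * ccf
}

#' Draw binomial read support at a site
#'
#' @param exp_vaf Expected VAF in `[0, 1]`.
#' @param depth Total depth (>= 1).
#' @return A list with `alt_depth` (Binomial(depth, exp_vaf) draw) and
#'   `depth`.
#' @export
sample_read_support <- function(exp_vaf, depth) {
  if (any(is.na(exp_vaf)) || any(exp_vaf < 0) || any(exp_vaf > 1)) {
    abort("expected VAF must be in [0, 1]", class = "panelvar_validation_error")
  }
  if (any(depth < 1)) {
    abort("depth must be >= 1", class = "panelvar_validation_error")
  }
  list(alt_depth = rbinom(length(exp_vaf), size = depth, prob = exp_vaf), depth = depth)
}

#' Simulate a synthetic panel cohort with known truth
#'
#' Generates a manifest, a fully annotated variant table, and a truth table
#' aligned row-for-row with the variants. Germline variants mix common
#' polymorphisms (population AF above the 1% rarity cutoff) with rare ones so
#' both filter branches are exercised; somatic variants carry expected VAF
#' `0.5 * blast_fraction * ccf` (doubled when hemizygous); read support is
#' binomial at a log-normal depth. X-linked genes are hemizygous in male
#' cases. A small fraction of records is given failing QUAL/DP/GQ so the QC
#' stage has work to do.
#'
#' @param config A [sim_config] object.
#' @param write_dir Optional directory; when given, `manifest.tsv`,
#'   `variants.tsv`, `variants.vcf`, and `truth.tsv` are written there.
#' @return A list with tibbles `manifest`, `variants`, `truth` (classes
#'   joined by `variant_id`), and `config`.
#' @export
simulate_cohort <- function(config = sim_config(), write_dir = NULL) {
  stopifnot(inherits(config, "panelvar_sim_config"))
  set.seed(config$seed)
  panel <- panel_genes()
  x_genes <- panel$gene[panel$chrom == "chrX"]

  manifest <- tibble(
    case_id = sprintf("SIM%02d", seq_len(config$n_cases)),
    sex = ifelse(runif(config$n_cases) < config$fraction_male, "male", "female"),
    blast_percent = round(runif(
      config$n_cases,
      config$blast_percent_range[1], config$blast_percent_range[2]
    ), 1),
    karyotype_note = NA_character_
  )

  per_case <- purrr::map(seq_len(config$n_cases), function(i) {
    simulate_case(manifest[i, ], config, panel, x_genes)
  })
  variants <- bind_rows(purrr::map(per_case, "variants"))
  truth <- bind_rows(purrr::map(per_case, "truth"))
  if (nrow(variants) > 0) {
    variants$vaf <- variants$alt_depth / variants$depth
    ids <- sprintf("VAR%05d", seq_len(nrow(variants)))
    variants <- tibble(variant_id = ids, variants)
    truth <- tibble(variant_id = ids, truth)
  } else {
    variants <- tibble(variant_id = character(0), variants)
    truth <- tibble(variant_id = character(0), truth)
  }
  validate_variants(variants)

  if (!is.null(write_dir)) {
    dir.create(write_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(manifest, file.path(write_dir, "manifest.tsv"), na = ".",
      progress = FALSE
    )
    write_variants_tsv(variants, file.path(write_dir, "variants.tsv"))
    write_variants_vcf(variants, file.path(write_dir, "variants.vcf"))
    readr::write_tsv(truth, file.path(write_dir, "truth.tsv"), na = ".",
      progress = FALSE
    )
  }
  list(manifest = manifest, variants = variants, truth = truth, config = config)
}

simulate_case <- function(case, config, panel, x_genes) {
  n_germ <- rpois(1, config$germline_per_case_mean)
  n_som <- rpois(1, config$somatic_per_case_mean)
  n <- n_germ + n_som
  if (n == 0) {
    return(list(variants = NULL, truth = NULL))
  }
  origin <- c(rep("germline", n_germ), rep("somatic", n_som))
  gene <- sample(panel$gene, n, replace = TRUE)
  chrom <- panel$chrom[match(gene, panel$gene)]
  hemi <- chrom == "chrX" & case$sex == "male"

  region <- character(n)
  impact <- character(n)
  rw <- default_region_weights()
  iw <- config$impact_category_weights
  # Somatic variants are drawn exonic/splicing-rich so downstream non-silent
  # statistics have events to work with; germline follows the cohort-wide mix.
  region[origin == "germline"] <- sample(names(rw), sum(origin == "germline"),
    replace = TRUE, prob = rw
  )
  region[origin == "somatic"] <- sample(c("exonic", "intronic", "UTR3", "downstream"),
    sum(origin == "somatic"),
    replace = TRUE, prob = c(0.75, 0.17, 0.04, 0.04)
  )
  coding <- region %in% c("exonic", "splicing")
  impact[!coding] <- "not_applicable"
  impact[coding] <- sample(names(iw), sum(coding), replace = TRUE, prob = iw)
  # An exonic draw of the "splicing" impact is re-homed to the splicing
  # region token (the convention used when rendering region tables).
  region[impact == "splicing"] <- "splicing"

  genotype <- ifelse(origin == "germline",
    ifelse(runif(n) < 0.3, "hom_alt", "het"), "het"
  )
  genotype[hemi] <- ifelse(origin[hemi] == "germline", "hemi", "het")

  is_sub <- origin == "somatic" & runif(n) < config$subclone_probability
  ccf <- rep(NA_real_, n)
  ccf[origin == "somatic"] <- 1
  ccf[is_sub] <- runif(sum(is_sub), config$subclone_ccf_range[1], config$subclone_ccf_range[2])
  blast_fraction <- case$blast_percent / 100 * config$tumor_purity

  exp_vaf <- vapply(seq_len(n), function(i) {
    if (origin[i] == "germline") {
      expected_vaf("germline",
        genotype = if (genotype[i] == "hemi") "het" else genotype[i],
        hemizygous = hemi[i]
      )
    } else {
      expected_vaf("somatic",
        genotype = "het", blast_fraction = blast_fraction,
        ccf = ccf[i], hemizygous = hemi[i]
      )
    }
  }, numeric(1))
  exp_vaf <- pmin(exp_vaf, 1)

  depth <- pmax(20L, as.integer(round(rlnorm(
    n,
    meanlog = log(config$depth_mean) - config$depth_dispersion^2 / 2,
    sdlog = config$depth_dispersion
  ))))
  support <- sample_read_support(exp_vaf, depth)

  common <- origin == "germline" & runif(n) < config$fraction_common_germline
  af_gnomad <- rep(NA_real_, n)
  af_1000g <- rep(NA_real_, n)
  af_gnomad[common] <- runif(sum(common), 0.011, 0.5)
  af_1000g[common] <- pmin(0.5, af_gnomad[common] * runif(sum(common), 0.6, 1.4))
  rare_known <- !common & runif(n) < 0.5
  af_gnomad[rare_known] <- runif(sum(rare_known), 1e-6, 0.009)

  nonsyn <- impact == "nonsynonymous_snv"
  sift <- rep(NA_character_, n)
  pp2 <- rep(NA_character_, n)
  sift[nonsyn] <- sample(sift_levels(), sum(nonsyn), replace = TRUE, prob = c(0.3, 0.7))
  pp2[nonsyn] <- sample(polyphen2_levels(), sum(nonsyn),
    replace = TRUE, prob = c(0.2, 0.15, 0.65)
  )
  clinvar <- sample(c(clinvar_levels(), NA_character_), n,
    replace = TRUE, prob = c(0.02, 0.02, 0.1, 0.16, 0.7)
  )
  phylop <- round(rnorm(n, mean = 1.5, sd = 2.5), 3)
  cadd <- rep(NA_real_, n)
  cadd[coding] <- round(runif(sum(coding), 0, 40), 2)

  is_indel <- impact %in% c(
    "frameshift_insertion", "frameshift_deletion",
    "nonframeshift_insertion", "nonframeshift_deletion"
  )
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1),
    USE.NAMES = FALSE
  )
  ins <- impact %in% c("frameshift_insertion", "nonframeshift_insertion")
  del <- impact %in% c("frameshift_deletion", "nonframeshift_deletion")
  alt[ins] <- paste0(ref[ins], ifelse(impact[ins] == "frameshift_insertion", "GT", "GTC"))
  ref[del] <- paste0(alt[del], ifelse(impact[del] == "frameshift_deletion", "AG", "AGT"))

  pos <- as.integer(match(gene, panel$gene) * 1000000L + sample.int(99999L, n, replace = TRUE))
  aa_pos <- sample.int(600L, n, replace = TRUE)
  hgvs_p <- rep(NA_character_, n)
  hgvs_p[coding & !is_indel] <- sprintf("p.%s%d%s",
    sample(LETTERS[c(1, 3, 4, 5, 7)], sum(coding & !is_indel), replace = TRUE),
    aa_pos[coding & !is_indel],
    sample(LETTERS[c(8, 11, 12, 16, 19)], sum(coding & !is_indel), replace = TRUE)
  )
  hgvs_p[coding & is_indel] <- sprintf("p.L%dfs", aa_pos[coding & is_indel])

  # ~4% of records fail each QC leg; the rest sit comfortably above threshold.
  qual <- round(runif(n, 200, 3000), 1)
  low_q <- runif(n) < 0.04
  qual[low_q] <- round(runif(sum(low_q), 5, 49.5), 1)
  gq <- pmin(99, round(rnorm(n, 80, 20)))
  gq[gq < 0] <- 0
  trt <- sample(1:8, n, replace = TRUE)
  tra <- vapply(trt, function(t) sample.int(t, 1), integer(1))

  variants <- tibble(
    case_id = case$case_id, chrom = chrom, pos = pos, ref = ref, alt = alt,
    qual = qual, depth = support$depth, alt_depth = support$alt_depth,
    genotype_quality = as.numeric(gq), genotype = genotype, vaf = NA_real_,
    gene = gene, genomic_region = region, functional_impact = impact,
    hgvs_p = hgvs_p, af_gnomad = af_gnomad, af_1000g = af_1000g,
    sift_class = sift, polyphen2_class = pp2, cadd_phred = cadd,
    phylop = phylop, clinvar_class = clinvar, cosmic_id = NA_character_,
    rsid = NA_character_,
    transcripts_affected = tra, transcripts_total = trt
  )
  truth <- tibble(
    case_id = case$case_id,
    true_origin = origin,
    clone_id = ifelse(origin == "somatic", ifelse(is_sub, 1L, 0L), NA_integer_),
    true_ccf = ccf,
    expected_vaf = exp_vaf,
    hemizygous = hemi
  )
  list(variants = variants, truth = truth)
}
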