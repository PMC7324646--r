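#' Round half away from zero
#'
#' Percentages are rendered with commercial (half-up) rounding rather than
#' IEEE round-half-even, matching how clinical summaries print rates.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Recurrent somatic mutations across the cohort
#'
#' Groups somatic variants by identical event — (gene, protein change) for
#' exonic variants, (gene, chrom, pos, ref, alt) otherwise — and reports
#' events seen in at least `min_cases` distinct cases, split into non-silent
#' and silent lists.
#'
#' @param classified Somatic-classified variant tibble carrying `origin` and
#'   `silence` columns (see [classify_origin]; `silence` is added via
#'   [classify_silence] when absent).
#' @param min_cases Minimum number of distinct cases.
#' @return A list with tibbles `non_silent` and `silent`, each with `gene`,
#'   `key`, `n_cases`, `case_ids`, `vafs`.
#' @export
detect_recurrent_somatic <- function(classified, min_cases = 2) {
  somatic <- filter(classified, .data$origin == "somatic")
  somatic <- ensure_silence(somatic)
  somatic <- somatic %>%
    mutate(key = ifelse(
      .data$genomic_region == "exonic" & !is.na(.data$hgvs_p),
      .data$hgvs_p,
      paste(.data$chrom, .data$pos, .data$ref, .data$alt, sep = ":")
    ))
  grouped <- somatic %>%
    group_by(.data$silence, .data$gene, .data$key) %>%
    summarise(
      n_cases = n_distinct(.data$case_id),
      case_ids = paste(sort(unique(.data$case_id)), collapse = ","),
      vafs = paste(round(.data$vaf[order(.data$case_id)], 4), collapse = ","),
      .groups = "drop"
    ) %>%
    filter(.data$n_cases >= .env$min_cases) %>%
    arrange(dplyr::desc(.data$n_cases), .data$gene)
  list(
    non_silent = grouped %>% filter(.data$silence == "non_silent") %>% select(-"silence"),
    silent = grouped %>% filter(.data$silence == "silent") %>% select(-"silence")
  )
}

ensure_silence <- function(variants) {
  if (!"silence" %in% names(variants)) {
    variants$silence <- classify_silence(
      variants$functional_impact, variants$genomic_region
    )
  }
  variants
}

#' Per-case, per-gene somatic mutation counts
#'
#' Expands the classified table to the full case x panel-gene grid (zero
#' counts included), the replicate structure the burden test runs on.
#'
#' @param classified Classified variant tibble.
#' @param manifest Cohort manifest (defines the case set, including cases
#'   with no somatic variants).
#' @param genes Character vector of panel genes; defaults to the bundled
#'   54-gene panel.
#' @return A tibble `case_id`, `gene`, `n_somatic`.
#' @export
somatic_gene_counts <- function(classified, manifest, genes = panel_genes()$gene) {
  somatic <- filter(classified, .data$origin == "somatic")
  grid <- tidyr::expand_grid(case_id = manifest$case_id, gene = genes)
  grid %>%
    left_join(
      count(somatic, .data$case_id, .data$gene, name = "n_somatic"),
      by = c("case_id", "gene")
    ) %>%
    mutate(n_somatic = ifelse(is.na(.data$n_somatic), 0L, .data$n_somatic))
}

#' Dunn's post hoc test of pairwise rank differences
#'
#' Large-sample z-tests on pairwise differences of mean ranks, with the
#' standard tie correction, as the post hoc companion to the Kruskal-Wallis
#' omnibus test. P-values are two-sided and adjusted across all pairs.
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping factor/vector, same length.
#' @param p_adjust_method Passed to [stats::p.adjust] (default
#'   `"bonferroni"`).
#' @return A tibble with `group1`, `group2`, `z`, `p`, `p_adjusted`.
#' @export
dunn_test <- function(values, groups, p_adjust_method = "bonferroni") {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  N <- length(values)
  r <- rank(values)
  mean_rank <- tapply(r, groups, mean)
  n_i <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  base_var <- N * (N + 1) / 12 - tie_term
  ids <- names(mean_rank)
  pairs <- utils::combn(ids, 2)
  z <- vapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]
    b <- pairs[2, k]
    se <- sqrt(base_var * (1 / n_i[[a]] + 1 / n_i[[b]]))
    if (se == 0) 0 else (mean_rank[[a]] - mean_rank[[b]]) / se
  }, numeric(1))
  p <- 2 * stats::pnorm(-abs(z))
  tibble(
    group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
    p_adjusted = pmin(1, p.adjust(p, method = p_adjust_method))
  )
}

#' Mutation-burden outlier test across cases
#'
#' Kruskal-Wallis omnibus test over per-gene somatic counts grouped by case;
#' when the omnibus rejects at `alpha`, pairwise Dunn tests (with
#' multiple-testing correction) identify which cases carry excess burden. A
#' case is flagged when its adjusted p-value beats `alpha` against a
#' majority of the other cases.
#'
#' @param gene_counts Output of [somatic_gene_counts] (columns `case_id`,
#'   `gene`, `n_somatic`).
#' @param alpha Significance level.
#' @param p_adjust_method Dunn correction method (default Bonferroni).
#' @return A list with `omnibus_p`, `pairwise` (Dunn tibble or `NULL` when
#'   the omnibus does not reject), and `flagged` (tibble `case_id`,
#'   `n_significant_pairs`, `n_other_cases`).
#' @export
burden_test <- function(gene_counts, alpha = 0.01, p_adjust_method = "bonferroni") {
  n_cases <- n_distinct(gene_counts$case_id)
  if (n_cases < 3) {
    abort("burden test needs at least 3 cases", class = "panelvar_validation_error")
  }
  if (length(unique(gene_counts$n_somatic)) == 1) {
    return(list(
      omnibus_p = 1,
      pairwise = NULL,
      flagged = tibble(
        case_id = character(0), n_significant_pairs = integer(0),
        n_other_cases = integer(0)
      )
    ))
  }
  omnibus <- kruskal.test(gene_counts$n_somatic, factor(gene_counts$case_id))
  flagged <- tibble(
    case_id = character(0), n_significant_pairs = integer(0),
    n_other_cases = integer(0)
  )
  pairwise <- NULL
  if (is.finite(omnibus$p.value) && omnibus$p.value < alpha) {
    pairwise <- dunn_test(gene_counts$n_somatic, gene_counts$case_id,
      p_adjust_method = p_adjust_method
    )
    sig <- filter(pairwise, .data$p_adjusted < .env$alpha)
    if (nrow(sig) > 0) {
      per_case <- count(
        tibble(case_id = c(sig$group1, sig$group2)), .data$case_id,
        name = "n_significant_pairs"
      )
      # excess-burden direction: flag only cases whose mean count exceeds the
      # cohort median case mean
      case_means <- gene_counts %>%
        group_by(.data$case_id) %>%
        summarise(mean_count = mean(.data$n_somatic), .groups = "drop")
      flagged <- per_case %>%
        filter(.data$n_significant_pairs > (n_cases - 1) / 2) %>%
        left_join(case_means, by = "case_id") %>%
        filter(.data$mean_count > stats::median(case_means$mean_count)) %>%
        mutate(n_other_cases = n_cases - 1L) %>%
        select("case_id", "n_significant_pairs", "n_other_cases") %>%
        arrange(.data$case_id)
    }
  }
  list(omnibus_p = unname(omnibus$p.value), pairwise = pairwise, flagged = flagged)
}

#' Read pharmacogenomic rules
#'
#' @param path TSV with columns `rsid`, `gene`, `ref`, `alt`,
#'   `risk_genotypes` (comma-separated unordered allele pairs), `annotation`.
#'   Defaults to the bundled rule set.
#' @return A tibble of rules.
#' @export
read_pgx_rules <- function(path = system.file("extdata", "pgx_rules.tsv",
                             package = "panelvar"
                           )) {
  rules <- readr::read_tsv(path, col_types = "cccccc", progress = FALSE)
  needed <- c("rsid", "gene", "ref", "alt", "risk_genotypes", "annotation")
  missing_cols <- setdiff(needed, names(rules))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "PGx rules lack column(s): %s",
      paste(missing_cols, collapse = ", ")
    ), class = "panelvar_configuration_error")
  }
  if (any(is.na(rules$risk_genotypes) | rules$risk_genotypes == "")) {
    abort("every PGx rule needs at least one risk genotype",
      class = "panelvar_validation_error"
    )
  }
  rules
}

normalize_genotype <- function(gt) {
  vapply(gt, function(g) {
    if (is.na(g)) return(NA_character_)
    paste(sort(strsplit(g, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Pharmacogenomic genotype lookup
#'
#' Runs on the QC-passing variant set *before* rarity filtering, because the
#' actionable pharmacogenomic polymorphisms are common variants that the
#' rarity filter would hide. For each rule, every cohort case receives a
#' genotype: from the call when the rsID is present (het = ref/alt, hom =
#' alt/alt, hemizygous = alt), homozygous reference when absent. A case is a
#' carrier when its genotype matches any of the rule's risk genotypes
#' (unordered).
#'
#' @param variants QC-passing variant tibble (pre-rarity).
#' @param manifest Cohort manifest (defines the case set).
#' @param rules Output of [read_pgx_rules].
#' @return A list with `genotypes` (tibble `rsid`, `case_id`, `genotype`,
#'   `carrier`) and `summary` (tibble `rsid`, `gene`, `n_cases`,
#'   `n_carriers`, `carrier_pct` half-up to the nearest percent,
#'   `carrier_fraction`, `annotation`).
#' @export
pharmaco_lookup <- function(variants, manifest, rules = read_pgx_rules()) {
  per_rule <- purrr::map(seq_len(nrow(rules)), function(k) {
    rule <- rules[k, ]
    risk <- normalize_genotype(strsplit(rule$risk_genotypes, ",")[[1]])
    hits <- variants %>%
      filter(!is.na(.data$rsid), .data$rsid == rule$rsid) %>%
      distinct(.data$case_id, .keep_all = TRUE)
    called <- setNames(
      dplyr::case_when(
        hits$genotype == "het" ~ paste0(rule$ref, rule$alt),
        hits$genotype == "hom_alt" ~ paste0(rule$alt, rule$alt),
        hits$genotype == "hemi" ~ rule$alt,
        TRUE ~ NA_character_
      ),
      hits$case_id
    )
    genotype <- ifelse(
      manifest$case_id %in% names(called),
      called[manifest$case_id],
      paste0(rule$ref, rule$ref)
    )
    genotype_norm <- normalize_genotype(genotype)
    tibble(
      rsid = rule$rsid, case_id = manifest$case_id,
      genotype = genotype_norm,
      carrier = !is.na(genotype_norm) & genotype_norm %in% risk
    )
  })
  genotypes <- bind_rows(per_rule)
  summary <- genotypes %>%
    group_by(.data$rsid) %>%
    summarise(
      n_cases = n(), n_carriers = sum(.data$carrier), .groups = "drop"
    ) %>%
    left_join(rules %>% select("rsid", "gene", "annotation"), by = "rsid") %>%
    mutate(
      carrier_fraction = .data$n_carriers / .data$n_cases,
      carrier_pct = round_half_up(100 * .data$carrier_fraction, 0)
    ) %>%
    select(
      "rsid", "gene", "n_cases", "n_carriers", "carrier_pct",
      "carrier_fraction", "annotation"
    )
  list(genotypes = genotypes, summary = summary)
}

#' Cohort-level summary of a classified, prioritized cohort
#'
#' Assembles the machine-readable cohort report: somatic counts and rates,
#' silent/non-silent partition, recurrence lists, burden flags,
#' germline-prioritization counts, germline x somatic co-occurrence, and the
#' pharmacogenomic genotype table. All counts are recomputed from the
#' classified table, never carried over from upstream stages.
#'
#' @param classified Origin-classified variant tibble ([classify_origin]);
#'   `silence` and `conservation_bin` columns are added when absent.
#' @param manifest Cohort manifest.
#' @param prioritized Optional [prioritize_germline] output (defaults to
#'   running it on the germline rows of `classified`).
#' @param assignments Optional [assign_clones] output (defaults to running
#'   it on non-silent somatic rows).
#' @param qc_variants Optional QC-passing pre-rarity variant set for the
#'   pharmacogenomic lookup.
#' @param pgx_rules Optional PGx rules tibble; bundled rules when `NULL` and
#'   `qc_variants` is given.
#' @param alpha,p_adjust_method Burden-test settings.
#' @return An object of class `panelvar_summary`.
#' @export
summarize_cohort <- function(classified, manifest, prioritized = NULL,
                             assignments = NULL, qc_variants = NULL,
                             pgx_rules = NULL, alpha = 0.01,
                             p_adjust_method = "bonferroni") {
  classified <- ensure_silence(classified)
  if (!"conservation_bin" %in% names(classified)) {
    classified$conservation_bin <- bin_conservation(classified$phylop)
  }
  somatic <- filter(classified, .data$origin == "somatic")
  germline <- filter(classified, .data$origin == "germline")
  if (is.null(prioritized)) prioritized <- prioritize_germline(germline)
  prio <- filter(prioritized, .data$verdict == "prioritized")
  nonsilent_somatic <- filter(somatic, .data$silence == "non_silent")
  if (is.null(assignments)) assignments <- assign_clones(nonsilent_somatic)

  n_cases <- nrow(manifest)
  is_snv <- nchar(somatic$ref) == 1 & nchar(somatic$alt) == 1
  burden_vector <- manifest %>%
    left_join(count(somatic, .data$case_id, name = "n_somatic"), by = "case_id") %>%
    mutate(n_somatic = ifelse(is.na(.data$n_somatic), 0L, .data$n_somatic)) %>%
    select("case_id", "n_somatic")

  recurrent <- detect_recurrent_somatic(classified)
  burden <- if (n_cases >= 3 && nrow(somatic) > 0) {
    burden_test(somatic_gene_counts(classified, manifest),
      alpha = alpha, p_adjust_method = p_adjust_method
    )
  } else {
    list(omnibus_p = NA_real_, pairwise = NULL, flagged = tibble(
      case_id = character(0), n_significant_pairs = integer(0),
      n_other_cases = integer(0)
    ))
  }

  cases_nonsilent_somatic <- unique(nonsilent_somatic$case_id)
  cases_prioritized <- unique(prio$case_id)
  both <- intersect(cases_nonsilent_somatic, cases_prioritized)
  somatic_only <- setdiff(cases_nonsilent_somatic, cases_prioritized)
  germline_only <- setdiff(cases_prioritized, cases_nonsilent_somatic)
  any_hit <- union(cases_nonsilent_somatic, cases_prioritized)

  pgx <- NULL
  if (!is.null(qc_variants)) {
    if (is.null(pgx_rules)) pgx_rules <- read_pgx_rules()
    pgx <- pharmaco_lookup(qc_variants, manifest, pgx_rules)
  }

  summary <- list(
    n_cases = n_cases,
    total_classified = nrow(classified),
    somatic = list(
      total = nrow(somatic),
      snv = sum(is_snv),
      indel = sum(!is_snv),
      non_silent = nrow(nonsilent_somatic),
      silent = nrow(somatic) - nrow(nonsilent_somatic)
    ),
    germline_total = nrow(germline),
    germline_prioritized = nrow(prio),
    rates = list(
      somatic_per_case = round(nrow(somatic) / n_cases, 2),
      nonsilent_any_per_case = round(
        (nrow(nonsilent_somatic) + nrow(prio)) / n_cases, 2
      ),
      cases_with_any_mutation = length(any_hit),
      cases_with_any_mutation_pct = round_half_up(
        100 * length(any_hit) / n_cases, 2
      ),
      fraction_cases_with_any_prioritized = length(cases_prioritized) / n_cases
    ),
    cooccurrence = list(
      both = length(both),
      somatic_only = length(somatic_only),
      germline_only = length(germline_only),
      neither = n_cases - length(any_hit)
    ),
    per_case_burden = burden_vector,
    recurrent_somatic = recurrent,
    burden = burden,
    clonal_assignments = assignments,
    pgx = pgx
  )
  structure(
    c(summary, list(classified = classified, prioritized = prioritized)),
    class = "panelvar_summary"
  )
}

#' @exportS3Method base::print
print.panelvar_summary <- function(x, ...) {
  cat(render_report_text(x), sep = "\n")
  invisible(x)
}

summary_to_list <- function(summary) {
  list(
    schema_version = "1.0",
    n_cases = summary$n_cases,
    total_classified = summary$total_classified,
    somatic = summary$somatic,
    germline_total = summary$germline_total,
    germline_prioritized = summary$germline_prioritized,
    rates = summary$rates,
    cooccurrence = summary$cooccurrence,
    per_case_burden = summary$per_case_burden,
    recurrent_somatic = list(
      non_silent = summary$recurrent_somatic$non_silent,
      silent = summary$recurrent_somatic$silent
    ),
    burden = list(
      omnibus_p = summary$burden$omnibus_p,
      flagged = summary$burden$flagged
    ),
    clonal_assignments = summary$clonal_assignments,
    pgx_summary = if (is.null(summary$pgx)) NULL else summary$pgx$summary
  )
}

render_report_text <- function(summary) {
  ri <- summarize_regions(summary$classified)
  lines <- c(
    "Cohort variant-interpretation report",
    "====================================",
    sprintf("Cases: %d", summary$n_cases),
    sprintf("Classified variants: %d", summary$total_classified),
    "",
    render_region_table(ri),
    "",
    sprintf(
      "Somatic mutations: %d (%d SNVs, %d indels; %.2f per case)",
      summary$somatic$total, summary$somatic$snv, summary$somatic$indel,
      summary$rates$somatic_per_case
    ),
    sprintf(
      "  non-silent: %d, silent: %d",
      summary$somatic$non_silent, summary$somatic$silent
    ),
    sprintf("Germline variants: %d (%d prioritized)",
      summary$germline_total, summary$germline_prioritized
    ),
    sprintf(
      "Cases with any non-silent somatic and/or prioritized germline mutation: %d (%.2f%%)",
      summary$rates$cases_with_any_mutation,
      summary$rates$cases_with_any_mutation_pct
    ),
    sprintf(
      "Co-occurrence: both %d, somatic only %d, germline only %d, neither %d",
      summary$cooccurrence$both, summary$cooccurrence$somatic_only,
      summary$cooccurrence$germline_only, summary$cooccurrence$neither
    ),
    sprintf(
      "Burden test omnibus p: %s; flagged cases: %s",
      format(summary$burden$omnibus_p, digits = 4),
      if (nrow(summary$burden$flagged) == 0) {
        "none"
      } else {
        paste(summary$burden$flagged$case_id, collapse = ", ")
      }
    )
  )
  if (!is.null(summary$pgx) && nrow(summary$pgx$summary) > 0) {
    s <- summary$pgx$summary
    lines <- c(lines, "", "Pharmacogenomic genotypes:", sprintf(
      "  %s (%s): %d/%d cases (%d%%) with a risk genotype — %s",
      s$rsid, s$gene, s$n_carriers, s$n_cases, s$carrier_pct, s$annotation
    ))
  }
  lines
}
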