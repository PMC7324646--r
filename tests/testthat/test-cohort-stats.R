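test_that("recurrent somatic detection recovers planted recurrences only", {
  ex <- worked_example_cohort()
  res <- detect_recurrent_somatic(ex$classified)
  stag2 <- res$non_silent[res$non_silent$gene == "STAG2", ]
  expect_equal(stag2$n_cases, 3L)
  expect_equal(stag2$key, "p.L526F")
  cdkn2a <- res$non_silent[res$non_silent$gene == "CDKN2A", ]
  expect_equal(cdkn2a$n_cases, 4L)
  expect_false("KIT" %in% res$non_silent$gene) # two events, one case only

  # case order must not matter
  shuffled <- ex$classified[rev(seq_len(nrow(ex$classified))), ]
  expect_equal(detect_recurrent_somatic(shuffled)$non_silent, res$non_silent)

  # singleton-only cohort yields empty lists
  solo <- blank_rows(3)
  solo$case_id <- c("A", "B", "C")
  solo$hgvs_p <- c("p.A1B", "p.C2D", "p.E3F")
  solo$origin <- "somatic"
  res0 <- detect_recurrent_somatic(solo)
  expect_equal(nrow(res0$non_silent), 0)
  expect_equal(nrow(res0$silent), 0)
})

test_that("Dunn z-statistic squared equals the Kruskal-Wallis statistic for two groups", {
  # known identity: with k = 2 groups the (tie-corrected) KW chi-square is the
  # square of the Dunn z for that pair — an independent cross-check of the
  # hand-computed rank variance
  set.seed(91)
  for (rep in 1:5) {
    x <- c(rpois(30, 2), rpois(25, 3.5))
    g <- rep(c("a", "b"), c(30, 25))
    z <- dunn_test(x, g)$z
    kw <- kruskal.test(x, factor(g))$statistic
    expect_equal(unname(z^2), unname(kw), tolerance = 1e-10)
  }
})

test_that("Dunn p-values agree with an exact permutation oracle on a tiny instance", {
  x <- c(
    1.2, 0.8, 1.5, 1.1,
    9.1, 8.7, 9.9, 9.5,
    1.4, 0.9, 1.3, 1.6
  )
  g <- rep(c("a", "b", "c"), each = 4)
  res <- dunn_test(x, g, p_adjust_method = "none")
  # exact permutation distribution of the pairwise mean-rank difference
  perm_p <- function(g1, g2) {
    r <- rank(x)
    obs <- abs(mean(r[g == g1]) - mean(r[g == g2]))
    idx <- which(g %in% c(g1, g2))
    combos <- utils::combn(idx, 4)
    stats <- apply(combos, 2, function(sel) {
      abs(mean(r[sel]) - mean(r[setdiff(idx, sel)]))
    })
    mean(stats >= obs - 1e-12)
  }
  for (k in seq_len(nrow(res))) {
    exact <- perm_p(res$group1[k], res$group2[k])
    # the normal approximation must agree with the exact tail: extreme
    # permutation p (separated pairs) maps to small normal p, central
    # permutation p to large normal p
    if (exact > 0.9) expect_gt(res$p[k], 0.4)
    if (exact <= 0.05) expect_lt(res$p[k], 0.05)
  }
  expect_lt(res$p[res$group1 == "a" & res$group2 == "b"], 0.05)
  expect_gt(res$p[res$group1 == "a" & res$group2 == "c"], 0.3)
})

test_that("burden test flags planted high-burden cases and only those", {
  cohort <- make_burden_cohort(planted = c("AM01", "AM03"), seed = 301)
  counts <- somatic_gene_counts(cohort$classified, cohort$manifest)
  expect_equal(nrow(counts), 26 * 54)
  res <- burden_test(counts, alpha = 0.01)
  expect_lt(res$omnibus_p, 0.01)
  expect_setequal(res$flagged$case_id, c("AM01", "AM03"))
})

test_that("identical burden everywhere yields omnibus p = 1 and no flags", {
  manifest <- tibble::tibble(
    case_id = sprintf("B%02d", 1:5), sex = "female",
    blast_percent = 60, karyotype_note = NA_character_
  )
  v0 <- blank_rows(0)
  v0$origin <- character(0)
  counts <- somatic_gene_counts(v0, manifest)
  res <- burden_test(counts)
  expect_equal(res$omnibus_p, 1)
  expect_equal(nrow(res$flagged), 0)
})

test_that("a small cohort with a modest excess is not flagged (power limit)", {
  manifest <- tibble::tibble(
    case_id = c("A", "B", "C"), sex = "female",
    blast_percent = 60, karyotype_note = NA_character_
  )
  v <- blank_rows(4)
  v$case_id <- c("A", "A", "B", "C")
  v$gene <- c("TET2", "WT1", "TET2", "NPM1")
  v$origin <- "somatic"
  res <- burden_test(somatic_gene_counts(v, manifest), alpha = 0.01)
  expect_equal(nrow(res$flagged), 0)
})

test_that("pharmacogenomic lookup counts risk genotypes over the whole cohort", {
  ex <- worked_example_cohort()
  res <- pharmaco_lookup(ex$pgx_variants, ex$manifest)
  expect_equal(res$summary$n_cases, 26L)
  expect_equal(res$summary$n_carriers, 19L)
  expect_equal(res$summary$carrier_pct, 73)

  # brute-force genotype scan oracle
  risk <- c("GG", "CG")
  carriers <- 0
  for (cid in ex$manifest$case_id) {
    hit <- ex$pgx_variants[
      ex$pgx_variants$case_id == cid &
        !is.na(ex$pgx_variants$rsid) & ex$pgx_variants$rsid == "rs1042522",
    ]
    gt <- if (nrow(hit) == 0) {
      "GG"
    } else if (hit$genotype[1] == "het") {
      paste(sort(c("G", "C")), collapse = "")
    } else {
      "CC"
    }
    if (gt %in% risk) carriers <- carriers + 1
  }
  expect_equal(res$summary$n_carriers, carriers)

  # a rule whose rsID is absent reports zero carriers, not an error
  rules <- read_pgx_rules()
  rules$rsid <- "rs0000000"
  res0 <- pharmaco_lookup(ex$pgx_variants, ex$manifest, rules)
  # every case defaults to homozygous reference GG, which is a risk genotype
  # for the bundled rule; with a non-risk reference genotype none carry
  rules$risk_genotypes <- "CC"
  res0 <- pharmaco_lookup(ex$pgx_variants, ex$manifest, rules)
  expect_equal(res0$summary$n_carriers, 0L)
  expect_equal(res0$summary$carrier_pct, 0)
})

test_that("cohort summary equals independent recomputation and is self-consistent", {
  sim <- simulate_cohort(sim_config(n_cases = 15, seed = 47, somatic_per_case_mean = 3))
  res <- suppressMessages(run_pipeline(
    run_config(manifest = sim$manifest, variants = sim$variants)
  ))
  s <- res$summary
  cl <- s$classified

  expect_equal(s$somatic$total, sum(cl$origin == "somatic"))
  som <- cl[cl$origin == "somatic", ]
  expect_equal(s$somatic$snv, sum(nchar(som$ref) == 1 & nchar(som$alt) == 1))
  expect_equal(s$somatic$snv + s$somatic$indel, s$somatic$total)
  expect_equal(s$somatic$non_silent + s$somatic$silent, s$somatic$total)
  expect_equal(s$germline_total, sum(cl$origin == "germline"))
  expect_equal(
    s$rates$somatic_per_case, round(s$somatic$total / s$n_cases, 2)
  )
  co <- s$cooccurrence
  expect_equal(co$both + co$somatic_only + co$germline_only + co$neither, s$n_cases)
  expect_equal(
    s$rates$cases_with_any_mutation,
    co$both + co$somatic_only + co$germline_only
  )
  expect_equal(sum(s$per_case_burden$n_somatic), s$somatic$total)
  expect_equal(nrow(s$per_case_burden), s$n_cases)
})
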