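manifest_for <- function(case_id, blast, sex = "female") {
  tibble::tibble(
    case_id = case_id, sex = sex, blast_percent = blast,
    karyotype_note = NA_character_
  )
}

test_that("origin follows the half-blast rule with a strict boundary", {
  v <- blank_rows(2)
  v$vaf <- c(0.25, 0.40)
  out <- classify_origin(v, manifest_for("C01", 80))
  expect_equal(out$somatic_threshold, c(0.40, 0.40))
  expect_equal(out$origin, c("somatic", "germline"))
})

test_that("classification errors and caveats are surfaced, not silent", {
  v <- blank_rows(1)
  expect_error(classify_origin(v, manifest_for("C99", 80)),
    class = "panelvar_classification_error"
  )
  expect_error(classify_origin(v, manifest_for("C01", NA_real_)),
    class = "panelvar_classification_error"
  )
  # X-linked gene in a male case is flagged
  vx <- blank_rows(1)
  vx$chrom <- "chrX"
  vx$gene <- "STAG2"
  out <- classify_origin(vx, manifest_for("C01", 80, sex = "male"))
  expect_equal(out$caveat, "x_hemizygous")
  # threshold below read-count resolution is flagged untestable
  vu <- blank_rows(1)
  vu$depth <- 1000L
  vu$alt_depth <- 1L
  vu$vaf <- 0.001
  out <- classify_origin(vu, manifest_for("C01", 0.1))
  expect_equal(out$caveat, "untestable")
})

test_that("germline-het misclassification matches the exact binomial tail at 100% blasts", {
  n <- 20000
  depth <- 5000L
  set.seed(77)
  v <- blank_rows(n)
  v$depth <- depth
  v$alt_depth <- rbinom(n, depth, 0.5)
  v$vaf <- v$alt_depth / v$depth
  out <- classify_origin(v, manifest_for("C01", 100))
  observed <- mean(out$origin == "somatic")
  expected <- pbinom(ceiling(0.5 * depth) - 1, depth, 0.5)
  mc_se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(observed - expected), 3 * mc_se)
})

test_that("increasing blast percentage can only flip germline to somatic", {
  set.seed(55)
  v <- blank_rows(200)
  v$vaf <- runif(200)
  lower <- classify_origin(v, manifest_for("C01", 40))$origin
  higher <- classify_origin(v, manifest_for("C01", 85))$origin
  expect_true(all(!(lower == "somatic" & higher == "germline")))
})

test_that("clonal ordering reproduces the seven worked-example co-mutated cases", {
  fixture <- worked_example_clonal_vafs()
  out <- assign_clones(fixture, delta_threshold = 0.1)
  expect_equal(nrow(out), nrow(fixture))
  merged <- merge(out, fixture, by = c("case_id", "gene", "hgvs_p", "vaf"))
  expect_equal(nrow(merged), nrow(fixture))
  expect_equal(merged$clone_label, merged$expected_clone)
  # spot-check the three canonical patterns
  am19 <- out[out$case_id == "AM19", ]
  expect_equal(am19$clone_label[order(-am19$vaf)], c("founding", "subclone"))
  am16 <- out[out$case_id == "AM16", ]
  expect_equal(am16$clone_label, c("founding", "founding"))
  am03 <- out[out$case_id == "AM03", ]
  expect_equal(
    am03$clone_label[order(-am03$vaf)],
    c("founding", "founding", "subclone")
  )
})

test_that("clone assignment is a proper VAF partition", {
  set.seed(12)
  v <- tibble::tibble(
    case_id = rep(sprintf("C%02d", 1:20), each = 4),
    gene = "TET2", hgvs_p = NA_character_,
    vaf = runif(80, 0, 0.5)
  )
  out <- assign_clones(v, delta_threshold = 0.07)
  by_case <- split(out, out$case_id)
  for (cc in by_case) {
    f <- cc$vaf[cc$clone_label == "founding"]
    s <- cc$vaf[cc$clone_label == "subclone"]
    expect_true(all(max(cc$vaf) - f <= 0.07 + 1e-12))
    if (length(s) > 0) {
      expect_true(min(f) >= max(s))
      expect_true(all(max(cc$vaf) - s > 0.07))
    }
  }
  # a case with a single qualifying variant is omitted, not an error
  single <- tibble::tibble(
    case_id = "X1", gene = "WT1", hgvs_p = NA_character_, vaf = 0.2
  )
  expect_equal(nrow(assign_clones(single)), 0)
})

test_that("simulated cohorts recover true origin labels almost perfectly", {
  sim <- simulate_cohort(sim_config(n_cases = 26, seed = 2, somatic_per_case_mean = 4))
  res <- suppressMessages(run_pipeline(
    run_config(manifest = sim$manifest, variants = sim$variants)
  ))
  tr <- merge(res$summary$classified, sim$truth, by = c("variant_id", "case_id"))
  het_auto <- tr$true_origin == "germline" & tr$genotype == "het" & !tr$hemizygous
  founding <- tr$true_origin == "somatic" & tr$clone_id == 0 & !tr$hemizygous
  expect_gte(mean(tr$origin[het_auto] == "germline"), 0.99)
  expect_gte(mean(tr$origin[founding] == "somatic"), 0.99)
})
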