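test_that("region/impact tabulation matches a brute-force tally", {
  sim <- simulate_cohort(sim_config(n_cases = 7, seed = 19))
  v <- utils::head(sim$variants, 500)
  ri <- summarize_regions(v)
  tab <- table(v$genomic_region)
  for (r in genomic_regions()) {
    expect_equal(
      ri$regions$n[ri$regions$genomic_region == r],
      as.integer(if (r %in% names(tab)) tab[[r]] else 0L),
      label = r
    )
  }
  coding <- v[v$genomic_region %in% c("exonic", "splicing"), ]
  itab <- table(coding$functional_impact)
  for (i in setdiff(functional_impacts(), "not_applicable")) {
    expect_equal(
      ri$impacts$n[ri$impacts$functional_impact == i],
      as.integer(if (i %in% names(itab)) itab[[i]] else 0L),
      label = i
    )
  }
  expect_equal(sum(ri$regions$n), ri$total)
  expect_equal(sum(ri$impacts$n), ri$coding_total)
})

test_that("tabulation is permutation-invariant and additive", {
  sim <- simulate_cohort(sim_config(n_cases = 4, seed = 23))
  v <- sim$variants
  set.seed(1)
  shuffled <- v[sample.int(nrow(v)), ]
  expect_equal(summarize_regions(v)$regions, summarize_regions(shuffled)$regions)
  half <- nrow(v) %/% 2
  a <- summarize_regions(v[seq_len(half), ])
  b <- summarize_regions(v[(half + 1):nrow(v), ])
  whole <- summarize_regions(v)
  expect_equal(a$regions$n + b$regions$n, whole$regions$n)
  expect_equal(a$impacts$n + b$impacts$n, whole$impacts$n)

  one <- blank_rows(1)
  one$functional_impact <- "synonymous_snv"
  ri1 <- summarize_regions(one)
  expect_equal(ri1$regions$n[ri1$regions$genomic_region == "exonic"], 1L)
  expect_equal(sum(ri1$regions$n), 1L)
  expect_equal(
    ri1$impacts$n[ri1$impacts$functional_impact == "synonymous_snv"], 1L
  )
  expect_equal(sum(ri1$impacts$n), 1L)
  one$genomic_region <- "weird"
  expect_error(summarize_regions(one), class = "panelvar_validation_error")
})

test_that("silence partition follows the protein-altering definition", {
  expect_equal(classify_silence("stopgain", "exonic"), "non_silent")
  expect_equal(classify_silence("nonframeshift_insertion", "exonic"), "silent")
  expect_equal(classify_silence("synonymous_snv", "exonic"), "silent")
  expect_equal(classify_silence("not_applicable", "splicing"), "non_silent")
  expect_equal(classify_silence("not_applicable", "intronic"), "silent")
  expect_equal(
    classify_silence("nonframeshift_insertion", "exonic",
      nonframeshift_is_nonsilent = TRUE
    ),
    "non_silent"
  )

  cats <- enumerated_somatic_categories()
  silence <- classify_silence(cats$functional_impact, cats$genomic_region)
  expect_equal(nrow(cats), 38)
  expect_equal(sum(silence == "non_silent"), 23)
  expect_equal(sum(silence == "silent"), 15)
})

test_that("nonsyn/syn ratio reproduces worked-example and handles degenerate counts", {
  expect_equal(
    nonsyn_syn_ratio(c(nonsynonymous_snv = 71, synonymous_snv = 61))$cohort_ratio,
    1.16
  )
  expect_equal(
    nonsyn_syn_ratio(c(nonsynonymous_snv = 10, synonymous_snv = 10))$cohort_ratio,
    1.00
  )
  expect_true(is.na(
    nonsyn_syn_ratio(c(nonsynonymous_snv = 5, synonymous_snv = 0))$cohort_ratio
  ))

  ref_path <- system.file("extdata", "reference_nonsyn_syn_synthetic.tsv",
    package = "panelvar"
  )
  out <- nonsyn_syn_ratio(
    c(nonsynonymous_snv = 71, synonymous_snv = 61),
    reference = ref_path
  )
  ref <- readr::read_tsv(ref_path, show_col_types = FALSE)
  expect_equal(out$reference_ratio, round(ref$nonsyn / ref$syn, 2))
})

test_that("conservation bins tile the score line exactly once", {
  expect_equal(bin_conservation(6.2), "high")
  expect_equal(bin_conservation(4.0), "moderate")
  expect_equal(bin_conservation(1.0), "moderate")
  expect_equal(bin_conservation(0.99), "non_conserved")
  expect_true(is.na(bin_conservation(NA_real_)))

  set.seed(8)
  x <- c(runif(500, -10, 10), 1, 4, NA)
  bins <- bin_conservation(x)
  expect_true(all(is.na(bins) == is.na(x)))
  ok <- !is.na(x)
  expect_true(all(
    (x[ok] > 4) == (bins[ok] == "high") &
      (x[ok] >= 1 & x[ok] <= 4) == (bins[ok] == "moderate") &
      (x[ok] < 1) == (bins[ok] == "non_conserved")
  ))
})
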