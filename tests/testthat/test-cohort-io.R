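test_that("manifest reading maps fields and enforces invariants", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "case_id\tsex\tblast_percent",
    "AM19\tmale\t73.2",
    "AM20\tfemale\t55"
  ), path)
  m <- read_manifest(path)
  expect_equal(m$blast_percent, c(73.2, 55))
  expect_equal(m$sex, c("male", "female"))

  writeLines(c("case_id\tsex\tblast_percent", "A\tmale\t101"), path)
  expect_error(read_manifest(path), class = "panelvar_validation_error")
  writeLines(c("case_id\tsex\tblast_percent", "A\tmale\t"), path)
  expect_error(read_manifest(path), class = "panelvar_validation_error")
  writeLines(c(
    "case_id\tsex\tblast_percent", "A\tmale\t50", "A\tfemale\t60"
  ), path)
  expect_error(read_manifest(path), class = "panelvar_validation_error")
  writeLines(c("case_id\tsex", "A\tmale"), path)
  expect_error(read_manifest(path),
    regexp = "blast_percent",
    class = "panelvar_configuration_error"
  )
})

test_that("manifest row count equals data-line count of the file", {
  path <- withr::local_tempfile(fileext = ".tsv")
  lines <- c(
    "case_id\tsex\tblast_percent",
    sprintf("AM%02d\t%s\t%.1f", 1:26, rep(c("male", "female"), 13), seq(30, 92.5, 2.5))
  )
  writeLines(lines, path)
  m <- read_manifest(path)
  expect_equal(nrow(m), length(readLines(path)) - 1L)
})

test_that("annotated-TSV round trip preserves every field", {
  sim <- simulate_cohort(sim_config(n_cases = 2, seed = 7, germline_per_case_mean = 25))
  v <- utils::head(sim$variants[, -1], 50)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variants_tsv(v, path)
  back <- read_variants(path, dialect = "annotated_tsv")
  expect_equal(as.data.frame(back), as.data.frame(v[, names(back)]))
})

test_that("VCF dialect computes VAF from AD, splits multiallelics, skips zero depth", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"q\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tAM01",
    "chr1\t100\t.\tA\tG\t900\t.\tGENE=TET2;REGION=exonic;IMPACT=nonsynonymous_snv;AF=0.9\tGT:DP:AD:GQ\t0/1:5000:4478,522:99",
    "chr2\t200\t.\tC\tT,G\t800\t.\tGENE=ASXL1;REGION=intronic;IMPACT=not_applicable\tGT:DP:AD:GQ\t0/1:1000:800,150,50:80",
    "chr3\t300\t.\tG\tA\t700\t.\tGENE=WT1;REGION=intronic;IMPACT=not_applicable\tGT:DP:AD:GQ\t0/1:0:0,0:50"
  ), path)
  expect_warning(v <- read_variants(path, dialect = "vcf"), "zero depth")
  # 4 alt-allele records in, 3 returned + 1 warned-skipped
  expect_equal(nrow(v), 3)
  expect_equal(v$alt_depth[1], 522L)
  expect_equal(v$vaf[1], 0.1044)
  # multiallelic split: one row per alt with its own AD entry
  expect_equal(v$alt[2:3], c("T", "G"))
  expect_equal(v$alt_depth[2:3], c(150L, 50L))
  expect_equal(v$case_id, rep("AM01", 3))
  expect_equal(v$gene[1], "TET2")
})

test_that("VCF writer and reader round-trip simulated records", {
  sim <- simulate_cohort(sim_config(n_cases = 2, seed = 11, germline_per_case_mean = 20))
  v <- sim$variants[, -1]
  path <- withr::local_tempfile(fileext = ".vcf")
  write_variants_vcf(v, path)
  back <- read_variants(path, dialect = "vcf")
  expect_equal(nrow(back), nrow(v))
  for (col in c(
    "case_id", "chrom", "pos", "ref", "alt", "depth", "alt_depth",
    "genotype", "gene", "genomic_region", "functional_impact", "vaf",
    "af_gnomad", "sift_class", "phylop"
  )) {
    expect_equal(back[[col]], v[[col]], tolerance = 1e-9, label = col)
  }
})

test_that("unknown category tokens are rejected with the allowed list", {
  sim <- simulate_cohort(sim_config(n_cases = 1, seed = 3, germline_per_case_mean = 5))
  v <- sim$variants[, -1]
  v$functional_impact[1] <- "missense_weird"
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variants_tsv(v, path)
  expect_error(read_variants(path, "annotated_tsv"),
    regexp = "allowed.*nonsynonymous_snv",
    class = "panelvar_validation_error"
  )
})

test_that("report files are valid, round-trip, and handle empty cohorts", {
  ex <- worked_example_cohort()
  s <- summarize_cohort(ex$classified, ex$manifest, qc_variants = ex$pgx_variants)
  dir <- withr::local_tempdir()
  files <- write_report(s, dir)
  expect_true(all(file.exists(files)))

  back <- readr::read_tsv(files[1], na = ".", show_col_types = FALSE)
  expect_equal(nrow(back), nrow(s$classified))
  expect_equal(back$origin, s$classified$origin)
  expect_equal(back$vaf, s$classified$vaf)

  js <- jsonlite::read_json(files[2])
  expect_equal(js$n_cases, s$n_cases)
  expect_equal(js$somatic$total, s$somatic$total)
  expect_equal(js$rates$somatic_per_case, s$rates$somatic_per_case)
  expect_equal(js$cooccurrence$both, s$cooccurrence$both)

  # empty cohort still writes valid zero-count files
  empty <- summarize_cohort(
    ex$classified[0, ],
    ex$manifest[0, ]
  )
  dir2 <- withr::local_tempdir()
  files2 <- write_report(empty, dir2)
  js2 <- jsonlite::read_json(files2[2])
  expect_equal(js2$somatic$total, 0)
  expect_equal(js2$n_cases, 0)
})

test_that("rendered region table column sums match the input counts", {
  ex <- worked_example_cohort()
  ri <- summarize_regions(ex$classified)
  txt <- render_region_table(ri)
  region_lines <- txt[2:7]
  shown <- as.integer(sub(".*\t", "", region_lines))
  expect_equal(sum(shown), nrow(ex$classified))
})
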