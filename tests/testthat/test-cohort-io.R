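test_that("read_score_file parses an 11-variant file, preserving order and case", {
  rows <- sprintf("rs%d\t%d\t%d\t%s\t%s\t%g", 1:11, 1:11, 1000 * (1:11),
                  rep(c("a", "G", "t", "C"), length.out = 11),
                  rep(c("g", "A", "c", "T"), length.out = 11),
                  seq(-0.2, 0.3, length.out = 11))
  path <- write_weights_fixture(rows, comments = "# CAC score, build GRCh37")
  w <- read_score_file(path)
  expect_s3_class(w, "grs_weights")
  expect_equal(nrow(w), 11)
  expect_equal(w$variant_id, paste0("rs", 1:11))
  expect_true(all(w$effect_allele %in% c("A", "C", "G", "T")))
  expect_equal(w$effect_weight, seq(-0.2, 0.3, length.out = 11))
})

test_that("read_score_file handles empty data and reports parse errors by line", {
  empty <- write_weights_fixture(character(0))
  expect_equal(nrow(read_score_file(empty)), 0)

  bad <- write_weights_fixture(c("rs1\t1\t100\tA\tG\t0.1",
                                 "rs2\t1\t200\tC\tT\tNA"))
  expect_error(read_score_file(bad), "line 3")

  missing_col <- tempfile(fileext = ".tsv")
  writeLines(c("rsID\tchr_name\tchr_position\teffect_allele\tother_allele",
               "rs1\t1\t100\tA\tG"), missing_col)
  expect_error(read_score_file(missing_col), "effect_weight")
})

test_that("read_score_file optional r2 column and filter work", {
  rows <- c("rs1\t1\t100\tA\tG\t0.1\t0.95", "rs2\t1\t200\tC\tT\t0.2\t0.25")
  path <- write_weights_fixture(
    rows, header = c("rsID", "chr_name", "chr_position", "effect_allele",
                     "other_allele", "effect_weight", "imputation_r2"))
  w <- read_score_file(path)
  expect_equal(w$imputation_r2, c(0.95, 0.25))
  expect_equal(read_score_file(path, r2_filter = TRUE)$variant_id, "rs1")
})

test_that("read_dosages converts VCF hard calls and passes dosages through", {
  wanted <- simple_weights("rs1", "G", "A", 0.1)
  gt <- write_vcf_fixture(list(c("rs1", "1", "100", "A", "G",
                                 "0/0", "0/1", "1/1")),
                          c("s1", "s2", "s3"), format = "GT")
  dm <- read_dosages(gt, wanted)
  expect_equal(unname(dm$dosages[, 1]), c(0, 1, 2))

  ds <- write_vcf_fixture(list(c("rs1", "1", "100", "A", "G",
                                 "0/1:1.37", "0/0:0.02", "1/1:1.99")),
                          c("s1", "s2", "s3"), format = "GT:DS")
  dm2 <- read_dosages(ds, wanted)
  expect_equal(unname(dm2$dosages[, 1]), c(1.37, 0.02, 1.99))
})

test_that("read_dosages records absent wanted variants and fails when none found", {
  set.seed(42)
  w <- gen_weights(11)
  dm_full <- gen_genotypes(w, 6)
  vcf <- tempfile(fileext = ".vcf")
  # drop one site from the file
  write_vcf_dosages(
    cacgrs:::new_dosage_matrix(dm_full$dosages[, -4, drop = FALSE],
                               dm_full$sample_ids, dm_full$variant_ids[-4],
                               ref = dm_full$ref[-4], alt = dm_full$alt[-4]),
    w, vcf)
  dm <- read_dosages(vcf, w)
  expect_equal(length(dm$variant_ids), 10)
  expect_equal(dm$missing_variants, w$variant_id[4])

  none <- simple_weights("rsX", "A", "G", 0.5)
  expect_error(read_dosages(vcf, none), "none of the")
})

test_that("read_dosages falls back to chr:pos + allele-set matching", {
  wanted <- simple_weights("rs_other_name", "G", "A", 0.1,
                           chr = "7", pos = 555)
  vcf <- write_vcf_fixture(list(c("rs1", "7", "555", "A", "G", "0/1", "1/1")),
                           c("s1", "s2"))
  dm <- read_dosages(vcf, wanted)
  expect_equal(unname(dm$dosages[, 1]), c(1, 2))
})

test_that("harmonize_alleles flips, keeps and drops correctly", {
  w <- simple_weights(c("v1", "v2", "v3", "v4"),
                      effect = c("A", "G", "A", "C"),
                      other  = c("G", "A", "T", "A"),
                      w = c(0.1, 0.2, 0.3, 0.4))
  d <- matrix(c(0.5, 1.2, 1.0, 0.7), nrow = 1)
  # v1: file ref = effect -> flip; v2: file alt = effect -> identity;
  # v3: palindromic A/T -> drop; v4: alleles disagree with file -> drop
  dm <- cacgrs:::new_dosage_matrix(d, "s1", c("v1", "v2", "v3", "v4"),
                                   ref = c("A", "A", "A", "G"),
                                   alt = c("G", "G", "T", "T"))
  h <- harmonize_alleles(dm, w)
  expect_equal(h$dosages$variant_ids, c("v1", "v2"))
  expect_equal(unname(h$dosages$dosages[1, ]), c(2 - 0.5, 1.2))
  expect_setequal(h$exclusions$reason, c("palindromic", "allele_mismatch"))
  expect_equal(h$weights$variant_id, c("v1", "v2"))
})

test_that("harmonization is idempotent and flip-consistent", {
  set.seed(7)
  for (rep in 1:5) {
    w <- gen_weights(8)
    dm <- gen_genotypes(w, 12)
    # recode a random subset of variants as ref = effect allele, d -> 2 - d
    fl <- sample(c(TRUE, FALSE), 8, replace = TRUE)
    d2 <- dm$dosages
    d2[, fl] <- 2 - d2[, fl]
    dm_flipped <- cacgrs:::new_dosage_matrix(
      d2, dm$sample_ids, dm$variant_ids,
      ref = ifelse(fl, dm$alt, dm$ref), alt = ifelse(fl, dm$ref, dm$alt))

    h1 <- harmonize_alleles(dm, w)
    h2 <- harmonize_alleles(dm_flipped, w)
    expect_equal(h2$dosages$dosages, h1$dosages$dosages)

    h11 <- harmonize_alleles(h1$dosages, w)
    expect_equal(h11$dosages$dosages, h1$dosages$dosages)
    expect_equal(nrow(h11$exclusions), 0)
  }
})

test_that("phenotype reading validates and round-trips a large synthetic table", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,age,sex,smoking,calc_lad_pct",
               "s1,60,male,1,10",
               "s2,55,female,,0",
               "s3,70,male,0,100"), csv)
  ph <- read_phenotypes(csv)
  expect_equal(sum(is.na(ph$smoking)), 1)
  expect_equal(ph$sex, c("male", "female", "male"))

  bad <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,calc_lad_pct", "s1,130"), bad)
  expect_error(read_phenotypes(bad), "s1")

  dup <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,age", "s1,60", "s1,61"), dup)
  expect_error(read_phenotypes(dup), "duplicate")

  # clinical-cohort-scale round-trip, bit-identical numerics
  set.seed(11)
  co <- gen_covariates(2742, "clinical")
  co$cad_case <- rbinom(2742, 1, 0.7)
  path <- tempfile(fileext = ".csv")
  write_phenotypes(co, path)
  co2 <- read_phenotypes(path)
  expect_equal(as.data.frame(co2), as.data.frame(co)[, names(co2)],
               ignore_attr = TRUE)
})

test_that("phenotype column mapping and sex labels are configurable", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("id,years,gender", "s1,60,M", "s2,55,F"), csv)
  map_yaml <- tempfile(fileext = ".yaml")
  writeLines(c("sample_id: id", "age: years", "sex: gender",
               "sex_labels:", "  male: M", "  female: F"), map_yaml)
  ph <- read_phenotypes(csv, mapping = map_yaml)
  expect_equal(ph$age, c(60, 55))
  expect_equal(ph$sex, c("male", "female"))
})

test_that("CAD case definition uses an inclusive threshold on the max stenosis", {
  co <- data.frame(
    sample_id = paste0("s", 1:5),
    stenosis_lad_pct = c(61.5, 49.9, 50.0, NA, NA),
    stenosis_rca_pct = c(10, 49.9, NA, 80, NA)
  )
  out <- define_cad_cases(co)
  expect_equal(out$cad_case, c(1, 0, 1, 1, NA))
  # custom threshold
  expect_equal(define_cad_cases(co, threshold_pct = 70)$cad_case,
               c(0, 0, 0, 1, NA))
})
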