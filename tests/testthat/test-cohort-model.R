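test_that("allele fractions enforce their invariants", {
  expect_error(allele_fraction("QUANTIFIED", value = 101), "0, 100")
  expect_error(allele_fraction("QUANTIFIED"), "needs a value")
  expect_error(allele_fraction("ABSENT", value = 5), "must not carry")
  expect_error(allele_fraction("PRESENT_UNQUANTIFIED", value = 5),
               "must not carry")
  expect_error(allele_fraction("QUANTIFIED", interval_low = 15,
                               interval_high = 10), "must not exceed")
  expect_equal(af_representative(af_q(23.6)), 23.6)
  expect_equal(af_representative(
    allele_fraction("QUANTIFIED", interval_low = 10, interval_high = 15)),
    12.5)
  expect_true(is.na(af_representative(af_absent())))
  expect_true(is.na(af_representative(
    allele_fraction("PRESENT_UNQUANTIFIED"))))
})

test_that("patient records reject dangling or blood-less variants", {
  v <- variant_call("TP53_1", "TP53", "c.524G>A")
  expect_error(
    patient_record("P1", variants = list(v),
                   observations = list(
                     tissue_observation("TP53_9", "PBL", af_q(10)))),
    "undeclared variant")
  expect_error(
    patient_record("P1", variants = list(v),
                   observations = list(
                     tissue_observation("TP53_1", "DIRECT_SKIN", af_q(10)))),
    "no PBL observation")
  expect_error(variant_call("TP53_1", "", "c.1A>G"), "non-empty")
  expect_error(clinical_context(wbc = 0), "positive")
})

test_that("cohort JSON round-trips field for field", {
  pts <- load_fixture_cohort()
  tmp <- tempfile(fileext = ".json")
  write_patients(pts, tmp, format = "json")
  back <- read_patients(tmp, format = "json")
  expect_equal(back, pts)
  # empty cohort is the identity too
  tmp2 <- tempfile(fileext = ".json")
  write_patients(list(), tmp2, format = "json")
  expect_equal(read_patients(tmp2), list())
})

test_that("cohort TSV dialect (three linked tables) round-trips", {
  pts <- load_fixture_cohort()
  dir <- tempfile()
  write_patients(pts, dir, format = "tsv")
  expect_true(all(file.exists(file.path(
    dir, c("patients.tsv", "variants.tsv", "observations.tsv")))))
  back <- read_patients(dir, format = "tsv")
  expect_equal(back, pts)
})

test_that("malformed documents fail with informative errors", {
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(list(foo = 1), tmp, auto_unbox = TRUE)
  expect_error(read_patients(tmp), "patients")
  dup <- list(simple_patient("A"), simple_patient("A"))
  tmp2 <- tempfile(fileext = ".json")
  expect_error(write_patients(dup, tmp2), "duplicate patient_id")
})

test_that("the packaged cohort has the documented structure", {
  pts <- load_fixture_cohort()
  expect_length(pts, 24L)

  genes_per_patient <- lapply(pts, function(p)
    unique(vapply(p$variants, `[[`, "", "gene")))
  expect_identical(sum(lengths(genes_per_patient) > 1L), 2L)

  tissues <- function(p) vapply(p$observations, `[[`, "", "tissue")
  expect_identical(sum(vapply(pts, function(p)
    "DIRECT_SKIN" %in% tissues(p), TRUE)), 11L)
  expect_identical(sum(vapply(pts, function(p)
    "TUMOUR" %in% tissues(p), TRUE)), 3L)

  tally <- table(unlist(genes_per_patient))
  expect_equal(as.integer(tally[c("TP53", "ATM", "CHEK2", "APC", "BRCA1")]),
               c(17L, 3L, 2L, 2L, 2L))

  by_id <- setNames(pts, vapply(pts, `[[`, "", "patient_id"))
  p29 <- by_id[["29"]]
  expect_equal(p29$variants[[1]]$cdna, "c.375G>A")
  expect_equal(af_representative(obs_29 <- p29$observations[[1]]$af), 50)
  fib <- Filter(function(o) o$tissue == "CULTURED_FIBROBLAST",
                p29$observations)
  expect_equal(af_representative(fib[[1]]$af), 50)

  p11 <- by_id[["11"]]
  expect_equal(p11$clinical$wbc, 84.9)
  expect_false(is.null(p11$clinical$heme_malignancy_dx))
})

test_that("VCF allele fractions equal an independent recomputation", {
  tmp <- write_test_vcf(tempfile(fileext = ".vcf"), c(
    "chr1\t100\trs1\tA\tG\t.\tPASS\t.\tGT:AD:DP\t0/1:250,250:500",
    "chr1\t200\t.\tA\tG,T\t.\tPASS\t.\tGT:AD:DP\t1/2:440,29,31:500",
    "chr1\t300\trs3\tA\tG\t.\tPASS\t.\tGT:AD:DP\t0/0:500,0:500",
    "chr1\t400\trs4\tA\tG\t.\tPASS\t.\tGT:AD:DP\t./.:0,0:0"))
  obs <- ingest_vcf(tmp, "S1", tissue = "PBL", age_at_sample = 60)
  expect_length(obs, 5L)  # multi-allelic record split per ALT

  # independent recomputation from the depths written above
  expect_equal(af_representative(obs[[1]]$af), 100 * 250 / 500)
  expect_equal(af_representative(obs[[2]]$af), 100 * 29 / 500)  # 5.8
  expect_equal(af_representative(obs[[3]]$af), 100 * 31 / 500)
  expect_identical(obs[[4]]$af$status, "ABSENT")  # alt depth 0
  expect_identical(obs[[5]]$af$status, "ABSENT")  # total depth 0
  expect_equal(obs[[1]]$variant_key, "rs1")
  expect_match(obs[[2]]$variant_key, "chr1:200")
  expect_identical(obs[[1]]$tissue, "PBL")
  expect_equal(obs[[1]]$age_at_sample, 60)
})

test_that("VCF ingestion falls back to the AF field and checks the sample", {
  tmp <- write_test_vcf(tempfile(fileext = ".vcf"), c(
    "chr1\t100\trs1\tA\tG\t.\tPASS\t.\tGT:AF\t0/1:0.5",
    "chr1\t200\trs2\tA\tG\t.\tPASS\t.\tGT:AF\t0/0:0"),
    format = "GT:AF")
  obs <- ingest_vcf(tmp, "S1")
  expect_equal(af_representative(obs[[1]]$af), 50)
  expect_identical(obs[[2]]$af$status, "ABSENT")
  expect_error(ingest_vcf(tmp, "NOSUCH"), "not found")
})
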