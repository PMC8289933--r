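fixture <- load_fixture_cohort()
by_id <- setNames(fixture, vapply(fixture, `[[`, "", "patient_id"))

test_that("presence grading follows the configured bands", {
  cfg <- threshold_config()
  call_at <- function(af, tissue = "CULTURED_FIBROBLAST", ref = 50)
    call_presence(tissue_observation("V_1", tissue,
                                     if (is.na(af)) af_absent() else af_q(af)),
                  pbl_reference_af = ref, config = cfg)$level
  expect_identical(call_at(NA), "ABSENT")
  expect_identical(call_at(0.5), "ABSENT")   # below detection floor
  expect_identical(call_at(5), "TRACE")
  expect_identical(call_at(15), "PRESENT_SUBHET")
  expect_identical(call_at(30), "PRESENT_HET")
  expect_identical(call_at(70), "PRESENT_HET")
  expect_identical(call_at(82.3), "PRESENT_HIGH")
})

test_that("raising the AF never lowers the presence level", {
  cfg <- threshold_config()
  lv <- vapply(seq(0.2, 99, by = 0.7), function(af)
    match(call_presence(tissue_observation("V_1", "MUSCLE", af_q(af)),
                        0, cfg)$level,
          c("ABSENT", "TRACE", "PRESENT_SUBHET", "PRESENT_HET",
            "PRESENT_HIGH")), 0L)
  expect_true(all(diff(lv) >= 0L))
})

test_that("contamination suspicion is skin-specific and ratio-gated", {
  # low skin positivity well under half the blood AF: flagged
  skin <- call_presence(
    tissue_observation("V_1", "DIRECT_SKIN", af_q(2.2)),
    pbl_reference_af = 15, config = threshold_config())
  expect_identical(skin$level, "TRACE")
  expect_true(skin$contamination_suspected)

  # same numbers in cultured fibroblasts: never flagged
  fib <- call_presence(
    tissue_observation("V_1", "CULTURED_FIBROBLAST", af_q(2.2)),
    pbl_reference_af = 15, config = threshold_config())
  expect_false(fib$contamination_suspected)

  # sub-het fibroblast call at blood level (mosaic pattern): not flagged
  m <- call_presence(
    tissue_observation("V_1", "CULTURED_FIBROBLAST", af_q(24)),
    pbl_reference_af = 23.6, config = threshold_config())
  expect_identical(m$level, "PRESENT_SUBHET")
  expect_false(m$contamination_suspected)

  # skin positivity close to the blood AF: genuine, not contamination
  g <- call_presence(
    tissue_observation("V_1", "DIRECT_SKIN", af_q(27)),
    pbl_reference_af = 23.6, config = threshold_config())
  expect_false(g$contamination_suspected)

  # unquantified low skin positivity with positive blood: flagged
  u <- call_presence(
    tissue_observation("V_1", "DIRECT_SKIN",
                       allele_fraction("PRESENT_UNQUANTIFIED")),
    pbl_reference_af = 12.5, config = threshold_config())
  expect_identical(u$level, "TRACE")
  expect_true(u$contamination_suspected)
  expect_match(u$basis, "unquantified")
})

test_that("evidence assembly: declining blood clone with negative tissues", {
  ev <- summarize_evidence(by_id[["2"]], "TP53_1")
  expect_identical(ev$calls[["PBL"]]$level, "TRACE")
  expect_identical(ev$calls[["DIRECT_SKIN"]]$level, "ABSENT")
  expect_identical(ev$calls[["CULTURED_FIBROBLAST"]]$level, "ABSENT")
  expect_equal(ev$pbl_af_fluctuation, 4.5)
  expect_equal(ev$pbl_af_series$af, c(5.8, 3.8, 1.3))
  expect_identical(unname(ev$reliability[["CULTURED_FIBROBLAST"]]), "HIGH")
  expect_identical(unname(ev$reliability[["DIRECT_SKIN"]]), "LOW")
})

test_that("skin-limited variants are surfaced but kept apart", {
  ev <- summarize_evidence(by_id[["10"]], "TP53_1")
  skin_only <- vapply(ev$skin_only_variants, `[[`, "", "cdna")
  expect_setequal(skin_only, c("c.880G>T", "c.380C>T"))
})

test_that("a single blood draw has zero fluctuation", {
  ev <- summarize_evidence(simple_patient("F0", pbl = 12), "TP53_1")
  expect_identical(ev$pbl_af_fluctuation, 0)
})

test_that("unknown variant keys are a lookup error", {
  expect_error(summarize_evidence(by_id[["2"]], "NOPE_1"), "unknown")
})

test_that("contamination is recognized through binomial noise at depth 500", {
  # skin truly at 0.3 x blood (blood 20%): the flag should almost always fire
  set.seed(500)
  depth <- 500
  hits <- 0L
  n_rep <- 1000L
  for (i in seq_len(n_rep)) {
    blood <- 100 * stats::rbinom(1, depth, 0.20) / depth
    skin_af <- sample_observed_af(6, depth)
    if (skin_af$status == "ABSENT") next
    pc <- call_presence(
      tissue_observation("V_1", "DIRECT_SKIN", skin_af),
      pbl_reference_af = blood, config = threshold_config())
    if (pc$contamination_suspected) hits <- hits + 1L
  }
  expect_gt(hits / n_rep, 0.95)
})
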