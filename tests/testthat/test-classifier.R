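fixture <- load_fixture_cohort()
by_id <- setNames(fixture, vapply(fixture, `[[`, "", "patient_id"))
conclusions <- classify_cohort(fixture)
names(conclusions) <- vapply(conclusions, `[[`, "", "patient_id")

test_that("every reference patient gets the published conclusion", {
  expect_length(conclusions, 24L)
  expect_length(attr(conclusions, "errors"), 0L)
  for (id in names(FIXTURE_EXPECTED_LABELS)) {
    expect_identical(conclusions[[id]]$primary_label,
                     unname(FIXTURE_EXPECTED_LABELS[[id]]),
                     label = paste("patient", id))
  }
})

test_that("hallmark cases fire the expected rules", {
  # heterozygous in blood and fibroblasts: full germline via G1
  vc29 <- classify_variant(by_id[["29"]], "TP53_1")
  expect_identical(vc29$label, "FULL_GERMLINE")
  expect_true("G1" %in% vapply(vc29$evidence, `[[`, "", "rule_id"))

  # sub-het in blood, fibroblasts positive at the same level: mosaic
  vc7 <- classify_variant(by_id[["7"]], "TP53_1")
  expect_identical(vc7$label, "MOSAIC")

  # unquantified polyp positivity still counts as a second tissue
  vc40 <- classify_variant(by_id[["40"]], "APC_1")
  expect_identical(vc40$label, "MOSAIC")

  # blood-restricted with negative fibroblasts and no malignancy: CH
  vc2 <- classify_variant(by_id[["2"]], "TP53_1")
  expect_identical(vc2$label, "CONFIRMED_CH")
  expect_true("C2" %in% vapply(vc2$evidence, `[[`, "", "rule_id"))

  # chart leukemia dominates; grossly elevated WBC sets the flag
  vc11 <- classify_variant(by_id[["11"]], "TP53_1")
  expect_identical(vc11$label, "HEME_MALIGNANCY_RELATED")
  expect_true(vc11$cbc_flag)
  expect_true("D4" %in% vapply(vc11$evidence, `[[`, "", "rule_id"))

  # apparently heterozygous TP53 contradicted by tumour: likely CH via C4
  vc41 <- classify_variant(by_id[["41"]], "TP53_1")
  expect_identical(vc41$label, "LIKELY_CH")
  ids41 <- vapply(vc41$evidence, `[[`, "", "rule_id")
  expect_true(all(c("D1", "D3", "C4") %in% ids41))

  # two pathogenic TP53 variants: the het-band one contradicted by D2
  vc16 <- classify_variant(by_id[["16"]], "TP53_2")
  expect_identical(vc16$label, "LIKELY_CH")
  expect_true("D2" %in% vapply(vc16$evidence, `[[`, "", "rule_id"))

  # heterozygous with nothing contradicting and no secondary tissue
  vc24 <- classify_variant(by_id[["24"]], "BRCA1_1")
  expect_identical(vc24$label, "LIKELY_GERMLINE")
})

test_that("patient-level conclusions wire co-findings and follow-up", {
  pc24 <- conclusions[["24"]]
  expect_identical(pc24$primary_label, "LIKELY_CH")
  co <- vapply(pc24$co_findings, `[[`, "", "label")
  expect_identical(unname(co), "LIKELY_GERMLINE")
  expect_true(all(c("FAMILY_VARIANT_TESTING", "CBC_MONITORING",
                    "CARDIOVASCULAR_RISK_PROGRAM") %in% pc24$follow_up))

  expect_identical(conclusions[["12"]]$follow_up, "HEMATOLOGY_REFERRAL")
  expect_setequal(conclusions[["29"]]$follow_up,
                  c("HEREDITARY_SURVEILLANCE", "FAMILY_VARIANT_TESTING"))
  # mildly raised WBC only flags CBC monitoring, never relabels
  expect_identical(conclusions[["10"]]$primary_label, "CONFIRMED_CH")
  expect_true(conclusions[["10"]]$cbc_flag)
})

test_that("skin-limited variants are annotations, never etiology labels", {
  vc <- classify_variant(by_id[["10"]], "TP53_2")
  expect_identical(vc$label, "UNRESOLVED")
  expect_identical(vc$evidence[[1]]$rule_id, "S1")
})

test_that("withdrawing the fibroblast confirmation demotes full germline", {
  p <- by_id[["29"]]
  p$observations <- Filter(function(o) o$tissue != "CULTURED_FIBROBLAST",
                           p$observations)
  vc <- classify_variant(p, "TP53_1")
  expect_identical(vc$label, "LIKELY_GERMLINE")
  expect_true("G2" %in% vapply(vc$evidence, `[[`, "", "rule_id"))
})

test_that("an all-consistent germline constellation is full germline", {
  p <- simple_patient("G1", pbl = 50,
                      tissues = list(CULTURED_FIBROBLAST = 50, TUMOUR = 60))
  expect_identical(classify_variant(p, "TP53_1")$label, "FULL_GERMLINE")
})

test_that("a missing blood observation is a precondition error", {
  expect_error(classify_variant(by_id[["2"]], "ABSENT_KEY"), "unknown")
})

test_that("classification is deterministic and total", {
  again <- classify_cohort(fixture)
  names(again) <- vapply(again, `[[`, "", "patient_id")
  expect_identical(lapply(again, `[[`, "primary_label"),
                   lapply(conclusions, `[[`, "primary_label"))
  expect_identical(lapply(again[["41"]]$variant_conclusions,
                          function(v) vapply(v$evidence, `[[`, "", "rule_id")),
                   lapply(conclusions[["41"]]$variant_conclusions,
                          function(v) vapply(v$evidence, `[[`, "", "rule_id")))
  expect_true(all(vapply(conclusions, function(pc)
    pc$primary_label %in% setdiff(CONCLUSION_LABELS, "UNRESOLVED"), TRUE)))
})

test_that("full germline always rests on a high-reliability heterozygous call", {
  g <- generate_cohort(sim_config(n_patients = 250, seed = 99))
  cc <- classify_cohort(g$patients)
  by_pid <- setNames(g$patients, vapply(g$patients, `[[`, "", "patient_id"))
  for (pc in cc) {
    for (vc in pc$variant_conclusions) {
      if (vc$label != "FULL_GERMLINE") next
      ev <- summarize_evidence(by_pid[[pc$patient_id]], vc$variant_key)
      high_het <- any(vapply(names(ev$calls), function(t)
        TISSUE_RELIABILITY[[t]] == "HIGH" &&
          ev$calls[[t]]$level == "PRESENT_HET", TRUE))
      expect_true(high_het, label = paste("patient", pc$patient_id))
    }
  }
})

test_that("a contamination-suspected call alone never yields mosaic", {
  # blood-restricted clone whose skin carry-over sits in the flagged range
  p <- simple_patient("K1", pbl = 20, tissues = list(DIRECT_SKIN = 6))
  vc <- classify_variant(p, "TP53_1")
  expect_false(vc$label == "MOSAIC")
  # the same skin level backed by clean fibroblasts stays CH
  q <- simple_patient("K2", pbl = 20,
                      tissues = list(DIRECT_SKIN = 6,
                                     CULTURED_FIBROBLAST = NA))
  expect_identical(classify_variant(q, "TP53_1")$label, "CONFIRMED_CH")
})

test_that("fibroblast absence overrides a discrepant skin positivity", {
  p <- simple_patient("K3", pbl = 20,
                      tissues = list(DIRECT_SKIN = 15,
                                     CULTURED_FIBROBLAST = NA))
  vc <- classify_variant(p, "TP53_1")
  expect_identical(vc$label, "CONFIRMED_CH")
})
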