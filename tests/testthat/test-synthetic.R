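test_that("binomial AF sampling hits the degenerate cases exactly", {
  set.seed(1)
  expect_identical(sample_observed_af(0, 500)$status, "ABSENT")
  expect_equal(af_representative(sample_observed_af(100, 500)), 100)
})

test_that("binomial AF sampling is unbiased at depth 500", {
  set.seed(2)
  reps <- replicate(10000, {
    af <- sample_observed_af(25, 500)
    af_representative(af)
  })
  # se of the mean = 100 * sqrt(.25*.75/500) / sqrt(10000) ~ 0.019;
  # 0.6 is a 3-sigma band on the spec'd scale
  expect_lt(abs(mean(reps) - 25), 0.6)
})

test_that("interval estimates exercise the copy-number path", {
  set.seed(3)
  af <- sample_observed_af(20, 500, as_interval = TRUE, halfwidth = 2.5)
  expect_identical(af$status, "QUANTIFIED")
  expect_null(af$value)
  expect_equal(af$interval_high - af$interval_low, 5)
})

test_that("cohort generation is deterministic given the seed", {
  a <- generate_cohort(sim_config(n_patients = 40, seed = 123))
  b <- generate_cohort(sim_config(n_patients = 40, seed = 123))
  expect_equal(a, b)
  c2 <- generate_cohort(sim_config(n_patients = 40, seed = 124))
  expect_false(identical(a, c2))
})

test_that("truth invariants hold for every generated patient", {
  g <- generate_cohort(sim_config(n_patients = 300, seed = 42))
  for (tr in g$truths) {
    afs <- tr$true_af_by_tissue
    if (tr$etiology == "GERMLINE")
      expect_true(all(afs == 50))
    if (tr$etiology %in% c("CH", "HEME_MALIGNANCY")) {
      high <- intersect(names(afs),
                        c("CULTURED_FIBROBLAST", "MUSCLE", "BUCCAL"))
      expect_true(all(afs[high] == 0))
      if ("DIRECT_SKIN" %in% names(afs))
        expect_equal(afs[["DIRECT_SKIN"]],
                     tr$contamination_used * afs[["PBL"]])
    }
    if (tr$etiology == "MOSAIC")
      expect_true(all(afs == afs[["PBL"]]))
  }
})

test_that("single-etiology weights produce a pure cohort", {
  cfg <- sim_config(n_patients = 30,
                    etiology_weights = c(GERMLINE = 1, MOSAIC = 0, CH = 0,
                                         HEME_MALIGNANCY = 0, CONTROL = 0),
                    seed = 5)
  g <- generate_cohort(cfg)
  expect_true(all(vapply(g$truths, `[[`, "", "etiology") == "GERMLINE"))
})

test_that("control patients are screened out by construction", {
  cfg <- sim_config(n_patients = 60,
                    etiology_weights = c(GERMLINE = 0, MOSAIC = 0, CH = 0,
                                         HEME_MALIGNANCY = 0, CONTROL = 1),
                    seed = 8)
  g <- generate_cohort(cfg)
  inc <- screen_cohort(g$patients)
  expect_false(any(vapply(inc, `[[`, TRUE, "included")))
})

test_that("the recovery matrix conserves marginals and ignores order", {
  g <- generate_cohort(sim_config(n_patients = 120, seed = 21))
  cc <- classify_cohort(g$patients)
  m <- evaluate_recovery(cc, g$truths)
  expect_identical(sum(m), 120L)
  truth_tab <- table(vapply(g$truths, `[[`, "", "etiology"))
  for (e in names(truth_tab))
    expect_identical(sum(m[e, ]), as.integer(truth_tab[[e]]))

  shuffled <- cc[sample(seq_along(cc))]
  attr(shuffled, "excluded") <- attr(cc, "excluded")
  attr(shuffled, "errors") <- attr(cc, "errors")
  expect_identical(evaluate_recovery(shuffled, g$truths), m)

  expect_error(evaluate_recovery(cc, g$truths[-1]), "differ")
})

test_that("a perfect assignment scores a clean diagonal", {
  # hand-built conclusions for ten germline truths
  truths <- lapply(1:10, function(i)
    structure(list(patient_id = paste0("G", i), etiology = "GERMLINE",
                   true_af_by_tissue = c(PBL = 50), contamination_used = 0),
              class = "synthetic_truth"))
  cons <- lapply(1:10, function(i)
    structure(list(patient_id = paste0("G", i),
                   primary_label = "FULL_GERMLINE"),
              class = "patient_conclusion"))
  attr(cons, "excluded") <- character()
  m <- evaluate_recovery(cons, truths)
  expect_identical(m["GERMLINE", "germline"], 10L)
  expect_identical(sum(m), 10L)
  expect_equal(recovery_accuracy(m), 1)
})
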