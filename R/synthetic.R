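#' @title Synthetic cohorts with known etiology
#' @description Generates patient records whose variant etiologies are known
#'   (germline, mosaic, clonal hematopoiesis, hematologic malignancy, or
#'   screen-negative controls) with binomial sequencing noise at a
#'   configurable read depth, so the screen, evidence and classifier stages
#'   can be validated against truth.
#' @name synthetic_cohort
NULL

ETIOLOGIES <- c("GERMLINE", "MOSAIC", "CH", "HEME_MALIGNANCY", "CONTROL")
RECOVERY_FAMILIES <- c("germline", "mosaic", "blood_restricted",
                       "malignancy", "excluded", "unresolved")

#' Simulation configuration
#'
#' Mosaic and CH clone sizes are specified as CELL fractions (percent of
#' cells carrying the heterozygous-in-clone variant); the expected allele
#' fraction is half the cell fraction. Etiology weights default to the
#' reference cohort's proportions with a 20% screened-out control margin.
#' Secondary tissues are sampled independently per tissue; cultured
#' fibroblasts get the highest probability since they are the workflow's
#' preferred confirmatory tissue.
#'
#' @param n_patients Cohort size.
#' @param etiology_weights Named non-negative weights over
#'   `r paste(ETIOLOGIES, collapse = ", ")`.
#' @param depth Reads per site (panel coverage), default 500.
#' @param n_pbl_draws Range (min, max) of blood draws per patient.
#' @param mosaic_cell_fraction Range of mosaic cell fractions, percent.
#' @param ch_cell_fraction Range of CH clone cell fractions, percent.
#' @param heme_af Range of blood AFs for malignancy-driven clones, percent.
#' @param skin_contamination Range of the blood-contamination coefficient of
#'   direct skin biopsies (skin AF = coefficient x blood AF) for
#'   blood-restricted etiologies.
#' @param tumour_admixture Range of the leukocyte-admixture coefficient for
#'   tumour tissue of blood-restricted etiologies (0 = tumour clean).
#' @param pbl_drift Range of the per-draw multiplicative drift of
#'   blood-restricted clone sizes across timepoints.
#' @param p_secondary Named per-tissue sampling probabilities.
#' @param p_chemo Named per-etiology chemotherapy probabilities.
#' @param p_whole_gene_del Probability a CH variant is a whole-gene deletion
#'   reported as an interval AF estimate.
#' @param del_halfwidth Half-width (percent) of interval AF estimates.
#' @param wbc_normal Mean and sd of the normal white-cell count, x10^9/L.
#' @param wbc_heme Meanlog and sdlog of the (log-normal) white-cell count
#'   under hematologic malignancy.
#' @param gene_weights Named gene mix for CH/mosaic arms; germline and
#'   malignancy arms always draw TP53, the gene whose incidental findings
#'   the family-history gate admits.
#' @param seed Integer seed; [generate_cohort()] is reproducible given it.
#' @export
sim_config <- function(
    n_patients = 100,
    etiology_weights = c(GERMLINE = 0.04, MOSAIC = 0.10, CH = 0.58,
                         HEME_MALIGNANCY = 0.08, CONTROL = 0.20),
    depth = 500,
    n_pbl_draws = c(1, 3),
    mosaic_cell_fraction = c(5, 30),
    ch_cell_fraction = c(4, 50),
    heme_af = c(30, 85),
    skin_contamination = c(0, 0.5),
    tumour_admixture = c(0, 0),
    pbl_drift = c(0.7, 1.3),
    p_secondary = c(DIRECT_SKIN = 0.5, CULTURED_FIBROBLAST = 0.7,
                    TUMOUR = 0.15, MUSCLE = 0.05, BUCCAL = 0.05),
    p_chemo = c(GERMLINE = 0.3, MOSAIC = 0.3, CH = 0.75,
                HEME_MALIGNANCY = 0.6, CONTROL = 0.3),
    p_whole_gene_del = 0.1,
    del_halfwidth = 2.5,
    wbc_normal = c(mean = 7, sd = 1.5),
    wbc_heme = c(meanlog = log(30), sdlog = 0.4),
    gene_weights = c(TP53 = 0.70, ATM = 0.12, CHEK2 = 0.08,
                     BRCA1 = 0.08, APC = 0.02),
    seed = NULL) {
  stopifnot(setequal(names(etiology_weights), ETIOLOGIES),
            all(etiology_weights >= 0), sum(etiology_weights) > 0,
            depth >= 1,
            n_pbl_draws[1] >= 1, n_pbl_draws[1] <= n_pbl_draws[2],
            mosaic_cell_fraction[1] <= mosaic_cell_fraction[2],
            ch_cell_fraction[1] <= ch_cell_fraction[2],
            skin_contamination[1] <= skin_contamination[2],
            all(p_secondary >= 0 & p_secondary <= 1))
  structure(as.list(environment()), class = "sim_config")
}

#' Draw an observed allele fraction under binomial sequencing noise
#'
#' Alt-read count is Binomial(depth, true_af/100); zero alt reads yield an
#' explicit ABSENT observation. Uses the session RNG; seed upstream.
#'
#' @param true_af True allele fraction, percent.
#' @param depth Reads at the site.
#' @param as_interval If TRUE, report an interval estimate (copy-number
#'   style) of the given half-width instead of a point value.
#' @param halfwidth Interval half-width, percent.
#' @return An [allele_fraction()].
#' @export
sample_observed_af <- function(true_af, depth, as_interval = FALSE,
                               halfwidth = 2.5) {
  stopifnot(true_af >= 0, true_af <= 100, depth >= 1)
  alt <- stats::rbinom(1L, size = as.integer(depth), prob = true_af / 100)
  if (alt == 0L) return(af_absent())
  obs <- 100 * alt / depth
  if (as_interval)
    allele_fraction("QUANTIFIED",
                    interval_low = max(0, obs - halfwidth),
                    interval_high = min(100, obs + halfwidth))
  else af_q(obs)
}

runif1 <- function(range) stats::runif(1L, range[1], range[2])

# non-LFS-spectrum labels (and late onsets) so generated TP53 carriers are
# never Chompret-positive by construction
NONLFS_CANCERS <- c("Serous Ovarian", "Colon", "Prostate", "Lung",
                    "Melanoma", "Stomach", "Kidney", "Pancreas")
VARIANT_TEMPLATES <- list(
  TP53 = list(cdna = "c.743G>A", protein = "p.(Arg248Gln)"),
  ATM = list(cdna = "c.7736_7737insC", protein = "p.(Arg2579Serfs*7)"),
  CHEK2 = list(cdna = "c.1111C>T", protein = "p.(His371Tyr)"),
  BRCA1 = list(cdna = "c.5503C>T", protein = "p.(Arg1835*)"),
  APC = list(cdna = "c.1383_1390del", protein = "p.(His462*)"))

sample_gene <- function(config) {
  sample(names(config$gene_weights), 1L, prob = config$gene_weights)
}

random_history <- function(test_age) {
  n_dx <- sample(0:2, 1L)
  dx <- lapply(seq_len(n_dx), function(i)
    cancer_diagnosis(sample(NONLFS_CANCERS, 1L),
                     age_at_dx = sample(46:max(46, test_age), 1L)))
  n_fam <- sample(0:5, 1L)
  fam <- lapply(seq_len(n_fam), function(i)
    family_member(sample(c("FIRST", "SECOND"), 1L),
                  list(cancer_diagnosis(sample(NONLFS_CANCERS, 1L)))))
  list(diagnoses = dx, family = fam)
}

#' Generate one synthetic patient with known truth
#'
#' @param patient_id Identifier for the record.
#' @param etiology One of `r paste(ETIOLOGIES, collapse = ", ")`.
#' @param config A [sim_config()].
#' @return List with elements `patient` (a [patient_record()]) and `truth`
#'   (class `synthetic_truth`: `patient_id`, `etiology`,
#'   `true_af_by_tissue`, `contamination_used`).
#' @export
generate_patient <- function(patient_id, etiology, config = sim_config()) {
  etiology <- match.arg(etiology, ETIOLOGIES)
  test_age <- sample(45:85, 1L)
  hist <- random_history(test_age)
  chemo <- if (stats::runif(1) < config$p_chemo[[etiology]]) "YES" else "NO"
  heme_dx <- NULL
  wbc <- if (etiology == "HEME_MALIGNANCY") {
    heme_dx <- sample(c("Chronic Lymphocytic Leukemia", "Multiple Myeloma",
                        "Acute Myeloid Leukemia"), 1L)
    stats::rlnorm(1, config$wbc_heme[["meanlog"]], config$wbc_heme[["sdlog"]])
  } else {
    max(2, stats::rnorm(1, config$wbc_normal[["mean"]],
                        config$wbc_normal[["sd"]]))
  }

  contamination <- runif1(config$skin_contamination)
  blood_restricted <- etiology %in% c("CH", "HEME_MALIGNANCY")
  gene <- switch(etiology,
    GERMLINE = "TP53", HEME_MALIGNANCY = "TP53",
    CONTROL = "TP53", sample_gene(config))
  tmpl <- VARIANT_TEMPLATES[[gene]]

  base_af <- switch(etiology,
    GERMLINE = 50,
    MOSAIC = runif1(config$mosaic_cell_fraction) / 2,
    CH = runif1(config$ch_cell_fraction) / 2,
    HEME_MALIGNANCY = runif1(config$heme_af),
    CONTROL = 50)
  true_af <- c(PBL = base_af)
  sampled <- names(config$p_secondary)[
    stats::runif(length(config$p_secondary)) < config$p_secondary]
  for (t in sampled) {
    true_af[[t]] <- if (!blood_restricted) base_af
      else if (t == "DIRECT_SKIN") contamination * base_af
      else if (t == "TUMOUR") runif1(config$tumour_admixture) * base_af
      else 0
  }

  is_del <- etiology == "CH" && stats::runif(1) < config$p_whole_gene_del
  variant <- variant_call(
    key = paste0(gene, "_1"), gene = gene,
    cdna = if (is_del) "c.(?_-21)_(*21_?)del" else tmpl$cdna,
    protein = if (is_del) NULL else tmpl$protein,
    kind = if (is_del) "WHOLE_GENE_DELETION" else "SNV",
    pathogenicity = if (etiology == "CONTROL" &&
                        stats::runif(1) < 0.5) "VUS" else "PATHOGENIC")

  # control arm: pathogenic variants get a Chompret-positive history
  # (early-onset breast) so the family-history gate closes; VUS controls
  # keep the random history
  if (etiology == "CONTROL" && variant$pathogenicity == "PATHOGENIC") {
    hist$diagnoses <- c(hist$diagnoses,
                        list(cancer_diagnosis("Breast", age_at_dx = 28)))
  }

  n_draws <- sample(seq(config$n_pbl_draws[1], config$n_pbl_draws[2]), 1L)
  obs <- list()
  for (d in seq_len(n_draws)) {
    af_d <- if (blood_restricted)
      min(100, base_af * runif1(config$pbl_drift)) else base_af
    obs[[length(obs) + 1L]] <- tissue_observation(
      variant$key, "PBL",
      sample_observed_af(af_d, config$depth, as_interval = is_del,
                         halfwidth = config$del_halfwidth),
      age_at_sample = test_age + d - 1L)
  }
  for (t in sampled) {
    obs[[length(obs) + 1L]] <- tissue_observation(
      variant$key, t,
      sample_observed_af(true_af[[t]], config$depth, as_interval = is_del,
                         halfwidth = config$del_halfwidth),
      age_at_sample = test_age)
  }

  patient <- patient_record(
    patient_id = patient_id,
    sex = sample(c("F", "M"), 1L),
    diagnoses = hist$diagnoses, family = hist$family,
    clinical = clinical_context(chemo_history = chemo, wbc = wbc,
                                heme_malignancy_dx = heme_dx),
    variants = list(variant), observations = obs)
  truth <- structure(list(patient_id = patient_id, etiology = etiology,
                          true_af_by_tissue = true_af,
                          contamination_used =
                            if (blood_restricted) contamination else 0),
                     class = "synthetic_truth")
  list(patient = patient, truth = truth)
}

#' Generate a synthetic cohort
#'
#' Etiologies are multinomial with the configured weights; fully
#' reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `patients` and `truths`, parallel by position.
#' @export
generate_cohort <- function(config = sim_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  w <- config$etiology_weights[ETIOLOGIES]
  etis <- sample(ETIOLOGIES, config$n_patients, replace = TRUE,
                 prob = w / sum(w))
  ids <- sprintf("S%04d", seq_len(config$n_patients))
  gen <- lapply(seq_len(config$n_patients), function(i)
    generate_patient(ids[i], etis[i], config))
  list(patients = lapply(gen, `[[`, "patient"),
       truths = lapply(gen, `[[`, "truth"))
}

#' Score classifier recovery against simulation truth
#'
#' Confusion matrix of true etiology against assigned label family.
#' Patients screened out are assigned `"excluded"`; truth `CONTROL` expects
#' exactly that. Order of the conclusions list does not matter.
#'
#' @param conclusions Result of [classify_cohort()] on the generated cohort
#'   (its `excluded` attribute is used).
#' @param truths The `truths` element of [generate_cohort()].
#' @return Integer matrix, rows = etiologies, columns =
#'   `r paste(RECOVERY_FAMILIES, collapse = ", ")`, marginals conserved.
#' @export
evaluate_recovery <- function(conclusions, truths) {
  truth_ids <- vapply(truths, `[[`, "", "patient_id")
  assigned <- c(
    stats::setNames(vapply(conclusions, function(pc)
      label_family(pc$primary_label), ""),
      vapply(conclusions, `[[`, "", "patient_id")),
    stats::setNames(rep("excluded", length(attr(conclusions, "excluded"))),
                    attr(conclusions, "excluded")))
  err_ids <- names(attr(conclusions, "errors"))
  if (length(err_ids))
    assigned[err_ids] <- "unresolved"
  if (!setequal(names(assigned), truth_ids))
    stop("conclusion and truth id sets differ")
  mat <- matrix(0L, nrow = length(ETIOLOGIES),
                ncol = length(RECOVERY_FAMILIES),
                dimnames = list(ETIOLOGIES, RECOVERY_FAMILIES))
  for (i in seq_along(truths)) {
    mat[truths[[i]]$etiology, assigned[[truth_ids[i]]]] <-
      mat[truths[[i]]$etiology, assigned[[truth_ids[i]]]] + 1L
  }
  mat
}

#' Label-family accuracy from a recovery confusion matrix
#'
#' @param confusion Matrix from [evaluate_recovery()].
#' @param etiologies Which truth rows to score (default all).
#' @return Fraction of patients assigned their expected label family.
#' @export
recovery_accuracy <- function(confusion, etiologies = ETIOLOGIES) {
  expected <- c(GERMLINE = "germline", MOSAIC = "mosaic",
                CH = "blood_restricted", HEME_MALIGNANCY = "malignancy",
                CONTROL = "excluded")
  rows <- confusion[etiologies, , drop = FALSE]
  hits <- sum(vapply(etiologies, function(e)
    confusion[e, expected[[e]]], 0L))
  total <- sum(rows)
  if (total == 0) return(NA_real_)
  hits / total
}
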