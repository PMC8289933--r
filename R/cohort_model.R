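#' @title Patient-record domain model
#' @description Constructors and validation for the records the triage
#'   workflow consumes: pathogenic variant calls from a hereditary-cancer
#'   panel, per-tissue allele-fraction observations, cancer and family
#'   history, and the clinical context used for chart review.
#' @name cohort_model
NULL

TISSUES <- c("PBL", "DIRECT_SKIN", "CULTURED_FIBROBLAST", "TUMOUR",
             "MUSCLE", "BUCCAL", "OTHER_NORMAL")
VARIANT_KINDS <- c("SNV", "INDEL", "SPLICE_SITE", "EXON_DELETION",
                   "WHOLE_GENE_DELETION")
PATHOGENICITIES <- c("PATHOGENIC", "LIKELY_PATHOGENIC", "VUS",
                     "LIKELY_BENIGN", "BENIGN")

#' Variant call
#'
#' @param key Identifier unique within the patient (e.g. `"TP53_1"`).
#' @param gene HGNC symbol.
#' @param cdna HGVS c. description as reported.
#' @param protein HGVS p. description; copy-number events may lack one.
#' @param kind One of `r paste(VARIANT_KINDS, collapse = ", ")`.
#' @param pathogenicity ACMG class (classification is an input, not computed).
#' @export
variant_call <- function(key, gene, cdna, protein = NULL,
                         kind = "SNV", pathogenicity = "PATHOGENIC") {
  kind <- match.arg(kind, VARIANT_KINDS)
  pathogenicity <- match.arg(pathogenicity, PATHOGENICITIES)
  if (!nzchar(gene)) stop("variant gene must be non-empty")
  if (!nzchar(cdna)) stop("variant cdna must be non-empty")
  if (!nzchar(key)) stop("variant key must be non-empty")
  structure(list(key = key, gene = gene, cdna = cdna, protein = protein,
                 kind = kind, pathogenicity = pathogenicity),
            class = "variant_call")
}

#' Tissue observation
#'
#' One allele-fraction measurement of one variant in one tissue at one age.
#'
#' @param variant_key Key of a [variant_call()] declared on the same patient.
#' @param tissue One of `r paste(TISSUES, collapse = ", ")`.
#' @param af An [allele_fraction()].
#' @param age_at_sample Age in years at sampling, optional.
#' @param note Free text (tumour site, laboratory remark), optional.
#' @export
tissue_observation <- function(variant_key, tissue, af,
                               age_at_sample = NULL, note = NULL) {
  tissue <- match.arg(tissue, TISSUES)
  stopifnot(inherits(af, "allele_fraction"))
  if (!is.null(age_at_sample)) {
    stopifnot(is.numeric(age_at_sample))
    if (age_at_sample < 0 || age_at_sample > 120)
      stop("age_at_sample out of range: ", age_at_sample)
  }
  structure(list(variant_key = variant_key, tissue = tissue, af = af,
                 age_at_sample = age_at_sample, note = note),
            class = "tissue_observation")
}

#' Cancer diagnosis
#' @param label Site/histology free text, non-empty.
#' @param age_at_dx Age at diagnosis in years, optional (never imputed).
#' @export
cancer_diagnosis <- function(label, age_at_dx = NULL) {
  if (!nzchar(label)) stop("diagnosis label must be non-empty")
  if (!is.null(age_at_dx)) {
    stopifnot(is.numeric(age_at_dx))
    if (age_at_dx < 0 || age_at_dx > 120)
      stop("age_at_dx out of range: ", age_at_dx)
  }
  structure(list(label = label, age_at_dx = age_at_dx),
            class = "cancer_diagnosis")
}

#' Family member with cancer history
#' @param degree `"FIRST"` or `"SECOND"` degree relative.
#' @param diagnoses List of [cancer_diagnosis()]; at least one.
#' @export
family_member <- function(degree, diagnoses) {
  degree <- match.arg(degree, c("FIRST", "SECOND"))
  if (length(diagnoses) < 1L) stop("family member needs at least one diagnosis")
  stopifnot(all(vapply(diagnoses, inherits, TRUE, "cancer_diagnosis")))
  structure(list(degree = degree, diagnoses = diagnoses),
            class = "family_member")
}

#' Clinical context from chart review
#'
#' @param chemo_history `"YES"`, `"NO"` or `"UNKNOWN"` systemic chemotherapy.
#' @param wbc White-blood-cell count, x10^9/L, optional.
#' @param heme_malignancy_dx Chart-review hematologic-malignancy diagnosis
#'   (e.g. chronic lymphocytic leukemia), optional. This field, not the cancer
#'   history list, is what the classifier treats as a malignancy diagnosis.
#' @param deceased Logical.
#' @export
clinical_context <- function(chemo_history = "UNKNOWN", wbc = NULL,
                             heme_malignancy_dx = NULL, deceased = FALSE) {
  chemo_history <- match.arg(chemo_history, c("YES", "NO", "UNKNOWN"))
  if (!is.null(wbc)) {
    stopifnot(is.numeric(wbc))
    if (wbc <= 0) stop("wbc must be positive when present")
  }
  stopifnot(is.logical(deceased), length(deceased) == 1L)
  structure(list(chemo_history = chemo_history, wbc = wbc,
                 heme_malignancy_dx = heme_malignancy_dx,
                 deceased = deceased),
            class = "clinical_context")
}

#' Patient record
#'
#' One proband: demographics, cancer and family history, clinical context,
#' declared variants and their per-tissue allele-fraction observations.
#' Every variant must carry at least one PBL observation (an explicit ABSENT
#' observation records that blood was sequenced and the variant not seen,
#' the pattern of skin-limited somatic findings).
#'
#' @param patient_id Unique identifier within a cohort.
#' @param sex `"F"`, `"M"` or `"U"`.
#' @param ethnicity Optional free text.
#' @param diagnoses List of [cancer_diagnosis()].
#' @param family List of [family_member()].
#' @param clinical A [clinical_context()].
#' @param variants List of [variant_call()] with unique keys.
#' @param observations List of [tissue_observation()]; keys must resolve.
#' @export
patient_record <- function(patient_id, sex = "U", ethnicity = NULL,
                           diagnoses = list(), family = list(),
                           clinical = clinical_context(),
                           variants = list(), observations = list()) {
  sex <- match.arg(sex, c("F", "M", "U"))
  if (!nzchar(patient_id)) stop("patient_id must be non-empty")
  stopifnot(all(vapply(diagnoses, inherits, TRUE, "cancer_diagnosis")),
            all(vapply(family, inherits, TRUE, "family_member")),
            inherits(clinical, "clinical_context"),
            all(vapply(variants, inherits, TRUE, "variant_call")),
            all(vapply(observations, inherits, TRUE, "tissue_observation")))
  keys <- vapply(variants, `[[`, "", "key")
  if (anyDuplicated(keys))
    stop("patient ", patient_id, ": duplicate variant keys")
  obs_keys <- vapply(observations, `[[`, "", "variant_key")
  bad <- setdiff(obs_keys, keys)
  if (length(bad))
    stop("patient ", patient_id,
         ": observation references undeclared variant: ",
         paste(bad, collapse = ", "))
  for (k in keys) {
    tiss <- vapply(observations[obs_keys == k], `[[`, "", "tissue")
    if (!"PBL" %in% tiss)
      stop("patient ", patient_id, ": variant ", k,
           " has no PBL observation")
  }
  structure(list(patient_id = patient_id, sex = sex, ethnicity = ethnicity,
                 diagnoses = diagnoses, family = family, clinical = clinical,
                 variants = variants, observations = observations),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record> %s: %d variant(s), %d observation(s)\n",
              x$patient_id, length(x$variants), length(x$observations)))
  invisible(x)
}

# observations of one variant, optionally one tissue
obs_for <- function(patient, variant_key, tissue = NULL) {
  sel <- vapply(patient$observations, function(o) {
    o$variant_key == variant_key && (is.null(tissue) || o$tissue == tissue)
  }, TRUE)
  patient$observations[sel]
}

variant_by_key <- function(patient, variant_key) {
  for (v in patient$variants) if (v$key == variant_key) return(v)
  stop("patient ", patient$patient_id, ": unknown variant_key ", variant_key)
}

is_plp <- function(variant) {
  variant$pathogenicity %in% c("PATHOGENIC", "LIKELY_PATHOGENIC")
}

# quantified representative PBL AFs of a variant, in input order
pbl_reps <- function(patient, variant_key) {
  obs <- obs_for(patient, variant_key, "PBL")
  reps <- vapply(obs, function(o) af_representative(o$af), 0)
  reps[!is.na(reps)]
}

# maximum quantified PBL AF, 0 if none
pbl_max_af <- function(patient, variant_key) {
  r <- pbl_reps(patient, variant_key)
  if (length(r)) max(r) else 0
}

# TRUE if any PBL draw detected the variant (quantified or unquantified)
pbl_detected <- function(patient, variant_key) {
  obs <- obs_for(patient, variant_key, "PBL")
  any(vapply(obs, function(o) o$af$status != "ABSENT", TRUE))
}

#' Threshold configuration for the triage workflow
#'
#' All allele-fraction thresholds are percentages. Defaults encode the
#' laboratory's empirical heterozygous band (30-70%) and the operating
#' definitions used to reproduce the reference cohort's assignments.
#'
#' @param het_low,het_high Heterozygous band bounds; fractions in
#'   \[`het_low`, `het_high`\] are called heterozygous.
#' @param category2_lower,category2_upper Low-AF screening band
#'   \[lower, upper). The lower default (1) is the assay noise floor rather
#'   than the nominal 10, and the upper default (28) treats fractions within
#'   two points of the heterozygous floor as borderline-het rather than low;
#'   set `c(10, 30)` for the strict nominal band.
#' @param detection_floor Below this a quantified AF is treated as absent.
#' @param trace_ceiling Below this a detected AF is a trace-level call.
#' @param contamination_ratio A direct-skin AF at or below this fraction of
#'   the patient's maximum blood AF is flagged as likely blood contamination.
#' @param wbc_normal_low,wbc_normal_high Normal white-cell band, x10^9/L.
#' @param tumour_germline_min Tumour AF below this counts against a germline
#'   interpretation (an expected germline allele should not vanish in tumour).
#' @param borderline_het_max Heterozygous-band AFs strictly below this value
#'   are "borderline het": eligible for the co-occurring-variant
#'   contradiction (rule D3). Default 50, the canonical germline expectation.
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(het_low = 30, het_high = 70,
                             category2_lower = 1, category2_upper = 28,
                             detection_floor = 1, trace_ceiling = 10,
                             contamination_ratio = 0.5,
                             wbc_normal_low = 4, wbc_normal_high = 11,
                             tumour_germline_min = 30,
                             borderline_het_max = 50) {
  stopifnot(detection_floor > 0,
            detection_floor <= trace_ceiling,
            trace_ceiling < het_low,
            het_low < het_high,
            het_high <= 100,
            category2_lower < category2_upper,
            wbc_normal_low < wbc_normal_high,
            contamination_ratio > 0, contamination_ratio <= 1)
  structure(list(het_low = het_low, het_high = het_high,
                 category2_lower = category2_lower,
                 category2_upper = category2_upper,
                 detection_floor = detection_floor,
                 trace_ceiling = trace_ceiling,
                 contamination_ratio = contamination_ratio,
                 wbc_normal_low = wbc_normal_low,
                 wbc_normal_high = wbc_normal_high,
                 tumour_germline_min = tumour_germline_min,
                 borderline_het_max = borderline_het_max),
            class = "threshold_config")
}
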