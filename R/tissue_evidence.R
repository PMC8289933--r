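#' @title Tissue evidence
#' @description Grades raw per-tissue allele fractions into presence calls,
#'   flags blood contamination of direct skin biopsies, and assembles the
#'   per-variant evidence the classifier consumes.
#' @name tissue_evidence
NULL

PRESENCE_LEVELS <- c("ABSENT", "TRACE", "PRESENT_SUBHET", "PRESENT_HET",
                     "PRESENT_HIGH")

#' Tissue reliability grades
#'
#' Cultured fibroblasts, muscle and buccal swabs are leukocyte-poor germline
#' surrogates (HIGH); tumour tissue is informative but admixture-prone
#' (MEDIUM); unprocessed direct skin biopsies carry blood and are LOW.
#' Buccal swabs are graded HIGH but their presence-call basis notes the
#' leukocyte-admixture caveat.
#' @export
TISSUE_RELIABILITY <- c(PBL = "SOURCE", DIRECT_SKIN = "LOW",
                        CULTURED_FIBROBLAST = "HIGH", TUMOUR = "MEDIUM",
                        MUSCLE = "HIGH", BUCCAL = "HIGH",
                        OTHER_NORMAL = "MEDIUM")

presence_rank <- function(level) match(level, PRESENCE_LEVELS)

#' Grade one observation into a presence call
#'
#' Levels, by representative AF: ABSENT below the detection floor (or an
#' explicit negative), TRACE below the trace ceiling, PRESENT_SUBHET below
#' the heterozygous band, PRESENT_HET within it, PRESENT_HIGH above it.
#' Detected-but-unquantified findings are graded TRACE. A direct-skin TRACE
#' or sub-het call at no more than `contamination_ratio` times the
#' patient's maximum blood AF (or unquantified, when blood is positive) is
#' flagged as suspected blood contamination of the biopsy.
#'
#' @param obs A [tissue_observation()].
#' @param pbl_reference_af Maximum representative PBL AF of the variant
#'   (0 when blood never detected it).
#' @param config A [threshold_config()].
#' @return List of class `presence_call`: `level`,
#'   `contamination_suspected`, `basis`.
#' @export
call_presence <- function(obs, pbl_reference_af, config = threshold_config()) {
  stopifnot(inherits(obs, "tissue_observation"))
  rep <- af_representative(obs$af)
  unquant <- obs$af$status == "PRESENT_UNQUANTIFIED"
  level <- if (obs$af$status == "ABSENT" ||
               (!is.na(rep) && rep < config$detection_floor)) {
    "ABSENT"
  } else if (unquant) {
    "TRACE"
  } else if (rep < config$trace_ceiling) {
    "TRACE"
  } else if (rep < config$het_low) {
    "PRESENT_SUBHET"
  } else if (rep <= config$het_high) {
    "PRESENT_HET"
  } else {
    "PRESENT_HIGH"
  }
  contam <- obs$tissue == "DIRECT_SKIN" &&
    level %in% c("TRACE", "PRESENT_SUBHET") &&
    ((unquant && pbl_reference_af > 0) ||
       (!is.na(rep) && rep <= config$contamination_ratio * pbl_reference_af))
  basis <- sprintf(
    "%s: %s%s vs blood max %.4g%%", obs$tissue,
    if (unquant) "detected, unquantified"
    else if (is.na(rep)) "absent" else sprintf("%.4g%%", rep),
    if (contam) " (within blood-contamination range)" else "",
    pbl_reference_af)
  if (obs$tissue == "BUCCAL")
    basis <- paste0(basis, "; buccal swabs are leukocyte-admixture-prone")
  structure(list(level = level, contamination_suspected = contam,
                 basis = basis),
            class = "presence_call")
}

#' Assemble the cross-tissue evidence for one variant
#'
#' Computes presence calls for every observed tissue (blood included) using
#' the maximum blood AF as the contamination reference, the ordered blood
#' AF series, the blood AF fluctuation (max minus min; reported
#' descriptively, never decisive), the tissue reliability grades, and the
#' patient's skin-limited variants (detected in direct skin but never in
#' blood - surfaced as report annotations only).
#'
#' For tissues measured more than once the call of the highest-AF
#' observation is kept.
#'
#' @param patient A [patient_record()].
#' @param variant_key Key of a declared variant with a PBL observation.
#' @param config A [threshold_config()].
#' @return List of class `tissue_evidence`.
#' @export
summarize_evidence <- function(patient, variant_key,
                               config = threshold_config()) {
  variant <- variant_by_key(patient, variant_key)  # errors on unknown key
  obs <- obs_for(patient, variant_key)
  ref <- pbl_max_af(patient, variant_key)

  calls <- list()
  for (o in obs) {
    pc <- call_presence(o, pbl_reference_af = ref, config = config)
    prev <- calls[[o$tissue]]
    if (is.null(prev) ||
        presence_rank(pc$level) > presence_rank(prev$level))
      calls[[o$tissue]] <- pc
  }

  pbl_obs <- obs_for(patient, variant_key, "PBL")
  ages <- vapply(pbl_obs, function(o)
    if (is.null(o$age_at_sample)) NA_real_ else o$age_at_sample, 0)
  reps <- vapply(pbl_obs, function(o) af_representative(o$af), 0)
  ord <- order(ages, seq_along(pbl_obs), na.last = TRUE)
  series <- data.frame(age = ages[ord], af = reps[ord])
  quant <- reps[!is.na(reps)]
  fluct <- if (length(quant) >= 2L) max(quant) - min(quant) else 0

  skin_only <- Filter(function(v) {
    !pbl_detected(patient, v$key) &&
      any(vapply(obs_for(patient, v$key, "DIRECT_SKIN"),
                 function(o) o$af$status != "ABSENT", TRUE))
  }, patient$variants)

  structure(list(
    variant_key = variant_key,
    calls = calls,
    reliability = TISSUE_RELIABILITY[names(calls)],
    skin_only_variants = skin_only,
    pbl_af_series = series,
    pbl_af_fluctuation = fluct),
    class = "tissue_evidence")
}

# convenience predicates over a tissue_evidence object ----------------------

ev_call_level <- function(evidence, tissue) {
  pc <- evidence$calls[[tissue]]
  if (is.null(pc)) NA_character_ else pc$level
}

# any HIGH-reliability tissue with the given level
ev_high_with_level <- function(evidence, level) {
  high <- names(evidence$calls)[TISSUE_RELIABILITY[names(evidence$calls)] == "HIGH"]
  any(vapply(high, function(t) evidence$calls[[t]]$level == level, TRUE))
}

# non-PBL tissues with a detected (non-ABSENT), non-contamination call
ev_second_tissue_detections <- function(evidence) {
  tiss <- setdiff(names(evidence$calls), "PBL")
  Filter(function(t) {
    pc <- evidence$calls[[t]]
    pc$level != "ABSENT" && !pc$contamination_suspected
  }, tiss)
}

# non-PBL tissues called ABSENT
ev_absent_tissues <- function(evidence) {
  tiss <- setdiff(names(evidence$calls), "PBL")
  Filter(function(t) evidence$calls[[t]]$level == "ABSENT", tiss)
}
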