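#' @title Inclusion screen
#' @description Decides which of the three inclusion categories a patient
#'   fulfils: (1) multiple pathogenic or likely pathogenic variants in blood;
#'   (2) pathogenic variants at low allele fraction; (3) pathogenic TP53
#'   variants in a patient whose history does not fulfil the Chompret
#'   criteria for Li-Fraumeni syndrome.
#' @name inclusion_screen
NULL

# Category 2 per variant: a quantified PBL draw in the low band, an
# unquantified-but-detected PBL finding (source laboratory flagged low), or -
# for a variant never seen in blood - a low-band AF in a secondary tissue
# (a secondary-tissue incidental finding, the skin-limited pattern).
variant_fires_cat2 <- function(patient, variant, config) {
  obs_pbl <- obs_for(patient, variant$key, "PBL")
  in_band <- function(rep) !is.na(rep) &&
    rep >= config$category2_lower && rep < config$category2_upper
  for (o in obs_pbl) {
    if (o$af$status == "PRESENT_UNQUANTIFIED") return(TRUE)
    if (o$af$status == "QUANTIFIED" && in_band(af_representative(o$af)))
      return(TRUE)
  }
  if (!pbl_detected(patient, variant$key)) {
    other <- Filter(function(o) o$tissue != "PBL",
                    obs_for(patient, variant$key))
    for (o in other) {
      if (o$af$status == "QUANTIFIED" && in_band(af_representative(o$af)))
        return(TRUE)
    }
  }
  FALSE
}

variant_fires_cat3 <- function(patient, variant, chompret) {
  variant$gene == "TP53" && is_plp(variant) &&
    pbl_detected(patient, variant$key) && !chompret$met
}

#' Screen one patient against the inclusion categories
#'
#' @param patient A [patient_record()].
#' @param config A [threshold_config()].
#' @param rules A [chompret_rules()].
#' @return List of class `inclusion_result`: `patient_id`, `categories`
#'   (integer subset of 1:3), `chompret` (the [evaluate_chompret()] result)
#'   and `included` (TRUE iff any category holds).
#' @export
screen_patient <- function(patient, config = threshold_config(),
                           rules = chompret_rules()) {
  stopifnot(inherits(patient, "patient_record"),
            inherits(config, "threshold_config"))
  chompret <- evaluate_chompret(patient, rules)
  plp <- Filter(is_plp, patient$variants)
  n_blood <- sum(vapply(plp, function(v)
    pbl_detected(patient, v$key), TRUE))
  cats <- integer()
  if (n_blood >= 2L) cats <- c(cats, 1L)
  if (any(vapply(plp, variant_fires_cat2, TRUE,
                 patient = patient, config = config)))
    cats <- c(cats, 2L)
  if (any(vapply(plp, variant_fires_cat3, TRUE,
                 patient = patient, chompret = chompret)))
    cats <- c(cats, 3L)
  structure(list(patient_id = patient$patient_id, categories = cats,
                 chompret = chompret, included = length(cats) > 0L),
            class = "inclusion_result")
}

#' Screen a cohort
#'
#' Element-wise [screen_patient()], order preserved.
#'
#' @param patients List of [patient_record()] with unique ids.
#' @inheritParams screen_patient
#' @return List of `inclusion_result`, one per patient.
#' @export
screen_cohort <- function(patients, config = threshold_config(),
                          rules = chompret_rules()) {
  check_unique_ids(patients)
  lapply(patients, screen_patient, config = config, rules = rules)
}

#' @export
print.inclusion_result <- function(x, ...) {
  cat(sprintf("<inclusion_result> %s: %s\n", x$patient_id,
              if (x$included)
                paste("categories", paste(x$categories, collapse = ","))
              else "not included"))
  invisible(x)
}

#' Tabulate inclusion results
#' @param inclusions List of results from [screen_cohort()].
#' @return data.frame with one row per patient.
#' @export
inclusion_table <- function(inclusions) {
  do.call(rbind, lapply(inclusions, function(r) data.frame(
    patient_id = r$patient_id,
    included = r$included,
    categories = paste(r$categories, collapse = ","),
    chompret_met = r$chompret$met,
    stringsAsFactors = FALSE)))
}
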