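#' Chompret criteria rule table
#'
#' The Chompret criteria for suspecting Li-Fraumeni syndrome, as a
#' configurable rule table (defaults follow the 2015 revision). The tumour
#' spectrum is a named list of categories, each a vector of lower-case
#' keywords matched against free-text diagnosis labels, so future criterion
#' revisions are data changes, not code changes.
#'
#' @param lfs_spectrum Named list of keyword vectors defining the LFS tumour
#'   spectrum.
#' @param rare_tumours Names of spectrum categories that qualify on their own
#'   regardless of age and family history.
#' @param proband_age_max Proband spectrum tumour must occur before this age
#'   (years) for the familial and multiple-primary criteria.
#' @param relative_age_max Relative's spectrum tumour must occur before this
#'   age for the familial criterion.
#' @param breast_only_age_max Breast cancer before this age qualifies with no
#'   family history.
#' @export
chompret_rules <- function(
    lfs_spectrum = list(
      breast = c("breast", "ductal carcinoma"),
      soft_tissue_sarcoma = c("sarcoma", "rhabdomyosarcoma"),
      osteosarcoma = c("osteosarcoma"),
      cns = c("brain", "cns", "glioma", "medulloblastoma", "astrocytoma"),
      adrenocortical = c("adrenocortical"),
      choroid_plexus = c("choroid plexus"),
      leukemia = c("leukemia", "leukaemia"),
      lung_bronchoalveolar = c("bronchoalveolar")),
    rare_tumours = c("adrenocortical", "choroid_plexus"),
    proband_age_max = 46,
    relative_age_max = 56,
    breast_only_age_max = 31) {
  stopifnot(length(lfs_spectrum) > 0,
            proband_age_max > 0, relative_age_max > 0,
            breast_only_age_max > 0,
            all(rare_tumours %in% names(lfs_spectrum)))
  structure(list(lfs_spectrum = lfs_spectrum, rare_tumours = rare_tumours,
                 proband_age_max = proband_age_max,
                 relative_age_max = relative_age_max,
                 breast_only_age_max = breast_only_age_max),
            class = "chompret_rules")
}

# spectrum category of a diagnosis label, or NA
spectrum_category <- function(label, rules) {
  lab <- tolower(label)
  for (cat in names(rules$lfs_spectrum)) {
    if (any(vapply(rules$lfs_spectrum[[cat]],
                   function(k) grepl(k, lab, fixed = TRUE), TRUE)))
      return(cat)
  }
  NA_character_
}

#' Evaluate the Chompret criteria for a patient
#'
#' Criteria are evaluated strictly from recorded data: a missing age can
#' never satisfy an age-bounded condition (unknown degrades to unmet), so
#' removing information can never flip the result from unmet to met.
#'
#' @param patient A [patient_record()].
#' @param rules A [chompret_rules()].
#' @return List of class `chompret_result` with fields `met` (logical),
#'   `fired_rule` (criterion label, or NULL) and `rationale` (character
#'   vector describing how each criterion was evaluated).
#' @export
evaluate_chompret <- function(patient, rules = chompret_rules()) {
  stopifnot(inherits(patient, "patient_record"),
            inherits(rules, "chompret_rules"))
  rationale <- character()
  fired <- NULL

  dx <- patient$diagnoses
  cats <- vapply(dx, function(d) spectrum_category(d$label, rules), "")
  ages <- vapply(dx, function(d)
    if (is.null(d$age_at_dx)) NA_real_ else d$age_at_dx, 0)
  in_spec <- !is.na(cats)

  # 1. familial presentation: proband spectrum tumour before proband_age_max
  #    AND a first/second-degree relative with a spectrum tumour (breast
  #    excluded when the proband's qualifying tumour is breast) before
  #    relative_age_max.
  proband_ok <- in_spec & !is.na(ages) & ages < rules$proband_age_max
  if (any(proband_ok)) {
    proband_cats <- cats[proband_ok]
    rel_hit <- FALSE
    for (fm in patient$family) {
      for (d in fm$diagnoses) {
        rcat <- spectrum_category(d$label, rules)
        if (is.na(rcat)) next
        if (rcat == "breast" && all(proband_cats == "breast")) next
        if (!is.null(d$age_at_dx) && d$age_at_dx < rules$relative_age_max) {
          rel_hit <- TRUE
          break
        }
      }
      if (rel_hit) break
    }
    if (rel_hit) {
      fired <- "familial_presentation"
      rationale <- c(rationale,
        "familial_presentation: met (early spectrum tumour in proband and a relative)")
    } else {
      rationale <- c(rationale, paste0(
        "familial_presentation: proband spectrum tumour before ",
        rules$proband_age_max,
        " present, but no relative spectrum tumour with a recorded age below ",
        rules$relative_age_max))
    }
  } else {
    rationale <- c(rationale, paste0(
      "familial_presentation: no proband spectrum tumour with recorded age below ",
      rules$proband_age_max))
  }

  # 2. multiple primaries: >=2 spectrum primaries, earliest recorded before
  #    proband_age_max.
  if (is.null(fired)) {
    if (sum(in_spec) >= 2) {
      spec_ages <- ages[in_spec]
      if (any(!is.na(spec_ages)) &&
          min(spec_ages, na.rm = TRUE) < rules$proband_age_max) {
        fired <- "multiple_primaries"
        rationale <- c(rationale,
          "multiple_primaries: met (two spectrum primaries, first early)")
      } else {
        rationale <- c(rationale,
          "multiple_primaries: two spectrum primaries but none recorded before ",
          rules$proband_age_max)
      }
    } else {
      rationale <- c(rationale,
                     "multiple_primaries: fewer than two spectrum primaries")
    }
  }

  # 3. rare tumours qualify regardless of age/family history.
  if (is.null(fired)) {
    if (any(cats %in% rules$rare_tumours)) {
      fired <- "rare_tumour"
      rationale <- c(rationale, "rare_tumour: met")
    } else {
      rationale <- c(rationale, "rare_tumour: none recorded")
    }
  }

  # 4. early-onset breast cancer, irrespective of family history.
  if (is.null(fired)) {
    breast_early <- cats == "breast" & !is.na(ages) &
      ages < rules$breast_only_age_max
    if (any(breast_early, na.rm = TRUE)) {
      fired <- "early_onset_breast"
      rationale <- c(rationale, paste0(
        "early_onset_breast: met (breast cancer before ",
        rules$breast_only_age_max, ")"))
    } else {
      rationale <- c(rationale, paste0(
        "early_onset_breast: no breast cancer recorded before ",
        rules$breast_only_age_max))
    }
  }

  structure(list(met = !is.null(fired), fired_rule = fired,
                 rationale = rationale),
            class = "chompret_result")
}
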