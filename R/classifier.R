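#' @title Etiology classifier
#' @description The per-variant decision cascade and per-patient conclusion:
#'   full germline, likely germline, mosaic, confirmed or likely clonal
#'   hematopoiesis (CH), or hematologic-malignancy-related, each with an
#'   ordered evidence trail of fired rules.
#' @name classifier
NULL

CONCLUSION_LABELS <- c("FULL_GERMLINE", "LIKELY_GERMLINE", "MOSAIC",
                       "CONFIRMED_CH", "LIKELY_CH",
                       "HEME_MALIGNANCY_RELATED", "UNRESOLVED")

# clinical priority when one patient-level label must be chosen among
# triggering variants of different families
LABEL_PRIORITY <- c("HEME_MALIGNANCY_RELATED", "FULL_GERMLINE", "MOSAIC",
                    "CONFIRMED_CH", "LIKELY_CH", "LIKELY_GERMLINE",
                    "UNRESOLVED")

FOLLOW_UPS <- c("HEREDITARY_SURVEILLANCE", "HEMATOLOGY_REFERRAL",
                "CBC_MONITORING", "FAMILY_VARIANT_TESTING",
                "CARDIOVASCULAR_RISK_PROGRAM")

#' Label family of a conclusion label
#'
#' Collapses the seven variant labels into the four etiology families used
#' for cohort summaries and synthetic-recovery scoring.
#'
#' @param label A conclusion label.
#' @return `"germline"`, `"mosaic"`, `"blood_restricted"`, `"malignancy"` or
#'   `"unresolved"`.
#' @export
label_family <- function(label) {
  unname(c(FULL_GERMLINE = "germline", LIKELY_GERMLINE = "germline",
           MOSAIC = "mosaic", CONFIRMED_CH = "blood_restricted",
           LIKELY_CH = "blood_restricted",
           HEME_MALIGNANCY_RELATED = "malignancy",
           UNRESOLVED = "unresolved")[label])
}

# ---- germline-contradiction (D) rules -------------------------------------

d_rules <- function(patient, variant, evidence, config) {
  fired <- list()
  pblmax <- pbl_max_af(patient, variant$key)

  # D1: tumour negative or well below the germline expectation
  tum <- evidence$calls[["TUMOUR"]]
  if (!is.null(tum)) {
    tum_obs <- obs_for(patient, variant$key, "TUMOUR")
    reps <- vapply(tum_obs, function(o) af_representative(o$af), 0)
    reps <- reps[!is.na(reps)]
    if (tum$level == "ABSENT" ||
        (length(reps) && max(reps) < config$tumour_germline_min))
      fired$D1 <- sprintf(
        "tumour AF below the germline expectation (%s; < %g%%)",
        tum$level, config$tumour_germline_min)
  }

  # D2: two or more pathogenic variants of the same gene detected in blood
  same_gene <- Filter(function(v) {
    v$gene == variant$gene && is_plp(v) && pbl_detected(patient, v$key)
  }, patient$variants)
  if (length(same_gene) >= 2L)
    fired$D2 <- sprintf("%d pathogenic %s variants detected in blood",
                        length(same_gene), variant$gene)

  # D3: a borderline-het variant co-occurring with a low-AF pathogenic
  # variant in another gene (joint clonal signature)
  if (pblmax < config$borderline_het_max) {
    other_low <- Filter(function(v) {
      v$key != variant$key && v$gene != variant$gene && is_plp(v) &&
        pbl_detected(patient, v$key) &&
        pbl_max_af(patient, v$key) <= config$het_low
    }, patient$variants)
    if (length(other_low))
      fired$D3 <- sprintf(
        "co-occurring low-AF pathogenic variant in %s",
        paste(vapply(other_low, `[[`, "", "gene"), collapse = "/"))
  }

  # D4: blood AF above the heterozygous band (LOH / clonal expansion)
  if (pblmax > config$het_high)
    fired$D4 <- sprintf("blood AF %.4g%% above the heterozygous band", pblmax)

  fired
}

#' Classify one variant
#'
#' Deterministic first-match rule cascade over the tissue evidence:
#' \describe{
#'   \item{G1}{Blood AF in the heterozygous band and a heterozygous call in
#'     a high-reliability tissue: FULL_GERMLINE.}
#'   \item{G2}{Blood AF in the heterozygous band, no high-reliability tissue
#'     sampled, nothing contradicting germline (no D rule, no absent
#'     secondary tissue, no chart hematologic malignancy): LIKELY_GERMLINE.}
#'   \item{M1}{Blood-detected variant below the heterozygous band also
#'     detected in a second tissue without contamination suspicion, and no
#'     high-reliability tissue negative: MOSAIC.}
#'   \item{C1}{Blood-detected variant with a chart hematologic-malignancy
#'     diagnosis (the chart dominates): HEME_MALIGNANCY_RELATED.}
#'   \item{C2}{Blood-restricted evidence - a high-reliability tissue absent,
#'     or direct skin absent corroborated by a second absent tissue:
#'     CONFIRMED_CH.}
#'   \item{C3}{Sub-heterozygous blood-restricted pattern with no informative
#'     secondary tissue (none sampled, low-reliability only, or only
#'     contamination-range skin positivity): LIKELY_CH.}
#'   \item{C4}{Heterozygous-or-higher blood AF with germline contradictions
#'     (D rules) and no germline confirmation: LIKELY_CH.}
#' }
#' Variants detected only in skin (never in blood) are not pushed through
#' the cascade: they are skin-limited somatic findings, returned UNRESOLVED
#' with an annotation, and never influence other variants.
#'
#' The white-cell count only ever sets `cbc_flag` (and a follow-up); it
#' never changes the label.
#'
#' @param patient A [patient_record()].
#' @param variant_key Key of the variant to classify.
#' @param evidence Optional precomputed [summarize_evidence()] result.
#' @param config A [threshold_config()].
#' @return List of class `variant_conclusion`: `patient_id`, `variant_key`,
#'   `label`, `evidence` (ordered list of rule_id/rationale pairs),
#'   `cbc_flag`.
#' @export
classify_variant <- function(patient, variant_key, evidence = NULL,
                             config = threshold_config()) {
  variant <- variant_by_key(patient, variant_key)
  if (!length(obs_for(patient, variant_key, "PBL")))
    stop("variant ", variant_key, " of patient ", patient$patient_id,
         " has no PBL observation")
  if (is.null(evidence))
    evidence <- summarize_evidence(patient, variant_key, config)

  wbc <- patient$clinical$wbc
  cbc_flag <- !is.null(wbc) &&
    (wbc < config$wbc_normal_low || wbc > config$wbc_normal_high)
  heme <- !is.null(patient$clinical$heme_malignancy_dx)

  trail <- list()
  note <- function(rule_id, rationale)
    trail[[length(trail) + 1L]] <<- list(rule_id = rule_id,
                                         rationale = rationale)
  conclude <- function(label) {
    structure(list(patient_id = patient$patient_id,
                   variant_key = variant_key, label = label,
                   evidence = trail, cbc_flag = cbc_flag),
              class = "variant_conclusion")
  }

  in_blood <- pbl_detected(patient, variant_key)
  if (!in_blood) {
    skin_pos <- any(vapply(obs_for(patient, variant_key, "DIRECT_SKIN"),
                           function(o) o$af$status != "ABSENT", TRUE))
    note("S1", if (skin_pos)
      "detected only in direct skin, never in blood: likely somatic event isolated to the skin; report annotation only"
      else "never detected in blood and no secondary-tissue positivity")
    return(conclude("UNRESOLVED"))
  }

  pblmax <- pbl_max_af(patient, variant_key)
  het_band <- pblmax >= config$het_low && pblmax <= config$het_high
  ds <- d_rules(patient, variant, evidence, config)
  for (id in names(ds)) note(id, ds[[id]])
  if (evidence$pbl_af_fluctuation > 0)
    note("FLX", sprintf(
      "blood AF fluctuation %.4g points across draws (descriptive only)",
      evidence$pbl_af_fluctuation))

  high_sampled <- any(TISSUE_RELIABILITY[setdiff(names(evidence$calls), "PBL")] == "HIGH")
  high_het <- ev_high_with_level(evidence, "PRESENT_HET")
  high_absent <- ev_high_with_level(evidence, "ABSENT")
  absents <- ev_absent_tissues(evidence)
  skin_absent <- "DIRECT_SKIN" %in% absents
  second_detects <- ev_second_tissue_detections(evidence)
  blood_restricted <- high_absent ||
    (skin_absent && length(absents) >= 2L)

  # G1
  if (het_band && high_het) {
    note("G1", sprintf(
      "blood AF %.4g%% heterozygous and confirmed heterozygous in a high-reliability tissue",
      pblmax))
    return(conclude("FULL_GERMLINE"))
  }
  # G2
  if (het_band && !high_sampled && !length(ds) && !length(absents) && !heme) {
    note("G2", sprintf(
      "blood AF %.4g%% heterozygous with no contradicting evidence; no high-reliability tissue available for confirmation",
      pblmax))
    return(conclude("LIKELY_GERMLINE"))
  }
  # M1
  if (pblmax < config$het_low && length(second_detects) && !high_absent) {
    note("M1", sprintf(
      "sub-heterozygous blood AF %.4g%% also detected in %s without contamination suspicion",
      pblmax, paste(second_detects, collapse = "/")))
    return(conclude("MOSAIC"))
  }
  # C1 - chart review dominates
  if (heme) {
    note("C1", sprintf(
      "chart hematologic-malignancy diagnosis (%s)%s",
      patient$clinical$heme_malignancy_dx,
      if (blood_restricted) " with blood-restricted tissue evidence" else ""))
    return(conclude("HEME_MALIGNANCY_RELATED"))
  }
  # C2
  if (blood_restricted) {
    note("C2", sprintf(
      "variant absent from %s: blood-restricted, clonal hematopoiesis confirmed",
      paste(absents, collapse = "/")))
    return(conclude("CONFIRMED_CH"))
  }
  # C3
  if (pblmax < config$het_low && !length(second_detects)) {
    note("C3",
      "sub-heterozygous blood-restricted pattern without informative secondary tissue: likely clonal hematopoiesis")
    return(conclude("LIKELY_CH"))
  }
  # C4
  if (pblmax >= config$het_low && length(ds)) {
    note("C4", sprintf(
      "blood AF %.4g%% with germline contradictions (%s) and no germline confirmation: likely clonal hematopoiesis",
      pblmax, paste(names(ds), collapse = "+")))
    return(conclude("LIKELY_CH"))
  }
  note("U0", "no rule fired")
  conclude("UNRESOLVED")
}

# variants that made the patient eligible: pathogenic, blood-detected, and
# individually firing Category 2 (via blood draws) or 3; when only the
# multiple-variant criterion holds, all blood-detected pathogenic variants.
triggering_keys <- function(patient, inclusion, config, rules) {
  plp <- Filter(function(v) is_plp(v) && pbl_detected(patient, v$key),
                patient$variants)
  direct <- Filter(function(v) {
    variant_fires_cat2(patient, v, config) ||
      variant_fires_cat3(patient, v, inclusion$chompret)
  }, plp)
  if (length(direct)) return(vapply(direct, `[[`, "", "key"))
  if (1L %in% inclusion$categories) return(vapply(plp, `[[`, "", "key"))
  character()
}

#' Conclude a patient from their classified variants
#'
#' The primary label is the conclusion of the variant(s) that triggered
#' inclusion; when several triggering variants fall in the CH family the
#' most confirmed wins, otherwise clinical priority
#' (malignancy > full germline > mosaic > CH > likely germline) decides.
#' Non-triggering variants become co-findings, and a germline-family
#' co-finding (e.g. a coincident heterozygous hit) adds hereditary
#' surveillance and family variant testing to the follow-up set.
#'
#' @param patient A [patient_record()].
#' @param inclusion The patient's [screen_patient()] result; must be included.
#' @param variant_conclusions Named list (by variant key) of
#'   [classify_variant()] results covering all the patient's variants.
#' @param config A [threshold_config()].
#' @param rules A [chompret_rules()].
#' @return List of class `patient_conclusion`.
#' @export
classify_patient <- function(patient, inclusion, variant_conclusions,
                             config = threshold_config(),
                             rules = chompret_rules()) {
  stopifnot(inherits(inclusion, "inclusion_result"))
  if (!inclusion$included)
    stop("patient ", patient$patient_id, " was not included by the screen")
  keys <- vapply(patient$variants, `[[`, "", "key")
  missing <- setdiff(keys, names(variant_conclusions))
  if (length(missing))
    stop("patient ", patient$patient_id, ": unclassified variants: ",
         paste(missing, collapse = ", "))

  trig <- triggering_keys(patient, inclusion, config, rules)
  if (!length(trig))
    stop("patient ", patient$patient_id,
         ": included but no triggering variant could be classified")
  trig_labels <- vapply(trig, function(k)
    variant_conclusions[[k]]$label, "")

  trig_labels <- unname(trig_labels)
  primary <- if (all(trig_labels %in% c("CONFIRMED_CH", "LIKELY_CH"))) {
    if ("CONFIRMED_CH" %in% trig_labels) "CONFIRMED_CH" else "LIKELY_CH"
  } else {
    trig_labels[order(match(trig_labels, LABEL_PRIORITY))][1]
  }

  co_keys <- setdiff(keys, trig)
  co_findings <- variant_conclusions[co_keys]

  follow_up <- switch(label_family(primary),
    germline = c("HEREDITARY_SURVEILLANCE", "FAMILY_VARIANT_TESTING"),
    mosaic = c("HEREDITARY_SURVEILLANCE", "FAMILY_VARIANT_TESTING"),
    blood_restricted = c("CBC_MONITORING", "CARDIOVASCULAR_RISK_PROGRAM"),
    malignancy = "HEMATOLOGY_REFERRAL",
    character())
  for (cf in co_findings) {
    if (cf$label %in% c("FULL_GERMLINE", "LIKELY_GERMLINE", "MOSAIC"))
      follow_up <- c(follow_up,
                     c("HEREDITARY_SURVEILLANCE", "FAMILY_VARIANT_TESTING"))
  }
  cbc_flag <- any(vapply(variant_conclusions[trig], `[[`, TRUE, "cbc_flag"))
  if (cbc_flag) follow_up <- c(follow_up, "CBC_MONITORING")
  follow_up <- intersect(FOLLOW_UPS, unique(follow_up))

  structure(list(patient_id = patient$patient_id,
                 primary_label = primary,
                 triggering_keys = trig,
                 categories = inclusion$categories,
                 variant_conclusions = variant_conclusions,
                 co_findings = co_findings,
                 follow_up = follow_up,
                 cbc_flag = cbc_flag),
            class = "patient_conclusion")
}

#' Run the whole triage workflow over a cohort
#'
#' Screen, tissue evidence, per-variant cascade and per-patient conclusion
#' for every included patient. Excluded patients are omitted with a notice;
#' a failure on one patient does not abort the cohort.
#'
#' @param patients List of [patient_record()].
#' @param config A [threshold_config()].
#' @param rules A [chompret_rules()].
#' @return List of `patient_conclusion` for the included patients, with
#'   attributes `excluded` (patient ids screened out) and `errors` (named
#'   character of per-patient failures, if any).
#' @export
classify_cohort <- function(patients, config = threshold_config(),
                            rules = chompret_rules()) {
  inclusions <- screen_cohort(patients, config, rules)
  out <- list()
  excluded <- character()
  errors <- character()
  for (i in seq_along(patients)) {
    p <- patients[[i]]
    inc <- inclusions[[i]]
    if (!inc$included) {
      excluded <- c(excluded, p$patient_id)
      next
    }
    res <- tryCatch({
      vcs <- list()
      for (v in p$variants)
        vcs[[v$key]] <- classify_variant(p, v$key, config = config)
      classify_patient(p, inc, vcs, config, rules)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[p$patient_id] <- conditionMessage(res)
    } else {
      out[[length(out) + 1L]] <- res
    }
  }
  attr(out, "excluded") <- excluded
  attr(out, "errors") <- errors
  out
}

#' @export
print.patient_conclusion <- function(x, ...) {
  cat(sprintf("<patient_conclusion> %s: %s (categories %s)\n",
              x$patient_id, x$primary_label,
              paste(x$categories, collapse = ",")))
  invisible(x)
}
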