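#' @title Conclusion reports
#' @description Flat per-patient report table and round-trip-safe
#'   serialization of patient conclusions.
#' @name report
NULL

#' Flatten patient conclusions into the report table
#'
#' One row per concluded patient, with the triggering variant(s), the
#' tissues tested, the maximum blood AF, categories, primary conclusion and
#' the rule ids of the evidence trail.
#'
#' @param conclusions List of `patient_conclusion` (see [classify_cohort()]).
#' @param patients The cohort the conclusions came from (for tissue/AF
#'   columns).
#' @return data.frame with columns patient_id, variant_key, gene, cdna,
#'   tissue, af_percent, category_set, conclusion, evidence.
#' @export
conclusions_table <- function(conclusions, patients) {
  by_id <- stats::setNames(patients, vapply(patients, `[[`, "", "patient_id"))
  rows <- lapply(conclusions, function(pc) {
    p <- by_id[[pc$patient_id]]
    trig <- pc$triggering_keys
    genes <- vapply(trig, function(k) variant_by_key(p, k)$gene, "")
    cdnas <- vapply(trig, function(k) variant_by_key(p, k)$cdna, "")
    tissues <- unique(vapply(p$observations, `[[`, "", "tissue"))
    afmax <- max(vapply(trig, function(k) pbl_max_af(p, k), 0))
    ev <- unlist(lapply(pc$variant_conclusions[trig], function(vc)
      vapply(vc$evidence, `[[`, "", "rule_id")))
    data.frame(
      patient_id = pc$patient_id,
      variant_key = paste(trig, collapse = ";"),
      gene = paste(unique(genes), collapse = ";"),
      cdna = paste(cdnas, collapse = ";"),
      tissue = paste(tissues, collapse = ";"),
      af_percent = afmax,
      category_set = paste(pc$categories, collapse = ","),
      conclusion = pc$primary_label,
      evidence = paste(unique(ev), collapse = "|"),
      stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(patient_id = character(), variant_key = character(),
                      gene = character(), cdna = character(),
                      tissue = character(), af_percent = numeric(),
                      category_set = character(), conclusion = character(),
                      evidence = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

conclusion_to_list <- function(pc) {
  list(patient_id = pc$patient_id,
       primary_label = pc$primary_label,
       triggering_keys = as.list(pc$triggering_keys),
       categories = as.list(pc$categories),
       variant_conclusions = lapply(pc$variant_conclusions, function(vc)
         list(patient_id = vc$patient_id, variant_key = vc$variant_key,
              label = vc$label,
              evidence = lapply(vc$evidence, function(e)
                list(rule_id = e$rule_id, rationale = e$rationale)),
              cbc_flag = vc$cbc_flag)),
       co_finding_keys = as.list(vapply(pc$co_findings, `[[`, "",
                                        "variant_key")),
       follow_up = as.list(pc$follow_up),
       cbc_flag = pc$cbc_flag)
}

conclusion_from_list <- function(x) {
  vcs <- lapply(x$variant_conclusions, function(vc)
    structure(list(patient_id = vc$patient_id,
                   variant_key = vc$variant_key, label = vc$label,
                   evidence = lapply(vc$evidence, function(e)
                     list(rule_id = e$rule_id, rationale = e$rationale)),
                   cbc_flag = isTRUE(vc$cbc_flag)),
              class = "variant_conclusion"))
  names(vcs) <- vapply(vcs, `[[`, "", "variant_key")
  structure(list(patient_id = x$patient_id,
                 primary_label = x$primary_label,
                 triggering_keys = unlist(x$triggering_keys),
                 categories = as.integer(unlist(x$categories)),
                 variant_conclusions = vcs,
                 co_findings = vcs[unlist(x$co_finding_keys)],
                 follow_up = as.character(unlist(x$follow_up)),
                 cbc_flag = isTRUE(x$cbc_flag)),
            class = "patient_conclusion")
}

#' Write patient conclusions
#'
#' `format = "json"` serializes the full structure (round-trip safe via
#' [read_conclusions()]); `format = "tsv"` writes the flat report table of
#' [conclusions_table()] (requires `patients`).
#'
#' @param conclusions List of `patient_conclusion`.
#' @param path Target file.
#' @param format `"json"` or `"tsv"`.
#' @param patients Cohort, required for the TSV report.
#' @export
write_conclusions <- function(conclusions, path, format = c("json", "tsv"),
                              patients = NULL) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(conclusions = lapply(conclusions, conclusion_to_list)),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    if (is.null(patients))
      stop("the TSV report needs the cohort (patients =)")
    utils::write.table(conclusions_table(conclusions, patients), path,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
  }
  invisible(path)
}

#' Read patient conclusions written by [write_conclusions()] (JSON)
#' @param path JSON file.
#' @return List of `patient_conclusion`.
#' @export
read_conclusions <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$conclusions))
    stop("malformed conclusions document: missing 'conclusions' in ", path)
  lapply(doc$conclusions, conclusion_from_list)
}
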