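#' @title Cohort summary
#' @description Descriptive statistics over a triaged cohort: conclusion,
#'   category and gene tallies, chemotherapy exposure among CH patients, and
#'   the secondary-tissue testing pattern. Percentages are stored at full
#'   precision; formatting is separate.
#' @name cohort_summary
NULL

#' Summarize a triaged cohort
#'
#' @param patients The cohort (list of [patient_record()]).
#' @param inclusions Results of [screen_cohort()] on the same cohort.
#' @param conclusions Results of [classify_cohort()] (included patients).
#' @param config A [threshold_config()] (used to recompute tissue evidence
#'   for the contamination-pattern count).
#' @return List of class `cohort_summary` with counts and exact percentages:
#'   label counts/percentages (plus combined CH = confirmed + likely),
#'   inclusion-category counts, patient-level gene counts (a patient with
#'   findings in two genes contributes to both), multi-gene patient count,
#'   chemotherapy fraction among CH patients, and counts of direct-skin,
#'   paired-culture, blood-contamination-pattern and tumour-tested patients.
#' @export
summarize_cohort <- function(patients, inclusions, conclusions,
                             config = threshold_config()) {
  ids_inc <- vapply(Filter(function(i) i$included, inclusions),
                    `[[`, "", "patient_id")
  ids_con <- vapply(conclusions, `[[`, "", "patient_id")
  if (!setequal(ids_inc, ids_con))
    stop("inclusion and conclusion id sets differ")
  by_id <- stats::setNames(patients, vapply(patients, `[[`, "", "patient_id"))
  n <- length(conclusions)
  pct <- function(k, d = n) if (d == 0) NA_real_ else 100 * k / d

  labels <- vapply(conclusions, `[[`, "", "primary_label")
  label_counts <- vapply(CONCLUSION_LABELS, function(l) sum(labels == l), 0L)
  ch_combined <- sum(labels %in% c("CONFIRMED_CH", "LIKELY_CH"))

  cat_counts <- vapply(1:3, function(k) sum(vapply(inclusions, function(i)
    i$included && k %in% i$categories, TRUE)), 0L)
  names(cat_counts) <- paste0("category", 1:3)

  # patient-level gene tallies over pathogenic findings of included patients
  gene_sets <- lapply(ids_con, function(id) {
    p <- by_id[[id]]
    unique(vapply(Filter(is_plp, p$variants), `[[`, "", "gene"))
  })
  genes <- sort(unique(unlist(gene_sets)))
  gene_counts <- vapply(genes, function(g)
    sum(vapply(gene_sets, function(s) g %in% s, TRUE)), 0L)
  gene_counts <- sort(gene_counts, decreasing = TRUE)
  multi_gene <- sum(vapply(gene_sets, length, 0L) >= 2L)

  chemo_ch <- sum(vapply(conclusions, function(pc) {
    pc$primary_label %in% c("CONFIRMED_CH", "LIKELY_CH") &&
      by_id[[pc$patient_id]]$clinical$chemo_history == "YES"
  }, TRUE))

  skin_tested <- vapply(ids_con, function(id)
    any(vapply(by_id[[id]]$observations, `[[`, "", "tissue") == "DIRECT_SKIN"),
    TRUE)
  paired_cultured <- vapply(ids_con, function(id) {
    tiss <- vapply(by_id[[id]]$observations, `[[`, "", "tissue")
    "DIRECT_SKIN" %in% tiss && "CULTURED_FIBROBLAST" %in% tiss
  }, TRUE)
  tumour_tested <- vapply(ids_con, function(id)
    any(vapply(by_id[[id]]$observations, `[[`, "", "tissue") == "TUMOUR"),
    TRUE)

  # contamination pattern: a variant whose direct-skin call is flagged as
  # blood contamination while cultured fibroblasts are negative
  contamination <- vapply(ids_con, function(id) {
    p <- by_id[[id]]
    any(vapply(p$variants, function(v) {
      if (!length(obs_for(p, v$key, "PBL"))) return(FALSE)
      ev <- summarize_evidence(p, v$key, config)
      skin <- ev$calls[["DIRECT_SKIN"]]
      fib <- ev$calls[["CULTURED_FIBROBLAST"]]
      !is.null(skin) && skin$contamination_suspected &&
        !is.null(fib) && fib$level == "ABSENT"
    }, TRUE))
  }, TRUE)

  structure(list(
    n_included = n,
    label_counts = label_counts,
    label_pct = vapply(label_counts, pct, 0),
    ch_combined_count = ch_combined,
    ch_combined_pct = pct(ch_combined),
    category_counts = cat_counts,
    category_pct = vapply(cat_counts, pct, 0),
    gene_counts = gene_counts,
    gene_pct = vapply(gene_counts, pct, 0),
    multi_gene_count = multi_gene,
    multi_gene_pct = pct(multi_gene),
    chemo_ch_count = chemo_ch,
    chemo_fraction_among_CH = pct(chemo_ch, ch_combined),
    n_direct_skin = sum(skin_tested),
    n_paired_cultured = sum(paired_cultured),
    n_contamination_pattern = sum(contamination),
    n_tumour_tested = sum(tumour_tested),
    pct_direct_skin = pct(sum(skin_tested)),
    pct_paired_cultured = pct(sum(paired_cultured), sum(skin_tested)),
    pct_contamination_pattern = pct(sum(contamination), sum(skin_tested)),
    pct_tumour_tested = pct(sum(tumour_tested))),
    class = "cohort_summary")
}

#' Format a cohort summary as a stable text report
#'
#' @param summary A [summarize_cohort()] result.
#' @param style `"fraction"` prints `count/denominator`; `"percent_1dp"`
#'   prints percentages with one decimal place.
#' @return Character vector of report lines.
#' @export
format_summary <- function(summary, style = c("fraction", "percent_1dp")) {
  style <- match.arg(style)
  n <- summary$n_included
  fmt <- function(k, p, d = n) {
    if (style == "fraction") sprintf("%d/%d", k, d)
    else if (is.na(p)) "NA" else sprintf("%.1f", p)
  }
  lab_line <- function(name, label)
    sprintf("%s: %s", name, fmt(summary$label_counts[[label]],
                                summary$label_pct[[label]]))
  lines <- c(
    sprintf("included: %d", n),
    sprintf("CH combined: %s", fmt(summary$ch_combined_count,
                                   summary$ch_combined_pct)),
    lab_line("CH confirmed", "CONFIRMED_CH"),
    lab_line("CH likely", "LIKELY_CH"),
    lab_line("mosaic", "MOSAIC"),
    lab_line("hematologic malignancy", "HEME_MALIGNANCY_RELATED"),
    lab_line("full germline", "FULL_GERMLINE"),
    lab_line("likely germline", "LIKELY_GERMLINE"),
    sprintf("category 1: %s", fmt(summary$category_counts[["category1"]],
                                  summary$category_pct[["category1"]])),
    sprintf("category 2: %s", fmt(summary$category_counts[["category2"]],
                                  summary$category_pct[["category2"]])),
    sprintf("category 3: %s", fmt(summary$category_counts[["category3"]],
                                  summary$category_pct[["category3"]])),
    vapply(names(summary$gene_counts), function(g)
      sprintf("gene %s: %s", g, fmt(summary$gene_counts[[g]],
                                    summary$gene_pct[[g]])), ""),
    sprintf("multi-gene patients: %s", fmt(summary$multi_gene_count,
                                           summary$multi_gene_pct)),
    sprintf("chemotherapy among CH: %s",
            fmt(summary$chemo_ch_count, summary$chemo_fraction_among_CH,
                summary$ch_combined_count)),
    sprintf("direct skin tested: %s",
            fmt(summary$n_direct_skin, summary$pct_direct_skin)),
    sprintf("paired fibroblast culture: %s",
            fmt(summary$n_paired_cultured, summary$pct_paired_cultured,
                summary$n_direct_skin)),
    sprintf("blood-contamination pattern: %s",
            fmt(summary$n_contamination_pattern,
                summary$pct_contamination_pattern, summary$n_direct_skin)),
    sprintf("tumour tested: %s",
            fmt(summary$n_tumour_tested, summary$pct_tumour_tested)))
  unname(lines)
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(format_summary(x, "fraction"), sep = "\n")
  invisible(x)
}
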