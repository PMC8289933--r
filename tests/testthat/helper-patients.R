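# compact constructors for hand-built test patients

simple_patient <- function(id = "P1", gene = "TP53", pbl = 50,
                           tissues = list(), pathogenicity = "PATHOGENIC",
                           diagnoses = list(), family = list(),
                           clinical = clinical_context(), key = NULL) {
  key <- if (is.null(key)) paste0(gene, "_1") else key
  obs <- lapply(pbl, function(v) tissue_observation(
    key, "PBL", if (is.na(v)) af_absent() else af_q(v)))
  for (t in names(tissues)) {
    v <- tissues[[t]]
    obs[[length(obs) + 1L]] <- tissue_observation(
      key, t, if (is.na(v)) af_absent() else af_q(v))
  }
  patient_record(
    patient_id = id,
    diagnoses = diagnoses, family = family, clinical = clinical,
    variants = list(variant_call(key, gene,
                                 cdna = "c.100A>G",
                                 pathogenicity = pathogenicity)),
    observations = obs)
}

# Dx Conclusion column of the genetic-findings table, patient id -> label
FIXTURE_EXPECTED_LABELS <- c(
  "2" = "CONFIRMED_CH", "3" = "CONFIRMED_CH", "5" = "LIKELY_CH",
  "6" = "LIKELY_CH", "7" = "MOSAIC", "8" = "LIKELY_CH",
  "10" = "CONFIRMED_CH", "11" = "HEME_MALIGNANCY_RELATED",
  "12" = "HEME_MALIGNANCY_RELATED", "13" = "CONFIRMED_CH",
  "14" = "LIKELY_CH", "15" = "CONFIRMED_CH", "16" = "LIKELY_CH",
  "18" = "CONFIRMED_CH", "19" = "LIKELY_CH", "22" = "LIKELY_CH",
  "24" = "LIKELY_CH", "27" = "LIKELY_CH", "29" = "FULL_GERMLINE",
  "33" = "MOSAIC", "40" = "MOSAIC", "41" = "LIKELY_CH",
  "42" = "CONFIRMED_CH", "43" = "CONFIRMED_CH")

# printed Secondary Finding Category column, patient id -> category set
FIXTURE_EXPECTED_CATEGORIES <- list(
  "2" = c(2L, 3L), "3" = c(2L, 3L), "5" = c(2L, 3L), "6" = c(2L, 3L),
  "7" = c(2L, 3L), "8" = c(2L, 3L), "10" = c(2L, 3L), "11" = c(1L, 3L),
  "12" = c(2L, 3L), "13" = c(2L, 3L), "14" = c(2L, 3L), "15" = c(2L, 3L),
  "16" = c(1L, 3L), "18" = 2L, "19" = 2L, "22" = 2L, "24" = c(1L, 2L),
  "27" = 2L, "29" = 3L, "33" = 2L, "40" = 2L, "41" = c(1L, 3L),
  "42" = 3L, "43" = 3L)

write_test_vcf <- function(path, records,
                           format = "GT:AD:DP", sample = "S1") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
  writeLines(c(header, records), path)
  path
}
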