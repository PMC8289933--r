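#' Ingest per-sample allele fractions from a VCF
#'
#' Builds [tissue_observation()]s from a VCF carrying per-sample allele depth
#' and total depth (`FORMAT` fields `AD`/`DP`), or a direct per-sample allele
#' fraction (`AF`). Depth fields are preferred; `AF` is the fallback.
#' Multi-allelic records are split per ALT allele. A record whose total depth
#' is zero yields an ABSENT observation, as does an alt depth of zero.
#'
#' The observation's `variant_key` is the VCF `ID` when set, otherwise
#' `CHROM:POS_REF>ALT` (suffixed with the ALT index for multi-allelic sites).
#'
#' @param path VCF file (v4.2+, plain text or bgzipped).
#' @param sample_id Sample column to extract.
#' @param tissue Tissue of the sample (see [tissue_observation()]).
#' @param age_at_sample Optional age in years.
#' @return List of [tissue_observation()], one per ALT allele.
#' @export
ingest_vcf <- function(path, sample_id, tissue = "PBL", age_at_sample = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  if (!sample_id %in% samples)
    stop("sample '", sample_id, "' not found in VCF (has: ",
         paste(samples, collapse = ", "), ")")
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix)))  # single-record VCFs come back as a bare vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  has_ad <- "AD" %in% unlist(strsplit(vcf@gt[, "FORMAT"], ":"))
  has_dp <- "DP" %in% unlist(strsplit(vcf@gt[, "FORMAT"], ":"))
  has_af <- "AF" %in% unlist(strsplit(vcf@gt[, "FORMAT"], ":"))
  if (!(has_ad && has_dp) && !has_af)
    stop("VCF has neither AD/DP nor AF FORMAT fields; cannot derive allele fractions")
  ad <- if (has_ad) vcfR::extract.gt(vcf, element = "AD")[, sample_id] else NULL
  dp <- if (has_dp) vcfR::extract.gt(vcf, element = "DP")[, sample_id] else NULL
  afv <- if (has_af) vcfR::extract.gt(vcf, element = "AF")[, sample_id] else NULL

  out <- list()
  for (i in seq_len(n)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    id <- unname(fix[i, "ID"])
    for (j in seq_along(alts)) {
      key <- if (!is.na(id) && nzchar(id) && id != ".") {
        if (length(alts) > 1L) paste0(id, "_", j) else id
      } else {
        paste0(fix[i, "CHROM"], ":", fix[i, "POS"], "_",
               fix[i, "REF"], ">", alts[j])
      }
      af <- NULL
      if (!is.null(ad) && !is.null(dp) && !is.na(ad[i]) && !is.na(dp[i])) {
        depths <- as.numeric(strsplit(ad[i], ",", fixed = TRUE)[[1]])
        total <- as.numeric(dp[i])
        altd <- depths[j + 1L]
        af <- if (total == 0 || is.na(altd) || altd == 0) af_absent()
              else af_q(100 * altd / total)
      } else if (!is.null(afv) && !is.na(afv[i])) {
        vals <- as.numeric(strsplit(afv[i], ",", fixed = TRUE)[[1]])
        v <- if (length(vals) >= j) vals[j] else vals[1]
        af <- if (v == 0) af_absent() else af_q(100 * v)
      } else {
        stop("record ", i, " lacks usable AD/DP and AF for sample ", sample_id)
      }
      out[[length(out) + 1L]] <-
        tissue_observation(key, tissue, af, age_at_sample = age_at_sample)
    }
  }
  out
}
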