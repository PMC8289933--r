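#' Allele-fraction measurement
#'
#' An allele fraction (AF) as reported by a clinical NGS laboratory: either a
#' quantified percentage (a point estimate, or an interval for copy-number
#' calls printed as ranges such as "10-15%"), a detected-but-unquantified
#' finding, or an explicit negative.
#'
#' @param status One of `"QUANTIFIED"`, `"PRESENT_UNQUANTIFIED"`, `"ABSENT"`.
#' @param value Percent in \[0, 100\]; point estimate, only for `QUANTIFIED`.
#' @param interval_low,interval_high Percent bounds for interval estimates
#'   (copy-number AFs); only for `QUANTIFIED`, used when `value` is absent.
#' @return An object of class `allele_fraction`.
#' @examples
#' allele_fraction("QUANTIFIED", value = 50)
#' allele_fraction("QUANTIFIED", interval_low = 10, interval_high = 15)
#' allele_fraction("ABSENT")
#' @export
allele_fraction <- function(status,
                            value = NULL,
                            interval_low = NULL,
                            interval_high = NULL) {
  status <- match.arg(status, c("QUANTIFIED", "PRESENT_UNQUANTIFIED", "ABSENT"))
  if (!is.null(value)) {
    stopifnot(is.numeric(value), length(value) == 1L)
    if (is.na(value) || value < 0 || value > 100)
      stop("allele fraction value must lie in [0, 100], got ", value)
  }
  has_interval <- !is.null(interval_low) || !is.null(interval_high)
  if (has_interval) {
    if (is.null(interval_low) || is.null(interval_high))
      stop("interval estimates need both interval_low and interval_high")
    stopifnot(is.numeric(interval_low), is.numeric(interval_high))
    if (interval_low > interval_high)
      stop("interval_low must not exceed interval_high")
    if (interval_low < 0 || interval_high > 100)
      stop("allele-fraction interval must lie in [0, 100]")
  }
  if (status == "ABSENT" && (!is.null(value) || has_interval))
    stop("ABSENT allele fraction must not carry a value or interval")
  if (status == "PRESENT_UNQUANTIFIED" && (!is.null(value) || has_interval))
    stop("PRESENT_UNQUANTIFIED allele fraction must not carry a value")
  if (status == "QUANTIFIED" && is.null(value) && !has_interval)
    stop("QUANTIFIED allele fraction needs a value or an interval")
  structure(
    list(status = status, value = value,
         interval_low = interval_low, interval_high = interval_high),
    class = "allele_fraction"
  )
}

#' Representative percentage of an allele fraction
#'
#' The single number the screen and classifier work with: the point estimate
#' if one was reported, otherwise the midpoint of an interval estimate,
#' otherwise `NA` (absent or unquantified findings carry no number).
#'
#' @param af An [allele_fraction()].
#' @return A single numeric percent, or `NA_real_`.
#' @export
af_representative <- function(af) {
  stopifnot(inherits(af, "allele_fraction"))
  if (!is.null(af$value)) return(af$value)
  if (!is.null(af$interval_low)) return((af$interval_low + af$interval_high) / 2)
  NA_real_
}

#' @export
print.allele_fraction <- function(x, ...) {
  rep <- af_representative(x)
  cat("<allele_fraction> ", x$status,
      if (!is.na(rep)) sprintf(" %.4g%%", rep),
      if (!is.null(x$interval_low))
        sprintf(" [%.4g-%.4g%%]", x$interval_low, x$interval_high),
      "\n", sep = "")
  invisible(x)
}

# shorthand used by the fixture and generator
af_q <- function(value) allele_fraction("QUANTIFIED", value = value)
af_absent <- function() allele_fraction("ABSENT")
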