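#' Evaluate ICP-OES method quality parameters
#'
#' Eurachem-style acceptance screening of method validation figures:
#' accuracy (CRM recovery) must fall inside the recovery band and
#' precision (replicate RSD) must not exceed the RSD ceiling. Both
#' checks use inclusive endpoints.
#'
#' @param qc QC table (see [reference_qc()] for the format); one row per
#'   element.
#' @param recovery_band Acceptable recovery range in percent,
#'   `c(lo, hi)`, endpoints included.
#' @param rsd_max Maximum acceptable RSD in percent, inclusive.
#' @return A data.frame verdict with columns `element`, `recovery_ok`,
#'   `precision_ok`, `overall_ok` (`overall_ok` is the conjunction).
#' @examples
#' evaluate_qc(reference_qc())
#' @export
evaluate_qc <- function(qc, recovery_band = c(80, 120), rsd_max = 15) {
  qc <- validate_qc_table(qc)
  stopifnot(length(recovery_band) == 2L, recovery_band[1] <= recovery_band[2],
            rsd_max >= 0)
  recovery_ok <- qc$recovery_pct >= recovery_band[1] &
    qc$recovery_pct <= recovery_band[2]
  precision_ok <- qc$rsd_pct <= rsd_max
  data.frame(element = qc$element,
             recovery_ok = recovery_ok,
             precision_ok = precision_ok,
             overall_ok = recovery_ok & precision_ok,
             stringsAsFactors = FALSE)
}

#' Per-element censoring summary
#'
#' Counts, for each element, how many measurements are quantified, below
#' the quantification limit, and below the detection limit. The three
#' counts always sum to the number of samples.
#'
#' @param samples A non-empty `propolis_samples` object.
#' @return A data.frame with columns `element`, `quantified`,
#'   `below_LOQ`, `below_LOD`, `n`.
#' @export
censoring_summary <- function(samples) {
  if (n_samples(samples) == 0L) stop("empty sample collection")
  counts <- table(factor(samples$element, PROPOLIS_ELEMENTS),
                  factor(samples$censor, CENSOR_LEVELS))
  out <- data.frame(element = rownames(counts),
                    quantified = as.integer(counts[, "quantified"]),
                    below_LOQ = as.integer(counts[, "below_LOQ"]),
                    below_LOD = as.integer(counts[, "below_LOD"]),
                    stringsAsFactors = FALSE)
  out$n <- out$quantified + out$below_LOQ + out$below_LOD
  out
}
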