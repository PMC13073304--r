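#' Detection frequency of an element across a collection
#'
#' Percentage of samples in which the element is quantified (not
#' left-censored): `100 * n_quantified / n`.
#'
#' @param samples A non-empty `propolis_samples` object.
#' @param element Element symbol.
#' @param rounding `"two_dp"` (two decimals) or `"integer"` (nearest
#'   whole percent). Exposed because survey reports mix precisions.
#' @return Detection frequency in percent.
#' @examples
#' detection_frequency(build_paper_fixture(1), "As")  # 16.67
#' @export
detection_frequency <- function(samples, element,
                                rounding = c("two_dp", "integer")) {
  rounding <- match.arg(rounding)
  element <- match.arg(element, PROPOLIS_ELEMENTS)
  if (n_samples(samples) == 0L) stop("empty sample collection")
  rows <- samples[samples$element == element, ]
  pct <- 100 * sum(rows$censor == "quantified") / nrow(rows)
  round(pct, digits = if (rounding == "two_dp") 2L else 0L)
}

#' Screen samples against a regulatory standard
#'
#' Compares each measurement with the standard's per-element rule. A
#' numeric maximum permissible limit (MPL) is exceeded only by a
#' quantified value strictly greater than the limit; censored
#' measurements never exceed a numeric MPL. The qualitative rule
#' `"absent"` is exceeded by any quantified detection. Elements the
#' standard does not regulate are reported as `not_regulated`.
#'
#' @param samples A `propolis_samples` object.
#' @param standard A [regulatory_standard()].
#' @return A data.frame with columns `sample_id`, `element`, `value`
#'   (`NA` when censored), `censor`, `limit` (`NA` for qualitative or
#'   absent rules), `rule` (`"mpl"`, `"absent"` or `"none"`), `verdict`
#'   (`"pass"`, `"exceed"` or `"not_regulated"`).
#' @examples
#' std <- regulatory_standard("efsa_2020_640")
#' scr <- screen_samples(build_paper_fixture(1), std)
#' subset(scr, verdict == "exceed")
#' @export
screen_samples <- function(samples, standard) {
  stopifnot(inherits(standard, "regulatory_standard"))
  out <- data.frame(sample_id = samples$sample_id,
                    element = samples$element,
                    value = samples$value,
                    censor = samples$censor,
                    limit = NA_real_,
                    rule = "none",
                    verdict = "not_regulated",
                    stringsAsFactors = FALSE)
  for (el in names(standard$limits)) {
    lim <- standard$limits[[el]]
    idx <- out$element == el
    if (identical(lim, "absent")) {
      out$rule[idx] <- "absent"
      out$verdict[idx] <- ifelse(out$censor[idx] == "quantified",
                                 "exceed", "pass")
    } else {
      out$rule[idx] <- "mpl"
      out$limit[idx] <- lim
      quantified <- out$censor[idx] == "quantified"
      out$verdict[idx] <- ifelse(quantified & out$value[idx] > lim,
                                 "exceed", "pass")
    }
  }
  out
}

#' Screen a single sample
#'
#' Convenience wrapper around [screen_samples()] for one sample id.
#'
#' @inheritParams screen_samples
#' @param sample_id The sample to screen.
#' @return The [screen_samples()] rows for that sample.
#' @export
screen_sample <- function(samples, sample_id, standard) {
  if (!sample_id %in% samples$sample_id) {
    stop("unknown sample_id: ", sample_id)
  }
  scr <- screen_samples(samples, standard)
  scr[scr$sample_id == sample_id, ]
}

#' Daily manganese intake check
#'
#' Mn has no concentration MPL in the packaged standards; instead a
#' daily intake bound applies. Intake is concentration times intake
#' rate: mg/kg x kg/day = mg/day. The bound is exceeded only by a
#' strictly greater intake.
#'
#' @param c_mn Mn concentration in propolis, ppm (mg/kg).
#' @param ingr Propolis intake rate, kg/day.
#' @param bound Daily intake bound, mg/day.
#' @return A list with `intake_mg_day` and logical `exceeds`.
#' @examples
#' mn_intake_check(47.57, ingr = 0.001)  # 0.04757 mg/day, well below 3
#' @export
mn_intake_check <- function(c_mn, ingr, bound = 3) {
  if (!is.finite(c_mn) || c_mn < 0) stop("c_mn must be finite and >= 0")
  if (!is.finite(ingr) || ingr <= 0) stop("ingr must be finite and > 0")
  if (!is.finite(bound) || bound <= 0) stop("bound must be finite and > 0")
  intake <- c_mn * ingr
  list(intake_mg_day = intake, exceeds = intake > bound)
}
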