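#' Elements covered by the propolis screening pipeline
#'
#' The four elements determined by ICP-OES in raw propolis: arsenic,
#' cadmium, lead and manganese. All concentration handling in the package
#' is restricted to this set; ppm is treated as exactly mg element per kg
#' propolis throughout (no density conversion).
#'
#' @format A character vector of element symbols.
#' @export
PROPOLIS_ELEMENTS <- c("As", "Cd", "Pb", "Mn")

CENSOR_LEVELS <- c("quantified", "below_LOQ", "below_LOD")

#' Reference ICP-OES method quality parameters
#'
#' Method validation figures for the propolis matrix: spike/CRM recovery
#' (accuracy), relative standard deviation of replicates (precision), and
#' the detection and quantification limits used to censor raw
#' concentrations. These are the package's default limits wherever a QC
#' table is optional.
#'
#' @return A data.frame with columns `element`, `recovery_pct`, `rsd_pct`,
#'   `lod`, `loq` (limits in ppm), one row per element.
#' @examples
#' reference_qc()
#' @export
reference_qc <- function() {
  path <- system.file("extdata", "qc_icpoes.csv", package = "propolistox",
                      mustWork = TRUE)
  qc <- read.csv(path, stringsAsFactors = FALSE)
  validate_qc_table(qc)
}

validate_qc_table <- function(qc) {
  need <- c("element", "recovery_pct", "rsd_pct", "lod", "loq")
  miss <- setdiff(need, names(qc))
  if (length(miss)) {
    stop("QC table is missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- setdiff(qc$element, PROPOLIS_ELEMENTS)
  if (length(bad)) stop("QC table has unknown element(s): ", paste(bad, collapse = ", "))
  num <- qc[, c("recovery_pct", "rsd_pct", "lod", "loq")]
  if (any(!is.finite(as.matrix(num))) || any(as.matrix(num) < 0)) {
    stop("QC table fields must be finite and nonnegative")
  }
  if (any(qc$lod <= 0)) stop("LOD must be > 0")
  if (any(qc$loq < qc$lod)) stop("LOQ must be >= LOD")
  qc
}

#' Toxicological reference values for oral exposure
#'
#' Oral reference doses (RfD, mg/kg bw/day) for the non-carcinogenic
#' hazard quotient, and cancer slope factors (SF, per mg/kg bw/day) for
#' the carcinogenic risk characterization. Manganese carries no slope
#' factor: it is not treated as carcinogenic and only a hazard quotient
#' is computed for it.
#'
#' @return A data.frame with columns `element`, `rfd`, `sf` (`sf` is `NA`
#'   for Mn).
#' @examples
#' tox_params()
#' @export
tox_params <- function() {
  data.frame(
    element = c("As", "Cd", "Pb", "Mn"),
    rfd = c(0.0003, 0.001, 0.004, 0.14),
    sf = c(1.5, 0.0061, 0.0085, NA_real_),
    stringsAsFactors = FALSE
  )
}

tox_for <- function(element, tox = tox_params()) {
  row <- tox[tox$element == element, , drop = FALSE]
  if (nrow(row) != 1L) stop("no toxicological parameters for element ", element)
  row
}

#' Define a dietary exposure scenario
#'
#' Bundles the exposure parameters of the average-daily-dose model:
#' propolis intake rate, exposure frequency and duration, body weight,
#' and the averaging-time rule. Two averaging conventions are supported:
#' `"match_ed"` (averaging time spans the exposure duration, the
#' convention for chronic non-carcinogenic dose) and `"lifetime"`
#' (averaging over a full life expectancy, the convention for lifetime
#' carcinogenic dose).
#'
#' @param ingr Intake rate of raw propolis, kg/day.
#' @param ef Exposure frequency, days/year (at most 365).
#' @param ed Exposure duration, years.
#' @param bw Body weight, kg.
#' @param at_rule Averaging-time rule, `"match_ed"` or `"lifetime"`.
#' @param life_expectancy Life expectancy in years, used when
#'   `at_rule = "lifetime"`.
#' @return An object of class `exposure_scenario`.
#' @seealso [default_scenario()] for the package defaults,
#'   [average_daily_dose()] for the dose model.
#' @examples
#' exposure_scenario(ingr = 0.001, ef = 90, ed = 40, bw = 75)
#' @export
exposure_scenario <- function(ingr, ef, ed, bw,
                              at_rule = c("match_ed", "lifetime"),
                              life_expectancy = 75.5) {
  at_rule <- match.arg(at_rule)
  vals <- c(ingr = ingr, ef = ef, ed = ed, bw = bw,
            life_expectancy = life_expectancy)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all exposure-scenario parameters must be finite and > 0")
  }
  if (ef > 365) stop("exposure frequency cannot exceed 365 days/year")
  structure(
    list(ingr = ingr, ef = ef, ed = ed, bw = bw, at_rule = at_rule,
         life_expectancy = life_expectancy),
    class = "exposure_scenario"
  )
}

#' Default adult exposure scenario for raw propolis
#'
#' One gram of raw propolis per day (0.001 kg/day), taken as a 3-month
#' cure each year (90 days/year) over 40 years of adult life, for a 75 kg
#' adult; life expectancy 75.5 years for lifetime averaging.
#'
#' @param at_rule Averaging-time rule; see [exposure_scenario()].
#' @return An `exposure_scenario`.
#' @export
default_scenario <- function(at_rule = c("match_ed", "lifetime")) {
  exposure_scenario(ingr = 0.001, ef = 90, ed = 40, bw = 75,
                    at_rule = match.arg(at_rule), life_expectancy = 75.5)
}

#' Averaging time of a scenario, in days
#'
#' `365 * ed` under the `"match_ed"` rule, `365 * life_expectancy` under
#' the `"lifetime"` rule.
#'
#' @param scenario An `exposure_scenario`.
#' @return Averaging time in days.
#' @export
at_days <- function(scenario) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  switch(scenario$at_rule,
         match_ed = 365 * scenario$ed,
         lifetime = 365 * scenario$life_expectancy)
}

#' @export
print.exposure_scenario <- function(x, ...) {
  cat("Exposure scenario:\n")
  cat(sprintf("  IngR %g kg/day, EF %g days/year, ED %g years, BW %g kg\n",
              x$ingr, x$ef, x$ed, x$bw))
  cat(sprintf("  AT rule: %s (AT = %g days)\n", x$at_rule, at_days(x)))
  invisible(x)
}

#' Load a packaged regulatory standard
#'
#' The package ships the three regulatory limit sets used for propolis
#' compliance screening:
#' \describe{
#'   \item{`efsa_2020_640`}{EFSA: Cd at most 0.1 ppm, Pb at most 1 ppm,
#'     As must be absent (any quantified detection is an exceedance);
#'     daily Mn intake bound of 3 mg/day.}
#'   \item{`iram_inta_15935`}{Argentine standard: Pb 10 ppm, As 2 ppm.}
#'   \item{`nrag_1135`}{Cuban standard: Pb 2 ppm, As 1 ppm.}
#' }
#' Numeric limits use a strict comparator: a value equal to the limit is
#' compliant, exceedance requires `value > limit`.
#'
#' @param name Standard identifier, one of [list_standards()].
#' @return A `regulatory_standard` object: a list with `name`, `limits`
#'   (per-element numeric MPL in ppm or the string `"absent"`), and
#'   optionally `mn_intake_bound_mg_day`.
#' @examples
#' regulatory_standard("efsa_2020_640")
#' @export
regulatory_standard <- function(name) {
  path <- system.file("extdata", "standards", paste0(name, ".json"),
                      package = "propolistox")
  if (!nzchar(path)) {
    stop("unknown standard '", name, "'; available: ",
         paste(list_standards(), collapse = ", "))
  }
  std <- jsonlite::read_json(path, simplifyVector = FALSE)
  validate_standard(std)
}

#' @rdname regulatory_standard
#' @export
list_standards <- function() {
  dir <- system.file("extdata", "standards", package = "propolistox")
  sort(sub("\\.json$", "", list.files(dir, pattern = "\\.json$")))
}

validate_standard <- function(std) {
  if (is.null(std$name) || is.null(std$limits)) {
    stop("standard must have 'name' and 'limits'")
  }
  bad <- setdiff(names(std$limits), PROPOLIS_ELEMENTS)
  if (length(bad)) stop("standard regulates unknown element(s): ",
                        paste(bad, collapse = ", "))
  for (el in names(std$limits)) {
    lim <- std$limits[[el]]
    ok <- identical(lim, "absent") ||
      (is.numeric(lim) && length(lim) == 1L && is.finite(lim) && lim > 0)
    if (!ok) stop("limit for ", el, " must be a positive number or \"absent\"")
  }
  if (!is.null(std$mn_intake_bound_mg_day) &&
      (!is.numeric(std$mn_intake_bound_mg_day) || std$mn_intake_bound_mg_day <= 0)) {
    stop("mn_intake_bound_mg_day must be a positive number")
  }
  structure(std, class = "regulatory_standard")
}

#' @export
print.regulatory_standard <- function(x, ...) {
  cat("Regulatory standard:", x$name, "\n")
  for (el in names(x$limits)) {
    lim <- x$limits[[el]]
    cat(sprintf("  %s: %s\n", el,
                if (identical(lim, "absent")) "must be absent" else paste(lim, "ppm")))
  }
  if (!is.null(x$mn_intake_bound_mg_day)) {
    cat(sprintf("  Mn daily intake bound: %g mg/day\n", x$mn_intake_bound_mg_day))
  }
  invisible(x)
}
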