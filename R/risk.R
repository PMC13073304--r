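#' Average daily dose of an element from propolis consumption
#'
#' Chronic dose model
#' \deqn{ADD = \frac{C \times IngR \times EF \times ED}{BW \times AT}}
#' with C the concentration in propolis (ppm = mg/kg), IngR the intake
#' rate (kg/day), EF the exposure frequency (days/year), ED the exposure
#' duration (years), BW body weight (kg) and AT the averaging time in
#' days. Under the `"match_ed"` averaging rule AT = 365 x ED, so ED
#' cancels and the dose is `C * IngR * EF / (BW * 365)`; under
#' `"lifetime"` AT spans the full life expectancy, giving the lifetime
#' average used for carcinogenic risk.
#'
#' @param c Concentration in ppm (mg/kg), nonnegative.
#' @param scenario An [exposure_scenario()].
#' @return Dose in mg per kg body weight per day.
#' @examples
#' average_daily_dose(117.01, default_scenario())
#' @export
average_daily_dose <- function(c, scenario) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  if (any(!is.finite(c)) || any(c < 0)) {
    stop("concentration must be finite and >= 0")
  }
  c * scenario$ingr * scenario$ef * scenario$ed /
    (scenario$bw * at_days(scenario))
}

#' Non-carcinogenic hazard quotient
#'
#' `HQ = ADD / RfD`, the ratio of the average daily dose to the oral
#' reference dose. HQ strictly greater than 1 flags a potential
#' non-carcinogenic risk; HQ = 1 exactly is still `no_concern`.
#'
#' @param add Average daily dose, mg/kg bw/day (from
#'   [average_daily_dose()] with the `"match_ed"` rule).
#' @param element Element symbol (looks up the RfD).
#' @param tox Toxicological parameter table (default [tox_params()]).
#' @return A list with `hq` and `label` (`"no_concern"` or
#'   `"potential_risk"`).
#' @export
hazard_quotient <- function(add, element, tox = tox_params()) {
  if (any(!is.finite(add)) || any(add < 0)) stop("add must be finite and >= 0")
  row <- tox_for(element, tox)
  if (is.na(row$rfd) || row$rfd <= 0) stop("missing RfD for ", element)
  hq <- add / row$rfd
  list(hq = hq, label = classify_hq(hq))
}

#' @rdname hazard_quotient
#' @param hq Hazard quotient value(s).
#' @export
classify_hq <- function(hq) {
  if (any(hq < 0)) stop("hq must be >= 0")
  ifelse(hq > 1, "potential_risk", "no_concern")
}

#' Carcinogenic risk from lifetime dose
#'
#' Characterizes incremental lifetime cancer risk from the lifetime
#' average daily dose and the cancer slope factor SF. The default
#' characterization is the standard product `CR = ADD x SF`
#' (dimensionless probability). The alternative quotient `CR = ADD / SF`
#' is available behind `formula = "divide"` for comparison, but it
#' inflates risk for small slope factors and is not used by any
#' packaged workflow; see the methods vignette for why the product is
#' the default. Mn has no slope factor and is an error.
#'
#' @param add_lifetime Lifetime average daily dose, mg/kg bw/day (from
#'   [average_daily_dose()] with the `"lifetime"` rule).
#' @param element Element symbol (`"Mn"` errors: non-carcinogenic).
#' @param tox Toxicological parameter table (default [tox_params()]).
#' @param formula `"multiply"` (default) or `"divide"`.
#' @return Carcinogenic risk, dimensionless.
#' @export
carcinogenic_risk <- function(add_lifetime, element, tox = tox_params(),
                              formula = c("multiply", "divide")) {
  formula <- match.arg(formula)
  if (any(!is.finite(add_lifetime)) || any(add_lifetime < 0)) {
    stop("add_lifetime must be finite and >= 0")
  }
  row <- tox_for(element, tox)
  if (is.na(row$sf)) {
    stop(element, " has no cancer slope factor (non-carcinogenic element)")
  }
  switch(formula,
         multiply = add_lifetime * row$sf,
         divide = add_lifetime / row$sf)
}

#' Classify carcinogenic risk into screening bands
#'
#' Partition of the nonnegative line, lower bounds inclusive:
#' \itemize{
#'   \item `very_low`: CR < 1e-6 (below the screening level)
#'   \item `above_screening`: 1e-6 <= CR < 1e-5
#'   \item `low`: 1e-5 <= CR < 1e-4
#'   \item `moderate`: 1e-4 <= CR < 1e-3
#'   \item `substantial`: CR >= 1e-3
#' }
#' Every nonnegative value receives exactly one label.
#'
#' @param cr Carcinogenic risk value(s), nonnegative.
#' @return Character vector of band labels.
#' @examples
#' classify_cr(c(0, 1.7e-6, 5e-4))
#' @export
classify_cr <- function(cr) {
  if (any(!is.finite(cr)) || any(cr < 0)) stop("cr must be finite and >= 0")
  ifelse(cr >= 1e-3, "substantial",
         ifelse(cr >= 1e-4, "moderate",
                ifelse(cr >= 1e-5, "low",
                       ifelse(cr >= 1e-6, "above_screening", "very_low"))))
}

#' Full deterministic risk assessment of a collection
#'
#' For every sample x element: substitutes censored concentrations per
#' the policy (default `"zero"`, so non-detects contribute no invented
#' dose), computes the chronic dose (`add_nc`, averaging time matching
#' the exposure duration) and the lifetime dose (`add_car`), the hazard
#' quotient with its label, and -- for the carcinogenic elements As, Cd,
#' Pb -- the carcinogenic risk with its screening band. Mn rows carry
#' `NA` for `add_car`, `cr` and `cr_label`.
#'
#' @param samples A `propolis_samples` object.
#' @param scenario An [exposure_scenario()]; its `at_rule` is overridden
#'   internally (`match_ed` for HQ, `lifetime` for CR).
#' @param tox Toxicological parameter table (default [tox_params()]).
#' @param policy Censoring substitution policy; default `"zero"`.
#' @param cr_formula Passed to [carcinogenic_risk()].
#' @return A data.frame with one row per sample x element: `sample_id`,
#'   `element`, `concentration`, `add_nc`, `add_car`, `hq`, `hq_label`,
#'   `cr`, `cr_label`.
#' @examples
#' head(assess_dataset(build_paper_fixture(1), default_scenario()))
#' @export
assess_dataset <- function(samples, scenario = default_scenario(),
                           tox = tox_params(), policy = "zero",
                           cr_formula = "multiply") {
  stopifnot(inherits(scenario, "exposure_scenario"))
  if (n_samples(samples) == 0L) {
    return(data.frame(sample_id = character(), element = character(),
                      concentration = numeric(), add_nc = numeric(),
                      add_car = numeric(), hq = numeric(),
                      hq_label = character(), cr = numeric(),
                      cr_label = character(), stringsAsFactors = FALSE))
  }
  s_nc <- scenario; s_nc$at_rule <- "match_ed"
  s_car <- scenario; s_car$at_rule <- "lifetime"

  conc <- substitute_censored(samples$value, samples$censor,
                              samples$lod, samples$loq, policy)
  out <- data.frame(sample_id = samples$sample_id, element = samples$element,
                    concentration = conc, stringsAsFactors = FALSE)
  out$add_nc <- average_daily_dose(conc, s_nc)
  out$add_car <- average_daily_dose(conc, s_car)
  rfd <- tox$rfd[match(out$element, tox$element)]
  out$hq <- out$add_nc / rfd
  out$hq_label <- classify_hq(out$hq)
  sf <- tox$sf[match(out$element, tox$element)]
  carcinogen <- !is.na(sf)
  out$cr <- NA_real_
  out$cr[carcinogen] <- vapply(which(carcinogen), function(i) {
    carcinogenic_risk(out$add_car[i], out$element[i], tox, cr_formula)
  }, numeric(1))
  out$cr_label <- NA_character_
  out$cr_label[carcinogen] <- classify_cr(out$cr[carcinogen])
  out$add_car[!carcinogen] <- NA_real_
  out
}
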