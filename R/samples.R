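#' Propolis sample collections
#'
#' A `propolis_samples` object is a long-format data.frame with one row
#' per sample x element measurement and columns:
#' \describe{
#'   \item{sample_id}{Sample label, unique across the collection.}
#'   \item{site}{Free-text region label.}
#'   \item{element}{One of `r paste(PROPOLIS_ELEMENTS, collapse = ", ")`.}
#'   \item{value}{Measured concentration in ppm (mg/kg) for quantified
#'     measurements, `NA` when left-censored. Raw censored values are
#'     never stored; numeric substitutes come only from
#'     [substitute_censored()].}
#'   \item{censor}{`"quantified"`, `"below_LOQ"` (detected but below the
#'     quantification limit) or `"below_LOD"` (below the detection
#'     limit).}
#'   \item{lod, loq}{The method detection and quantification limits in
#'     ppm attached to the measurement.}
#' }
#' Every sample carries exactly one measurement per element.
#'
#' @param x A data.frame with the columns above.
#' @return `x`, validated, with class `propolis_samples`.
#' @export
as_propolis_samples <- function(x) {
  need <- c("sample_id", "site", "element", "value", "censor", "lod", "loq")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  x <- as.data.frame(x)[need]
  x$sample_id <- as.character(x$sample_id)
  x$site <- as.character(x$site)
  x$element <- as.character(x$element)
  x$censor <- as.character(x$censor)

  bad_el <- setdiff(unique(x$element), PROPOLIS_ELEMENTS)
  if (length(bad_el)) stop("unknown element(s): ", paste(bad_el, collapse = ", "))
  bad_cen <- setdiff(unique(x$censor), CENSOR_LEVELS)
  if (length(bad_cen)) stop("unknown censor flag(s): ", paste(bad_cen, collapse = ", "))

  if (any(!is.finite(x$lod)) || any(x$lod <= 0)) stop("lod must be finite and > 0")
  if (any(!is.finite(x$loq)) || any(x$loq < x$lod)) stop("loq must be finite and >= lod")

  q <- x$censor == "quantified"
  if (any(is.na(x$value[q]))) stop("quantified measurements must carry a value")
  if (any(x$value[q] < 0, na.rm = TRUE)) stop("negative concentration value")
  if (any(x$value[q] < x$loq[q])) {
    stop("quantified value below its LOQ; flag it below_LOQ instead")
  }
  if (any(!is.na(x$value[!q]))) {
    stop("censored measurements must not store a raw value")
  }

  # exactly one measurement per element per sample
  tab <- table(x$sample_id, x$element)
  if (any(tab != 1L) || ncol(tab) != length(PROPOLIS_ELEMENTS)) {
    stop("each sample must have exactly one measurement per element (",
         paste(PROPOLIS_ELEMENTS, collapse = ", "), ")")
  }
  site_per_id <- tapply(x$site, x$sample_id, function(s) length(unique(s)))
  if (any(site_per_id != 1L)) stop("inconsistent site label within a sample")

  # canonical ordering: sample then element
  x <- x[order(match(x$sample_id, unique(x$sample_id)),
               match(x$element, PROPOLIS_ELEMENTS)), ]
  rownames(x) <- NULL
  class(x) <- c("propolis_samples", "data.frame")
  x
}

#' @export
print.propolis_samples <- function(x, ...) {
  ids <- unique(x$sample_id)
  cat(sprintf("<propolis_samples> %d samples x %d elements\n",
              length(ids), length(PROPOLIS_ELEMENTS)))
  cen <- table(x$censor)[CENSOR_LEVELS]
  cen[is.na(cen)] <- 0
  cat(sprintf("  censoring: %d quantified, %d below LOQ, %d below LOD\n",
              cen[[1]], cen[[2]], cen[[3]]))
  NextMethod()
}

#' Number of samples in a collection
#' @param samples A `propolis_samples` object.
#' @return Integer count of distinct samples.
#' @export
n_samples <- function(samples) length(unique(samples$sample_id))

#' Substitute numeric values for left-censored measurements
#'
#' Left-censored ICP-OES results (below LOD or below LOQ) carry no raw
#' value; downstream numeric work (summaries, chemometrics, dose
#' computation) requires a substitution rule. Vectorized over
#' measurements; quantified values pass through unchanged.
#'
#' @param value Numeric concentrations (ppm), `NA` where censored.
#' @param censor Censor flags (`"quantified"`, `"below_LOQ"`,
#'   `"below_LOD"`).
#' @param lod,loq Detection and quantification limits (ppm).
#' @param policy Substitution rule for censored entries: `"zero"` (0),
#'   `"half_lod"` (LOD/2), `"lod"` (LOD), or `"half_loq"` (LOQ/2).
#' @return Numeric vector of concentrations with no `NA`.
#' @examples
#' substitute_censored(NA, "below_LOQ", lod = 0.0028, loq = 0.008,
#'                     policy = "half_loq") # 0.004
#' @export
substitute_censored <- function(value, censor, lod, loq,
                                policy = c("zero", "half_lod", "lod", "half_loq")) {
  policy <- match.arg(policy)
  sub <- switch(policy,
                zero = 0 * lod,
                half_lod = lod / 2,
                lod = lod,
                half_loq = loq / 2)
  out <- ifelse(censor == "quantified", value, sub)
  if (any(!is.finite(out))) stop("non-finite substituted concentration")
  out
}

#' Sample-by-element concentration matrix
#'
#' Pivots a collection to a numeric matrix (rows = samples, columns =
#' elements) with censored cells filled per the substitution policy.
#'
#' @param samples A `propolis_samples` object.
#' @inheritParams substitute_censored
#' @return Numeric matrix with sample ids as rownames and elements as
#'   colnames.
#' @export
concentration_matrix <- function(samples, policy = "half_loq") {
  v <- substitute_censored(samples$value, samples$censor,
                           samples$lod, samples$loq, policy)
  ids <- unique(samples$sample_id)
  m <- matrix(NA_real_, nrow = length(ids), ncol = length(PROPOLIS_ELEMENTS),
              dimnames = list(ids, PROPOLIS_ELEMENTS))
  m[cbind(match(samples$sample_id, ids),
          match(samples$element, PROPOLIS_ELEMENTS))] <- v
  m
}

#' Read a propolis concentration table from CSV
#'
#' Expects a wide comma-separated, UTF-8 table with a header row: columns
#' `sample_id`, `site`, then one value column per element (`As`, `Cd`,
#' `Pb`, `Mn`). Value cells are either a plain decimal number (decimal
#' point, ppm) or one of the censoring tokens `"<LOD"` / `"<LOQ"`.
#' Detection and quantification limits are attached from the QC table.
#'
#' @param path Path to the CSV file.
#' @param qc QC table providing per-element `lod`/`loq`
#'   (default [reference_qc()]).
#' @return A `propolis_samples` object. An empty (header-only) file
#'   yields an empty collection with a warning.
#' @seealso [write_samples()] for the inverse.
#' @export
read_samples <- function(path, qc = reference_qc()) {
  if (!file.exists(path)) stop_io("samples file not found: ", path)
  qc <- validate_qc_table(qc)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  check.names = FALSE)
  miss <- setdiff(c("sample_id", "site", PROPOLIS_ELEMENTS), names(raw))
  if (length(miss)) {
    stop_io("samples file ", path, " is missing column(s): ",
            paste(miss, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    warning("samples file ", path, " contains no rows")
    return(empty_samples())
  }
  if (anyDuplicated(raw$sample_id)) {
    stop("duplicate sample_id in ", path, ": ",
         paste(unique(raw$sample_id[duplicated(raw$sample_id)]), collapse = ", "))
  }
  long <- do.call(rbind, lapply(PROPOLIS_ELEMENTS, function(el) {
    tok <- trimws(raw[[el]])
    censor <- ifelse(tok == "<LOD", "below_LOD",
                     ifelse(tok == "<LOQ", "below_LOQ", "quantified"))
    value <- suppressWarnings(as.numeric(tok))
    value[censor != "quantified"] <- NA_real_
    if (any(censor == "quantified" & is.na(value))) {
      stop("non-numeric ", el, " value in ", path, ": ",
           paste(tok[censor == "quantified" & is.na(value)], collapse = ", "))
    }
    if (any(value < 0, na.rm = TRUE)) stop("negative ", el, " value in ", path)
    qrow <- qc[qc$element == el, ]
    data.frame(sample_id = raw$sample_id, site = raw$site, element = el,
               value = value, censor = censor,
               lod = qrow$lod, loq = qrow$loq, stringsAsFactors = FALSE)
  }))
  as_propolis_samples(long)
}

empty_samples <- function() {
  structure(
    data.frame(sample_id = character(), site = character(),
               element = character(), value = numeric(),
               censor = character(), lod = numeric(), loq = numeric(),
               stringsAsFactors = FALSE),
    class = c("propolis_samples", "data.frame")
  )
}

#' Write a propolis concentration table to CSV
#'
#' Inverse of [read_samples()]: writes the wide CSV dialect with
#' `"<LOD"`/`"<LOQ"` tokens for censored cells and full-precision
#' decimal values, so that write-then-read round-trips exactly.
#'
#' @param samples A `propolis_samples` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  ids <- unique(samples$sample_id)
  site <- samples$site[match(ids, samples$sample_id)]
  wide <- data.frame(sample_id = ids, site = site, stringsAsFactors = FALSE)
  for (el in PROPOLIS_ELEMENTS) {
    rows <- samples[samples$element == el, ]
    rows <- rows[match(ids, rows$sample_id), ]
    tok <- ifelse(rows$censor == "below_LOD", "<LOD",
                  ifelse(rows$censor == "below_LOQ", "<LOQ",
                         vapply(rows$value, format, "", digits = 17)))
    wide[[el]] <- tok
  }
  write.csv(wide, path, row.names = FALSE)
  invisible(path)
}
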