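# Build a fully quantified propolis_samples object from a numeric
# sample-by-element matrix (rownames = ids). Tiny LOD/LOQ so any
# positive value validates as quantified.
samples_from_matrix <- function(m, site = "toy", lod = 1e-09, loq = 2e-09) {
  stopifnot(identical(colnames(m), PROPOLIS_ELEMENTS))
  ids <- rownames(m) %||% sprintf("T%02d", seq_len(nrow(m)))
  long <- do.call(rbind, lapply(PROPOLIS_ELEMENTS, function(el) {
    data.frame(sample_id = ids, site = site, element = el,
               value = m[, el], censor = "quantified",
               lod = lod, loq = loq, stringsAsFactors = FALSE)
  }))
  as_propolis_samples(long)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random positive toy matrix with standard element columns.
random_toy_matrix <- function(n, seed) {
  set.seed(seed)
  m <- matrix(exp(rnorm(n * 4)), n, 4,
              dimnames = list(sprintf("T%02d", seq_len(n)), PROPOLIS_ELEMENTS))
  m
}
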