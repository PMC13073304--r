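#' Pearson correlation report for the element matrix
#'
#' Computes the element-by-element Pearson correlation matrix of the
#' substituted concentration matrix and classifies each pair:
#' `high` when r > 0.5, `moderate` when 0.3 <= r <= 0.5, `weak`
#' otherwise (the classification is one-sided; strong negative
#' correlations also fall in `weak`, which matches how trace-element
#' source studies read these bands). Pairs involving a zero-variance
#' element are labelled `undefined` with a warning.
#'
#' @param samples A `propolis_samples` object with at least 3 samples.
#' @param policy Censoring substitution policy (see
#'   [substitute_censored()]); default `"half_loq"`, the package's
#'   summary-statistics convention.
#' @return An object of class `correlation_report`: list with `matrix`
#'   (4 x 4 Pearson r) and `labels` (data.frame `element_a`,
#'   `element_b`, `r`, `label` for the six unordered pairs).
#' @export
correlation_report <- function(samples, policy = "half_loq") {
  if (n_samples(samples) < 3L) stop("correlation requires at least 3 samples")
  m <- concentration_matrix(samples, policy)
  sds <- apply(m, 2, stats::sd)
  degenerate <- names(sds)[sds == 0]
  if (length(degenerate)) {
    warning("zero-variance element(s): ", paste(degenerate, collapse = ", "),
            "; their pairs are labelled undefined")
  }
  cm <- suppressWarnings(cor(m))
  diag(cm) <- 1
  pairs <- utils::combn(colnames(m), 2)
  labels <- data.frame(element_a = pairs[1, ], element_b = pairs[2, ],
                       r = cm[t(pairs)], stringsAsFactors = FALSE)
  labels$label <- classify_correlation(labels$r)
  labels$label[labels$element_a %in% degenerate |
                 labels$element_b %in% degenerate] <- "undefined"
  structure(list(matrix = cm, labels = labels), class = "correlation_report")
}

classify_correlation <- function(r) {
  ifelse(is.na(r), "undefined",
         ifelse(r > 0.5, "high",
                ifelse(r >= 0.3, "moderate", "weak")))
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("Correlation report (Pearson):\n")
  print(round(x$matrix, 3))
  cat("\nPair classification (high: r > 0.5; moderate: 0.3 <= r <= 0.5):\n")
  print(x$labels, row.names = FALSE)
  invisible(x)
}

#' Principal component analysis of the element matrix
#'
#' PCA of the substituted sample-by-element matrix. By default the
#' matrix is standardized (correlation-matrix PCA), appropriate because
#' the four elements span roughly three orders of magnitude in ppm.
#' Components are ordered by decreasing explained variance, and each
#' loading vector is sign-fixed so that its largest-magnitude entry is
#' positive, making outputs reproducible across platforms.
#'
#' @param samples A `propolis_samples` object with at least 3 samples.
#' @param policy Censoring substitution policy; default `"half_loq"`.
#' @param standardize Scale each element to unit variance (default
#'   `TRUE`). With `standardize = TRUE` a constant element column is an
#'   error (named in the message).
#' @return An object of class `pca_result`: list with
#'   `explained_variance_pct` (per component, sums to 100), `loadings`
#'   (element x component), `scores` (sample x component).
#' @export
run_pca <- function(samples, policy = "half_loq", standardize = TRUE) {
  if (n_samples(samples) < 3L) stop("PCA requires at least 3 samples")
  m <- concentration_matrix(samples, policy)
  if (standardize) {
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0)) {
      stop("constant column(s) cannot be standardized: ",
           paste(names(sds)[sds == 0], collapse = ", "))
    }
  }
  p <- prcomp(m, center = TRUE, scale. = standardize)
  loadings <- p$rotation
  scores <- p$x
  for (j in seq_len(ncol(loadings))) {
    k <- which.max(abs(loadings[, j]))
    if (loadings[k, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  var_pct <- 100 * p$sdev^2 / sum(p$sdev^2)
  structure(
    list(explained_variance_pct = setNames(var_pct, colnames(loadings)),
         loadings = loadings, scores = scores),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA of element concentrations:\n")
  cat("  explained variance (%):",
      paste(sprintf("%s %.1f", names(x$explained_variance_pct),
                    x$explained_variance_pct), collapse = ", "), "\n")
  cat("  loadings:\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Ward hierarchical clustering of samples
#'
#' Agglomerative clustering of samples using Ward's minimum-variance
#' criterion on Euclidean distances of the (optionally z-scored)
#' concentration matrix. The agglomeration is an explicit Lance-Williams
#' recursion: at each step every active cluster pair is scanned and the
#' pair with the smallest Ward distance is merged, ties broken by the
#' lowest-index pair. Merge heights are on the Euclidean distance scale
#' (the height of a two-singleton merge equals their point distance) and
#' are guaranteed non-decreasing.
#'
#' @param samples A `propolis_samples` object with at least 2 samples
#'   and unique sample ids.
#' @param policy Censoring substitution policy; default `"half_loq"`.
#' @param normalize z-score each element before computing distances
#'   (default `TRUE`); without it Pb's range dominates the geometry.
#' @return An object of classes `ward_dendrogram` and `hclust`
#'   (compatible with [stats::cutree()], [stats::cophenetic()],
#'   [ape::as.phylo()]).
#' @export
ward_cluster <- function(samples, policy = "half_loq", normalize = TRUE) {
  if (any(table(samples$sample_id, samples$element) > 1L)) {
    stop("duplicate sample ids")
  }
  m <- concentration_matrix(samples, policy)
  if (nrow(m) < 2L) stop("clustering requires at least 2 samples")
  if (normalize) {
    sds <- apply(m, 2, stats::sd)
    sds[sds == 0] <- 1   # constant column carries no distance information
    m <- scale(m, center = TRUE, scale = sds)
  }
  ward_linkage(as.matrix(m))
}

# Lance-Williams Ward agglomeration on squared Euclidean distances.
# Heights are reported as sqrt(S) so a first merge of two singletons
# sits at their Euclidean distance.
ward_linkage <- function(x) {
  n <- nrow(x)
  labels <- rownames(x) %||% as.character(seq_len(n))
  S <- as.matrix(dist(x))^2
  size <- rep(1L, n)
  node <- -seq_len(n)            # hclust convention: negatives are leaves
  active <- seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    best <- c(NA_integer_, NA_integer_)
    best_d <- Inf
    for (a in seq_along(active)[-length(active)]) {
      i <- active[a]
      for (b in (a + 1L):length(active)) {
        j <- active[b]
        if (S[i, j] < best_d) {    # strict < keeps the lowest-index pair on ties
          best_d <- S[i, j]
          best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- c(node[i], node[j])
    height[step] <- sqrt(best_d)
    # Lance-Williams update for Ward's criterion (on squared distances)
    ni <- size[i]; nj <- size[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- size[k]
      S[i, k] <- S[k, i] <-
        ((ni + nk) * S[i, k] + (nj + nk) * S[j, k] - nk * S[i, j]) /
        (ni + nj + nk)
    }
    size[i] <- ni + nj
    node[i] <- step
    active <- setdiff(active, j)
  }

  structure(
    list(merge = merge, height = height, order = dendrogram_order(merge),
         labels = labels, method = "ward", dist.method = "euclidean",
         call = match.call()),
    class = c("ward_dendrogram", "hclust")
  )
}

dendrogram_order <- function(merge) {
  rec <- function(i) {
    if (i < 0) return(-i)
    c(rec(merge[i, 1]), rec(merge[i, 2]))
  }
  rec(nrow(merge))
}

#' @export
print.ward_dendrogram <- function(x, ...) {
  cat(sprintf("Ward dendrogram: %d leaves, merge heights %.3g .. %.3g\n",
              length(x$labels), min(x$height), max(x$height)))
  invisible(x)
}

#' Export a dendrogram as Newick
#'
#' Writes the cluster tree in Newick format with sample ids as leaf
#' names and branch lengths derived from merge heights.
#'
#' @param dendrogram A `ward_dendrogram` (or any `hclust`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_newick <- function(dendrogram, path) {
  phy <- ape::as.phylo(stats::as.hclust(dendrogram))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Flag multivariate outlier samples in PCA score space
#'
#' A sample is flagged when the Euclidean distance of its score vector
#' from the score centroid exceeds `k` times the median such distance.
#' With all-identical rows every distance is zero and nothing is
#' flagged.
#'
#' @param pca A [run_pca()] result.
#' @param k Distance multiplier (default 2).
#' @return Character vector of flagged sample ids (possibly empty).
#' @export
flag_outliers <- function(pca, k = 2) {
  stopifnot(inherits(pca, "pca_result"), k > 0)
  s <- pca$scores
  centroid <- colMeans(s)
  d <- sqrt(rowSums(sweep(s, 2, centroid)^2))
  names(d)[d > k * median(d)]
}
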