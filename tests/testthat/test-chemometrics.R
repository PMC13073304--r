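test_that("correlation report is symmetric with unit diagonal and banded labels", {
  for (seed in 1:5) {
    s <- samples_from_matrix(random_toy_matrix(8, seed))
    cr <- correlation_report(s)
    expect_equal(cr$matrix, t(cr$matrix))
    expect_equal(unname(diag(cr$matrix)), rep(1, 4))
    expect_true(all(abs(cr$matrix) <= 1 + 1e-12))
  }
  # band classification: high > 0.5, moderate in [0.3, 0.5], weak otherwise
  expect_equal(propolistox:::classify_correlation(c(0.80, 0.51, 0.5, 0.4,
                                                    0.3, 0.29, -0.8)),
               c("high", "high", "moderate", "moderate", "moderate",
                 "weak", "weak"))
})

test_that("identical columns correlate at 1; zero variance is undefined", {
  m <- random_toy_matrix(6, 2)
  m[, "Mn"] <- m[, "Cd"]  # identical columns
  cr <- correlation_report(samples_from_matrix(m))
  expect_equal(cr$matrix["Cd", "Mn"], 1)
  expect_equal(cr$labels$label[cr$labels$element_a == "Cd" &
                                 cr$labels$element_b == "Mn"], "high")

  m[, "As"] <- 5  # constant column
  expect_warning(cr2 <- correlation_report(samples_from_matrix(m)),
                 "zero-variance")
  as_pairs <- cr2$labels$element_a == "As" | cr2$labels$element_b == "As"
  expect_true(all(cr2$labels$label[as_pairs] == "undefined"))
})

test_that("PCA matches an independent eigen-decomposition oracle", {
  m <- random_toy_matrix(5, 4)
  s <- samples_from_matrix(m)
  pca <- run_pca(s, standardize = TRUE)

  # oracle: direct eigen solve of the correlation matrix
  e <- eigen(cor(m), symmetric = TRUE)
  expect_equal(unname(pca$explained_variance_pct),
               100 * e$values / sum(e$values), tolerance = 1e-10)
  for (j in 1:4) {
    v <- e$vectors[, j]
    if (v[which.max(abs(v))] < 0) v <- -v  # same sign convention
    expect_equal(unname(pca$loadings[, j]), v, tolerance = 1e-8)
  }

  # scores are the projections of the standardized data
  z <- scale(m)
  expect_equal(unname(pca$scores), unname(z %*% pca$loadings),
               tolerance = 1e-8)
})

test_that("PCA conserves variance, decorrelates scores, fixes signs", {
  for (seed in 1:10) {
    s <- samples_from_matrix(random_toy_matrix(7, seed + 100))
    pca <- run_pca(s)
    expect_equal(sum(pca$explained_variance_pct), 100, tolerance = 1e-9)
    expect_true(all(pca$explained_variance_pct >= 0))
    expect_true(all(diff(pca$explained_variance_pct) <= 1e-12))
    # scores' covariance is diagonal
    cv <- crossprod(scale(pca$scores, scale = FALSE)) / (7 - 1)
    expect_equal(cv, diag(diag(cv), 4), ignore_attr = TRUE,
                 tolerance = 1e-10)
    # sign convention: largest-magnitude loading entry positive
    for (j in 1:4) {
      l <- pca$loadings[, j]
      expect_gte(l[which.max(abs(l))], 0)
    }
  }
})

test_that("rank-1 structure loads PC1 with all the variance", {
  m <- random_toy_matrix(6, 3)
  base <- log(m[, "Cd"])
  for (el in PROPOLIS_ELEMENTS) m[, el] <- exp(base) * c(As = 1, Cd = 2, Pb = 3, Mn = 4)[el]
  pca <- run_pca(samples_from_matrix(m), standardize = TRUE)
  expect_equal(unname(pca$explained_variance_pct[1]), 100, tolerance = 1e-9)
})

test_that("PCA errors on a constant column when standardizing", {
  m <- random_toy_matrix(5, 6)
  m[, "Pb"] <- 1.5
  expect_error(run_pca(samples_from_matrix(m), standardize = TRUE), "Pb")
  expect_silent(run_pca(samples_from_matrix(m), standardize = FALSE))
})

test_that("Ward clustering agrees with the hclust ward.D2 oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(4:9, 1)
    x <- matrix(rnorm(n * 3), n, 3,
                dimnames = list(sprintf("s%02d", 1:n), NULL))
    mine <- propolistox:::ward_linkage(x)
    ref <- stats::hclust(dist(x), method = "ward.D2")
    # cophenetic distances are invariant to merge-ordering conventions
    co_m <- as.matrix(stats::cophenetic(mine))[rownames(x), rownames(x)]
    co_r <- as.matrix(stats::cophenetic(ref))[rownames(x), rownames(x)]
    expect_equal(co_m, co_r, tolerance = 1e-10)
  }
})

test_that("Ward merge heights are non-decreasing on 200 random datasets", {
  for (seed in 1:200) {
    set.seed(seed)
    x <- matrix(rnorm(8 * 3), 8, 3)
    h <- propolistox:::ward_linkage(x)
    expect_true(all(diff(h$height) >= -1e-12))
  }
})

test_that("identical rows merge first at height zero; ties break low-index", {
  m <- random_toy_matrix(5, 8)
  m[4, ] <- m[2, ]  # duplicate pair among 5
  h <- ward_cluster(samples_from_matrix(m), normalize = FALSE)
  expect_equal(h$height[1], 0)
  expect_setequal(h$merge[1, ], c(-2L, -4L))

  # two equidistant candidate pairs: the lowest-index pair merges first
  x <- matrix(c(0, 5, 10, 10.5, 20, 20.5), ncol = 1)
  ht <- propolistox:::ward_linkage(x)
  expect_equal(sort(ht$merge[1, ]), c(-4L, -3L))  # pair (3,4) before (5,6)

  dup <- samples_from_matrix(m)
  dup$sample_id[dup$sample_id == "T04"] <- "T02"
  expect_error(ward_cluster(structure(dup, class = c("propolis_samples",
                                                     "data.frame"))),
               "duplicate|exactly one")
})

test_that("fixture Pb outlier sites co-cluster and are flagged, any seed", {
  for (seed in c(1, 7, 33, 99)) {
    fx <- build_paper_fixture(seed)
    # raw-scale geometry: the two gross Pb contamination sites dominate
    ct <- stats::cutree(ward_cluster(fx, normalize = FALSE), k = 3)
    expect_equal(ct[["P06"]], ct[["P10"]])
    expect_equal(sum(ct == ct[["P06"]]), 2L)

    fl <- flag_outliers(run_pca(fx, standardize = FALSE))
    expect_true(all(c("P06", "P10") %in% fl))
  }
})

test_that("outlier flagging is empty for identical rows, catches gross spikes", {
  m <- matrix(1, 6, 4, dimnames = list(sprintf("T%02d", 1:6),
                                       PROPOLIS_ELEMENTS))
  pca <- run_pca(samples_from_matrix(m), standardize = FALSE)
  expect_length(flag_outliers(pca), 0)

  # single gross outlier injected by the generator is flagged
  sp <- generator_spec(
    n_samples = 20,
    meanlog = c(As = 0, Cd = 0, Pb = 0, Mn = 0),
    sdlog = c(As = 0.3, Cd = 0.3, Pb = 0.3, Mn = 0.3),
    correlation = diag(4),
    outliers = data.frame(sample = 7L, element = "Pb", multiplier = 100),
    seed = 4
  )
  g <- generate_samples(sp)
  fl <- flag_outliers(run_pca(g, policy = "half_loq", standardize = FALSE))
  expect_true("S007" %in% fl)
  # verify by direct distance computation
  sc <- run_pca(g, standardize = FALSE)$scores
  d <- sqrt(rowSums(sweep(sc, 2, colMeans(sc))^2))
  expect_identical(names(which(d > 2 * median(d))), fl)
})

test_that("dendrograms export to Newick with all leaves", {
  fx <- build_paper_fixture(1)
  h <- ward_cluster(fx)
  path <- withr::local_tempfile(fileext = ".nwk")
  export_newick(h, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, unique(fx$sample_id))
})
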