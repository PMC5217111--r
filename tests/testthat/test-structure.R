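floored_fixture <- function(n_genes = 30, seed = 22) {
  set.seed(seed)
  mat <- matrix(exp(rnorm(n_genes * 8, log(100), 1)), n_genes, 8)
  cm <- make_counts(mat, HYPOXIA_TIMES)
  cm$counts <- floor_values(cm$counts)
  cm
}

test_that("time-point PCA satisfies its variance and geometry contracts", {
  cm <- floored_fixture()
  pc <- pca_timepoints(cm$counts, cm$samples, input = "log2_counts")
  expect_equal(sum(pc$variance_fraction), 1, tolerance = 1e-9)
  # loadings columns orthonormal
  ltl <- crossprod(pc$loadings)
  expect_equal(ltl, diag(ncol(pc$loadings)), tolerance = 1e-9,
               ignore_attr = TRUE)
  # retained scores reproduce pairwise Euclidean distances between rows
  m <- t(log2(as.matrix(cm$counts[-1])))
  sc <- as.matrix(pc$scores[grep("^PC", names(pc$scores))])
  expect_equal(as.matrix(dist(sc)), as.matrix(dist(m)), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("PCA handles rank-1 and duplicated-time-point structure", {
  # two perfectly correlated genes: PC1 captures everything
  mat <- rbind(20 * 2^(0:7), 40 * 2^(0:7))
  cm2 <- make_counts(mat, HYPOXIA_TIMES, gene_ids = c("a", "b"))
  pc <- pca_timepoints(cm2$counts, cm2$samples, input = "log2_counts")
  expect_equal(pc$variance_fraction[1], 1, tolerance = 1e-9)

  # duplicated time-point rows give coincident scores
  dup <- make_counts(cbind(c(20, 40), c(20, 40), c(80, 20), c(60, 30)),
                     c(0, 5, 10, 30), gene_ids = c("a", "b"))
  pcd <- pca_timepoints(dup$counts, dup$samples, input = "log2_counts")
  s <- as.matrix(pcd$scores[grep("^PC", names(pcd$scores))])
  expect_equal(s[1, ], s[2, ], tolerance = 1e-9)

  # constant matrix: variance undefined
  cst <- make_counts(matrix(20, 3, 4), c(0, 5, 10, 30))
  expect_error(pca_timepoints(cst$counts, cst$samples, input = "log2_counts"),
               "constant")
})

test_that("PCA variance fractions match an eigen-decomposition oracle", {
  m <- matrix(c(1, 4, 2, 8,
                3, 1, 7, 2,
                2, 6, 4, 9), nrow = 4)
  cm <- make_counts(t(2^m * 20), c(0, 5, 10, 30))
  pc <- pca_timepoints(cm$counts, cm$samples, input = "log2_counts")
  centered <- sweep(m + log2(20), 2, colMeans(m + log2(20)))
  ev <- eigen(crossprod(centered), symmetric = TRUE)$values
  expect_equal(pc$variance_fraction[seq_along(ev)] , ev / sum(ev),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("tidy and glance views of the PCA are consistent", {
  cm <- floored_fixture()
  pc <- pca_timepoints(cm$counts, cm$samples)
  td <- tidy(pc, "scores")
  expect_true(all(c("sample_id", "component", "score") %in% names(td)))
  gl <- glance(pc)
  expect_equal(gl$pc1_variance, pc$variance_fraction[1])
  expect_equal(nrow(tidy(pc, "variance")), length(pc$variance_fraction))
  expect_s3_class(autoplot(pc), "ggplot")
})

test_that("Euclidean distances follow the direct formula", {
  cm <- make_counts(cbind(c(20, 20), c(20 * 2^3, 20 * 2^4)), c(0, 5),
                    gene_ids = c("a", "b"))
  d <- euclidean_distance_matrix(cm$counts, cm$samples, input = "log2_ratio")
  expect_equal(unname(diag(d)), c(0, 0))
  expect_equal(d[1, 2], 5)  # log2 ratios (0,0) vs (3,4)
  # triangle inequality on random matrices
  set.seed(23)
  for (i in 1:25) {
    cm <- floored_fixture(n_genes = 10, seed = 100 + i)
    d <- euclidean_distance_matrix(cm$counts, cm$samples, "log2_counts")
    expect_equal(d, t(d))
    for (a in 1:3) for (b in 4:6) for (cc in 7:8) {
      expect_lte(d[a, b], d[a, cc] + d[cc, b] + 1e-12)
    }
  }
})

test_that("uncentered correlation is cosine-like and scale-invariant", {
  expect_equal(uncentered_correlation(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(uncentered_correlation(c(1, 0), c(0, 1)), 0)
  x <- c(1, -2, 3)
  y <- c(2, 1, -1)
  expect_equal(uncentered_correlation(5 * x, y), uncentered_correlation(x, y))
  expect_error(uncentered_correlation(c(0, 0), c(1, 2)), "zero vector")
  expect_gte(uncentered_correlation(x, y), -1)
  expect_lte(uncentered_correlation(x, y), 1)
})

test_that("UPGMA reproduces the three-item hand computation", {
  d <- matrix(c(0, 0.1, 0.5,
                0.1, 0, 0.5,
                0.5, 0.5, 0), 3, 3)
  hc <- oxytime:::upgma_tree(d, labels = c("g1", "g2", "g3"))
  expect_equal(hc$height, c(0.1, 0.5))
  expect_equal(hc$merge[1, ], c(-2L, -1L))
  expect_equal(sort(hc$merge[2, ]), c(-3L, 1L))
})

test_that("identical profiles merge at height zero", {
  m <- rbind(c(1, 2, 3), c(2, 4, 6), c(5, 1, 0))  # rows 1,2 parallel
  hc <- average_linkage_cluster(m, metric = "uncentered")
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
})

test_that("UPGMA heights are monotone and match brute force / hclust", {
  set.seed(24)
  for (i in 1:5) {
    m <- matrix(rnorm(20 * 6), 20, 6)
    rownames(m) <- sprintf("g%02d", 1:20)
    hc <- average_linkage_cluster(m, metric = "uncentered")
    expect_true(all(diff(hc$height) >= -1e-12))
    d <- oxytime:::uncentered_distance_matrix(m)
    expect_equal(hc$height, brute_force_upgma_heights(d), tolerance = 1e-9)
    # independent route: stats::hclust average linkage, same distances
    ref <- stats::hclust(as.dist(d), method = "average")
    expect_equal(cophenetic(hc), cophenetic(ref), tolerance = 1e-9)
  }
})

test_that("UPGMA output is invariant to input row order", {
  set.seed(25)
  m <- matrix(rnorm(12 * 5), 12, 5)
  rownames(m) <- sprintf("g%02d", 1:12)
  hc1 <- average_linkage_cluster(m)
  perm <- sample(12)
  hc2 <- average_linkage_cluster(m[perm, ])
  expect_equal(as.matrix(cophenetic(hc1))[rownames(m), rownames(m)],
               as.matrix(cophenetic(hc2))[rownames(m), rownames(m)],
               tolerance = 1e-12)
})

test_that("dendrograms export to Newick and read back intact", {
  skip_if_not_installed("ape")
  set.seed(26)
  m <- matrix(rnorm(8 * 5), 8, 5)
  rownames(m) <- sprintf("g%d", 1:8)
  hc <- average_linkage_cluster(m)
  f <- withr::local_tempfile(fileext = ".newick")
  write_dendrogram_newick(hc, f)
  phy <- ape::read.tree(f)
  expect_setequal(phy$tip.label, rownames(m))
})
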