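# Whole-transcriptome structure: PCA over time points, Euclidean distances
# between samples, and UPGMA clustering of genes with uncentered
# correlation.

# time points x genes input matrix under one of the two log2 conventions
structure_input_matrix <- function(counts, samples,
                                   input = c("log2_ratio", "log2_counts")) {
  input <- match.arg(input)
  samples <- validate_sample_sheet(samples)
  samples <- arrange(samples, .data$time_minutes)
  validate_count_matrix(counts, samples)
  if (input == "log2_ratio") {
    m <- t(count_values(log2_ratio_to_t0(counts, samples)))
  } else {
    vals <- count_values(counts)
    if (any(vals <= 0)) abort("log2 counts need strictly positive values (floor first)")
    m <- t(log2(vals))
  }
  rownames(m) <- samples$sample_id
  m
}

#' Principal component analysis over time points
#'
#' Q-mode PCA (singular value decomposition via [stats::prcomp()]) of the
#' time points x genes matrix of log2 expression. Each gene column is mean
#' centered across time points; no variance scaling. Two input conventions
#' coexist: log2 fold changes to t = 0 (default, the convention behind the
#' headline time-course figure) or log2 of the floored normalized counts.
#' Component signs are arbitrary.
#'
#' @param counts Floored normalized count tibble.
#' @param samples Sample sheet.
#' @param input `"log2_ratio"` (default) or `"log2_counts"`.
#' @return An object of class `oxytime_pca`: `scores` (tibble: `sample_id`,
#'   `time_minutes`, `PC1`, ...), `loadings` (genes x components matrix),
#'   `variance_fraction` (per component, sums to 1), `input`.
#' @export
pca_timepoints <- function(counts, samples,
                           input = c("log2_ratio", "log2_counts")) {
  input <- match.arg(input)
  m <- structure_input_matrix(counts, samples, input)
  if (nrow(m) < 2L || ncol(m) < 2L) abort("need >= 2 time points and >= 2 genes")
  centered <- sweep(m, 2L, colMeans(m))
  if (sum(centered^2) == 0) {
    abort("matrix is constant across time points; variance fractions undefined")
  }
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  samples <- arrange(validate_sample_sheet(samples), .data$time_minutes)
  scores <- bind_cols(
    tibble(sample_id = samples$sample_id, time_minutes = samples$time_minutes),
    as_tibble(pc$x)
  )
  structure(
    list(scores = scores, loadings = pc$rotation,
         variance_fraction = pc$sdev^2 / sum(pc$sdev^2), input = input),
    class = "oxytime_pca"
  )
}

#' @export
print.oxytime_pca <- function(x, ...) {
  vf <- round(100 * x$variance_fraction[1:min(3, length(x$variance_fraction))], 1)
  cat("PCA over", nrow(x$scores), "time points,", nrow(x$loadings), "genes",
      sprintf("(input: %s)\n", x$input))
  cat("Variance captured:", paste0("PC", seq_along(vf), " ", vf, "%",
                                   collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a time-point PCA
#'
#' @param x An `oxytime_pca` object.
#' @param matrix Which component to tidy: `"scores"` (time-point
#'   projections, long format), `"loadings"` (gene loadings, long format)
#'   or `"variance"` (per-component variance fractions).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.oxytime_pca <- function(x, matrix = c("scores", "loadings", "variance"),
                             ...) {
  matrix <- match.arg(matrix)
  if (matrix == "scores") {
    tidyr::pivot_longer(x$scores, cols = dplyr::starts_with("PC"),
                        names_to = "component", values_to = "score")
  } else if (matrix == "loadings") {
    as_tibble(x$loadings, rownames = "gene_id") |>
      tidyr::pivot_longer(cols = dplyr::starts_with("PC"),
                          names_to = "component", values_to = "loading")
  } else {
    tibble(component = paste0("PC", seq_along(x$variance_fraction)),
           variance_fraction = x$variance_fraction)
  }
}

#' One-row summary of a time-point PCA
#'
#' @param x An `oxytime_pca` object.
#' @param ... Unused.
#' @return Tibble with `n_timepoints`, `n_genes`, `pc1_variance`,
#'   `pc2_variance` (fractions).
#' @export
glance.oxytime_pca <- function(x, ...) {
  tibble(n_timepoints = nrow(x$scores), n_genes = nrow(x$loadings),
         pc1_variance = x$variance_fraction[1L],
         pc2_variance = x$variance_fraction[2L])
}

#' Euclidean distances between time-point samples
#'
#' [stats::dist()] on the time points x genes log2 matrix:
#' `d_ij = sqrt(sum_genes (x_i - x_j)^2)`.
#'
#' @inheritParams pca_timepoints
#' @return Symmetric numeric matrix with zero diagonal, labeled by sample
#'   id.
#' @export
euclidean_distance_matrix <- function(counts, samples,
                                      input = c("log2_ratio", "log2_counts")) {
  m <- structure_input_matrix(counts, samples, match.arg(input))
  as.matrix(dist(m))
}

#' Uncentered correlation between two profiles
#'
#' Cosine-type similarity `s = sum(x*y) / sqrt(sum(x^2) * sum(y^2))`, the
#' clustering similarity used with average linkage; the clustering distance
#' is `1 - s`. Scale-invariant for positive rescalings; undefined for an
#' all-zero vector.
#'
#' @param x,y Numeric vectors of equal length, neither all zero.
#' @return Similarity in `[-1, 1]`.
#' @export
uncentered_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  sx <- sum(x^2)
  sy <- sum(y^2)
  if (sx == 0 || sy == 0) abort("uncentered correlation undefined for a zero vector")
  sum(x * y) / sqrt(sx * sy)
}

# pairwise 1 - uncentered correlation, rows of m as items
uncentered_distance_matrix <- function(m) {
  norms <- sqrt(rowSums(m^2))
  if (any(norms == 0)) abort("zero row(s): uncentered correlation undefined")
  s <- tcrossprod(m / norms)
  d <- 1 - s
  d[d < 0] <- 0  # clip negative round-off
  diag(d) <- 0
  d
}

#' Agglomerative UPGMA clustering of gene profiles
#'
#' Average-linkage hierarchical clustering: repeatedly merge the closest
#' pair of clusters, with inter-cluster distance the arithmetic mean of all
#' cross-pair distances. Distance ties are broken by the lexicographically
#' smallest pair of member ids, making the dendrogram reproducible and
#' independent of input row order. Merge heights are nondecreasing (UPGMA
#' is monotone).
#'
#' @param x Genes x time-points numeric matrix with rownames, or a count
#'   tibble (`gene_id` + value columns).
#' @param metric `"uncentered"` (distance `1 -` uncentered correlation,
#'   default) or `"euclidean"`.
#' @return An object of class `hclust` (merge, height, order, labels),
#'   usable with [stats::cophenetic()], [stats::cutree()] and, via
#'   `ape::as.phylo()`, Newick export.
#' @export
average_linkage_cluster <- function(x, metric = c("uncentered", "euclidean")) {
  metric <- match.arg(metric)
  if (is.data.frame(x)) {
    m <- count_values(x)
  } else {
    m <- as.matrix(x)
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("item", seq_len(nrow(m)))
  if (nrow(m) < 2L) abort("need at least 2 items to cluster")
  d <- switch(metric,
              uncentered = uncentered_distance_matrix(m),
              euclidean = as.matrix(dist(m)))
  upgma_tree(d, labels = rownames(m), dist_method = metric)
}

# UPGMA on a full distance matrix with the lexicographic tie-break.
upgma_tree <- function(d, labels, dist_method = "unknown") {
  n <- nrow(d)
  stopifnot(length(labels) == n)
  work <- d
  diag(work) <- Inf
  active <- rep(TRUE, n)
  sizes <- rep(1, n)
  minlab <- labels              # lexicographically smallest member per cluster
  code <- -seq_len(n)           # hclust coding: negatives are singletons
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- work[idx, idx, drop = FALSE]
    m <- min(sub)
    cand <- which(sub == m, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    if (nrow(cand) > 1L) {
      keys <- apply(cand, 1L, function(rc) {
        l <- sort(c(minlab[idx[rc[1L]]], minlab[idx[rc[2L]]]))
        paste(l, collapse = "\r")
      })
      cand <- cand[order(keys)[1L], , drop = FALSE]
    }
    i <- idx[cand[1L, 1L]]
    j <- idx[cand[1L, 2L]]
    merge[s, ] <- sort(c(code[i], code[j]))
    height[s] <- m
    # average-linkage (Lance-Williams) update into slot i
    newd <- (sizes[i] * work[i, ] + sizes[j] * work[j, ]) / (sizes[i] + sizes[j])
    work[i, ] <- newd
    work[, i] <- newd
    work[i, i] <- Inf
    active[j] <- FALSE
    work[j, ] <- Inf
    work[, j] <- Inf
    sizes[i] <- sizes[i] + sizes[j]
    minlab[i] <- min(minlab[i], minlab[j])
    code[i] <- s
  }
  leaf_order <- integer(0)
  walk <- function(k) {
    for (v in merge[k, ]) {
      if (v < 0L) leaf_order <<- c(leaf_order, -v) else walk(v)
    }
  }
  if (n > 1L) walk(n - 1L)
  structure(
    list(merge = merge, height = height, order = leaf_order,
         labels = labels, method = "average", dist.method = dist_method,
         call = match.call()),
    class = "hclust"
  )
}

#' Write a dendrogram as a Newick tree
#'
#' Converts an `hclust` dendrogram to `phylo` (branch lengths are height
#' differences between nested merges) and writes Newick text.
#'
#' @param hc An `hclust` object (e.g. from [average_linkage_cluster()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("the 'ape' package is required for Newick export")
  }
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
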