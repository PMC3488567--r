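#' Euclidean distances along one axis of an expression matrix
#'
#' Distances between samples are computed across all genes; distances between
#' genes across all samples. No standardisation is applied: the pipeline
#' clusters log2 intensities as-is (z-scoring, when wanted, is done upstream).
#'
#' @param x an [expression_matrix()].
#' @param axis `"samples"` or `"genes"`.
#' @return a `dist` object.
#' @export
euclidean_distances <- function(x, axis = c("samples", "genes")) {
  axis <- match.arg(axis)
  if (anyNA(x) || !all(is.finite(x))) stop("non-finite values in matrix")
  m <- if (axis == "samples") x else t(x)
  stats::dist(m, method = "euclidean")
}

#' Average-linkage (UPGMA) dendrogram
#'
#' Iteratively merges the pair of clusters with minimal mean inter-cluster
#' distance; the distance from a merged cluster to any other is the
#' size-weighted mean of its parts' distances. Merge heights are
#' non-decreasing for metric input.
#'
#' @param d a `dist` object over at least 2 items.
#' @return an `hclust` object (merge matrix, heights, labels).
#' @export
average_linkage <- function(d) {
  if (!inherits(d, "dist")) stop("`d` must be a dist object")
  if (attr(d, "Size") < 2L) stop("need at least 2 items to cluster")
  stats::hclust(d, method = "average")
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the k-1 highest merges; deterministic, with ties resolved by merge
#' order (earlier merges are kept intact).
#'
#' @param tree an `hclust` object.
#' @param k number of clusters, 1..n.
#' @return named integer vector, item id -> cluster index.
#' @export
cut_dendrogram <- function(tree, k) {
  n <- length(tree$labels)
  if (k < 1L || k > n) stop("k must be in 1..", n)
  stats::cutree(tree, k = k)
}

#' Two-way hierarchical clustering over a gene subset
#'
#' Builds the paired trees the heatmap view of the pipeline rests on: a gene
#' dendrogram over `gene_subset` (distances across all samples) and a sample
#' dendrogram over all samples (distances across `gene_subset` only).
#'
#' @param x an [expression_matrix()].
#' @param gene_subset character vector of gene ids, length >= 2; default all.
#' @param set_name label carried along for reporting.
#' @return list with `gene_tree`, `sample_tree` (both `hclust`) and
#'   `set_name`, class `"two_way_clustering"`.
#' @export
two_way_cluster <- function(x, gene_subset = colnames(x), set_name = "all") {
  gene_subset <- unique(gene_subset)
  if (length(gene_subset) < 2L) stop("gene_subset must contain >= 2 genes")
  missing <- setdiff(gene_subset, colnames(x))
  if (length(missing))
    stop("genes not in matrix: ", paste(utils::head(missing, 5), collapse = ", "))
  sub <- x[, gene_subset, drop = FALSE]
  structure(list(
    gene_tree   = average_linkage(euclidean_distances(sub, "genes")),
    sample_tree = average_linkage(euclidean_distances(sub, "samples")),
    set_name    = set_name), class = "two_way_clustering")
}
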