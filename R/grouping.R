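#' Parameters of the pathway-anchored grouping pipeline
#'
#' @param min_set_size pathway sets must have strictly more covered genes
#'   than this to enter the pipeline (150; 20 is the exploratory floor).
#' @param max_clusters_per_set representative gene clusters kept per set.
#' @param min_cluster_genes smallest candidate gene subtree considered.
#' @param max_cluster_frac largest candidate subtree, as a fraction of the
#'   set (caps degenerate near-whole-set candidates).
#' @param min_score candidate gene clusters must score strictly above this
#'   adjusted Rand index against the reference partition to be selected; the
#'   default sits well above chance-level ARI fluctuation (~0.03 at n = 146)
#'   and well below the scores of genuinely representative clusters
#'   (0.3-0.8), so structure-free sets yield empty selections. Set to 0 to
#'   accept any positive score.
#' @param k_groups clusters to cut sample trees into (4 with cell lines,
#'   3 tumor-only).
#' @param n_random_sets,random_set_size stability resampling: number and
#'   size of the random gene subsets re-clustered against the assignment.
#' @param seed integer seed for the random draws.
#' @return list of class `"grouping_params"`.
#' @export
grouping_params <- function(min_set_size = 150L, max_clusters_per_set = 4L,
                            min_cluster_genes = 5L, max_cluster_frac = 0.8,
                            min_score = 0.1,
                            k_groups = 4L, n_random_sets = 5L,
                            random_set_size = 660L, seed = 1L) {
  p <- list(min_set_size = as.integer(min_set_size),
            max_clusters_per_set = as.integer(max_clusters_per_set),
            min_cluster_genes = as.integer(min_cluster_genes),
            max_cluster_frac = max_cluster_frac,
            min_score = min_score,
            k_groups = as.integer(k_groups),
            n_random_sets = as.integer(n_random_sets),
            random_set_size = as.integer(random_set_size),
            seed = as.integer(seed))
  stopifnot(p$k_groups >= 2L, p$min_cluster_genes >= 1L,
            p$max_clusters_per_set >= 0L, p$n_random_sets >= 0L)
  structure(p, class = "grouping_params")
}

# all leaf-label sets of internal dendrogram nodes with size in [lo, hi]
subtree_members <- function(tree, lo, hi) {
  n <- length(tree$labels)
  members <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    mem <- integer(0)
    for (j in 1:2) {
      node <- tree$merge[i, j]
      mem <- c(mem, if (node < 0) -node else members[[node]])
    }
    members[[i]] <- mem
  }
  sizes <- lengths(members)
  keep <- which(sizes >= lo & sizes <= hi)
  lapply(members[keep], function(m) tree$labels[m])
}

#' Select gene clusters that best represent the overall sample clustering
#'
#' Operationalises the visual "best represented the overall array
#' clustering" criterion: every internal node of the gene dendrogram with
#' `min_cluster_genes` to `max_cluster_frac * |set|` members is a candidate;
#' each is scored by the adjusted Rand index between the k-group cut of a
#' sample clustering computed on the candidate's genes alone and the
#' reference partition from the full matrix. Up to `max_clusters_per_set`
#' disjoint candidates scoring above `min_score` are returned, greedily by
#' score.
#'
#' @param x an [expression_matrix()].
#' @param twoway a [two_way_cluster()] result for one gene set.
#' @param reference_partition named cluster vector over all samples (the
#'   k-group cut of the full-matrix sample tree).
#' @param params a [grouping_params()].
#' @return list of character vectors (gene clusters), best first, with
#'   attribute `scores`; empty when no candidate scores above `min_score` —
#'   the expected outcome for small, structure-free gene sets.
#' @export
select_representative_clusters <- function(x, twoway, reference_partition,
                                           params = grouping_params()) {
  if (params$max_clusters_per_set == 0L) return(list())
  genes <- twoway$gene_tree$labels
  hi <- max(params$min_cluster_genes,
            floor(params$max_cluster_frac * length(genes)))
  cands <- subtree_members(twoway$gene_tree, params$min_cluster_genes, hi)
  if (!length(cands)) return(list())
  scores <- vapply(cands, function(g) {
    part <- cut_dendrogram(
      average_linkage(euclidean_distances(x[, g, drop = FALSE], "samples")),
      params$k_groups)
    adjusted_rand_index(part, reference_partition)
  }, numeric(1))
  ord <- order(scores, decreasing = TRUE)
  selected <- list(); sel_scores <- numeric(0); used <- character(0)
  for (i in ord) {
    if (scores[i] <= params$min_score) break
    if (length(selected) >= params$max_clusters_per_set) break
    if (length(intersect(cands[[i]], used))) next
    selected[[length(selected) + 1L]] <- cands[[i]]
    sel_scores <- c(sel_scores, scores[i])
    used <- c(used, cands[[i]])
  }
  attr(selected, "scores") <- sel_scores
  selected
}

# map cut clusters to A/B/C/CELL_LINE labels (labels are conventional):
# CELL_LINE = majority cell-line cluster; B = most distant tumor cluster by
# mean cophenetic distance to the others; of the remaining two, A = the
# tighter cluster (smaller mean intra-cluster cophenetic distance).
label_clusters <- function(part, tree, annotation = NULL,
                           override = NULL) {
  ids <- names(part)
  ks <- sort(unique(part))
  if (!is.null(override)) {
    lab <- override[as.character(part)]
    names(lab) <- ids
    return(lab)
  }
  coph <- as.matrix(stats::cophenetic(tree))[ids, ids]
  remaining <- ks
  out <- stats::setNames(rep(NA_character_, length(part)), ids)
  if (!is.null(annotation)) {
    cl_frac <- vapply(ks, function(k) {
      s <- ids[part == k]
      mean(annotation$sample_class[match(s, annotation$sample_id)] ==
             "cell_line")
    }, numeric(1))
    if (any(cl_frac > 0.5)) {
      kcl <- ks[which.max(cl_frac)]
      out[part == kcl] <- "CELL_LINE"
      remaining <- setdiff(ks, kcl)
    }
  }
  if (length(remaining) > 3L) {
    # no annotation: treat the most separated cluster as CELL_LINE
    sep <- vapply(remaining, function(k)
      mean(coph[part == k, part != k & part %in% remaining]), numeric(1))
    kcl <- remaining[which.max(sep)]
    out[part == kcl] <- "CELL_LINE"
    remaining <- setdiff(remaining, kcl)
  }
  if (length(remaining) >= 1L) {
    if (length(remaining) == 1L) {
      out[part == remaining] <- "A"
    } else {
      dist_out <- vapply(remaining, function(k)
        mean(coph[part == k, part %in% setdiff(remaining, k)]), numeric(1))
      kB <- remaining[which.max(dist_out)]
      out[part == kB] <- "B"
      rest <- setdiff(remaining, kB)
      if (length(rest) == 1L) {
        out[part == rest] <- "A"
      } else {
        tight <- vapply(rest, function(k) {
          m <- coph[part == k, part == k, drop = FALSE]
          if (nrow(m) < 2) 0 else mean(m[upper.tri(m)])
        }, numeric(1))
        kA <- rest[which.min(tight)]
        out[part == kA] <- "A"
        out[part == setdiff(rest, kA)] <- "C"
      }
    }
  }
  out
}

#' Re-cluster samples on the combined representative gene clusters
#'
#' The union of all selected gene clusters (the signature-gene analogue of
#' the pipeline) is re-clustered two-way; the sample tree is cut at
#' `k_groups` and clusters are mapped to the conventional labels A/B/C (and
#' CELL_LINE when annotation identifies a majority cell-line cluster).
#'
#' @param x an [expression_matrix()].
#' @param selected_clusters list of gene-id vectors pooled across sets.
#' @param params a [grouping_params()].
#' @param annotation optional sample annotation (for the CELL_LINE label).
#' @param label_override optional named map cluster-index -> label.
#' @return list of class `"group_assignment"`: `labels` (named vector),
#'   `signature_genes`, `sample_tree`, `params`.
#' @export
combine_and_recluster <- function(x, selected_clusters,
                                  params = grouping_params(),
                                  annotation = NULL, label_override = NULL) {
  union_genes <- unique(unlist(selected_clusters))
  if (length(union_genes) < 2L)
    stop("union of selected clusters has fewer than 2 genes")
  tw <- two_way_cluster(x, union_genes, set_name = "combined")
  part <- cut_dendrogram(tw$sample_tree, params$k_groups)
  labels <- label_clusters(part, tw$sample_tree, annotation, label_override)
  structure(list(labels = labels, signature_genes = union_genes,
                 sample_tree = tw$sample_tree, params = params),
            class = "group_assignment")
}

#' Run the full pathway-anchored grouping pipeline
#'
#' Composes the stages: absent-probe filtering, pathway-set size filtering,
#' a reference sample partition from the full matrix, per-set two-way
#' clustering with representative-cluster selection, and a joint
#' re-clustering of the pooled clusters into the final group assignment.
#'
#' @param x an [expression_matrix()].
#' @param gene_sets named list of gene-id vectors.
#' @param params a [grouping_params()].
#' @param annotation optional sample annotation.
#' @param detection_floor passed to [filter_absent_probes()].
#' @return a `"group_assignment"` (see [combine_and_recluster()]) with an
#'   extra `selection_report` data.frame (set, cluster size, score).
#' @export
run_pathway_grouping <- function(x, gene_sets, params = grouping_params(),
                                 annotation = NULL,
                                 detection_floor = min(x) + 1e-6) {
  x <- filter_absent_probes(x, detection_floor)
  sets <- filter_by_set_size(gene_sets, x, params$min_set_size)
  if (!length(sets))
    stop("no gene set exceeds min_set_size = ", params$min_set_size,
         "; consider the exploratory threshold 20")
  reference <- cut_dendrogram(
    average_linkage(euclidean_distances(x, "samples")), params$k_groups)
  selected <- list()
  report <- list()
  for (nm in names(sets)) {
    tw <- two_way_cluster(x, sets[[nm]], set_name = nm)
    cl <- select_representative_clusters(x, tw, reference, params)
    if (length(cl)) {
      selected <- c(selected, cl)
      report[[nm]] <- data.frame(set = nm, cluster = seq_along(cl),
                                 n_genes = lengths(cl),
                                 score = attr(cl, "scores"))
    }
  }
  if (!length(selected))
    stop("no representative gene clusters found in any set")
  out <- combine_and_recluster(x, selected, params, annotation)
  out$selection_report <- do.call(rbind, c(report, make.row.names = FALSE))
  out
}

#' Stability of a grouping under random gene subsets
#'
#' Draws `n_random_sets` gene subsets of size `random_set_size` uniformly
#' without replacement, clusters the samples on each, cuts at `k_groups`,
#' and returns the adjusted Rand index of each cut against the assignment.
#' High values mean the grouping is carried genome-wide, not only by the
#' signature genes.
#'
#' @param x an [expression_matrix()].
#' @param assignment a `"group_assignment"` or a named label vector.
#' @param params a [grouping_params()] (supplies counts, size and seed).
#' @return numeric vector of ARI values, one per random set.
#' @export
stability_by_random_sets <- function(x, assignment,
                                     params = grouping_params()) {
  labels <- if (inherits(assignment, "group_assignment"))
    assignment$labels else assignment
  if (params$random_set_size > ncol(x))
    stop("random_set_size exceeds number of genes")
  if (params$n_random_sets == 0L) return(numeric(0))
  set.seed(params$seed)
  vapply(seq_len(params$n_random_sets), function(i) {
    genes <- sample(colnames(x), params$random_set_size)
    part <- cut_dendrogram(
      average_linkage(euclidean_distances(x[, genes, drop = FALSE],
                                          "samples")),
      params$k_groups)
    adjusted_rand_index(part, labels[names(part)])
  }, numeric(1))
}
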