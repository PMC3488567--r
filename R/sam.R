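#' Parameters for the SAM-type differential statistic
#'
#' @param s0_strategy `"median_si"` (fudge factor = median of the per-gene
#'   pooled standard errors) or `"fixed"`.
#' @param s0_value the fudge factor when `s0_strategy = "fixed"`.
#' @param n_permutations label permutations for the FDR step (>= 10).
#' @param fold_change_min minimum effective fold change (>= 1) for
#'   [top_classifiers()]; inclusive at the boundary.
#' @param seed integer seed for the permutations.
#' @return list of class `"sam_params"`.
#' @export
sam_params <- function(s0_strategy = c("median_si", "fixed"), s0_value = 0,
                       n_permutations = 100L, fold_change_min = 2.0,
                       seed = 1L) {
  s0_strategy <- match.arg(s0_strategy)
  stopifnot(n_permutations >= 10L, fold_change_min >= 1)
  structure(list(s0_strategy = s0_strategy, s0_value = s0_value,
                 n_permutations = as.integer(n_permutations),
                 fold_change_min = fold_change_min, seed = as.integer(seed)),
            class = "sam_params")
}

# resolve a two-class contrast such as "B_vs_AC" against a label vector;
# returns list(class1 = ids, class2 = ids)
resolve_contrast <- function(labels, contrast, exclude = "CELL_LINE") {
  labels <- labels[!labels %in% exclude]
  parts <- strsplit(contrast, "_vs_", fixed = TRUE)[[1L]]
  if (length(parts) != 2L)
    stop("contrast must look like 'B_vs_AC' or 'A_vs_C'")
  split_side <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]
  g1 <- split_side(parts[1]); g2 <- split_side(parts[2])
  list(class1 = names(labels)[labels %in% g1],
       class2 = names(labels)[labels %in% g2])
}

sam_core <- function(x, class1, class2, s0) {
  n1 <- length(class1); n2 <- length(class2)
  x1 <- x[class1, , drop = FALSE]; x2 <- x[class2, , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  ss1 <- colSums(sweep(x1, 2L, m1)^2)
  ss2 <- colSums(sweep(x2, 2L, m2)^2)
  si <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  d <- (m1 - m2) / (si + s0)
  d[si + s0 == 0 & m1 == m2] <- 0  # constant gene, identical means
  list(d = d, lfc = m1 - m2, si = si)
}

#' SAM-type moderated d-statistic for a two-class contrast
#'
#' Per gene, d = (mean1 - mean2) / (s + s0), with s the pooled standard
#' error of the mean difference and s0 a fudge factor stabilising
#' low-variance genes. Fold change is 2^(difference of log2 means), the
#' input already being log2 scale.
#'
#' @param x an [expression_matrix()].
#' @param labels named group labels over (a superset of) the samples.
#' @param contrast string `"<g1>_vs_<g2>"`, single-letter group codes, e.g.
#'   `"B_vs_AC"` or `"A_vs_C"`.
#' @param params a [sam_params()].
#' @param exclude labels dropped before contrasting (default cell lines).
#' @return data.frame (class `"differential_result"`): gene, d_score,
#'   mean_log2_fc, fold_change, s_i; attribute `s0`.
#' @export
sam_d_statistic <- function(x, labels, contrast, params = sam_params(),
                            exclude = "CELL_LINE") {
  cls <- resolve_contrast(labels[rownames(x)[rownames(x) %in% names(labels)]],
                          contrast, exclude)
  if (length(cls$class1) < 2L || length(cls$class2) < 2L)
    stop("each contrast class needs at least 2 samples")
  core <- sam_core(x, cls$class1, cls$class2, s0 = 0)
  s0 <- switch(params$s0_strategy,
               median_si = stats::median(core$si),
               fixed = params$s0_value)
  core <- sam_core(x, cls$class1, cls$class2, s0 = s0)
  out <- data.frame(gene = colnames(x), d_score = unname(core$d),
                    mean_log2_fc = unname(core$lfc),
                    fold_change = unname(2^core$lfc),
                    s_i = unname(core$si), stringsAsFactors = FALSE)
  attr(out, "s0") <- s0
  attr(out, "classes") <- cls
  class(out) <- c("differential_result", class(out))
  out
}

#' Permutation false-discovery rate for the SAM statistic
#'
#' Class labels are permuted (seeded) to build null d distributions. For
#' each gene, the q-value is the median, over permutations, of the number of
#' null |d| values at or above the gene's |d|, divided by the observed count
#' at that threshold, clipped to [0, 1] and then monotonised so q never
#' decreases as |d| decreases.
#'
#' @inheritParams sam_d_statistic
#' @return the [sam_d_statistic()] data.frame with a `q_value` column.
#' @export
permutation_fdr <- function(x, labels, contrast, params = sam_params(),
                            exclude = "CELL_LINE") {
  res <- sam_d_statistic(x, labels, contrast, params, exclude)
  cls <- attr(res, "classes")
  s0 <- attr(res, "s0")
  ids <- c(cls$class1, cls$class2)
  n1 <- length(cls$class1)
  n_perm <- params$n_permutations
  n_distinct <- choose(length(ids), n1)
  if (n_perm > n_distinct) {
    warning("n_permutations exceeds the ", n_distinct,
            " distinct label splits; capped")
    n_perm <- n_distinct
  }
  set.seed(params$seed)
  abs_obs <- abs(res$d_score)
  ord <- order(abs_obs, decreasing = TRUE)
  thresholds <- abs_obs[ord]
  observed_count <- seq_along(thresholds)  # genes with |d| >= own threshold
  fp <- matrix(0, n_perm, length(thresholds))
  for (p in seq_len(n_perm)) {
    perm1 <- sample(ids, n1)
    null_d <- abs(sam_core(x[ids, , drop = FALSE], perm1,
                           setdiff(ids, perm1), s0)$d)
    # null values >= each gene's threshold, thresholds sorted decreasing
    fp[p, ] <- length(null_d) -
      findInterval(thresholds, sort(null_d), left.open = TRUE)
  }
  med_fp <- apply(fp, 2L, stats::median)
  q <- pmin(1, pmax(0, med_fp / observed_count))
  q <- cummax(q)  # monotone: larger |d| never has larger q
  res$q_value <- NA_real_
  res$q_value[ord] <- q
  res
}

#' Top group-classifier genes after fold-change filtering
#'
#' Keeps genes whose effective fold change (2^|log2 FC|) is at least
#' `fold_change_min` and returns the `n_top` with largest |d|, with the
#' direction of regulation in class 1.
#'
#' @param result a `"differential_result"` (q-values optional).
#' @param params a [sam_params()] (supplies `fold_change_min`).
#' @param n_top number of genes to return.
#' @return data.frame ranked by |d|: gene, d_score, fold_change, direction
#'   (`"up"`/`"down"` in class 1), q_value if present.
#' @export
top_classifiers <- function(result, params = sam_params(), n_top = 48L) {
  if (n_top == 0L) return(result[0, , drop = FALSE])
  eff_fc <- 2^abs(result$mean_log2_fc)
  keep <- result[eff_fc >= params$fold_change_min, , drop = FALSE]
  keep <- keep[order(abs(keep$d_score), decreasing = TRUE), , drop = FALSE]
  keep <- utils::head(keep, n_top)
  keep$direction <- ifelse(keep$mean_log2_fc >= 0, "up", "down")
  rownames(keep) <- NULL
  keep
}
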