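#' Parameters for the constrained label-shuffling significance test
#'
#' @param n_shuffles constrained label shuffles (500 in the study design).
#' @param n_top_variables variables re-selected and refit per shuffle (4).
#' @param constraint_fraction at least this fraction of the constrained
#'   group's slots must be filled by stratum samples originally labeled
#'   otherwise (1/3).
#' @param constraint_stratum annotation column and value defining the
#'   stratum (subtype ccRCC).
#' @param constrained_group the group whose composition is constrained (A).
#' @param n_trees random-forest ensemble size.
#' @param seed integer seed.
#' @return list of class `"shuffle_params"`.
#' @export
shuffle_params <- function(n_shuffles = 500L, n_top_variables = 4L,
                           constraint_fraction = 1 / 3,
                           constraint_stratum = c(subtype = "ccRCC"),
                           constrained_group = "A", n_trees = 500L,
                           seed = 1L) {
  stopifnot(n_shuffles >= 1L, n_top_variables >= 1L,
            constraint_fraction >= 0, constraint_fraction <= 1)
  structure(list(n_shuffles = as.integer(n_shuffles),
                 n_top_variables = as.integer(n_top_variables),
                 constraint_fraction = constraint_fraction,
                 constraint_stratum = constraint_stratum,
                 constrained_group = constrained_group,
                 n_trees = as.integer(n_trees), seed = as.integer(seed)),
            class = "shuffle_params")
}

#' Rank genes by random-forest variable importance
#'
#' Fits a seeded random-forest classifier (bootstrap + feature-subsampled
#' trees, sqrt(p) candidate features per split) and orders genes by impurity
#' (Gini) importance decrease.
#'
#' @param x an [expression_matrix()] (or plain numeric matrix).
#' @param labels named class labels covering the rows of `x`.
#' @param params a [shuffle_params()] (supplies `n_trees` and `seed`).
#' @param seed overrides `params$seed`.
#' @return data.frame: gene, importance, sorted decreasing.
#' @export
rank_variables <- function(x, labels, params = shuffle_params(),
                           seed = params$seed) {
  y <- factor(labels[rownames(x)])
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  if (all(apply(x, 2L, stats::var) == 0))
    stop("constant matrix: no variable can be ranked")
  fit <- ranger::ranger(x = as.matrix(unclass(x)), y = y,
                        num.trees = params$n_trees, importance = "impurity",
                        num.threads = 1L, seed = seed)
  imp <- sort(fit$variable.importance, decreasing = TRUE)
  data.frame(gene = names(imp), importance = unname(imp),
             stringsAsFactors = FALSE)
}

# ridge-regularised LDA fallback for singular pooled covariance
ridge_lda_accuracy <- function(xm, y, lambda = 1e-6) {
  p <- ncol(xm)
  levs <- levels(y)
  mus <- lapply(levs, function(l) colMeans(xm[y == l, , drop = FALSE]))
  pooled <- Reduce(`+`, lapply(levs, function(l) {
    xi <- xm[y == l, , drop = FALSE]
    crossprod(sweep(xi, 2L, colMeans(xi)))
  })) / (nrow(xm) - length(levs))
  pooled <- pooled + diag(lambda * mean(diag(pooled)) + lambda, p)
  w <- solve(pooled)
  priors <- as.numeric(table(y)[levs]) / length(y)
  disc <- sapply(seq_along(levs), function(i) {
    m <- mus[[i]]
    xm %*% (w %*% m) - as.numeric(t(m) %*% w %*% m) / 2 + log(priors[i])
  })
  factor(levs[max.col(disc)], levels = levs)
}

#' Resubstitution accuracy of a linear discriminant classifier
#'
#' Fits LDA on the given gene subset and reports resubstitution accuracy,
#' misclassification count and the confusion matrix. A singular pooled
#' covariance falls back to a ridge-regularised discriminant with a warning.
#'
#' @param x an [expression_matrix()] (or plain numeric matrix).
#' @param labels named class labels covering the rows of `x`.
#' @param gene_subset non-empty character vector of gene ids.
#' @return list: accuracy, n_misclassified, confusion (table).
#' @export
lda_accuracy <- function(x, labels, gene_subset) {
  if (length(gene_subset) < 1L) stop("gene_subset must be non-empty")
  xm <- as.matrix(unclass(x))[, gene_subset, drop = FALSE]
  y <- factor(labels[rownames(xm)])
  pred <- tryCatch({
    fit <- MASS::lda(xm, grouping = y)
    stats::predict(fit, xm)$class
  }, error = function(e) {
    warning("singular pooled covariance; using ridge-regularised LDA (",
            conditionMessage(e), ")")
    ridge_lda_accuracy(xm, y)
  })
  acc <- mean(pred == y)
  list(accuracy = acc, n_misclassified = sum(pred != y),
       confusion = table(truth = y, predicted = pred))
}

#' One constrained label shuffle
#'
#' Permutes group labels preserving group sizes exactly, while forcing at
#' least `ceil(constraint_fraction * |constrained group|)` of the slots of
#' the constrained group to be filled by stratum samples (e.g. ccRCC)
#' originally labeled otherwise. The remaining assignment is uniform among
#' valid completions.
#'
#' @param labels named group labels.
#' @param annotation data.frame with `sample_id` and the stratum column.
#' @param params a [shuffle_params()].
#' @param seed integer seed for this draw.
#' @return named shuffled labels over the same samples.
#' @export
constrained_shuffle <- function(labels, annotation,
                                params = shuffle_params(), seed) {
  if (!missing(seed)) set.seed(seed)
  ids <- names(labels)
  grp <- params$constrained_group
  n_grp <- sum(labels == grp)
  quota <- ceiling(params$constraint_fraction * n_grp)
  out <- stats::setNames(rep(NA_character_, length(labels)), ids)
  if (quota > 0) {
    col <- names(params$constraint_stratum)
    stratum_val <- params$constraint_stratum[[1L]]
    in_stratum <- annotation[[col]][match(ids, annotation$sample_id)] ==
      stratum_val
    pool <- ids[in_stratum & labels != grp]
    if (length(pool) < quota)
      stop("constraint infeasible: need ", quota, " ", stratum_val,
           " samples from outside ", grp, ", have ", length(pool))
    forced <- sample(pool, quota)
    out[forced] <- grp
  } else {
    forced <- character(0)
  }
  remaining_ids <- setdiff(ids, forced)
  counts <- table(labels)
  counts[grp] <- counts[grp] - length(forced)
  remaining_labels <- rep(names(counts), counts)
  out[remaining_ids] <- sample(remaining_labels)
  out
}

#' Constrained label-shuffling significance test of the grouping
#'
#' The observed pipeline: rank all genes by random-forest importance, keep
#' the top `n_top_variables`, refit the forest on them, and record the
#' accuracy. Each of `n_shuffles` constrained shuffles reruns the identical
#' pipeline (re-selecting variables under the shuffled labels, preserving
#' the selection bias under the null). The p-value is
#' (#\{shuffle accuracy >= original\} + 1) / (n_shuffles + 1).
#'
#' The accuracy compared across shuffles is the forest's out-of-bag
#' accuracy; resubstitution and LDA accuracies on the selected variables are
#' reported alongside for the original labels.
#'
#' @param x an [expression_matrix()].
#' @param labels named group labels over the rows of `x`.
#' @param annotation data.frame with `sample_id` and the stratum column.
#' @param params a [shuffle_params()].
#' @return list of class `"shuffle_test"` with fields `original_accuracy`
#'   (OOB), `original_resubstitution`, `original_lda`, `n_misclassified`,
#'   `top_variables`, `shuffle_accuracies`, `n_as_good`, `p_value`.
#' @export
shuffle_significance_test <- function(x, labels, annotation,
                                      params = shuffle_params()) {
  xm <- as.matrix(unclass(x))
  labels <- labels[rownames(xm)]
  run_once <- function(lab, seed) {
    rk <- rank_variables(xm, lab, params, seed = seed)
    top <- utils::head(rk$gene, params$n_top_variables)
    y <- factor(lab[rownames(xm)])
    refit <- ranger::ranger(x = xm[, top, drop = FALSE], y = y,
                            num.trees = params$n_trees, num.threads = 1L,
                            seed = seed)
    oob <- mean(refit$predictions == y, na.rm = TRUE)
    list(oob = oob, top = top, y = y, refit = refit)
  }
  orig <- run_once(labels, params$seed)
  resub <- mean(stats::predict(orig$refit,
                               data = xm[, orig$top, drop = FALSE])$predictions ==
                  orig$y)
  ldar <- lda_accuracy(xm, labels, orig$top)
  shuffle_acc <- numeric(params$n_shuffles)
  for (b in seq_len(params$n_shuffles)) {
    sh <- constrained_shuffle(labels, annotation, params,
                              seed = params$seed + b)
    shuffle_acc[b] <- run_once(sh, seed = params$seed + b)$oob
  }
  n_as_good <- sum(shuffle_acc >= orig$oob)
  structure(list(
    original_accuracy = orig$oob,
    original_resubstitution = resub,
    original_lda = ldar$accuracy,
    n_misclassified = round((1 - orig$oob) * nrow(xm)),
    top_variables = orig$top,
    shuffle_accuracies = shuffle_acc,
    n_as_good = n_as_good,
    p_value = (n_as_good + 1) / (params$n_shuffles + 1)),
    class = "shuffle_test")
}
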