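#' Read a gene-set collection from GMT
#'
#' One set per line: name, description, then member gene ids, tab-separated.
#' Duplicate genes within a set are removed; duplicate set names are an
#' error.
#'
#' @param path GMT file path.
#' @return named list of character vectors with attribute `description`.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has fewer than 3 fields")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(names(sets)))
    stop("duplicate set names in ", path)
  attr(sets, "description") <- vapply(fields, `[`, character(1), 2L)
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description optional per-set description (recycled).
#' @export
write_gene_sets <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Keep gene sets large enough for cluster discovery
#'
#' Only sets with strictly more than `min_size` member genes that are present
#' in the expression matrix are retained. Membership is counted against the
#' matrix, not the nominal set size, because pathway annotations typically
#' exceed array coverage.
#'
#' @param sets named list of character vectors.
#' @param x an [expression_matrix()] defining the gene universe.
#' @param min_size retain sets with more than this many covered genes.
#' @return the filtered collection (possibly empty), member lists restricted
#'   to covered genes.
#' @export
filter_by_set_size <- function(sets, x, min_size = 150L) {
  stopifnot(min_size >= 0L)
  genes <- colnames(x)
  covered <- lapply(sets, intersect, genes)
  keep <- lengths(covered) > min_size
  out <- covered[keep]
  attr(out, "description") <- attr(sets, "description")[keep]
  out
}
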