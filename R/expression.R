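#' Construct a validated expression matrix
#'
#' The package-wide container for log2-scale expression data is a plain
#' numeric matrix oriented samples x genes, with unique sample ids as row
#' names and unique gene ids as column names. This constructor validates the
#' invariants every downstream operation relies on: finite values, unique
#' ids, and at least 2 samples and 2 genes.
#'
#' @param values numeric matrix, samples in rows, genes in columns.
#' @param sample_ids,gene_ids optional character vectors overriding dimnames.
#' @return the validated matrix with class `c("expr_matrix", "matrix", ...)`.
#' @export
expression_matrix <- function(values, sample_ids = rownames(values),
                              gene_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(sample_ids) || is.null(gene_ids))
    stop("sample and gene identifiers are required")
  rownames(values) <- as.character(sample_ids)
  colnames(values) <- as.character(gene_ids)
  validate_expression_matrix(values)
  class(values) <- unique(c("expr_matrix", class(values)))
  values
}

validate_expression_matrix <- function(x) {
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("expression matrix needs at least 2 samples and 2 genes")
  if (anyNA(x) || !all(is.finite(x)))
    stop("expression matrix contains missing or non-finite values")
  if (anyDuplicated(rownames(x)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate gene ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  invisible(x)
}

#' Read an expression matrix from TSV or GCT
#'
#' TSV layout: header row of sample ids, first column gene ids (i.e. file is
#' genes x samples, the common export convention) OR samples x genes; the
#' orientation is auto-detected from the first header field. A first header
#' cell of `sample_id` (case-insensitive) marks a samples-in-rows file;
#' anything else (e.g. `gene_id`, `NAME`, empty) marks genes-in-rows. GCT 1.2
#' is always genes x samples. The returned matrix is always samples x genes.
#'
#' @param path file path.
#' @param format `"tsv"` or `"gct"`; default guessed from the extension.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, format = c("auto", "tsv", "gct")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  if (format == "gct") read_expression_gct(path) else read_expression_tsv(path)
}

read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("malformed header in ", path)
  first <- names(df)[1L]
  ids <- as.character(df[[1L]])
  body <- df[, -1L, drop = FALSE]
  bad <- !vapply(body, is.numeric, logical(1))
  if (any(bad))
    stop("non-numeric column(s) in ", path, ": ",
         paste(names(body)[bad], collapse = ", "))
  m <- as.matrix(body)
  rownames(m) <- ids
  samples_in_rows <- grepl("^sample", first, ignore.case = TRUE)
  if (!samples_in_rows) m <- t(m)
  expression_matrix(m)
}

read_expression_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || !grepl("^#1\\.2", lines[1L]))
    stop("not a GCT 1.2 file: ", path)
  dims <- as.integer(strsplit(lines[2L], "\t", fixed = TRUE)[[1L]][1:2])
  df <- utils::read.delim(text = paste(lines[-(1:2)], collapse = "\n"),
                          header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(df) != dims[1L] || ncol(df) - 2L != dims[2L])
    stop("GCT dimension line (", dims[1L], " x ", dims[2L],
         ") inconsistent with body (", nrow(df), " x ", ncol(df) - 2L, ")")
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cells in GCT body of ", path)
  rownames(m) <- as.character(df[[1L]])
  expression_matrix(t(m))
}

#' Write an expression matrix
#'
#' TSV is written genes x samples with a `gene_id` first column (the layout
#' [read_expression()] auto-detects); GCT as version 1.2.
#'
#' @param x an [expression_matrix()].
#' @param path output path.
#' @param format `"tsv"` or `"gct"`.
#' @export
write_expression <- function(x, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  validate_expression_matrix(x)
  g <- t(x)  # genes x samples on disk
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(g), g, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(g), ncol(g), sep = "\t")), con)
    df <- data.frame(NAME = rownames(g), Description = "na", g,
                     check.names = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Remove genes absent in every sample
#'
#' Proxy for the Affymetrix absent-call filter: a gene is dropped only when
#' its value is at or below `detection_floor` in *all* samples; a single
#' sample above the floor retains the gene. The default floor is the matrix
#' minimum plus a small epsilon, which removes exactly the genes pinned at
#' the detection limit.
#'
#' @param x an [expression_matrix()].
#' @param detection_floor log2-scale detection floor.
#' @return the filtered [expression_matrix()].
#' @export
filter_absent_probes <- function(x, detection_floor = min(x) + 1e-6) {
  validate_expression_matrix(x)
  absent <- apply(x <= detection_floor, 2L, all)
  if (all(absent)) stop("all genes fall below the detection floor")
  expression_matrix(x[, !absent, drop = FALSE])
}
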