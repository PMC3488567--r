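#' Parameters for copy-number calling
#'
#' @param gain_threshold segment means strictly above this are gains (0.13).
#' @param loss_threshold segment means strictly below this are losses
#'   (-0.13).
#' @param cnv_min_size segments shorter than this (bp) are treated as
#'   germline CNV noise and dropped before calling (100 kb).
#' @param small_region_max upper bound (bp, exclusive) for the focal-region
#'   analysis (5 Mb).
#' @return list of class `"cna_params"`.
#' @export
cna_call_params <- function(gain_threshold = 0.13, loss_threshold = -0.13,
                            cnv_min_size = 1e5, small_region_max = 5e6) {
  stopifnot(loss_threshold < 0, gain_threshold > 0,
            cnv_min_size < small_region_max)
  structure(list(gain_threshold = gain_threshold,
                 loss_threshold = loss_threshold,
                 cnv_min_size = cnv_min_size,
                 small_region_max = small_region_max),
            class = "cna_params")
}

validate_segments <- function(segments) {
  need <- c("case_id", "chromosome", "start", "end", "value")
  miss <- setdiff(need, names(segments))
  if (length(miss)) stop("segment table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(segments)) {
    if (any(segments$start >= segments$end))
      stop("segments must have start < end")
    if (!all(is.finite(segments$value)))
      stop("non-finite segment values")
  }
  invisible(segments)
}

#' Read a SEG file
#'
#' Standard SEG columns (sample, chromosome, start, end, optional marker
#' count, segment mean), 1-based inclusive coordinates; converted to the
#' package's 0-based half-open convention (so lengths are preserved as
#' end - start). Chromosomes outside 1-22 (X, Y, ...) are dropped.
#'
#' @param path SEG file.
#' @return data.frame: case_id, chromosome, start, end, value.
#' @export
read_seg <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 5L) stop("SEG file needs >= 5 columns")
  value_col <- ncol(df)
  chrom <- sub("^chr", "", as.character(df[[2L]]))
  out <- data.frame(case_id = as.character(df[[1L]]),
                    chromosome = suppressWarnings(as.integer(chrom)),
                    start = as.numeric(df[[3L]]) - 1,  # to 0-based half-open
                    end = as.numeric(df[[4L]]),
                    value = as.numeric(df[[value_col]]),
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$chromosome) & out$chromosome %in% 1:22, ,
             drop = FALSE]
  rownames(out) <- NULL
  validate_segments(out)
}

#' Write segments as SEG (1-based inclusive)
#'
#' @param segments internal 0-based half-open segment table.
#' @param path output path.
#' @export
write_seg <- function(segments, path) {
  validate_segments(segments)
  out <- data.frame(ID = segments$case_id, chrom = segments$chromosome,
                    loc.start = segments$start + 1, loc.end = segments$end,
                    seg.mean = segments$value)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a UCSC cytoBand file
#'
#' Native UCSC convention: chrom, chromStart (0-based), chromEnd, band name,
#' Giemsa stain; no header. Only chromosomes 1-22 are retained.
#'
#' @param path cytoBand.txt path.
#' @return data.frame: chromosome, start, end, band (e.g. "3p25").
#' @export
read_cytoband <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  chrom <- sub("^chr", "", as.character(df[[1L]]))
  out <- data.frame(chromosome = suppressWarnings(as.integer(chrom)),
                    start = as.numeric(df[[2L]]), end = as.numeric(df[[3L]]),
                    band = paste0(chrom, df[[4L]]),
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$chromosome) & out$chromosome %in% 1:22, ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Synthetic uniform cytoband map on the toy genome
#'
#' @param bands_per_chromosome equal-width bands per 100 Mb chromosome.
#' @return data.frame in the [read_cytoband()] layout.
#' @export
toy_cytobands <- function(bands_per_chromosome = 8L) {
  genome <- toy_genome()
  do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
    len <- genome$length_bp[i]
    br <- round(seq(0, len, length.out = bands_per_chromosome + 1L))
    data.frame(chromosome = genome$chromosome[i],
               start = br[-length(br)], end = br[-1L],
               band = sprintf("%dq%02d", genome$chromosome[i],
                              seq_len(bands_per_chromosome)))
  }))
}

#' Call gains and losses on segments
#'
#' Segments shorter than `cnv_min_size` are dropped (CNV filter); the rest
#' get status gain (value strictly above `gain_threshold`), loss (strictly
#' below `loss_threshold`) or neutral.
#'
#' @param segments segment table (0-based half-open).
#' @param params a [cna_call_params()].
#' @return the filtered table with a `status` column.
#' @export
call_gains_losses <- function(segments, params = cna_call_params()) {
  validate_segments(segments)
  keep <- (segments$end - segments$start) >= params$cnv_min_size
  out <- segments[keep, , drop = FALSE]
  out$status <- ifelse(out$value > params$gain_threshold, "gain",
                       ifelse(out$value < params$loss_threshold, "loss",
                              "neutral"))
  rownames(out) <- NULL
  out
}

#' Map called segments onto cytobands, per case
#'
#' A band receives a case's status when any called non-neutral segment
#' overlaps it by at least 1 bp; a band overlapped by both gains and losses
#' of the same case is `concurrent`. Bands without overlap are `neutral`.
#'
#' @param called_segments output of [call_gains_losses()].
#' @param cytoband_map [read_cytoband()]/[toy_cytobands()] table.
#' @return data.frame: case_id x band status matrix in long form (case_id,
#'   band, status), with attribute `bands` (the band table).
#' @export
map_to_cytobands <- function(called_segments, cytoband_map) {
  bad <- setdiff(unique(called_segments$chromosome),
                 unique(cytoband_map$chromosome))
  if (length(bad))
    stop("segment chromosome(s) absent from cytoband map: ",
         paste(bad, collapse = ", "))
  seg <- called_segments[called_segments$status != "neutral", , drop = FALSE]
  cases <- unique(called_segments$case_id)
  grid <- expand.grid(case_id = cases, band = cytoband_map$band,
                      stringsAsFactors = FALSE)
  grid$status <- "neutral"
  if (nrow(seg)) {
    seg_gr <- GenomicRanges::GRanges(
      seqnames = as.character(seg$chromosome),
      ranges = IRanges::IRanges(start = seg$start + 1, end = seg$end))
    band_gr <- GenomicRanges::GRanges(
      seqnames = as.character(cytoband_map$chromosome),
      ranges = IRanges::IRanges(start = cytoband_map$start + 1,
                                end = cytoband_map$end))
    hits <- GenomicRanges::findOverlaps(seg_gr, band_gr)
    hit_df <- unique(data.frame(
      case_id = seg$case_id[S4Vectors::queryHits(hits)],
      band = cytoband_map$band[S4Vectors::subjectHits(hits)],
      status = seg$status[S4Vectors::queryHits(hits)],
      stringsAsFactors = FALSE))
    agg <- stats::aggregate(status ~ case_id + band, data = hit_df,
                            FUN = function(s) {
                              if (all(c("gain", "loss") %in% s)) "concurrent"
                              else s[1L]
                            })
    key <- paste(grid$case_id, grid$band, sep = "\r")
    grid$status[match(paste(agg$case_id, agg$band, sep = "\r"), key)] <-
      agg$status
  }
  attr(grid, "bands") <- cytoband_map
  grid
}

#' Cytoband gain/loss frequency profile across cases
#'
#' Per band, the percentage of cases with a gain (or concurrent) and with a
#' loss (or concurrent), plus a flag marking bands where both gain and loss
#' occur somewhere in the case set.
#'
#' @param band_status output of [map_to_cytobands()].
#' @return data.frame: band, gain_percent, loss_percent, concurrent_flag,
#'   n_cases.
#' @export
frequency_profile <- function(band_status) {
  n_cases <- length(unique(band_status$case_id))
  if (n_cases < 1L) stop("need at least one case")
  sp <- split(band_status$status, band_status$band)
  out <- data.frame(
    band = names(sp),
    gain_percent = vapply(sp, function(s)
      100 * sum(s %in% c("gain", "concurrent")) / n_cases, numeric(1)),
    loss_percent = vapply(sp, function(s)
      100 * sum(s %in% c("loss", "concurrent")) / n_cases, numeric(1)),
    concurrent_flag = vapply(sp, function(s)
      any(s %in% c("gain", "concurrent")) &&
        any(s %in% c("loss", "concurrent")), logical(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  out$n_cases <- n_cases
  out
}

#' Focal (sub-5 Mb) regions and the genes they cover
#'
#' Restricts called non-neutral segments to lengths in
#' `[cnv_min_size, small_region_max)`, collapses identical intervals with
#' identical direction across cases into regions, and lists the annotated
#' genes each region overlaps by at least 1 bp.
#'
#' @param called_segments output of [call_gains_losses()].
#' @param gene_annotation data.frame: chromosome, start, end (0-based
#'   half-open), gene_id.
#' @param params a [cna_call_params()].
#' @return list: `regions` (chromosome, start, end, status, n_cases, genes
#'   as comma string), `n_regions`, `n_gains`, `n_losses`, `genes` (unique
#'   gene ids hit).
#' @export
small_regions_and_genes <- function(called_segments, gene_annotation,
                                    params = cna_call_params()) {
  seg <- called_segments[called_segments$status != "neutral", , drop = FALSE]
  len <- seg$end - seg$start
  seg <- seg[len >= params$cnv_min_size & len < params$small_region_max, ,
             drop = FALSE]
  if (!nrow(seg)) {
    return(list(regions = data.frame(), n_regions = 0L, n_gains = 0L,
                n_losses = 0L, genes = character(0)))
  }
  key <- paste(seg$chromosome, seg$start, seg$end, seg$status, sep = "\r")
  regions <- seg[!duplicated(key), c("chromosome", "start", "end", "status")]
  regions$n_cases <- as.integer(table(key)[key[!duplicated(key)]])
  reg_gr <- GenomicRanges::GRanges(
    seqnames = as.character(regions$chromosome),
    ranges = IRanges::IRanges(start = regions$start + 1, end = regions$end))
  gene_gr <- GenomicRanges::GRanges(
    seqnames = as.character(gene_annotation$chromosome),
    ranges = IRanges::IRanges(start = gene_annotation$start + 1,
                              end = gene_annotation$end))
  hits <- GenomicRanges::findOverlaps(reg_gr, gene_gr)
  gene_lists <- split(gene_annotation$gene_id[S4Vectors::subjectHits(hits)],
                      factor(S4Vectors::queryHits(hits),
                             levels = seq_len(nrow(regions))))
  regions$genes <- vapply(gene_lists, function(g)
    paste(unique(g), collapse = ","), character(1))
  rownames(regions) <- NULL
  list(regions = regions,
       n_regions = nrow(regions),
       n_gains = sum(regions$status == "gain"),
       n_losses = sum(regions$status == "loss"),
       genes = unique(gene_annotation$gene_id[S4Vectors::subjectHits(hits)]))
}
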