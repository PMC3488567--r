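#' Specification of a synthetic RCC study cohort
#'
#' Defines the study conditions the generators emulate: a 146-array cohort
#' (97 primary tumors, 15 metastases, 34 cell lines), three planted tumor
#' groups of 49/24/24 primaries, group-specific signature genes at the
#' observed fold-change ranges, a genome-wide backdrop of moderately
#' group-structured genes, a dedicated marker block separating cell lines,
#' and a block of absent probes pinned at the detection limit.
#'
#' @param n_primary,n_metastasis,n_cell_lines cohort composition.
#' @param group_sizes named counts for groups A/B/C among the primaries
#'   (must sum to `n_primary`); metastases are added to the groups in
#'   proportion.
#' @param n_genes total genes (scaled down from the 22k-probe array).
#' @param n_pathway_sets,pathway_set_size large pathway-like gene sets.
#' @param n_small_sets small (< 150 gene) structure-free sets.
#' @param signature_genes_per_group planted strong classifier genes for each
#'   of the two contrasts (B vs A/C; A vs C).
#' @param log2_fc_B_vs_AC_up,log2_fc_B_vs_AC_down,log2_fc_A_vs_C fold-change
#'   ranges (log2) from which planted effect sizes are drawn.
#' @param n_structured genome-wide moderately informative genes (carry the
#'   group signal that makes random gene subsets recover the grouping).
#' @param structured_shift log2 range of the moderate one-group shifts.
#' @param n_cellline_markers size of the gene block shifted in cell lines.
#' @param n_absent genes pinned at the detection floor in every sample.
#' @param baseline_mean,noise_sd,cellline_shift log2-scale Gaussian model.
#' @param seed integer seed; every generator is deterministic given it.
#' @return a list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_primary = 97L, n_metastasis = 15L,
                        n_cell_lines = 34L,
                        group_sizes = c(A = 49L, B = 24L, C = 24L),
                        n_genes = 2000L,
                        n_pathway_sets = 4L, pathway_set_size = 200L,
                        n_small_sets = 3L,
                        signature_genes_per_group = 40L,
                        log2_fc_B_vs_AC_up = log2(c(5.2, 14.4)),
                        log2_fc_B_vs_AC_down = log2(c(5.7, 8.7)),
                        log2_fc_A_vs_C = log2(c(4.2, 16.0)),
                        n_structured = 600L,
                        structured_shift = c(0.8, 1.6),
                        n_cellline_markers = 250L,
                        n_absent = 50L,
                        baseline_mean = 7.0, noise_sd = 0.7,
                        cellline_shift = 2.0,
                        seed = 1L) {
  spec <- list(n_primary = as.integer(n_primary),
               n_metastasis = as.integer(n_metastasis),
               n_cell_lines = as.integer(n_cell_lines),
               group_sizes = group_sizes,
               n_genes = as.integer(n_genes),
               n_pathway_sets = as.integer(n_pathway_sets),
               pathway_set_size = as.integer(pathway_set_size),
               n_small_sets = as.integer(n_small_sets),
               signature_genes_per_group = as.integer(signature_genes_per_group),
               log2_fc_B_vs_AC_up = log2_fc_B_vs_AC_up,
               log2_fc_B_vs_AC_down = log2_fc_B_vs_AC_down,
               log2_fc_A_vs_C = log2_fc_A_vs_C,
               n_structured = as.integer(n_structured),
               structured_shift = structured_shift,
               n_cellline_markers = as.integer(n_cellline_markers),
               n_absent = as.integer(n_absent),
               baseline_mean = baseline_mean, noise_sd = noise_sd,
               cellline_shift = cellline_shift,
               seed = as.integer(seed))
  with(spec, {
    stopifnot(n_primary > 0, n_metastasis >= 0, n_cell_lines >= 0,
              all(group_sizes > 0), length(group_sizes) == 3L,
              noise_sd >= 0)
    if (sum(group_sizes) != n_primary)
      stop("group_sizes must sum to n_primary")
    for (r in list(log2_fc_B_vs_AC_up, log2_fc_B_vs_AC_down, log2_fc_A_vs_C,
                   structured_shift))
      if (r[1] > r[2]) stop("effect range must have lower <= upper")
    demand <- 2L * signature_genes_per_group + n_structured +
      n_cellline_markers + n_absent
    if (demand > n_genes)
      stop("gene role demand (", demand, ") exceeds n_genes (", n_genes, ")")
  })
  structure(spec, class = "cohort_spec")
}

# proportional integer split by largest remainder
largest_remainder <- function(total, weights) {
  raw <- total * weights / sum(weights)
  out <- floor(raw)
  rem <- total - sum(out)
  if (rem > 0) {
    idx <- order(raw - out, decreasing = TRUE)[seq_len(rem)]
    out[idx] <- out[idx] + 1
  }
  stats::setNames(as.integer(out), names(weights))
}

#' Generate the synthetic expression cohort
#'
#' Gaussian log2 intensities around a common baseline, with planted effects:
#' group-B signature genes shifted up/down in group B by draws from the
#' B-vs-A/C fold-change ranges, A-vs-C signature genes shifted in A (mostly)
#' or C, a broad block of moderately one-group-shifted genes providing the
#' genome-wide signal, a disjoint block shifted in all cell lines so they
#' form their own cluster, and absent genes held constant at the detection
#' floor. The A and C centroids end up closer to each other than either is
#' to B, so A nests within the C clade as in the real cohort.
#'
#' @param spec a [cohort_spec()].
#' @param seed overrides `spec$seed`.
#' @return list with `matrix` (an [expression_matrix()]), `annotation`
#'   (data.frame: sample_id, sample_class, subtype, stage, grade,
#'   sarcomatoid), and `truth` (list: `labels` named sample -> group,
#'   `roles` named gene -> role, `effects` data.frame of planted shifts).
#' @export
generate_expression <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)

  gs <- spec$group_sizes
  meta_split <- largest_remainder(spec$n_metastasis, gs)
  prim_ids <- sprintf("T%03d", seq_len(spec$n_primary))
  meta_ids <- if (spec$n_metastasis > 0)
    sprintf("M%03d", seq_len(spec$n_metastasis)) else character(0)
  cell_ids <- if (spec$n_cell_lines > 0)
    sprintf("L%03d", seq_len(spec$n_cell_lines)) else character(0)
  sample_ids <- c(prim_ids, meta_ids, cell_ids)

  labels <- c(rep(names(gs), gs), rep(names(meta_split), meta_split),
              rep("CELL_LINE", spec$n_cell_lines))
  names(labels) <- sample_ids

  annotation <- synth_annotation(spec, sample_ids, labels, gs)

  gene_ids <- sprintf("G%04d", seq_len(spec$n_genes))
  nsig <- spec$signature_genes_per_group
  roles <- rep("background", spec$n_genes)
  idx <- 0L
  take <- function(n) { r <- idx + seq_len(n); idx <<- idx + n; r }
  i_sigB <- take(nsig);              roles[i_sigB] <- "signature_B"
  i_sigAC <- take(nsig);             roles[i_sigAC] <- "signature_A_vs_C"
  i_str <- take(spec$n_structured);  roles[i_str] <- "pathway_structured"
  i_cl <- take(spec$n_cellline_markers); roles[i_cl] <- "cellline_marker"
  i_abs <- take(spec$n_absent);      roles[i_abs] <- "absent"
  names(roles) <- gene_ids

  # planted effect table: one row per (gene, target group) shift
  n_up <- ceiling(2 * nsig / 3)                       # 32-up/16-down ratio
  dir_B <- rep(c(1, -1), c(n_up, nsig - n_up))
  delta_B <- ifelse(dir_B > 0,
                    stats::runif(nsig, spec$log2_fc_B_vs_AC_up[1],
                                 spec$log2_fc_B_vs_AC_up[2]),
                    -stats::runif(nsig, spec$log2_fc_B_vs_AC_down[1],
                                  spec$log2_fc_B_vs_AC_down[2]))
  n_Ahigh <- ceiling(0.8 * nsig)                      # mostly A-high
  tgt_AC <- rep(c("A", "C"), c(n_Ahigh, nsig - n_Ahigh))
  delta_AC <- stats::runif(nsig, spec$log2_fc_A_vs_C[1],
                           spec$log2_fc_A_vs_C[2])
  # group B sits at an intermediate level on the A-vs-C genes (the A-vs-C
  # contrast leaves B free); this makes the strongest genes three-level and
  # hence informative for the full grouping, as the few-gene classifier
  # accuracy of the study requires
  mid_frac <- stats::runif(nsig, 0.35, 0.65)
  tgt_str <- rep_len(c("A", "B", "C"), spec$n_structured)
  delta_str <- sample(c(-1, 1), spec$n_structured, replace = TRUE) *
    stats::runif(spec$n_structured, spec$structured_shift[1],
                 spec$structured_shift[2])
  effects <- data.frame(
    gene = gene_ids[c(i_sigB, i_sigAC, i_sigAC, i_str, i_cl)],
    role = roles[c(i_sigB, i_sigAC, i_sigAC, i_str, i_cl)],
    target = c(rep("B", nsig), tgt_AC, rep("B", nsig), tgt_str,
               rep("CELL_LINE", spec$n_cellline_markers)),
    delta = c(delta_B, delta_AC, mid_frac * delta_AC, delta_str,
              rep(spec$cellline_shift, spec$n_cellline_markers)),
    row.names = NULL, stringsAsFactors = FALSE)

  n <- length(sample_ids)
  mu <- matrix(spec$baseline_mean, n, spec$n_genes,
               dimnames = list(sample_ids, gene_ids))
  for (r in seq_len(nrow(effects))) {
    in_group <- labels == effects$target[r]
    mu[in_group, effects$gene[r]] <- mu[in_group, effects$gene[r]] +
      effects$delta[r]
  }
  values <- mu + matrix(stats::rnorm(n * spec$n_genes, sd = spec$noise_sd),
                        n, spec$n_genes)
  values[, i_abs] <- 0  # pinned at detection floor, no noise

  list(matrix = expression_matrix(values),
       annotation = annotation,
       truth = list(labels = labels, roles = roles, effects = effects))
}

synth_annotation <- function(spec, sample_ids, labels, gs) {
  subtype <- character(length(sample_ids))
  cls <- rep(c("primary_tumor", "metastasis", "cell_line"),
             c(spec$n_primary, spec$n_metastasis, spec$n_cell_lines))
  # emulate the real cross-tabulation: A almost pure ccRCC, C enriched pRCC
  mix <- list(A = c(ccRCC = 48, pRCC = 1, chRCC = 0, `cc/pRCC` = 0),
              B = c(ccRCC = 17, pRCC = 6, chRCC = 1, `cc/pRCC` = 0),
              C = c(ccRCC = 10, pRCC = 11, chRCC = 1, `cc/pRCC` = 2))
  prim <- cls == "primary_tumor"
  for (g in names(gs)) {
    sel <- which(prim & labels == g)
    counts <- largest_remainder(length(sel), mix[[g]] + 1e-9)
    subtype[sel] <- rep(names(counts), counts)
  }
  subtype[cls == "metastasis"] <- "ccRCC"   # metastases of ccRCC
  subtype[cls == "cell_line"] <- "other"
  tumor <- cls != "cell_line"
  stage <- ifelse(tumor,
                  sample(c("pT1/pT2", "pT3/pT4"), length(sample_ids),
                         replace = TRUE, prob = c(62, 35)), "unknown")
  grade <- ifelse(tumor,
                  sample(1:4, length(sample_ids), replace = TRUE,
                         prob = c(7, 43, 41, 6)), NA)
  sarcomatoid <- ifelse(tumor, stats::runif(length(sample_ids)) < 0.1, NA)
  data.frame(sample_id = sample_ids, sample_class = cls, subtype = subtype,
             stage = stage, grade = grade, sarcomatoid = sarcomatoid,
             stringsAsFactors = FALSE)
}

#' Generate pathway-like gene sets over a synthetic cohort
#'
#' Emits `n_pathway_sets` large sets, each holding a quota of signature and
#' structured genes plus background fill, and `n_small_sets` small (< 150
#' gene) sets of background genes only — the structure-free pathways in which
#' the pipeline should find nothing.
#'
#' @param spec a [cohort_spec()].
#' @param truth the `truth` element from [generate_expression()].
#' @param seed overrides `spec$seed` (offset internally).
#' @return named list of gene-id vectors.
#' @export
generate_gene_sets <- function(spec, truth, seed = spec$seed) {
  set.seed(seed + 1000L)
  roles <- truth$roles
  sig <- names(roles)[roles %in% c("signature_B", "signature_A_vs_C")]
  str <- names(roles)[roles == "pathway_structured"]
  cl <- names(roles)[roles == "cellline_marker"]
  bg <- names(roles)[roles == "background"]
  k <- spec$n_pathway_sets
  sig_q <- split(sig, rep_len(seq_len(k), length(sig)))
  str_pool <- sample(str)
  cl_pool <- sample(cl)
  big_names <- rep_len(c("Wnt", "Inflammation", "Angiogenesis", "Integrin",
                         paste0("Pathway", seq_len(max(0, k - 4)))), k)
  sets <- vector("list", k)
  used_str <- 0L; used_cl <- 0L
  for (i in seq_len(k)) {
    members <- sig_q[[i]]
    n_cl <- min(15L, (length(cl_pool) - used_cl) %/% max(1L, k - i + 1L))
    members <- c(members, cl_pool[used_cl + seq_len(n_cl)])
    used_cl <- used_cl + n_cl
    n_str <- min(40L, max(0L, spec$pathway_set_size - length(members) - 100L))
    members <- c(members, str_pool[used_str + seq_len(n_str)])
    used_str <- used_str + n_str
    fill <- spec$pathway_set_size - length(members)
    members <- c(members, sample(bg, fill))
    sets[[i]] <- sample(members)   # shuffle so signal genes are not adjacent
  }
  names(sets) <- big_names
  small_sizes <- rep_len(c(21L, 60L, 120L), spec$n_small_sets)
  small_names <- rep_len(c("Apoptosis", "HIF_signaling",
                           "Cysteine_biosynthesis"), spec$n_small_sets)
  for (i in seq_len(spec$n_small_sets))
    sets[[small_names[i]]] <- sample(bg, small_sizes[i])
  sets
}

#' Toy genome model used by the segment generator
#'
#' 22 autosomes of 100 Mb each. Used both to place synthetic segments and to
#' derive the synthetic uniform cytoband map.
#'
#' @return data.frame with `chromosome` and `length_bp`.
#' @export
toy_genome <- function() {
  data.frame(chromosome = 1:22, length_bp = 100e6L)
}

#' Generate copy-number segments with group-dependent burden
#'
#' Each tumor draws a Poisson number of true events (mean ordered
#' A < B <= C) from a fixed catalog of plantable small regions (100 kb to
#' 5 Mb, segment mean beyond +/-0.13), plus sub-100 kb decoys that the CNV
#' size filter must drop and near-zero neutral segments. Coordinates are
#' 0-based half-open on the [toy_genome()].
#'
#' @param spec a [cohort_spec()].
#' @param truth the `truth` element from [generate_expression()].
#' @param seed overrides `spec$seed` (offset internally).
#' @param event_means named Poisson means of true-event counts per group.
#' @param n_decoys_mean,n_neutral_mean Poisson means of decoy (< 100 kb,
#'   large ratio) and neutral segments per tumor.
#' @param n_catalog size of the plantable small-region catalog.
#' @return list with `segments` (data.frame: case_id, chromosome, start, end,
#'   value) and `catalog` (the planted region table: chromosome, start, end,
#'   direction).
#' @export
generate_cna_segments <- function(spec, truth, seed = spec$seed,
                                  event_means = c(A = 2, B = 5, C = 6),
                                  n_decoys_mean = 2, n_neutral_mean = 3,
                                  n_catalog = 30L) {
  set.seed(seed + 2000L)
  genome <- toy_genome()
  catalog <- data.frame(
    chromosome = sample(genome$chromosome, n_catalog, replace = TRUE),
    start = round(stats::runif(n_catalog, 0, 90e6)),
    direction = rep_len(c("gain", "loss"), n_catalog))
  catalog$end <- catalog$start +
    round(stats::runif(n_catalog, 1.5e5, 4.8e6))

  tumors <- names(truth$labels)[truth$labels != "CELL_LINE"]
  rows <- list()
  for (s in tumors) {
    g <- truth$labels[[s]]
    n_ev <- stats::rpois(1, event_means[[g]])
    if (n_ev > 0) {
      picks <- sample(nrow(catalog), min(n_ev, nrow(catalog)))
      sgn <- ifelse(catalog$direction[picks] == "gain", 1, -1)
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = s, chromosome = catalog$chromosome[picks],
        start = catalog$start[picks], end = catalog$end[picks],
        value = sgn * stats::runif(length(picks), 0.2, 0.8))
    }
    n_dec <- stats::rpois(1, n_decoys_mean)
    if (n_dec > 0) {
      st <- round(stats::runif(n_dec, 0, 99e6))
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = s, chromosome = sample(22, n_dec, replace = TRUE),
        start = st, end = st + round(stats::runif(n_dec, 1e4, 9e4)),
        value = sample(c(-1, 1), n_dec, TRUE) * stats::runif(n_dec, 0.2, 0.6))
    }
    n_neu <- stats::rpois(1, n_neutral_mean)
    if (n_neu > 0) {
      st <- round(stats::runif(n_neu, 0, 95e6))
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = s, chromosome = sample(22, n_neu, replace = TRUE),
        start = st, end = st + round(stats::runif(n_neu, 2e5, 3e6)),
        value = stats::runif(n_neu, -0.08, 0.08))
    }
  }
  segments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(case_id = character(0), chromosome = integer(0),
               start = numeric(0), end = numeric(0), value = numeric(0))
  rownames(segments) <- NULL
  list(segments = segments,
       catalog = catalog[, c("chromosome", "start", "end", "direction")])
}

#' Generate clinical and IHC data obeying the three-marker rule
#'
#' Survival times are exponential with hazards ordered A < B < C (best
#' outcome in A, worst in C) with uniform right censoring. IHC columns are
#' drawn so that an `assignable_fraction` of tumors maps to its true group
#' under the MVD/DEK/MSH6 rule; the rest deliberately violate it (mid-band
#' MVD, or DEK-negative with MSH6-positive).
#'
#' @param spec a [cohort_spec()].
#' @param truth the `truth` element from [generate_expression()].
#' @param assignable_fraction fraction of tumors with rule-conforming IHC.
#' @param seed overrides `spec$seed` (offset internally).
#' @param hazards named per-month hazards for groups A/B/C.
#' @param censor_range months; uniform censoring window.
#' @return data.frame: sample_id, true_group, assignable, time (months),
#'   event (0/1), mvd_count, dek_pct, msh6_pct. Tumors only.
#' @export
generate_clinical <- function(spec, truth, assignable_fraction = 0.75,
                              seed = spec$seed,
                              hazards = c(A = 0.008, B = 0.02, C = 0.04),
                              censor_range = c(6, 120)) {
  stopifnot(assignable_fraction > 0, assignable_fraction <= 1)
  set.seed(seed + 3000L)
  tumors <- names(truth$labels)[truth$labels != "CELL_LINE"]
  g <- truth$labels[tumors]
  n <- length(tumors)
  death <- stats::rexp(n, rate = hazards[g])
  censor <- stats::runif(n, censor_range[1], censor_range[2])
  time <- pmax(pmin(death, censor), 0.1)
  event <- as.integer(death <= censor)
  assignable <- stats::runif(n) < assignable_fraction

  mvd <- numeric(n); dek <- numeric(n); msh6 <- numeric(n)
  pos <- function(k) stats::runif(k, 5, 90)    # clearly > 1% positivity
  neg <- function(k) stats::runif(k, 0, 0.9)   # clearly <= 1%
  for (grp in c("A", "B", "C")) {
    i <- which(assignable & g == grp)
    k <- length(i)
    if (!k) next
    if (grp == "A") {
      mvd[i] <- round(stats::runif(k, 110, 250)); dek[i] <- pos(k); msh6[i] <- pos(k)
    } else if (grp == "B") {
      mvd[i] <- round(stats::runif(k, 0, 250)); dek[i] <- stats::runif(k, 0, 90)
      msh6[i] <- neg(k)
    } else {
      mvd[i] <- round(stats::runif(k, 0, 45)); dek[i] <- pos(k); msh6[i] <- pos(k)
    }
  }
  i <- which(!assignable)
  if (length(i)) {
    mode_mid <- stats::runif(length(i)) < 0.5   # mid-band MVD, both markers on
    mvd[i] <- ifelse(mode_mid, round(stats::runif(length(i), 55, 95)),
                     round(stats::runif(length(i), 110, 250)))
    dek[i] <- ifelse(mode_mid, pos(length(i)), neg(length(i)))
    msh6[i] <- pos(length(i))                   # MSH6-positive blocks B
  }
  data.frame(sample_id = tumors, true_group = unname(g),
             assignable = assignable, time = time, event = event,
             mvd_count = mvd, dek_pct = dek, msh6_pct = msh6,
             stringsAsFactors = FALSE)
}

#' Generate the full synthetic study
#'
#' Convenience wrapper running all four generators with sub-seeds derived
#' from one seed.
#'
#' @param spec a [cohort_spec()].
#' @param seed overrides `spec$seed`.
#' @param assignable_fraction passed to [generate_clinical()].
#' @return list: `matrix`, `annotation`, `truth`, `gene_sets`, `cna`
#'   (segments + catalog), `clinical`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = spec$seed,
                            assignable_fraction = 0.75) {
  expr <- generate_expression(spec, seed)
  list(matrix = expr$matrix, annotation = expr$annotation,
       truth = expr$truth,
       gene_sets = generate_gene_sets(spec, expr$truth, seed),
       cna = generate_cna_segments(spec, expr$truth, seed),
       clinical = generate_clinical(spec, expr$truth, assignable_fraction,
                                    seed))
}

#' Write a simulated cohort to plain-text files
#'
#' Writes expression (TSV), gene sets (GMT), segments (SEG, 1-based
#' inclusive), clinical and truth-label TSVs into a directory.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$matrix, file.path(dir, "expression.tsv"))
  write_gene_sets(cohort$gene_sets, file.path(dir, "gene_sets.gmt"))
  write_seg(cohort$cna$segments, file.path(dir, "segments.seg"))
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- data.frame(sample_id = names(cohort$truth$labels),
                      label = unname(cohort$truth$labels))
  utils::write.table(truth, file.path(dir, "truth_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
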