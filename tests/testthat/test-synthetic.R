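test_that("default cohort has the study composition", {
  spec <- cohort_spec(seed = 2)
  co <- generate_expression(spec)
  expect_equal(nrow(co$matrix), 146L)
  expect_equal(ncol(co$matrix), 2000L)
  prim <- co$annotation$sample_id[co$annotation$sample_class ==
                                    "primary_tumor"]
  expect_equal(as.vector(table(co$truth$labels[prim])[c("A", "B", "C")]),
               c(49L, 24L, 24L))
  expect_equal(sum(co$truth$labels == "CELL_LINE"), 34L)
  expect_equal(length(prim), 97L)
  expect_equal(sum(co$annotation$sample_class == "metastasis"), 15L)
  # metastases are extra members of A/B/C
  met <- co$annotation$sample_id[co$annotation$sample_class == "metastasis"]
  expect_true(all(co$truth$labels[met] %in% c("A", "B", "C")))
  # roles cover all genes, labels all samples
  expect_setequal(names(co$truth$roles), colnames(co$matrix))
  expect_setequal(names(co$truth$labels), rownames(co$matrix))
})

test_that("generators are pure functions of (spec, seed)", {
  spec <- cohort_spec(seed = 8)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(unclass(a$matrix), unclass(b$matrix))
  expect_identical(a$gene_sets, b$gene_sets)
  expect_identical(a$cna$segments, b$cna$segments)
  expect_identical(a$clinical, b$clinical)
  c2 <- simulate_cohort(cohort_spec(seed = 9))
  expect_false(identical(unclass(a$matrix), unclass(c2$matrix)))
})

test_that("zero-noise limit recovers every planted effect exactly", {
  spec <- cohort_spec(noise_sd = 0, seed = 4)
  co <- generate_expression(spec)
  x <- co$matrix; lab <- co$truth$labels
  eff <- co$truth$effects
  sigB <- eff[eff$role == "signature_B", ]
  for (i in seq_len(nrow(sigB))) {
    g <- sigB$gene[i]
    diff <- mean(x[lab == "B", g]) - mean(x[lab %in% c("A", "C"), g])
    expect_equal(diff, sigB$delta[i], tolerance = 1e-12)
  }
  sigAC <- eff[eff$role == "signature_A_vs_C" & eff$target %in% c("A", "C"), ]
  for (i in seq_len(nrow(sigAC))) {
    g <- sigAC$gene[i]
    diff <- mean(x[lab == "A", g]) - mean(x[lab == "C", g])
    expected <- if (sigAC$target[i] == "A") sigAC$delta[i] else -sigAC$delta[i]
    expect_equal(diff, expected, tolerance = 1e-12)
  }
})

test_that("infeasible gene-role demand is rejected", {
  expect_error(cohort_spec(n_genes = 100), "exceeds n_genes")
  expect_error(cohort_spec(group_sizes = c(A = 10, B = 10, C = 10)),
               "sum to n_primary")
})

test_that("CNA burden is ordered A < C and coordinates are valid", {
  # ~200 tumors for a stable Monte-Carlo comparison of the group means
  spec <- cohort_spec(n_primary = 201, n_metastasis = 0,
                      group_sizes = c(A = 67, B = 67, C = 67), seed = 6)
  labels <- setNames(rep(c("A", "B", "C"), each = 67),
                     sprintf("T%03d", 1:201))
  truth <- list(labels = labels)
  cna <- generate_cna_segments(spec, truth, seed = 6)
  seg <- cna$segments
  expect_true(all(seg$start < seg$end))
  expect_true(all(seg$chromosome %in% 1:22))
  called <- call_gains_losses(seg)
  altered <- called[called$status != "neutral", ]
  counts <- table(factor(altered$case_id, levels = names(labels)))
  mean_by_group <- tapply(as.vector(counts), labels[names(counts)], mean)
  expect_lt(mean_by_group[["A"]], mean_by_group[["C"]])
  expect_lte(mean_by_group[["B"]], mean_by_group[["C"]] + 0.5)

  # zero events and no decoys: everything stays inside the neutral band
  quiet <- generate_cna_segments(spec, truth, seed = 7,
                                 event_means = c(A = 0, B = 0, C = 0),
                                 n_decoys_mean = 0)
  expect_true(all(abs(quiet$segments$value) < 0.13))
})

test_that("clinical generator obeys the marker rule and hazard ordering", {
  spec <- cohort_spec(seed = 12)
  co <- generate_expression(spec)
  clin <- generate_clinical(spec, co$truth, assignable_fraction = 1)
  status <- call_marker_status(clin$mvd_count, clin$dek_pct, clin$msh6_pct)
  expect_equal(assign_group_by_markers(status), clin$true_group)

  clin75 <- generate_clinical(spec, co$truth, assignable_fraction = 0.75)
  status75 <- call_marker_status(clin75$mvd_count, clin75$dek_pct,
                                 clin75$msh6_pct)
  assigned <- assign_group_by_markers(status75)
  frac <- mean(assigned != "unassigned")
  expect_gt(frac, 0.75 - 3 * sqrt(0.75 * 0.25 / nrow(clin75)))
  expect_lt(frac, 0.75 + 3 * sqrt(0.75 * 0.25 / nrow(clin75)))
  # non-assignable rows really violate the rule
  expect_true(all(assigned[!clin75$assignable] == "unassigned"))

  # exponential medians: survival is best in A, worst in C at n = 500/group
  labels <- setNames(rep(c("A", "B", "C"), each = 500),
                     sprintf("T%04d", 1:1500))
  big <- generate_clinical(spec, list(labels = labels), seed = 31,
                           censor_range = c(1e6, 2e6))  # effectively none
  med <- tapply(big$time, big$true_group, median)
  expect_gt(med[["A"]], med[["B"]])
  expect_gt(med[["B"]], med[["C"]])
})

test_that("a written cohort can be read back", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(n_primary = 12, n_metastasis = 2, n_cell_lines = 4,
                      group_sizes = c(A = 4, B = 4, C = 4), n_genes = 60,
                      n_pathway_sets = 2, pathway_set_size = 20,
                      n_small_sets = 1, signature_genes_per_group = 4,
                      n_structured = 9, n_cellline_markers = 6,
                      n_absent = 2, seed = 13)
  co <- simulate_cohort(spec)
  write_cohort(co, dir)
  x <- read_expression(file.path(dir, "expression.tsv"))
  expect_equal(unclass(x)[rownames(co$matrix), colnames(co$matrix)],
               unclass(co$matrix), tolerance = 1e-9, ignore_attr = TRUE)
  sets <- read_gene_sets(file.path(dir, "gene_sets.gmt"))
  expect_equal(sets, co$gene_sets, ignore_attr = TRUE)
  seg <- read_seg(file.path(dir, "segments.seg"))
  expect_equal(seg$end - seg$start,
               co$cna$segments$end - co$cna$segments$start)
})
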