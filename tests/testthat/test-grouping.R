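# A compact structured cohort used by several blocks below: small enough to
# keep per-test clustering cheap, with the same architecture as the default.
small_cohort <- function(seed = 1) {
  spec <- cohort_spec(n_primary = 36, n_metastasis = 6, n_cell_lines = 12,
                      group_sizes = c(A = 18, B = 9, C = 9), n_genes = 400,
                      n_pathway_sets = 2, pathway_set_size = 120,
                      n_small_sets = 2, signature_genes_per_group = 12,
                      n_structured = 120, n_cellline_markers = 60,
                      n_absent = 10, seed = seed)
  simulate_cohort(spec)
}

test_that("representative-cluster selection finds the planted subtree first", {
  co <- small_cohort(seed = 2)
  x <- filter_absent_probes(co$matrix)
  params <- grouping_params(k_groups = 4, min_set_size = 100)
  reference <- cut_dendrogram(
    average_linkage(euclidean_distances(x, "samples")), 4)
  informative <- names(co$truth$roles)[co$truth$roles %in%
    c("signature_B", "signature_A_vs_C", "pathway_structured",
      "cellline_marker")]
  set_name <- names(co$gene_sets)[1]
  tw <- two_way_cluster(x, co$gene_sets[[set_name]], set_name)
  sel <- select_representative_clusters(x, tw, reference, params)
  expect_gt(length(sel), 0)
  # the top-scoring cluster is dominated by planted informative genes
  expect_gt(mean(sel[[1]] %in% informative), 0.8)
  expect_true(all(diff(attr(sel, "scores")) <= 1e-12))
  # disjointness
  expect_equal(anyDuplicated(unlist(sel)), 0L)

  expect_identical(
    select_representative_clusters(x, tw, reference,
                                   grouping_params(max_clusters_per_set = 0)),
    list())
})

test_that("joint re-clustering recovers the planted groups", {
  co <- small_cohort(seed = 3)
  params <- grouping_params(k_groups = 4, min_set_size = 100)
  # zero-noise: recovery must be exact
  spec0 <- cohort_spec(n_primary = 36, n_metastasis = 0, n_cell_lines = 12,
                       group_sizes = c(A = 18, B = 9, C = 9), n_genes = 400,
                       n_pathway_sets = 2, pathway_set_size = 120,
                       n_small_sets = 2, signature_genes_per_group = 12,
                       n_structured = 120, n_cellline_markers = 60,
                       n_absent = 10, noise_sd = 0, seed = 4)
  co0 <- simulate_cohort(spec0)
  informative0 <- names(co0$truth$roles)[co0$truth$roles %in%
    c("signature_B", "signature_A_vs_C", "cellline_marker")]
  asg0 <- combine_and_recluster(co0$matrix, list(informative0), params,
                                annotation = co0$annotation)
  expect_equal(adjusted_rand_index(asg0$labels, co0$truth$labels), 1)

  # background-only gene unions carry no group information
  bg <- names(co$truth$roles)[co$truth$roles == "background"]
  asg_bg <- combine_and_recluster(co$matrix, list(bg), params,
                                  annotation = co$annotation)
  expect_lt(abs(adjusted_rand_index(asg_bg$labels, co$truth$labels)), 0.2)

  expect_error(combine_and_recluster(co$matrix, list("G0001"), params),
               "fewer than 2")
})

test_that("the full pipeline recovers truth and isolates cell lines", {
  co <- small_cohort(seed = 5)
  params <- grouping_params(k_groups = 4, min_set_size = 100)
  asg <- run_pathway_grouping(co$matrix, co$gene_sets, params,
                              annotation = co$annotation)
  expect_gte(adjusted_rand_index(asg$labels, co$truth$labels), 0.9)
  cl <- names(co$truth$labels)[co$truth$labels == "CELL_LINE"]
  expect_true(all(asg$labels[cl] == asg$labels[cl][1]))
  expect_true(all(asg$labels[cl] == "CELL_LINE"))
  # determinism
  asg2 <- run_pathway_grouping(co$matrix, co$gene_sets, params,
                               annotation = co$annotation)
  expect_identical(asg$labels, asg2$labels)
  # selection never draws from the small structure-free sets
  small_names <- names(co$gene_sets)[lengths(co$gene_sets) < 100]
  expect_false(any(asg$selection_report$set %in% small_names))

  # only small sets available -> the documented error path
  small_only <- co$gene_sets[lengths(co$gene_sets) < 100]
  expect_error(run_pathway_grouping(co$matrix, small_only, params),
               "min_set_size")
})

test_that("random-gene-set stability reflects genome-wide signal", {
  co <- small_cohort(seed = 6)
  params <- grouping_params(k_groups = 4, min_set_size = 100,
                            n_random_sets = 5, random_set_size = 150,
                            seed = 11)
  asg <- run_pathway_grouping(co$matrix, co$gene_sets, params,
                              annotation = co$annotation)
  aris <- stability_by_random_sets(co$matrix, asg, params)
  expect_length(aris, 5)
  expect_true(all(aris >= 0.7))

  # pure noise: no stability
  set.seed(99)
  noise <- expression_matrix(
    matrix(rnorm(60 * 300), 60, 300,
           dimnames = list(sprintf("s%02d", 1:60), sprintf("g%03d", 1:300))))
  fake <- setNames(rep(c("A", "B", "C", "CELL_LINE"), each = 15),
                   rownames(noise))
  null_aris <- stability_by_random_sets(
    noise, fake, grouping_params(k_groups = 4, n_random_sets = 5,
                                 random_set_size = 100, seed = 12))
  expect_lt(mean(abs(null_aris)), 0.2)

  expect_length(
    stability_by_random_sets(co$matrix, asg,
                             grouping_params(n_random_sets = 0,
                                             random_set_size = 150)), 0)
})

test_that("group A nests within the C clade of the tumor-only tree", {
  co <- small_cohort(seed = 7)
  tumors <- names(co$truth$labels)[co$truth$labels != "CELL_LINE"]
  tree <- average_linkage(euclidean_distances(co$matrix[tumors, ], "samples"))
  coph <- as.matrix(cophenetic(tree))
  lab <- co$truth$labels[tumors]
  mean_coph <- function(g1, g2)
    mean(coph[names(lab)[lab == g1], names(lab)[lab == g2]])
  expect_lt(mean_coph("A", "C"), mean_coph("A", "B"))
})
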