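seg_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(case_id = r[[1]], chromosome = as.integer(r[[2]]),
               start = as.numeric(r[[3]]), end = as.numeric(r[[4]]),
               value = as.numeric(r[[5]]))))
}

test_that("gain/loss calling applies thresholds and the CNV size filter", {
  seg <- seg_df(list("t1", 1, 0e6, 1e6, 0.20),     # 1 Mb gain
                list("t1", 2, 0e6, 5e4, -0.20),    # 50 kb -> dropped
                list("t1", 3, 0e6, 1e6, 0.13),     # boundary -> neutral
                list("t1", 4, 0e6, 1e6, -0.14),    # loss
                list("t1", 5, 0e6, 1e5, 0.30))     # exactly 100 kb -> kept
  called <- call_gains_losses(seg)
  expect_equal(nrow(called), 4L)
  expect_equal(called$status[called$chromosome == 1], "gain")
  expect_equal(called$status[called$chromosome == 3], "neutral")
  expect_equal(called$status[called$chromosome == 4], "loss")
  expect_false(2 %in% called$chromosome)

  # raising the gain threshold never increases gain calls
  n_gain <- function(thr) sum(call_gains_losses(
    seg, cna_call_params(gain_threshold = thr))$status == "gain")
  thrs <- c(0.05, 0.13, 0.25, 0.35)
  expect_true(all(diff(vapply(thrs, n_gain, numeric(1))) <= 0))
})

test_that("cytoband mapping handles spans, concurrency and absences", {
  bands <- data.frame(chromosome = c(1, 1, 2),
                      start = c(0, 50e6, 0), end = c(50e6, 100e6, 100e6),
                      band = c("1q01", "1q02", "2q01"))
  seg <- seg_df(list("t1", 1, 49e6, 51e6, 0.3),   # spans both chr1 bands
                list("t2", 2, 10e6, 12e6, 0.3),
                list("t2", 2, 11e6, 13e6, -0.3))  # overlapping loss
  called <- call_gains_losses(seg)
  bs <- map_to_cytobands(called, bands)
  get <- function(case, band) bs$status[bs$case_id == case & bs$band == band]
  expect_equal(get("t1", "1q01"), "gain")
  expect_equal(get("t1", "1q02"), "gain")
  expect_equal(get("t1", "2q01"), "neutral")
  expect_equal(get("t2", "2q01"), "concurrent")
  # exactly one status per case and band
  expect_equal(nrow(bs), 2 * 3)
  expect_true(all(bs$status %in% c("gain", "loss", "concurrent", "neutral")))

  seg_bad <- seg_df(list("t1", 9, 0, 2e6, 0.3))
  expect_error(map_to_cytobands(call_gains_losses(seg_bad), bands),
               "absent from cytoband map")

  # all-neutral input stays neutral
  quiet <- call_gains_losses(seg_df(list("t1", 1, 0, 2e6, 0.01)))
  expect_true(all(map_to_cytobands(quiet, bands)$status == "neutral"))
})

test_that("frequency profiles are percentages of cases", {
  bands <- data.frame(chromosome = 1, start = 0, end = 100e6, band = "1q01")
  seg <- seg_df(list("t1", 1, 0, 2e6, 0.3),
                list("t2", 1, 0, 2e6, 0.01))
  fp <- frequency_profile(map_to_cytobands(call_gains_losses(seg), bands))
  expect_equal(fp$gain_percent, 50)
  expect_equal(fp$loss_percent, 0)
  expect_false(fp$concurrent_flag)
  expect_equal(fp$n_cases, 2L)
})

test_that("higher-burden groups show more altered bands", {
  spec <- cohort_spec(seed = 41)
  labels <- setNames(rep(c("A", "C"), each = 100), sprintf("T%03d", 1:200))
  cna <- generate_cna_segments(spec, list(labels = labels), seed = 41)
  called <- call_gains_losses(cna$segments)
  bs <- map_to_cytobands(called, toy_cytobands())
  frac_altered <- tapply(bs$status != "neutral",
                         bs$case_id, mean)[names(labels)]
  frac_altered[is.na(frac_altered)] <- 0
  w <- wilcox.test(frac_altered[labels == "A"], frac_altered[labels == "C"],
                   alternative = "less")
  expect_lt(w$p.value, 0.05)
})

test_that("focal regions respect the 5 Mb bound and list covered genes", {
  genes <- data.frame(chromosome = c(1, 1, 1, 2),
                      start = c(1e6, 2e6, 3e6, 1e6),
                      end = c(1.5e6, 2.5e6, 3.5e6, 2e6),
                      gene_id = c("GA", "GB", "GC", "GD"))
  seg <- seg_df(list("t1", 1, 0.5e6, 5.4e6, 0.3),   # 4.9 Mb gain -> kept
                list("t2", 1, 0.5e6, 5.6e6, 0.3),   # 5.1 Mb -> excluded
                list("t3", 2, 0.5e6, 1.2e6, -0.3))  # 700 kb loss
  out <- small_regions_and_genes(call_gains_losses(seg), genes)
  expect_equal(out$n_regions, 2L)
  expect_equal(out$n_gains, 1L)
  expect_equal(out$n_losses, 1L)
  gain_region <- out$regions[out$regions$status == "gain", ]
  expect_equal(strsplit(gain_region$genes, ",")[[1]], c("GA", "GB", "GC"))
  expect_setequal(out$genes, c("GA", "GB", "GC", "GD"))
})

test_that("planted focal regions are recovered from synthetic segments", {
  spec <- cohort_spec(seed = 43)
  co <- generate_expression(spec)
  cna <- generate_cna_segments(spec, co$truth, seed = 43)
  called <- call_gains_losses(cna$segments)
  genes <- data.frame(chromosome = 1, start = 1, end = 2, gene_id = "dummy")
  out <- small_regions_and_genes(called, genes)
  key <- function(df) paste(df$chromosome, df$start, df$end)
  cat_key <- key(cna$catalog)
  # every recovered region is a planted one, with the planted direction
  idx <- match(key(out$regions), cat_key)
  expect_false(anyNA(idx))
  expect_equal(out$regions$status, cna$catalog$direction[idx])
  # nearly the whole catalog is hit somewhere in 112 tumors
  expect_gte(length(unique(idx)), nrow(cna$catalog) - 3)
})

test_that("SEG round trip and cytoband parsing preserve coordinates", {
  seg <- seg_df(list("t1", 1, 100, 5e6, 0.2), list("t2", 21, 0, 3e5, -0.4))
  p <- withr::local_tempfile(fileext = ".seg")
  write_seg(seg, p)
  back <- read_seg(p)
  expect_equal(back$start, seg$start)
  expect_equal(back$end, seg$end)
  expect_equal(back$value, seg$value)

  cb <- withr::local_tempfile()
  writeLines(c("chr1\t0\t2300000\tp36.33\tgneg",
               "chr1\t2300000\t5400000\tp36.32\tgpos25",
               "chrX\t0\t4300000\tp22.33\tgneg"), cb)
  bands <- read_cytoband(cb)
  expect_equal(nrow(bands), 2L)            # X excluded
  expect_equal(bands$band[1], "1p36.33")
  expect_equal(bands$end[1] - bands$start[1], 2300000)

  tb <- toy_cytobands()
  expect_setequal(unique(tb$chromosome), 1:22)
  expect_true(all(tb$start < tb$end))
})
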