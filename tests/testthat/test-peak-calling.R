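test_that("build_coverage matches the brute-force per-base oracle", {
  mod <- gene_model("G", "chrT", "+",
                    list(t1 = data.frame(start = 0L, end = 2000L)),
                    start = 0L, end = 2000L)
  reads <- data.frame(start = c(0L, 5L), end = c(15L, 15L))
  prof <- build_coverage(reads, mod)
  expect_equal(prof$depth[11], 2)          # both reads cover base 10
  expect_equal(sum(prof$depth), sum(reads$end - reads$start))

  expect_equal(build_coverage(reads[0, ], mod)$depth, numeric(2000))

  set.seed(101)
  n <- 1000L
  starts <- sample(-20:2020, n, replace = TRUE)
  reads <- data.frame(start = starts, end = starts + 50L)
  prof <- build_coverage(reads, mod)
  expect_equal(prof$depth, oracle_coverage(reads, mod))
  expect_gt(prof$n_clipped, 0L)
})

test_that("scanner reproduces hand-walkable shapes", {
  params <- peak_params()
  expect_equal(nrow(scan_candidate_peaks(fake_profile(numeric(1000)),
                                         params)), 0L)

  # rectangular block (depth 100 over bases 100-199, 1 elsewhere). Hand walk:
  # the pooled-median start rule first fires for the 8-window segment at base
  # 80 (20 bases of 1 + 20 of 100, median 50.5 > 50); termination excludes
  # the trailing all-background segment, ending the peak at base 200.
  depth <- rep(1, 1000); depth[101:200] <- 100
  got <- scan_candidate_peaks(fake_profile(depth), params)
  expect_equal(nrow(got), 1L)
  expect_equal(got$start, 80)
  expect_equal(got$end, 200)
  expect_equal(got$max_depth, 100)
  expect_equal(got, cbind(gene_id = "gX", oracle_scan(depth, params)),
               ignore_attr = TRUE)

  # two blocks separated by a zero-depth gap give two distinct peaks
  depth <- rep(0, 1000); depth[101:200] <- 50; depth[401:500] <- 80
  got <- scan_candidate_peaks(fake_profile(depth), params)
  expect_equal(nrow(got), 2L)
  expect_equal(got, cbind(gene_id = "gX", oracle_scan(depth, params)),
               ignore_attr = TRUE)

  expect_error(peak_params(stop_fraction = 1.2), "stop_fraction")
  expect_error(peak_params(window = 0), "positive")
})

test_that("scanner equals the window-walk oracle on random profiles", {
  # smaller sweep here; the full 500-profile equivalence runs in acceptance
  params <- peak_params()
  set.seed(202)
  for (k in 1:60) {
    depth <- random_profile()
    expect_equal(
      scan_candidate_peaks(fake_profile(depth), params)[, -1],
      oracle_scan(depth, params),
      ignore_attr = TRUE, info = paste("profile", k))
  }
})

test_that("raising start_fold never increases candidate count", {
  set.seed(303)
  folds <- c(1.5, 2.5, 4, 8)
  for (k in 1:20) {
    depth <- random_profile()
    n <- vapply(folds, function(f) {
      nrow(scan_candidate_peaks(fake_profile(depth),
                                peak_params(start_fold = f)))
    }, numeric(1))
    expect_true(all(diff(n) <= 0))
  }
})

test_that("permutation p-values behave at the edges", {
  mod <- gene_model("G", "chrT", "+",
                    list(t1 = data.frame(start = 0L, end = 10000L)),
                    start = 0L, end = 10000L)
  empty <- build_coverage(data.frame(start = integer(0), end = integer(0)),
                          mod)
  expect_equal(permutation_pvalue(0, permutation_null(empty, mod)), 1.0)
  expect_equal(permutation_pvalue(5, rep(0, 500)), 1 / 501)

  # every read stacked in one 5 bp window of a 10 kb gene: p below 0.05
  reads <- data.frame(start = rep(4000L, 30), end = rep(4050L, 30))
  prof <- build_coverage(reads, mod)
  set.seed(404)
  null <- permutation_null(prof, mod, peak_params())
  expect_lte(permutation_pvalue(max(prof$depth), null), 0.05)
})

test_that("retention rule matches the published boundary exactly", {
  params <- peak_params()
  pk <- data.frame(p_value = c(0.2, 0.049, 0.2),
                   max_depth = c(10, 3, 9))
  got <- retain_peaks(pk, params)$retained
  expect_identical(got, c(TRUE, TRUE, FALSE))
})

test_that("enrichment filter reproduces the fourfold worked examples", {
  params <- peak_params()
  mkreads <- function(n, gene = "G", s = 100L) {
    data.frame(gene_id = rep(gene, n), start = rep(s, n),
               end = rep(s + 50L, n))
  }
  peak <- data.frame(gene_id = "G", start = 100L, end = 200L)
  # equal library sizes: IP = 8, input = 2 -> enrichment 4.0, enriched
  filler_ip <- mkreads(92, gene = "F")    # equalize library sizes off-peak
  filler_in <- mkreads(98, gene = "F")
  got <- enrichment_filter(peak, rbind(mkreads(8), filler_ip),
                           rbind(mkreads(2), filler_in), params)
  expect_equal(got$enrichment, 4.0)
  expect_true(got$is_enriched)

  got <- enrichment_filter(peak, rbind(mkreads(7), mkreads(93, gene = "F")),
                           rbind(mkreads(2), filler_in), params)
  expect_equal(got$enrichment, 3.5)
  expect_false(got$is_enriched)

  # empty input at the peak: pseudo-floor of one normalized read applies,
  # a 10-read IP peak is still enriched and flagged
  got <- enrichment_filter(peak, rbind(mkreads(10), mkreads(90, gene = "F")),
                           mkreads(100, gene = "F"), params)
  expect_true(got$input_floored)
  expect_equal(got$enrichment, 10)
  expect_true(got$is_enriched)

  expect_error(enrichment_filter(peak, mkreads(0), mkreads(5)), "empty IP")
})

test_that("raising enrich_fold never increases enriched peaks", {
  cfg <- sim_config(seed = 31)
  models <- simulate_gene_models(cfg)
  reads <- simulate_rip_reads(cfg, models)
  input <- reads[grepl("^input_", reads$sample), ]
  ip <- reads[reads$sample == "ip_r1", ]
  n <- vapply(c(2, 4, 8, 16), function(f) {
    pk <- call_peaks_one_rep(models, ip, input,
                             peak_params(enrich_fold = f))
    sum(pk$is_enriched)
  }, numeric(1))
  expect_true(all(diff(n) <= 0))
})

test_that("target genes require reproducibility across all IP replicates", {
  base <- data.frame(gene_id = "G", chrom = "chrT", start = 100L, end = 200L,
                     max_depth = 20, p_value = 0.001, retained = TRUE,
                     is_enriched = TRUE)
  none <- base[0, ]
  # peak in rep1 only (2 reps): excluded
  got <- call_targets(list(r1 = base, r2 = none))
  expect_length(got$target_genes, 0L)
  # identical peak in both reps: included
  got <- call_targets(list(r1 = base, r2 = base))
  expect_equal(got$target_genes, "G")
  # union rule keeps the rep1-only peak
  got <- call_targets(list(r1 = base, r2 = none), rule = "union")
  expect_equal(got$target_genes, "G")
})

test_that("the default fixture recovers exactly the planted target genes", {
  cfg <- sim_config(seed = 8)
  models <- simulate_gene_models(cfg)
  reads <- simulate_rip_reads(cfg, models)
  res <- call_peaks(models, reads)
  expect_setequal(res$target_genes, unique(cfg$planted_peaks$gene_id))
})
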