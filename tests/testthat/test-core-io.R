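test_that("GTF coordinates convert 1-based inclusive -> 0-based half-open", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "G"; transcript_id "G.t1";',
    'chr1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id "G"; transcript_id "G.t1";',
    'chr1\tsrc\texon\t101\t400\t.\t+\t.\tgene_id "G"; transcript_id "G.t2";'),
    path)
  models <- read_gtf(path)
  expect_length(models, 1L)
  g <- models[["G"]]
  expect_length(g$transcripts, 2L)  # two transcripts grouped under one gene
  t1 <- g$transcripts[["G.t1"]]
  expect_equal(t1$start, c(100L, 300L))
  expect_equal(t1$end, c(200L, 400L))
  expect_equal(t1$end[1] - t1$start[1], 100L)
  expect_equal(g$exonic_length, 300L)
})

test_that("malformed GTF lines are rejected with their line number", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "G"; transcript_id "t";',
    "chr1\tbroken line"), path)
  expect_error(read_gtf(path), "line 2")
  writeLines('chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "G";', path)
  expect_error(read_gtf(path), "transcript_id")
})

test_that("synthetic GTF round-trips through write_gtf/read_gtf", {
  cfg <- sim_config(seed = 11, n_genes = 3)
  models <- simulate_gene_models(cfg)
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(models, path)
  back <- read_gtf(path)
  expect_equal(names(back), names(models))
  for (g in names(models)) {
    expect_equal(back[[g]], models[[g]])
  }
})

test_that("written GTF agrees with rtracklayer as an independent reader", {
  skip_if_not_installed("rtracklayer")
  models <- simulate_gene_models(sim_config(seed = 12, n_genes = 3))
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(models, path)
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  for (g in names(models)) {
    mine <- do.call(rbind, models[[g]]$transcripts)
    theirs <- ex[ex$gene_id == g]
    expect_setequal(BiocGenerics::start(theirs) - 1L, unique(mine$start))
    expect_setequal(BiocGenerics::end(theirs), unique(mine$end))
  }
})

test_that("write_bed emits BED6 and round-trips random peaks", {
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(data.frame(chrom = "chr1", start = 120L, end = 180L,
                       name = "pk1", max_depth = 37, strand = "+"), path)
  expect_equal(readLines(path), "chr1\t120\t180\tpk1\t37\t+")

  write_bed(data.frame(), path)
  expect_length(readLines(path), 0L)
  expect_equal(nrow(read_bed(path)), 0L)

  set.seed(42)
  n <- 100L
  start <- sample.int(1e6, n)
  peaks <- data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                      start = start, end = start + sample.int(500, n),
                      name = sprintf("p%03d", 1:n),
                      max_depth = runif(n, 0, 2000),
                      strand = sample(c("+", "-"), n, TRUE))
  write_bed(peaks, path)
  back <- read_bed(path)
  expect_equal(back$start, peaks$start)
  expect_equal(back$end, peaks$end)
  expect_equal(back$chrom, peaks$chrom)
  expect_true(all(back$score >= 0 & back$score <= 1000))
  expect_error(write_bed(data.frame(chrom = "c", start = 10L, end = 10L,
                                    name = "x", max_depth = 1), path),
               "end must be > start")
})

test_that("bedGraph reader densifies, zero-fills and rejects overlaps", {
  path <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines("chr1\t0\t5\t3", path)
  cov <- read_coverage_bedgraph(path)
  expect_equal(cov$chr1, c(3, 3, 3, 3, 3))

  writeLines(character(0), path)
  expect_length(read_coverage_bedgraph(path), 0L)

  writeLines(c("chr1\t0\t5\t3", "chr1\t3\t8\t1"), path)
  expect_error(read_coverage_bedgraph(path), "overlap")

  cov <- list(chr9 = c(0, 0, 2, 2, 5.5, 0, 1, 0))
  write_coverage_bedgraph(cov, path)
  expect_equal(read_coverage_bedgraph(path)$chr9[1:7], cov$chr9[1:7])
})

test_that("junction table loads typed rows and validates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tdonor\tacceptor\tsample\tcount",
               "G1\t100\t200\ts1\t30"), path)
  jt <- read_junction_table(path, c(s1 = "a", s2 = "b"))
  expect_equal(jt$counts$count, 30L)
  expect_s3_class(jt, "JunctionCountTable")

  writeLines(c("gene_id\tdonor\tacceptor\tsample\tcount",
               "G1\t100\t200\ts1\t-1"), path)
  expect_error(read_junction_table(path, c(s1 = "a", s2 = "b")), "negative")
  writeLines(c("gene_id\tdonor\tacceptor\tsample\tcount",
               "G1\t300\t200\ts1\t5"), path)
  expect_error(read_junction_table(path, c(s1 = "a", s2 = "b")),
               "donor must be < acceptor")
  writeLines(c("gene_id\tdonor\tacceptor\tsample\tcount",
               "G1\t100\t200\tsX\t5"), path)
  expect_error(read_junction_table(path, c(s1 = "a", s2 = "b")),
               "missing from group map: sX")
})

test_that("count matrix reader enforces invariants and names offenders", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "G1\t5\t0", "G2\t1\t0"), path)
  expect_error(read_count_matrix(path), "zero-sum count column.*s2")
  writeLines(c("gene_id\ts1\ts2", "G1\t5\t-2", "G2\t1\t3"), path)
  expect_error(read_count_matrix(path), "negative count")
  writeLines(c("gene_id\ts1\ts2", "G1\t5\t2", "G2\t1\t3"), path)
  m <- read_count_matrix(path, c(s1 = "a", s2 = "b"))
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(attr(m, "groups"), c(s1 = "a", s2 = "b"))
})

test_that("decay table reader validates times, positivity and t = 0", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("condition\treplicate\ttime_min\trel_abundance",
               "c\t1\t0\t1", "c\t1\t20\t0.8"), path)
  expect_equal(nrow(read_decay_table(path)), 2L)
  writeLines(c("condition\treplicate\ttime_min\trel_abundance",
               "c\t1\t20\t0.8"), path)
  expect_error(read_decay_table(path), "t = 0")
  writeLines(c("condition\treplicate\ttime_min\trel_abundance",
               "c\t1\t0\t1", "c\t1\t20\t0"), path)
  expect_error(read_decay_table(path), "> 0")
})

test_that("every artifact emitted by the generator loads through core_io", {
  outdir <- withr::local_tempdir()
  sim <- simulate_dataset(sim_config(seed = 13), outdir = outdir)
  models <- read_gtf(file.path(outdir, "genes.gtf"))
  expect_length(models, 30L)
  reads <- read_reads_table(file.path(outdir, "reads.tsv"))
  expect_gt(nrow(reads), 0L)
  jt <- read_junction_table(file.path(outdir, "junctions.tsv"),
                            file.path(outdir, "junction_groups.json"))
  expect_equal(sort(unique(unname(jt$groups))), c("case", "ctrl"))
  m <- read_count_matrix(file.path(outdir, "counts.tsv"),
                         file.path(outdir, "counts_groups.json"))
  expect_equal(unname(m), unname(unclass(sim$counts)[, ]),
               ignore_attr = TRUE)
  expect_equal(nrow(read_decay_table(file.path(outdir, "decay.tsv"))),
               nrow(sim$decay))
})
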