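test_that("splice graph holds annotated plus observed junctions", {
  mod <- gene_model("G1", "chrT", "+",
                    list(t1 = data.frame(start = c(0L, 300L),
                                         end = c(100L, 400L))))
  g <- build_splice_graph(mod)
  expect_equal(nrow(g$junctions), 1L)
  expect_equal(g$junctions$donor, 100L)
  expect_equal(g$junctions$acceptor, 300L)

  jt <- junction_count_table(
    data.frame(gene_id = "G1", donor = c(100L, 150L),
               acceptor = c(300L, 250L), sample = "s1",
               count = c(10L, 3L)),
    c(s1 = "a", s2 = "b"))
  g <- build_splice_graph(mod, jt)
  expect_equal(nrow(g$junctions), 2L)
  expect_true(g$junctions$novel[g$junctions$donor == 150L])
  expect_false(g$junctions$novel[g$junctions$donor == 100L])

  jt_bad <- junction_count_table(
    data.frame(gene_id = "G1", donor = 100L, acceptor = 9999L,
               sample = "s1", count = 1L), c(s1 = "a", s2 = "b"))
  expect_warning(build_splice_graph(mod, jt_bad), "crossing the bounds")
})

test_that("canonical topologies classify to their event types", {
  # three-exon skipping gene: one cassetteExon with the canonical sets
  mod <- tiny_cassette_model()
  ev <- detect_events(build_splice_graph(mod))
  expect_length(ev, 1L)
  expect_equal(ev[[1]]$event_type, "cassetteExon")
  expect_equal(ev[[1]]$inclusion,
               data.frame(donor = c(120L, 490L), acceptor = c(370L, 740L)),
               ignore_attr = TRUE)
  expect_equal(ev[[1]]$exclusion,
               data.frame(donor = 120L, acceptor = 740L),
               ignore_attr = TRUE)

  # two donors sharing one acceptor within overlapping exons: A5SS on '+'
  mod <- gene_model("G2", "chrT", "+", list(
    t1 = data.frame(start = c(0L, 420L), end = c(170L, 540L)),
    t2 = data.frame(start = c(0L, 420L), end = c(120L, 540L))))
  ev <- detect_events(build_splice_graph(mod))
  expect_length(ev, 1L)
  expect_equal(ev[[1]]$event_type, "A5SS")
  # the same genomic topology on '-' is an alternative 3' splice site
  mod <- gene_model("G3", "chrT", "-", list(
    t1 = data.frame(start = c(0L, 420L), end = c(170L, 540L)),
    t2 = data.frame(start = c(0L, 420L), end = c(120L, 540L))))
  ev <- detect_events(build_splice_graph(mod))
  expect_equal(ev[[1]]$event_type, "A3SS")
})

test_that("all 12 planted fixture events classify with their designed tags", {
  cfg <- sim_config(seed = 2)
  d <- simulate_dataset(cfg)
  planted <- attr(d$models, "planted_events")
  events <- unlist(lapply(d$models, function(m) {
    detect_events(build_splice_graph(m, d$junctions))
  }), recursive = FALSE)
  got <- data.frame(gene_id = vapply(events, `[[`, "", "gene_id"),
                    type = vapply(events, `[[`, "", "event_type"))
  expect_equal(nrow(got), 12L)  # no extras among planted genes
  got <- got[match(planted$gene_id, got$gene_id), ]
  expect_equal(got$type, planted$type)
})

test_that("classification is invariant to junction input order", {
  cfg <- sim_config(seed = 4)
  d <- simulate_dataset(cfg)
  cnt <- d$junctions$counts
  set.seed(99)
  shuffled <- junction_count_table(cnt[sample(nrow(cnt)), ],
                                   d$junctions$groups)
  key <- function(jt) {
    evs <- unlist(lapply(d$models, function(m) {
      detect_events(build_splice_graph(m, jt))
    }), recursive = FALSE)
    sort(vapply(evs, function(e) paste(e$gene_id, e$event_type), ""))
  }
  expect_identical(key(d$junctions), key(shuffled))
})

test_that("event_ratio does the stated arithmetic", {
  ev <- bare_event(1)
  mk <- function(inc, exc) junction_count_table(
    data.frame(gene_id = "e1", donor = 100L, acceptor = c(200L, 300L),
               sample = "s1", count = c(inc, exc)),
    c(s1 = "a", s2 = "b"))
  expect_equal(event_ratio(ev, mk(30L, 10L), "s1"), 0.75)
  expect_true(is.na(event_ratio(ev, mk(0L, 0L), "s1")))
  expect_equal(event_ratio(ev, mk(0L, 17L), "s1"), 0.0)
})

test_that("ratio estimator converges to psi at high depth", {
  set.seed(55)
  for (psi in c(0.15, 0.5, 0.9)) {
    jt <- bare_event_counts(1, psi, psi, depth = 1e5, n_rep = 2L)
    r <- event_ratio(bare_event(1), jt, "a_r1")
    expect_lt(abs(r - psi), 0.01)
  }
})

test_that("ratio t test matches closed form and handles degeneracy", {
  ev <- list(bare_event(1))
  mk_jt <- function(r1, r2, depth = 1000L) {
    samples <- c(sprintf("a_r%d", seq_along(r1)),
                 sprintf("b_r%d", seq_along(r2)))
    groups <- stats::setNames(rep(c("a", "b"), c(length(r1), length(r2))),
                              samples)
    ratios <- c(r1, r2)
    rows <- do.call(rbind, lapply(seq_along(samples), function(i) {
      inc <- round(depth * ratios[i])
      data.frame(gene_id = "e1", donor = 100L, acceptor = c(200L, 300L),
                 sample = samples[i], count = c(inc, depth - inc))
    }))
    junction_count_table(rows, groups)
  }
  # identical ratio vectors: t = 0, p = 1
  res <- test_ratio_alteration(ev, mk_jt(c(0.4, 0.5, 0.6), c(0.4, 0.5, 0.6)))
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_value, 1)

  # strong shift agrees with stats::t.test as the oracle
  r1 <- c(0.30, 0.31, 0.29); r2 <- c(0.70, 0.69, 0.71)
  res <- test_ratio_alteration(ev, mk_jt(r1, r2, depth = 100000L))
  oracle <- stats::t.test(r1, r2)
  expect_lt(res$p_value, 0.001)
  expect_equal(res$p_value, oracle$p.value, tolerance = 1e-6)
  expect_equal(abs(res$t_statistic), abs(oracle$statistic[[1]]),
               tolerance = 1e-6)
  expect_equal(res$delta_ratio, 0.4, tolerance = 1e-4)

  # <2 defined ratios in a group: skipped with a reason
  jt <- mk_jt(c(0.4, 0.5), c(0.4, 0.5))
  jt$counts$count[jt$counts$sample == "a_r1"] <- 0L
  res <- test_ratio_alteration(ev, jt)
  expect_match(res$status, "skipped")
  expect_false(res$significant)
})

test_that("bh_fdr is the step-up adjustment", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(66)
  for (k in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), p.adjust(p, method = "BH"))
  }
})

test_that("summarize_rase counts significant events per designed type", {
  cfg <- sim_config(seed = 2)
  d <- simulate_dataset(cfg)
  events <- unlist(lapply(d$models, function(m) {
    detect_events(build_splice_graph(m, d$junctions))
  }), recursive = FALSE)
  res <- test_ratio_alteration(events, d$junctions)
  tab <- summarize_rase(res)
  design <- table(cfg$junction_design$type)
  for (ty in names(design)) {
    expect_equal(tab$n_significant[tab$event_type == ty],
                 unname(design[ty]), info = ty)
  }
  expect_equal(tab$n_significant[tab$event_type == "total"],
               sum(tab$n_significant[tab$event_type != "total"]))

  none <- res; none$significant <- FALSE
  expect_true(all(summarize_rase(none)$n_significant == 0))
})
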