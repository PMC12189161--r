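# Independent, deliberately naive oracle implementations and tiny fixtures.
# These never share code with the package internals they check.

# brute-force per-base overlap count
oracle_coverage <- function(reads, model) {
  L <- model$end - model$start
  depth <- numeric(L)
  for (i in seq_len(nrow(reads))) {
    s <- max(reads$start[i], model$start)
    e <- min(reads$end[i], model$end)
    if (e > s) {
      idx <- (s - model$start + 1L):(e - model$start)
      depth[idx] <- depth[idx] + 1
    }
  }
  depth
}

# literal window-walk transcription of the scanning rules
oracle_scan <- function(depth, params, baseline = NULL) {
  L <- length(depth)
  empty <- data.frame(start = integer(0), end = integer(0),
                      max_depth = numeric(0), median_depth = numeric(0))
  if (L == 0L || all(depth == 0)) return(empty)
  if (is.null(baseline)) baseline <- max(mean(depth), params$baseline_floor)
  ws <- seq.int(0L, L - 1L, by = params$step)
  we <- pmin(ws + params$window, L)
  nw <- length(ws)
  rl <- params$run_length
  bases <- function(i, j) depth[(ws[i] + 1L):we[j]]
  wmean <- function(i) mean(bases(i, i))
  out <- list()
  i <- 1L
  while (i <= nw - rl + 1L) {
    run_a <- all(vapply(i:(i + rl - 1L), wmean, numeric(1)) >
                   params$start_fold * baseline)
    run_b <- stats::median(bases(i, i + rl - 1L)) > params$median_start
    if (!(run_a || run_b)) { i <- i + 1L; next }
    w <- i + rl - 1L
    last <- nw; resume <- nw + 1L; terminated <- FALSE
    repeat {
      w <- w + 1L
      if (w > nw) break
      if (mean(bases(w - rl + 1L, w)) <
            params$stop_fraction * max(bases(i, w))) {
        last <- max(i, w - rl); resume <- w + 1L; terminated <- TRUE
        break
      }
    }
    if (!terminated) { last <- nw; resume <- nw + 1L }
    out[[length(out) + 1L]] <- data.frame(
      start = ws[i], end = we[last], max_depth = max(bases(i, last)),
      median_depth = stats::median(bases(i, last)))
    i <- resume
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

# wrap a raw depth vector as a CoverageProfile
fake_profile <- function(depth, gene_id = "gX") {
  structure(list(gene_id = gene_id, depth = depth, n_reads = 0L,
                 read_lengths = integer(0), n_clipped = 0L),
            class = "CoverageProfile")
}

random_profile <- function(max_len = 2000L) {
  L <- sample(200:max_len, 1L)
  depth <- stats::rpois(L, sample(c(0.2, 1, 3), 1L))
  for (b in seq_len(sample(0:3, 1L))) {
    w <- sample(20:min(300L, L - 1L), 1L)
    s <- sample(0:(L - w), 1L)
    depth[(s + 1L):(s + w)] <- depth[(s + 1L):(s + w)] +
      stats::rpois(w, sample(c(5, 20, 80), 1L))
  }
  depth
}

# minimal three-exon gene (cassette topology) on '+'
tiny_cassette_model <- function(gene_id = "G1", shift = 0L, strand = "+") {
  ex <- function(s, e) data.frame(start = s + shift, end = e + shift)
  gene_model(gene_id, "chrT", strand,
             list(t1 = rbind(ex(0, 120), ex(370, 490), ex(740, 860)),
                  t2 = rbind(ex(0, 120), ex(740, 860))),
             start = shift, end = shift + 1000L)
}

# a config with no planted signal anywhere (uniform background world)
null_sim_config <- function(seed, n_genes = 10L, ...) {
  sim_config(
    seed = seed, n_genes = n_genes,
    planted_peaks = data.frame(gene_id = character(0), offset = integer(0),
                               width = integer(0), fold = numeric(0),
                               ip_only = logical(0)),
    junction_design = data.frame(gene_id = character(0), type = character(0),
                                 strand = character(0), psi1 = numeric(0),
                                 psi2 = numeric(0), depth = numeric(0),
                                 n_rep = integer(0)),
    de_design = data.frame(gene_id = character(0), lfc = numeric(0)),
    ...)
}

# synthetic single-junction event object for ratio-test harnesses
bare_event <- function(id, gene_id = paste0("e", id)) {
  list(gene_id = gene_id, event_type = "cassetteExon",
       inclusion = data.frame(donor = 100L, acceptor = 200L),
       exclusion = data.frame(donor = 100L, acceptor = 300L),
       region_start = 100L, region_end = 300L)
}

# junction table for a set of bare events: one inclusion and one exclusion
# junction per event, counts drawn as depth ~ Pois(depth), inc ~ Bin(depth,
# psi[group]); fully vectorized so large null simulations stay fast
bare_event_counts <- function(n_events, psi1, psi2, depth = 200,
                              n_rep = 3L) {
  samples <- c(sprintf("a_r%d", 1:n_rep), sprintf("b_r%d", 1:n_rep))
  groups <- stats::setNames(rep(c("a", "b"), each = n_rep), samples)
  psi <- c(rep(psi1, n_rep), rep(psi2, n_rep))
  grid_ev <- rep(seq_len(n_events), each = length(samples))
  grid_s <- rep(seq_along(samples), n_events)
  d <- stats::rpois(length(grid_ev), depth)
  inc <- stats::rbinom(length(grid_ev), d, psi[grid_s])
  tab <- data.frame(
    gene_id = rep(paste0("e", grid_ev), 2L),
    donor = 100L,
    acceptor = rep(c(200L, 300L), each = length(grid_ev)),
    sample = rep(samples[grid_s], 2L),
    count = c(inc, d - inc))
  junction_count_table(tab, groups)
}
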