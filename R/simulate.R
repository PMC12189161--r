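# Synthetic-data generator: produces every input the pipeline consumes with
# known planted signal (peaks, splicing-ratio shifts, DE genes, decay rates),
# recorded in a ground-truth manifest. Fully deterministic under one seed.

#' Simulation configuration
#'
#' Defaults describe the package's reference fixture: 30 genes on one toy
#' chromosome, 2 IP + 2 input RIP libraries, three planted IP-only peaks at
#' 5/10/20-fold over background, 12 planted splicing-ratio shifts covering all
#' nine junction-defined event types, 5 planted DE genes at |log2FC| > 1, and
#' actinomycin-D decay series for a control (half-life 60.31 min) and a
#' knockdown (47.82 min) condition. Exactly one gene (`g01`) is planted in
#' all three evidence channels.
#'
#' @param seed integer master seed.
#' @param n_genes number of genes (>= 18 with default designs).
#' @param gene_length_range gene body length range, bp.
#' @param read_length simulated read length, bp.
#' @param background_rate expected background reads per kb per sample.
#' @param n_ip,n_input RIP library replicate counts.
#' @param planted_peaks data.frame: gene_id, offset (bp from gene start, NA =
#'   centered), width (bp), fold (> 1), ip_only (logical).
#' @param junction_design data.frame: gene_id, type (one of the nine event
#'   types), strand, psi1, psi2 (inclusion ratios per group, in `[0, 1]`),
#'   depth (mean junction depth), n_rep (replicates per group).
#' @param de_design data.frame: gene_id, lfc (log2 fold change, group 2 vs 1).
#' @param de_n_rep count-matrix replicates per group.
#' @param de_dispersion negative-binomial dispersion.
#' @param de_mu_range log-uniform range of baseline gene means.
#' @param de_mu_planted baseline mean forced for planted DE genes.
#' @param decay_design data.frame: condition, half_life (min, may be `Inf`),
#'   cv (lognormal noise CV), n_rep.
#' @param decay_times time points in minutes (must include 0).
#' @param overlap_gene gene planted in all three evidence sets.
#' @return list of class `SimulationConfig`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 30L,
                       gene_length_range = c(4000L, 8000L),
                       read_length = 50L,
                       background_rate = 20,
                       n_ip = 2L,
                       n_input = 2L,
                       planted_peaks = NULL,
                       junction_design = NULL,
                       de_design = NULL,
                       de_n_rep = 3L,
                       de_dispersion = 0.02,
                       de_mu_range = c(100, 2000),
                       de_mu_planted = 800,
                       decay_design = NULL,
                       decay_times = c(0, 20, 40, 60),
                       overlap_gene = "g01") {
  gid <- function(i) sprintf("g%02d", i)
  gids <- gid(seq_len(n_genes))
  # default designs shrink with n_genes so tiny worlds stay valid
  if (is.null(planted_peaks)) {
    planted_peaks <- data.frame(
      gene_id = c("g01", "g13", "g14"), offset = NA_integer_,
      width = c(300L, 1000L, 150L), fold = c(10, 5, 20), ip_only = TRUE)
    planted_peaks <- planted_peaks[planted_peaks$gene_id %in% gids, ,
                                   drop = FALSE]
  }
  if (is.null(junction_design)) {
    junction_design <- data.frame(
      gene_id = gid(1:12),
      type = c("cassetteExon", "ES", "A5SS", "A3SS", "MXE", "5pMXE",
               "3pMXE", "A3SS&ES", "A5SS&ES", "cassetteExon", "A5SS", "ES"),
      strand = c(rep("+", 9), "-", "-", "+"),
      psi1 = c(0.2, 0.7, 0.3, 0.7, 0.3, 0.65, 0.3, 0.7, 0.3, 0.75, 0.35, 0.65),
      psi2 = c(0.8, 0.3, 0.7, 0.35, 0.65, 0.3, 0.7, 0.3, 0.7, 0.35, 0.75, 0.25),
      depth = 200, n_rep = 3L)
    junction_design <- junction_design[junction_design$gene_id %in% gids, ,
                                       drop = FALSE]
  }
  if (is.null(de_design)) {
    de_design <- data.frame(gene_id = c("g01", "g15", "g16", "g17", "g18"),
                            lfc = c(2.5, 2, -2, 1.5, -1.5))
    de_design <- de_design[de_design$gene_id %in% gids, , drop = FALSE]
  }
  if (is.null(decay_design)) {
    decay_design <- data.frame(condition = c("control", "knockdown"),
                               half_life = c(60.31, 47.82),
                               cv = 0.05, n_rep = 3L)
  }
  cfg <- structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         gene_length_range = as.integer(gene_length_range),
         read_length = as.integer(read_length),
         background_rate = background_rate,
         n_ip = as.integer(n_ip), n_input = as.integer(n_input),
         planted_peaks = planted_peaks, junction_design = junction_design,
         de_design = de_design, de_n_rep = as.integer(de_n_rep),
         de_dispersion = de_dispersion, de_mu_range = de_mu_range,
         de_mu_planted = de_mu_planted,
         decay_design = decay_design, decay_times = decay_times,
         overlap_gene = overlap_gene),
    class = "SimulationConfig")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  abort_if(cfg$n_genes < 1L, "n_genes must be >= 1")
  jd <- cfg$junction_design
  abort_if(any(jd$psi1 < 0 | jd$psi1 > 1 | jd$psi2 < 0 | jd$psi2 > 1),
           "splicing ratios psi must lie in [0, 1]")
  abort_if(any(!jd$type %in% names(event_templates())),
           "unknown event type in junction_design")
  abort_if(any(cfg$planted_peaks$fold <= 1),
           "planted peak fold-enrichment must be > 1")
  abort_if(any(cfg$decay_design$half_life <= 0), "half-life must be > 0")
  abort_if(!0 %in% cfg$decay_times, "decay time points must include 0")
  abort_if(any(cfg$decay_times < 0), "negative decay time")
  gmax <- max(vapply(event_templates(), function(t) t$span, numeric(1))) + 200L
  abort_if(cfg$gene_length_range[1] < gmax,
           "gene_length_range too small to host the exon templates (need >= ",
           gmax, " bp)")
  invisible(TRUE)
}

# --- exon-structure templates ------------------------------------------------

# Each template: transcripts (exon data.frames, relative coords), the designed
# event's inclusion/exclusion junctions (intron intervals), variable region,
# and total span. Templates are written for '+' orientation and mirrored for
# '-' genes, which preserves the biological event type.
event_templates <- function() {
  ex <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(start = m[, 1], end = m[, 2])
  }
  jn <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(donor = m[, 1], acceptor = m[, 2])
  }
  list(
    cassetteExon = list(
      transcripts = list(t1 = ex(0, 120, 370, 490, 740, 860),
                         t2 = ex(0, 120, 740, 860)),
      incl = jn(120, 370, 490, 740), excl = jn(120, 740),
      region = c(370, 490), span = 860),
    ES = list(
      transcripts = list(t1 = ex(0, 120, 370, 490, 740, 860, 1110, 1230),
                         t2 = ex(0, 120, 1110, 1230)),
      incl = jn(120, 370, 490, 740, 860, 1110), excl = jn(120, 1110),
      region = c(370, 860), span = 1230),
    A5SS = list(
      transcripts = list(t1 = ex(0, 170, 420, 540), t2 = ex(0, 120, 420, 540)),
      incl = jn(170, 420), excl = jn(120, 420),
      region = c(120, 170), span = 540),
    A3SS = list(
      transcripts = list(t1 = ex(0, 120, 370, 490), t2 = ex(0, 120, 420, 490)),
      incl = jn(120, 370), excl = jn(120, 420),
      region = c(370, 420), span = 490),
    MXE = list(
      transcripts = list(t1 = ex(0, 120, 370, 490, 1110, 1230),
                         t2 = ex(0, 120, 740, 860, 1110, 1230)),
      incl = jn(120, 370, 490, 1110), excl = jn(120, 740, 860, 1110),
      region = c(370, 860), span = 1230),
    `5pMXE` = list(
      transcripts = list(t1 = ex(0, 120, 740, 860, 1110, 1230),
                         t2 = ex(370, 490, 740, 860, 1110, 1230)),
      incl = jn(120, 740), excl = jn(490, 740),
      region = c(0, 490), span = 1230),
    `3pMXE` = list(
      transcripts = list(t1 = ex(0, 120, 370, 490, 740, 860),
                         t2 = ex(0, 120, 370, 490, 1110, 1230)),
      incl = jn(490, 740), excl = jn(490, 1110),
      region = c(740, 1230), span = 1230),
    `A3SS&ES` = list(
      transcripts = list(t1 = ex(0, 120, 370, 490, 740, 860),
                         t2 = ex(0, 120, 790, 860)),
      incl = jn(120, 370, 490, 740), excl = jn(120, 790),
      region = c(370, 790), span = 860),
    `A5SS&ES` = list(
      transcripts = list(t1 = ex(0, 120, 420, 540, 790, 910),
                         t2 = ex(0, 170, 790, 910)),
      incl = jn(120, 420, 540, 790), excl = jn(170, 790),
      region = c(120, 540), span = 910),
    constitutive = list(
      transcripts = list(t1 = ex(0, 120, 370, 490, 740, 860)),
      incl = NULL, excl = NULL, region = NULL, span = 860)
  )
}

mirror_template <- function(tpl) {
  L <- tpl$span
  flip_ex <- function(ex) {
    out <- data.frame(start = L - ex$end, end = L - ex$start)
    out[order(out$start), , drop = FALSE]
  }
  flip_jn <- function(j) {
    if (is.null(j)) return(NULL)
    out <- data.frame(donor = L - j$acceptor, acceptor = L - j$donor)
    out[order(out$donor), , drop = FALSE]
  }
  list(transcripts = lapply(tpl$transcripts, flip_ex),
       incl = flip_jn(tpl$incl), excl = flip_jn(tpl$excl),
       region = if (is.null(tpl$region)) NULL else sort(L - tpl$region),
       span = L)
}

encode_junctions <- function(j) {
  paste(sprintf("%d:%d", as.integer(j$donor), as.integer(j$acceptor)),
        collapse = ",")
}

decode_junctions <- function(s) {
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  data.frame(donor = as.integer(vapply(parts, `[`, "", 1L)),
             acceptor = as.integer(vapply(parts, `[`, "", 2L)))
}

# --- generators --------------------------------------------------------------

#' Simulate gene models
#'
#' Lays non-overlapping genes along one toy chromosome. Genes named in the
#' config's `junction_design` receive the exon template of their designed
#' event type ('-' strand genes get the mirrored template); remaining genes
#' get a constitutive 3-exon structure.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; defaults to a stream derived from `config$seed`.
#' @return list of `GeneModel` with attributes `planted_events` (data.table:
#'   gene_id, type, incl/excl junction strings in absolute coordinates,
#'   region) and `chrom`.
#' @export
simulate_gene_models <- function(config, seed = derive_seed(config$seed, 1L)) {
  set.seed(seed)
  tpls <- event_templates()
  gids <- sprintf("g%02d", seq_len(config$n_genes))
  jd <- config$junction_design
  abort_if(any(!jd$gene_id %in% gids), "junction_design names unknown genes")
  chrom <- "chrS"
  pos <- 1000L
  models <- list()
  ev_rows <- list()
  for (g in gids) {
    row <- jd[jd$gene_id == g, , drop = FALSE]
    if (nrow(row) == 1L) {
      tpl <- tpls[[row$type]]
      strand <- row$strand
      if (strand == "-") tpl <- mirror_template(tpl)
    } else {
      tpl <- tpls$constitutive
      strand <- "+"
    }
    glen <- sample(config$gene_length_range[1]:config$gene_length_range[2], 1L)
    pad_max <- glen - tpl$span - 100L
    pad <- if (pad_max <= 100L) 50L else sample(100:pad_max, 1L)
    shift <- pos + pad
    txs <- lapply(tpl$transcripts, function(ex) {
      data.frame(start = ex$start + shift, end = ex$end + shift)
    })
    models[[g]] <- gene_model(g, chrom, strand, txs,
                              start = pos, end = pos + glen)
    if (nrow(row) == 1L) {
      abs_j <- function(j) {
        j$donor <- j$donor + shift; j$acceptor <- j$acceptor + shift; j
      }
      ev_rows[[g]] <- data.table::data.table(
        gene_id = g, type = row$type, strand = strand,
        incl_junctions = encode_junctions(abs_j(tpl$incl)),
        excl_junctions = encode_junctions(abs_j(tpl$excl)),
        region_start = tpl$region[1] + shift,
        region_end = tpl$region[2] + shift,
        psi1 = row$psi1, psi2 = row$psi2,
        depth = row$depth, n_rep = row$n_rep)
    }
    pos <- pos + glen + 1000L
  }
  attr(models, "planted_events") <- data.table::rbindlist(ev_rows)
  attr(models, "chrom") <- chrom
  models
}

#' Simulate RIP-seq read placements
#'
#' Background reads fall uniformly over each gene at
#' `Poisson(background_rate x length/1000)` per sample; each planted peak adds
#' `Poisson(fold x background_rate x width/1000)` reads confined to its window
#' in IP samples (and in input too unless `ip_only`).
#'
#' @param config a [sim_config()].
#' @param models output of [simulate_gene_models()].
#' @param seed RNG seed.
#' @return data.table of reads (sample, gene_id, chrom, start, end, strand)
#'   with attribute `planted_peaks` giving absolute peak windows.
#' @export
simulate_rip_reads <- function(config, models,
                               seed = derive_seed(config$seed, 2L)) {
  set.seed(seed)
  rl <- config$read_length
  samples <- c(sprintf("ip_r%d", seq_len(config$n_ip)),
               sprintf("input_r%d", seq_len(config$n_input)))
  is_ip <- grepl("^ip_", samples)
  pk <- config$planted_peaks
  pk_abs <- NULL
  if (nrow(pk) > 0L) {
    abort_if(any(!pk$gene_id %in% names(models)),
             "planted peak on unknown gene")
    pk_abs <- do.call(rbind, lapply(seq_len(nrow(pk)), function(i) {
      mod <- models[[pk$gene_id[i]]]
      glen <- mod$end - mod$start
      off <- pk$offset[i]
      if (is.na(off)) off <- (glen - pk$width[i]) %/% 2L
      abort_if(off < 0 || off + pk$width[i] > glen,
               "planted peak outside gene bounds: ", pk$gene_id[i])
      abort_if(pk$width[i] <= rl, "peak width must exceed read length")
      data.frame(gene_id = pk$gene_id[i], start = mod$start + off,
                 end = mod$start + off + pk$width[i], fold = pk$fold[i],
                 ip_only = pk$ip_only[i])
    }))
  }
  out <- list()
  for (s in seq_along(samples)) {
    for (g in names(models)) {
      mod <- models[[g]]
      glen <- mod$end - mod$start
      n_bg <- stats::rpois(1L, config$background_rate * glen / 1000)
      starts <- if (n_bg > 0L) {
        mod$start + sample.int(glen - rl + 1L, n_bg, replace = TRUE) - 1L
      } else integer(0)
      if (!is.null(pk_abs)) {
        rows <- pk_abs[pk_abs$gene_id == g, , drop = FALSE]
        for (i in seq_len(nrow(rows))) {
          if (rows$ip_only[i] && !is_ip[s]) next
          w <- rows$end[i] - rows$start[i]
          n_pk <- stats::rpois(1L, rows$fold[i] * config$background_rate *
                                 w / 1000)
          if (n_pk > 0L) {
            starts <- c(starts, rows$start[i] +
                          sample.int(w - rl + 1L, n_pk, replace = TRUE) - 1L)
          }
        }
      }
      if (length(starts) > 0L) {
        out[[length(out) + 1L]] <- data.table::data.table(
          sample = samples[s], gene_id = g, chrom = mod$chrom,
          start = as.integer(starts), end = as.integer(starts) + rl,
          strand = mod$strand)
      }
    }
  }
  reads <- data.table::rbindlist(out)
  attr(reads, "planted_peaks") <- pk_abs
  reads
}

#' Simulate a splice-junction count table
#'
#' For each planted event, sample and group: total event depth is a Poisson
#' draw around the designed mean; the inclusion total is
#' `Binomial(depth, psi_group)` and is split evenly (multinomially) across the
#' event's inclusion junctions, the remainder across the exclusion junctions,
#' so that the summed inclusion ratio converges to psi. Constitutive annotated
#' junctions receive independent Poisson counts at the same mean depth.
#'
#' @param config a [sim_config()].
#' @param models output of [simulate_gene_models()].
#' @param seed RNG seed.
#' @return a `JunctionCountTable` (groups `ctrl` / `case`).
#' @export
simulate_junction_counts <- function(config, models,
                                     seed = derive_seed(config$seed, 3L)) {
  set.seed(seed)
  ev <- attr(models, "planted_events")
  n_rep <- if (nrow(ev) > 0L) max(ev$n_rep) else 3L
  samples <- c(sprintf("ctrl_r%d", seq_len(n_rep)),
               sprintf("case_r%d", seq_len(n_rep)))
  groups <- stats::setNames(rep(c("ctrl", "case"), each = n_rep), samples)
  base_depth <- if (nrow(ev) > 0L) mean(ev$depth) else 200

  split_counts <- function(total, k) {
    if (k == 1L) return(total)
    as.integer(stats::rmultinom(1L, total, rep(1 / k, k)))
  }
  rows <- list()
  event_j <- character(0)
  for (i in seq_len(nrow(ev))) {
    inc <- decode_junctions(ev$incl_junctions[i])
    exc <- decode_junctions(ev$excl_junctions[i])
    event_j <- c(event_j, paste(ev$gene_id[i], c(inc$donor, exc$donor),
                                c(inc$acceptor, exc$acceptor)))
    psi <- c(rep(ev$psi1[i], n_rep), rep(ev$psi2[i], n_rep))
    for (s in seq_along(samples)) {
      depth <- stats::rpois(1L, ev$depth[i])
      n_inc <- stats::rbinom(1L, depth, psi[s])
      rows[[length(rows) + 1L]] <- data.table::data.table(
        gene_id = ev$gene_id[i],
        donor = c(inc$donor, exc$donor),
        acceptor = c(inc$acceptor, exc$acceptor),
        sample = samples[s],
        count = c(split_counts(n_inc, nrow(inc)),
                  split_counts(depth - n_inc, nrow(exc))))
    }
  }
  for (g in names(models)) {
    ann <- gene_annotated_junctions(models[[g]])
    if (nrow(ann) == 0L) next
    keep <- !paste(g, ann$donor, ann$acceptor) %in% event_j
    ann <- ann[keep, ]
    if (nrow(ann) == 0L) next
    for (s in samples) {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        gene_id = g, donor = ann$donor, acceptor = ann$acceptor, sample = s,
        count = stats::rpois(nrow(ann), base_depth))
    }
  }
  junction_count_table(data.table::rbindlist(rows), groups)
}

#' Simulate a negative-binomial count matrix
#'
#' Gene means are log-uniform over `de_mu_range`; planted DE genes get a
#' baseline mean of `de_mu_planted` and a group-2 mean scaled by `2^lfc`.
#'
#' @param config a [sim_config()].
#' @param models output of [simulate_gene_models()].
#' @param seed RNG seed.
#' @return integer matrix genes x samples with `groups` attribute
#'   (`ctrl` / `case`).
#' @export
simulate_counts <- function(config, models,
                            seed = derive_seed(config$seed, 4L)) {
  set.seed(seed)
  gids <- names(models)
  n_rep <- config$de_n_rep
  samples <- c(sprintf("rna_ctrl_r%d", seq_len(n_rep)),
               sprintf("rna_case_r%d", seq_len(n_rep)))
  mu <- exp(stats::runif(length(gids), log(config$de_mu_range[1]),
                         log(config$de_mu_range[2])))
  names(mu) <- gids
  lfc <- stats::setNames(rep(0, length(gids)), gids)
  de <- config$de_design
  abort_if(any(!de$gene_id %in% gids), "de_design names unknown genes")
  mu[de$gene_id] <- config$de_mu_planted
  lfc[de$gene_id] <- de$lfc
  size <- 1 / config$de_dispersion
  m <- matrix(0L, nrow = length(gids), ncol = length(samples),
              dimnames = list(gids, samples))
  for (j in seq_along(samples)) {
    mu_j <- if (j <= n_rep) mu else mu * 2^lfc
    m[, j] <- stats::rnbinom(length(gids), mu = mu_j, size = size)
  }
  attr(m, "groups") <- stats::setNames(rep(c("ctrl", "case"), each = n_rep),
                                       samples)
  attr(m, "true_lfc") <- lfc
  m
}

#' Simulate actinomycin-D decay time courses
#'
#' Raw abundance at time t is `exp(-ln2 t / H)` times multiplicative
#' lognormal noise with the configured CV (qPCR ratios are positive and
#' roughly log-normal); each replicate's series is then divided by its own
#' noisy t = 0 draw, as a 2^-ddCt readout relative to t = 0 would be.
#' `half_life = Inf` yields a flat (no-decay) series.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return data.table: condition, replicate, time_min, rel_abundance.
#' @export
simulate_decay <- function(config, seed = derive_seed(config$seed, 5L)) {
  set.seed(seed)
  dd <- config$decay_design
  times <- sort(config$decay_times)
  abort_if(any(times < 0), "negative time")
  rows <- list()
  for (i in seq_len(nrow(dd))) {
    H <- dd$half_life[i]
    sdlog <- sqrt(log(1 + dd$cv[i]^2))
    for (r in seq_len(dd$n_rep[i])) {
      mean_curve <- if (is.finite(H)) exp(-log(2) * times / H) else
        rep(1, length(times))
      noise <- if (sdlog > 0) stats::rlnorm(length(times), -sdlog^2 / 2, sdlog)
        else rep(1, length(times))
      raw <- mean_curve * noise
      rows[[length(rows) + 1L]] <- data.table::data.table(
        condition = dd$condition[i], replicate = r, time_min = times,
        rel_abundance = raw / raw[times == 0])
    }
  }
  data.table::rbindlist(rows)
}

#' Generate the full synthetic dataset
#'
#' Runs every generator under one master seed and (optionally) writes all
#' artifacts plus a ground-truth manifest to `outdir`: `genes.gtf`,
#' `reads.tsv`, `junctions.tsv` + `junction_groups.json`, `counts.tsv` +
#' `counts_groups.json`, `decay.tsv`, `manifest.json`.
#'
#' @param config a [sim_config()].
#' @param outdir output directory, or `NULL` to skip writing.
#' @return list with elements `models`, `reads`, `junctions`, `counts`,
#'   `decay`, `manifest`.
#' @export
simulate_dataset <- function(config = sim_config(), outdir = NULL) {
  models <- simulate_gene_models(config)
  reads <- simulate_rip_reads(config, models)
  junctions <- simulate_junction_counts(config, models)
  counts <- simulate_counts(config, models)
  decay <- simulate_decay(config)
  ev <- attr(models, "planted_events")
  manifest <- list(
    seed = config$seed,
    overlap_gene = config$overlap_gene,
    peak_genes = unique(config$planted_peaks$gene_id),
    planted_peaks = attr(reads, "planted_peaks"),
    planted_events = as.data.frame(ev),
    de_genes = config$de_design$gene_id,
    de_design = config$de_design,
    decay_design = config$decay_design)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_gtf(models, file.path(outdir, "genes.gtf"))
    data.table::fwrite(reads, file.path(outdir, "reads.tsv"), sep = "\t")
    data.table::fwrite(junctions$counts, file.path(outdir, "junctions.tsv"),
                       sep = "\t")
    write_group_map(junctions$groups,
                    file.path(outdir, "junction_groups.json"))
    cdt <- data.table::data.table(gene_id = rownames(counts))
    cdt <- cbind(cdt, data.table::as.data.table(unclass(counts)))
    data.table::fwrite(cdt, file.path(outdir, "counts.tsv"), sep = "\t")
    write_group_map(attr(counts, "groups"),
                    file.path(outdir, "counts_groups.json"))
    data.table::fwrite(decay, file.path(outdir, "decay.tsv"), sep = "\t")
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(models = models, reads = reads, junctions = junctions,
       counts = counts, decay = decay, manifest = manifest)
}
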