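# Junction-based alternative-splicing event detection, splicing ratios, and
# group-wise ratio-alteration testing under BH-FDR.
#
# Event vocabulary (junctions only; intron retention is out of scope):
#   cassetteExon  one skippable internal exon vs. a single bridging junction
#   ES            >= 2 consecutive internal exons skipped together
#   A5SS / A3SS   two junctions sharing one end, the other end shifted within
#                 overlapping exons (alternative donor / acceptor site)
#   MXE           two internal exons never on the same path, each with its
#                 own inclusion junction pair between common flanks
#   5pMXE / 3pMXE mutually exclusive alternative first / last exons
#   A3SS&ES/A5SS&ES a skipping junction whose distal end also shifts the
#                 acceptor / donor relative to the inclusion chain
# All rules are stated in genomic coordinates and renamed by strand (on '-'
# the donor is the genomic-right intron end, so A5SS <-> A3SS and
# 5pMXE <-> 3pMXE swap).

#' Build a splice graph for one gene
#'
#' Collects the gene's annotated junctions and the observed junctions from a
#' count table; junctions crossing the gene bounds are dropped with a
#' warning. Observed junctions absent from the annotation are flagged novel.
#'
#' @param model a `GeneModel`.
#' @param junctions a `JunctionCountTable` (or `NULL` for annotation only).
#' @return list of class `SpliceGraph`: `gene_id`, `strand`, `exons`
#'   (data.table with first/last flags), `junctions` (data.table with
#'   donor, acceptor, annotated, novel), `counts` (per-sample counts in long
#'   form).
#' @export
build_splice_graph <- function(model, junctions = NULL) {
  ann <- gene_annotated_junctions(model)
  ann$annotated <- TRUE
  counts <- NULL
  if (!is.null(junctions)) {
    counts <- junctions$counts[junctions$counts$gene_id == model$gene_id, ]
    if (nrow(counts) > 0L) {
      bad <- counts$donor < model$start | counts$acceptor > model$end
      if (any(bad)) {
        warning(sum(bad), " junction(s) crossing the bounds of gene ",
                model$gene_id, " dropped")
        counts <- counts[!bad, ]
      }
    }
  }
  obs <- if (!is.null(counts) && nrow(counts) > 0L) {
    unique(counts[, c("donor", "acceptor")])
  } else {
    data.table::data.table(donor = integer(0), acceptor = integer(0))
  }
  obs$observed <- rep(TRUE, nrow(obs))
  j <- merge(ann, obs, by = c("donor", "acceptor"), all = TRUE)
  j$annotated[is.na(j$annotated)] <- FALSE
  j$novel <- !j$annotated
  j$observed <- NULL
  data.table::setorder(j, donor, acceptor)
  structure(list(gene_id = model$gene_id, strand = model$strand,
                 exons = gene_exon_table(model), junctions = j,
                 counts = counts),
            class = "SpliceGraph")
}

# exon indices whose end/start equals a position
exons_ending_at <- function(exons, pos) which(exons$end == pos)
exons_starting_at <- function(exons, pos) which(exons$start == pos)

exons_overlap_any <- function(exons, ia, ib) {
  if (length(ia) == 0L || length(ib) == 0L) return(FALSE)
  any(outer(seq_along(ia), seq_along(ib), Vectorize(function(x, y) {
    intervals_overlap(exons$start[ia[x]], exons$end[ia[x]],
                      exons$start[ib[y]], exons$end[ib[y]])
  })))
}

has_junction <- function(j, d, a) any(j$donor == d & j$acceptor == a)

# Enumerate inclusion chains: sequences of >= 2 junctions where consecutive
# junctions are bridged by an exactly-annotated exon. Returns a list of
# integer vectors of junction row indices.
enumerate_chains <- function(graph, max_links = 4L) {
  j <- graph$junctions
  exons <- graph$exons
  nj <- nrow(j)
  if (nj < 2L) return(list())
  # successor map: junction b can follow junction a if an annotated exon is
  # exactly [a$acceptor, b$donor]
  succ <- lapply(seq_len(nj), function(a) {
    which(vapply(seq_len(nj), function(b) {
      j$donor[b] > j$acceptor[a] &&
        any(exons$start == j$acceptor[a] & exons$end == j$donor[b])
    }, logical(1)))
  })
  chains <- list()
  grow <- function(chain) {
    if (length(chain) >= 2L) chains[[length(chains) + 1L]] <<- chain
    if (length(chain) >= max_links) return(invisible(NULL))
    for (nxt in succ[[chain[length(chain)]]]) grow(c(chain, nxt))
    invisible(NULL)
  }
  for (a in seq_len(nj)) grow(a)
  chains
}

strand_name <- function(type, strand) {
  if (strand != "-") return(type)
  swap <- c(A5SS = "A3SS", A3SS = "A5SS", `5pMXE` = "3pMXE",
            `3pMXE` = "5pMXE", `A3SS&ES` = "A5SS&ES", `A5SS&ES` = "A3SS&ES")
  if (type %in% names(swap)) unname(swap[type]) else type
}

make_event <- function(gene_id, type, j, incl_idx, excl_idx, region) {
  list(gene_id = gene_id, event_type = type,
       inclusion = j[incl_idx, c("donor", "acceptor")],
       exclusion = j[excl_idx, c("donor", "acceptor")],
       region_start = region[1], region_end = region[2])
}

#' Detect alternative splicing events in a splice graph
#'
#' Classifies junction patterns into the nine event types (see the module
#' header comment for the rules). Inclusion sets follow the package
#' convention: the exon-retaining chain for skipping-family events, the
#' shorter-intron junction for alternative-site events, and the path of the
#' transcript-5'-most variable exon for mutually-exclusive families. Novel
#' junctions not participating in any event are reported in the
#' `unclassified` attribute.
#'
#' @param graph a [build_splice_graph()] result.
#' @return list of `SpliceEvent` (deduplicated); attribute `unclassified`
#'   holds leftover novel junctions.
#' @export
detect_events <- function(graph) {
  j <- graph$junctions
  exons <- graph$exons
  strand <- graph$strand
  events <- list()
  used <- rep(FALSE, nrow(j))
  add <- function(type, incl_idx, excl_idx, region) {
    events[[length(events) + 1L]] <<- make_event(
      graph$gene_id, strand_name(type, strand), j, incl_idx, excl_idx, region)
    used[c(incl_idx, excl_idx)] <<- TRUE
  }
  if (nrow(j) >= 2L) {
    chains <- enumerate_chains(graph)
    # --- skipping family -----------------------------------------------------
    for (chain in chains) {
      D <- j$donor[chain[1L]]
      A <- j$acceptor[chain[length(chain)]]
      n_skipped <- length(chain) - 1L
      for (s in seq_len(nrow(j))) {
        if (s %in% chain) next
        ds <- j$donor[s]; as_ <- j$acceptor[s]
        if (ds == D && as_ == A) {
          add(if (n_skipped == 1L) "cassetteExon" else "ES",
              chain, s, c(j$acceptor[chain[1L]], j$donor[chain[length(chain)]]))
        } else if (ds == D && as_ != A &&
                     exons_overlap_any(exons, exons_starting_at(exons, as_),
                                       exons_starting_at(exons, A))) {
          add("A3SS&ES", chain, s,
              c(j$acceptor[chain[1L]], max(as_, A)))
        } else if (as_ == A && ds != D &&
                     exons_overlap_any(exons, exons_ending_at(exons, ds),
                                       exons_ending_at(exons, D))) {
          add("A5SS&ES", chain, s,
              c(min(ds, D), j$donor[chain[length(chain)]]))
        }
      }
    }
    # --- pairwise patterns ---------------------------------------------------
    for (a in seq_len(nrow(j) - 1L)) {
      for (b in (a + 1L):nrow(j)) {
        da <- j$donor[a]; aa <- j$acceptor[a]
        db <- j$donor[b]; ab <- j$acceptor[b]
        if (aa == ab && da != db) {
          # shared genomic-right end, alternative left ends
          lo <- if (da < db) a else b; hi <- if (da < db) b else a
          ex_lo <- exons_ending_at(exons, j$donor[lo])
          ex_hi <- exons_ending_at(exons, j$donor[hi])
          if (exons_overlap_any(exons, ex_lo, ex_hi)) {
            # alt donor within one exon: inclusion keeps the extension
            add("A5SS", hi, lo, c(j$donor[lo], j$donor[hi]))
          } else if (length(ex_lo) > 0L && length(ex_hi) > 0L &&
                       all(exons$first[ex_lo]) && all(exons$first[ex_hi]) &&
                       !any(vapply(ex_lo, function(x) any(vapply(ex_hi,
                         function(y) has_junction(j, exons$end[x],
                                                  exons$start[y]),
                         logical(1))), logical(1)))) {
            add("5pMXE", lo, hi,
                c(min(exons$start[ex_lo]), max(exons$end[ex_hi])))
          }
        } else if (da == db && aa != ab) {
          lo <- if (aa < ab) a else b; hi <- if (aa < ab) b else a
          ex_lo <- exons_starting_at(exons, j$acceptor[lo])
          ex_hi <- exons_starting_at(exons, j$acceptor[hi])
          if (exons_overlap_any(exons, ex_lo, ex_hi)) {
            add("A3SS", lo, hi, c(j$acceptor[lo], j$acceptor[hi]))
          } else if (length(ex_lo) > 0L && length(ex_hi) > 0L) {
            term_lo <- all(exons$last[ex_lo]); term_hi <- all(exons$last[ex_hi])
            no_bridge <- !any(vapply(ex_lo, function(x) any(vapply(ex_hi,
              function(y) has_junction(j, exons$end[x], exons$start[y]),
              logical(1))), logical(1)))
            if (term_lo && term_hi && no_bridge) {
              add("3pMXE", lo, hi,
                  c(min(exons$start[ex_lo]), max(exons$end[ex_hi])))
            } else if (!term_lo && !term_hi && no_bridge) {
              # internal MXE: need each variable exon's outgoing junction to a
              # common downstream acceptor
              out_lo <- which(vapply(seq_len(nrow(j)), function(k) {
                any(exons$start[ex_lo] == j$acceptor[lo] &
                      exons$end[ex_lo] == j$donor[k])
              }, logical(1)))
              out_hi <- which(vapply(seq_len(nrow(j)), function(k) {
                any(exons$start[ex_hi] == j$acceptor[hi] &
                      exons$end[ex_hi] == j$donor[k])
              }, logical(1)))
              common <- intersect(j$acceptor[out_lo], j$acceptor[out_hi])
              if (length(common) > 0L) {
                A2 <- common[1L]
                add("MXE",
                    c(lo, out_lo[j$acceptor[out_lo] == A2][1L]),
                    c(hi, out_hi[j$acceptor[out_hi] == A2][1L]),
                    c(min(exons$start[ex_lo]), max(exons$end[ex_hi])))
              }
            }
          }
        }
      }
    }
  }
  # MXE-family inclusion convention: path of the transcript-5'-most variable
  # exon. The pairwise loop assigns the genomic-left path as inclusion, which
  # is 5'-most on '+'; swap on '-'.
  if (strand == "-") {
    for (i in seq_along(events)) {
      if (events[[i]]$event_type %in% c("MXE", "5pMXE", "3pMXE")) {
        tmp <- events[[i]]$inclusion
        events[[i]]$inclusion <- events[[i]]$exclusion
        events[[i]]$exclusion <- tmp
      }
    }
  }
  # dedupe by (type, junction sets)
  if (length(events) > 0L) {
    key <- vapply(events, function(e) paste(
      e$event_type, encode_junctions(e$inclusion),
      encode_junctions(e$exclusion), sep = "|"), character(1))
    events <- events[!duplicated(key)]
  }
  leftover <- j[j$novel & !used, , drop = FALSE]
  attr(events, "unclassified") <- leftover
  events
}

#' Per-sample splicing ratio of an event
#'
#' `ratio = sum(inclusion counts) / (sum(inclusion) + sum(exclusion))`;
#' `NA` when the denominator is zero.
#'
#' @param event a `SpliceEvent` from [detect_events()].
#' @param junctions a `JunctionCountTable`.
#' @param sample sample id.
#' @return numeric ratio in `[0, 1]` or `NA`.
#' @export
event_ratio <- function(event, junctions, sample) {
  cnt <- junctions$counts
  get_sum <- function(jset) {
    s <- 0
    for (i in seq_len(nrow(jset))) {
      s <- s + sum(cnt$count[cnt$gene_id == event$gene_id &
                               cnt$donor == jset$donor[i] &
                               cnt$acceptor == jset$acceptor[i] &
                               cnt$sample == sample])
    }
    s
  }
  inc <- get_sum(event$inclusion)
  exc <- get_sum(event$exclusion)
  if (inc + exc == 0) return(NA_real_)
  inc / (inc + exc)
}

# Closed-form two-sample t (Welch or pooled). Degenerate zero-variance
# cases: equal means -> t = 0, p = 1; unequal -> p = 0.
two_sample_t <- function(x, y, var_equal = FALSE) {
  nx <- length(x); ny <- length(y)
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- if (se > 0) se^4 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
      else NA_real_
  }
  if (!is.finite(se) || se == 0) {
    if (isTRUE(all.equal(mx, my))) return(list(t = 0, p = 1, df = NA_real_))
    return(list(t = sign(mx - my) * Inf, p = 0, df = NA_real_))
  }
  t <- (mx - my) / se
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjusted p-values with cumulative-minimum enforcement.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted values, same order as input.
#' @export
bh_fdr <- function(p) {
  abort_if(any(p < 0 | p > 1, na.rm = TRUE), "p-values must lie in [0, 1]")
  n <- length(p)
  if (n == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

#' Test group-wise splicing-ratio alteration
#'
#' Computes per-sample ratios for each event, runs a two-sample t test per
#' event (Welch by default; `var_equal = TRUE` restores the pooled-variance
#' Student's t) on the two groups, adjusts across all tested events with
#' [bh_fdr()], and flags events significant at `fdr_cut`. Events with fewer
#' than two defined ratios in either group are skipped (status `skipped`).
#'
#' @param events list of `SpliceEvent`.
#' @param junctions a `JunctionCountTable`.
#' @param var_equal use pooled-variance Student's t instead of Welch.
#' @param fdr_cut FDR significance cutoff.
#' @param min_junction_reads optional minimum total event depth per sample for
#'   a ratio to count as defined (default 0 = no filter).
#' @return data.frame, one row per event: gene_id, event_type, region,
#'   inclusion/exclusion junction strings, group means, delta_ratio,
#'   t_statistic, p_value, fdr, significant, status.
#' @export
test_ratio_alteration <- function(events, junctions, var_equal = FALSE,
                                  fdr_cut = 0.05, min_junction_reads = 0) {
  groups <- junctions$groups
  gl <- split(names(groups), unname(groups))
  abort_if(length(gl) != 2L, "need exactly two groups")
  g1 <- gl[[1L]]; g2 <- gl[[2L]]
  samples <- c(g1, g2)
  n_ev <- length(events)
  if (n_ev == 0L) {
    res <- data.frame(gene_id = character(0), event_type = character(0),
                      p_value = numeric(0))
    res$fdr <- numeric(0); res$significant <- logical(0)
    return(res)
  }
  # one merge resolves every event's junction counts at once
  jmap <- data.table::rbindlist(lapply(seq_len(n_ev), function(i) {
    ev <- events[[i]]
    data.table::data.table(
      event = i,
      role = rep(c("incl", "excl"), c(nrow(ev$inclusion),
                                      nrow(ev$exclusion))),
      gene_id = ev$gene_id,
      rbind(ev$inclusion, ev$exclusion))
  }))
  cnt <- junctions$counts[junctions$counts$sample %in% samples, ]
  m <- merge(jmap, cnt, by = c("gene_id", "donor", "acceptor"),
             allow.cartesian = TRUE)
  inc <- matrix(0, n_ev, length(samples),
                dimnames = list(NULL, samples))
  exc <- inc
  if (nrow(m) > 0L) {
    agg <- m[, list(count = sum(count)), by = c("event", "role", "sample")]
    idx <- cbind(agg$event, match(agg$sample, samples))
    is_inc <- agg$role == "incl"
    inc[idx[is_inc, , drop = FALSE]] <- agg$count[is_inc]
    exc[idx[!is_inc, , drop = FALSE]] <- agg$count[!is_inc]
  }
  total <- inc + exc
  ratio <- inc / total            # NaN where total == 0
  ratio[total < max(min_junction_reads, 1)] <- NA_real_
  rows <- lapply(seq_len(n_ev), function(i) {
    ev <- events[[i]]
    r1 <- ratio[i, g1]; r2 <- ratio[i, g2]
    r1 <- r1[!is.na(r1)]; r2 <- r2[!is.na(r2)]
    ok <- length(r1) >= 2L && length(r2) >= 2L
    tt <- if (ok) two_sample_t(r1, r2, var_equal) else
      list(t = NA_real_, p = NA_real_)
    data.frame(
      gene_id = ev$gene_id, event_type = ev$event_type,
      region_start = ev$region_start, region_end = ev$region_end,
      inclusion = encode_junctions(ev$inclusion),
      exclusion = encode_junctions(ev$exclusion),
      mean_ratio_1 = if (length(r1)) mean(r1) else NA_real_,
      mean_ratio_2 = if (length(r2)) mean(r2) else NA_real_,
      delta_ratio = (if (length(r2)) mean(r2) else NA_real_) -
        (if (length(r1)) mean(r1) else NA_real_),
      t_statistic = tt$t, p_value = tt$p,
      status = if (ok) "tested" else "skipped: <2 defined ratios in a group",
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- NA_real_
  tested <- !is.na(res$p_value)
  res$fdr[tested] <- bh_fdr(res$p_value[tested])
  res$significant <- !is.na(res$fdr) & res$fdr < fdr_cut
  res
}

#' Count significant events per type
#'
#' @param results output of [test_ratio_alteration()].
#' @return data.frame with one row per event type plus a `total` row.
#' @export
summarize_rase <- function(results) {
  types <- c("ES", "A5SS", "A3SS", "MXE", "5pMXE", "3pMXE", "cassetteExon",
             "A3SS&ES", "A5SS&ES")
  sig <- results[results$significant, , drop = FALSE]
  n <- vapply(types, function(t) sum(sig$event_type == t), integer(1))
  data.frame(event_type = c(types, "total"),
             n_significant = c(n, sum(n)), row.names = NULL)
}
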