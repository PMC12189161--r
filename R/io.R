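# Tabular and genomics-format readers/writers. All on-disk interval formats
# here (BED, bedGraph) are 0-based half-open, matching internal coordinates.

#' Write peaks as BED6
#'
#' The score column is the peak's maximum per-base depth scaled by
#' `score_scale` and clamped to `[0, 1000]` as BED requires.
#'
#' @param peaks `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `max_depth` and optionally `strand` (default `"+"`).
#' @param path output path.
#' @param score_scale multiplier applied to `max_depth` before clamping.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path, score_scale = 1) {
  peaks <- as.data.frame(peaks)
  if (nrow(peaks) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  validate_interval(peaks$chrom, peaks$start, peaks$end)
  strand <- if ("strand" %in% names(peaks)) peaks$strand else "+"
  score <- pmin(pmax(round(peaks$max_depth * score_scale), 0), 1000)
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", peaks$chrom,
                     as.integer(peaks$start), as.integer(peaks$end),
                     peaks$name, as.integer(score), strand), path)
  invisible(path)
}

#' Read a BED6 file
#' @param path BED file path (track/browser header lines are skipped).
#' @return `data.frame` with columns chrom/start/end/name/score/strand.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = integer(0), strand = character(0)))
  }
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  abort_if(ncol(f) < 6L, "BED6 requires 6 columns, found ", ncol(f))
  out <- data.frame(chrom = f[, 1L], start = as.integer(f[, 2L]),
                    end = as.integer(f[, 3L]), name = f[, 4L],
                    score = as.integer(f[, 5L]), strand = f[, 6L])
  validate_interval(out$chrom, out$start, out$end, out$strand)
  out
}

#' Read per-base coverage from a bedGraph file
#'
#' @param path 4-column bedGraph (chrom, start, end, depth), 0-based
#'   half-open. Overlapping intervals are an error (depth would be
#'   ambiguous). Positions not covered by any interval get depth 0.
#' @return named list, one numeric depth vector per chromosome, each running
#'   from position 0 to the last covered base of that chromosome.
#' @export
read_coverage_bedgraph <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^(track|browser|#|\\s*$)", lines))
  if (length(keep) == 0L) return(structure(list(), names = character(0)))
  f <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(f) != 4L)
  abort_if(length(bad) > 0L, "malformed bedGraph line ", keep[bad[1L]],
           ": expected 4 fields")
  m <- do.call(rbind, f)
  dt <- data.table::data.table(chrom = m[, 1L], start = as.integer(m[, 2L]),
                               end = as.integer(m[, 3L]),
                               depth = as.numeric(m[, 4L]))
  validate_interval(dt$chrom, dt$start, dt$end)
  out <- list()
  for (ch in unique(dt$chrom)) {
    sub <- dt[dt$chrom == ch, ][order(start)]
    abort_if(nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)]),
             "overlapping bedGraph intervals on ", ch,
             ": per-base depth is ambiguous")
    v <- numeric(max(sub$end))
    for (i in seq_len(nrow(sub))) {
      v[(sub$start[i] + 1L):sub$end[i]] <- sub$depth[i]
    }
    out[[ch]] <- v
  }
  out
}

#' Write per-base coverage as bedGraph
#' @param coverage named list of per-chromosome depth vectors (position 1 of
#'   the vector is genomic position 0).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coverage_bedgraph <- function(coverage, path) {
  lines <- character(0)
  for (ch in names(coverage)) {
    v <- coverage[[ch]]
    if (length(v) == 0L) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    nz <- r$values != 0
    if (any(nz)) {
      lines <- c(lines, sprintf("%s\t%d\t%d\t%s", ch, starts[nz], ends[nz],
                                format(r$values[nz], trim = TRUE,
                                       scientific = FALSE)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a splice-junction count table
#'
#' TSV with header `gene_id`, `donor`, `acceptor`, `sample`, `count`.
#' `donor`/`acceptor` are the genomic-left/right ends of the intron
#' (0-based half-open intron interval), regardless of strand.
#'
#' @param path TSV path.
#' @param groups named character vector or path to a JSON group map
#'   (sample -> group); must cover every sample and contain two groups.
#' @return object of class `JunctionCountTable`: list with `counts`
#'   (data.table) and `groups`.
#' @export
read_junction_table <- function(path, groups) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("gene_id", "sample")))
  need <- c("gene_id", "donor", "acceptor", "sample", "count")
  abort_if(!all(need %in% names(dt)), "junction table must have columns ",
           paste(need, collapse = ", "))
  bad <- which(dt$count < 0)
  abort_if(length(bad) > 0L, "row ", bad[1L], ": negative junction count")
  bad <- which(dt$donor >= dt$acceptor)
  abort_if(length(bad) > 0L, "row ", bad[1L], ": junction donor must be < acceptor")
  junction_count_table(dt[, need, with = FALSE], groups)
}

#' Construct a junction count table from in-memory counts
#' @param counts data.frame/data.table with columns gene_id, donor, acceptor,
#'   sample, count.
#' @param groups named character vector (sample -> group) or JSON path.
#' @return `JunctionCountTable`.
#' @export
junction_count_table <- function(counts, groups) {
  groups <- resolve_group_map(groups)
  counts <- data.table::as.data.table(counts)
  unknown <- setdiff(unique(counts$sample), names(groups))
  abort_if(length(unknown) > 0L, "samples missing from group map: ",
           paste(unknown, collapse = ", "))
  abort_if(length(unique(groups)) != 2L,
           "group map must define exactly two groups")
  structure(list(counts = counts, groups = groups),
            class = "JunctionCountTable")
}

resolve_group_map <- function(groups) {
  if (is.character(groups) && length(groups) == 1L && file.exists(groups)) {
    groups <- unlist(jsonlite::read_json(groups, simplifyVector = TRUE))
  }
  abort_if(is.null(names(groups)) || any(!nzchar(names(groups))),
           "group map must be named sample -> group")
  groups
}

#' Read a gene x sample count matrix
#'
#' TSV with a `gene_id` column followed by one integer column per sample.
#'
#' @param path TSV path.
#' @param groups named character vector or JSON path (sample -> group);
#'   optional, but required by downstream differential tests.
#' @return integer matrix (genes x samples) with a `groups` attribute.
#' @export
read_count_matrix <- function(path, groups = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  abort_if(!"gene_id" %in% names(dt), "count matrix needs a gene_id column")
  m <- as.matrix(dt[, -"gene_id"])
  rownames(m) <- dt$gene_id
  bad <- which(m < 0, arr.ind = TRUE)
  abort_if(nrow(bad) > 0L, "negative count at row ", bad[1L, 1L],
           " sample ", colnames(m)[bad[1L, 2L]])
  zero <- colnames(m)[colSums(m) == 0]
  abort_if(length(zero) > 0L, "zero-sum count column for sample: ",
           paste(zero, collapse = ", "))
  if (!is.null(groups)) {
    groups <- resolve_group_map(groups)
    unknown <- setdiff(colnames(m), names(groups))
    abort_if(length(unknown) > 0L, "samples missing from group map: ",
             paste(unknown, collapse = ", "))
    attr(m, "groups") <- groups[colnames(m)]
  }
  storage.mode(m) <- "integer"
  m
}

#' Read an actinomycin-D decay time-course table
#'
#' TSV with header `condition`, `replicate`, `time_min`, `rel_abundance`.
#'
#' @param path TSV path.
#' @return data.table, validated (times >= 0, abundances > 0, each
#'   condition/replicate series contains t = 0).
#' @export
read_decay_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("condition", "replicate", "time_min", "rel_abundance")
  abort_if(!all(need %in% names(dt)), "decay table must have columns ",
           paste(need, collapse = ", "))
  bad <- which(dt$time_min < 0)
  abort_if(length(bad) > 0L, "row ", bad[1L], ": negative time")
  bad <- which(dt$rel_abundance <= 0)
  abort_if(length(bad) > 0L, "row ", bad[1L], ": rel_abundance must be > 0")
  has0 <- dt[, list(ok = any(time_min == 0)), by = c("condition", "replicate")]
  abort_if(any(!has0$ok), "every condition/replicate series needs a t = 0 row")
  dt
}

#' Read read placements (BED-like read interval TSV)
#'
#' TSV with header `sample`, `gene_id`, `chrom`, `start`, `end`, `strand`:
#' one aligned read per row, 0-based half-open.
#'
#' @param path TSV path.
#' @return data.table of reads.
#' @export
read_reads_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("sample", "gene_id", "chrom", "start", "end", "strand")
  abort_if(!all(need %in% names(dt)), "reads table must have columns ",
           paste(need, collapse = ", "))
  validate_interval(dt$chrom, dt$start, dt$end, dt$strand)
  dt
}

#' Write a sample -> group map as JSON
#' @param groups named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_group_map <- function(groups, path) {
  jsonlite::write_json(as.list(groups), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
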