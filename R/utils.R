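# Internal assertion / validation helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(paste0(...), call. = FALSE)
  invisible(NULL)
}

#' Validate a genomic interval
#'
#' Intervals are 0-based half-open throughout the package (BED convention);
#' GTF conversion at the file boundary is the only place a +/-1 occurs.
#'
#' @param chrom chromosome name.
#' @param start 0-based inclusive start (bp).
#' @param end 0-based exclusive end (bp).
#' @param strand one of `"+"`, `"-"`, `"."`.
#' @return invisibly `TRUE`; errors describe the violated invariant.
#' @export
validate_interval <- function(chrom, start, end, strand = ".") {
  abort_if(any(is.na(chrom)) || any(!nzchar(chrom)), "empty chromosome name")
  abort_if(any(start < 0), "interval start must be >= 0")
  abort_if(any(end <= start), "interval end must be > start")
  abort_if(any(!strand %in% c("+", "-", ".")),
           "strand must be one of '+', '-', '.'")
  invisible(TRUE)
}

# Length of the union of a set of half-open intervals given as two vectors.
interval_union_length <- function(start, end) {
  if (length(start) == 0L) return(0L)
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  tot <- 0L; cur_s <- start[1L]; cur_e <- end[1L]
  for (i in seq_along(start)[-1L]) {
    if (start[i] > cur_e) {
      tot <- tot + (cur_e - cur_s)
      cur_s <- start[i]; cur_e <- end[i]
    } else {
      cur_e <- max(cur_e, end[i])
    }
  }
  as.integer(tot + (cur_e - cur_s))
}

# TRUE where intervals [s1,e1) and [s2,e2) share >= 1 bp (vectorised).
intervals_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

# Derive a stream-specific 32-bit seed from a master seed; keeps independent
# generators for independent simulation stages reproducible under one seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset * 7919) %% 2147483647)
}
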