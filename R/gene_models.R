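# Gene models: the annotation frame shared by every stage.

#' Construct a gene model
#'
#' A `GeneModel` holds a gene's interval and its transcript structures. All
#' coordinates are 0-based half-open. Exons within a transcript must be
#' non-overlapping; they are stored sorted by genomic start (the 5'->3'
#' biological order is recovered from `strand`).
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"`, `"-"` or `"."`.
#' @param transcripts named list; each element a `data.frame` with integer
#'   columns `start`, `end` (one row per exon).
#' @param start,end optional gene interval; defaults to the exon span.
#' @return an object of class `GeneModel`.
#' @export
gene_model <- function(gene_id, chrom, strand, transcripts,
                       start = NULL, end = NULL) {
  abort_if(length(transcripts) == 0L, "gene ", gene_id, ": no transcripts")
  abort_if(is.null(names(transcripts)) || any(!nzchar(names(transcripts))),
           "gene ", gene_id, ": transcripts must be named by transcript_id")
  ex_all_s <- integer(0); ex_all_e <- integer(0)
  transcripts <- lapply(transcripts, function(ex) {
    ex <- as.data.frame(ex)[, c("start", "end")]
    ex$start <- as.integer(ex$start); ex$end <- as.integer(ex$end)
    validate_interval(chrom, ex$start, ex$end, strand)
    ex <- ex[order(ex$start), , drop = FALSE]
    abort_if(nrow(ex) > 1L && any(ex$start[-1L] < ex$end[-nrow(ex)]),
             "gene ", gene_id, ": overlapping exons within one transcript")
    rownames(ex) <- NULL
    ex
  })
  for (ex in transcripts) {
    ex_all_s <- c(ex_all_s, ex$start); ex_all_e <- c(ex_all_e, ex$end)
  }
  start <- as.integer(start %||% min(ex_all_s))
  end <- as.integer(end %||% max(ex_all_e))
  abort_if(start > min(ex_all_s) || end < max(ex_all_e),
           "gene ", gene_id, ": exons outside the gene interval")
  structure(
    list(gene_id = gene_id, chrom = chrom, start = start, end = end,
         strand = strand, transcripts = transcripts,
         exonic_length = interval_union_length(ex_all_s, ex_all_e)),
    class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel %s %s:%d-%d(%s) | %d transcript(s), exonic %d bp\n",
              x$gene_id, x$chrom, x$start, x$end, x$strand,
              length(x$transcripts), x$exonic_length))
  invisible(x)
}

# Unique exons across transcripts with first/last flags in transcript
# orientation (on '-' the first exon is the genomic-rightmost).
gene_exon_table <- function(model) {
  rows <- lapply(names(model$transcripts), function(tx) {
    ex <- model$transcripts[[tx]]
    n <- nrow(ex)
    first_idx <- if (model$strand == "-") n else 1L
    last_idx <- if (model$strand == "-") 1L else n
    data.table::data.table(start = ex$start, end = ex$end,
                           first = seq_len(n) == first_idx,
                           last = seq_len(n) == last_idx)
  })
  dt <- data.table::rbindlist(rows)
  dt[, list(first = any(first), last = any(last)), by = c("start", "end")]
}

# Annotated introns (junctions) of a model: one row per adjacent exon pair in
# any transcript; donor/acceptor are the genomic-left/right intron ends.
gene_annotated_junctions <- function(model) {
  rows <- lapply(model$transcripts, function(ex) {
    n <- nrow(ex)
    if (n < 2L) return(NULL)
    data.table::data.table(donor = ex$end[-n], acceptor = ex$start[-1L])
  })
  dt <- data.table::rbindlist(rows)
  if (nrow(dt) == 0L) return(dt)
  unique(dt)
}

#' Read gene models from a GTF file
#'
#' Accepts the GTF2.2 dialect: tab-separated, 9 columns, 1-based inclusive
#' coordinates, attributes carrying `gene_id` and `transcript_id`. Only exon
#' features are used to build transcript structures; an optional gene feature
#' widens the gene interval.
#'
#' @param path GTF file path.
#' @return list of [gene_model()] objects, one per `gene_id`, in file order.
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) return(list())
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 9L)
  abort_if(length(bad) > 0L,
           "malformed GTF line ", keep[bad[1L]], ": expected 9 tab-separated ",
           "fields, found ", nf[bad[1L]])
  m <- do.call(rbind, fields)
  feat <- m[, 3L]
  start1 <- suppressWarnings(as.integer(m[, 4L]))
  end1 <- suppressWarnings(as.integer(m[, 5L]))
  bad <- which(is.na(start1) | is.na(end1) | end1 < start1)
  abort_if(length(bad) > 0L,
           "malformed GTF line ", keep[bad[1L]], ": bad coordinates")
  attr_field <- m[, 9L]
  gid <- sub('.*gene_id "([^"]+)".*', "\\1", attr_field)
  gid[!grepl('gene_id "', attr_field, fixed = TRUE)] <- NA_character_
  tid <- sub('.*transcript_id "([^"]+)".*', "\\1", attr_field)
  tid[!grepl('transcript_id "', attr_field, fixed = TRUE)] <- NA_character_
  abort_if(anyNA(gid), "GTF line ", keep[which(is.na(gid))[1L]],
           ": missing gene_id attribute")

  is_exon <- feat == "exon"
  bad <- which(is_exon & is.na(tid))
  abort_if(length(bad) > 0L, "GTF line ", keep[bad[1L]],
           ": exon without transcript_id")

  ex <- data.table::data.table(
    gene_id = gid[is_exon], transcript_id = tid[is_exon],
    chrom = m[is_exon, 1L], strand = m[is_exon, 7L],
    start = start1[is_exon] - 1L, end = end1[is_exon])
  abort_if(nrow(ex) == 0L, "GTF file contains no exon features")

  gene_feat <- data.table::data.table(
    gene_id = gid[feat == "gene"],
    start = start1[feat == "gene"] - 1L, end = end1[feat == "gene"])

  out <- list()
  for (g in unique(ex$gene_id)) {
    sub <- ex[ex$gene_id == g, ]
    abort_if(length(unique(sub$chrom)) > 1L || length(unique(sub$strand)) > 1L,
             "gene ", g, ": exons on multiple chromosomes or strands")
    txs <- split(sub[, c("start", "end")], sub$transcript_id)
    gf <- gene_feat[gene_feat$gene_id == g, ]
    out[[g]] <- gene_model(
      g, sub$chrom[1L], sub$strand[1L], txs,
      start = if (nrow(gf)) min(gf$start) else NULL,
      end = if (nrow(gf)) max(gf$end) else NULL)
  }
  out
}

#' Write gene models to a GTF file
#'
#' Emits gene, transcript and exon features with 1-based inclusive
#' coordinates, inverse of [read_gtf()].
#'
#' @param models list of `GeneModel` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  lines <- character(0)
  fmt <- function(chrom, feat, s0, e0, strand, attrs) {
    sprintf("%s\tripsplice\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, feat, s0 + 1L, e0, strand, attrs)
  }
  for (mod in models) {
    ga <- sprintf('gene_id "%s";', mod$gene_id)
    lines <- c(lines, fmt(mod$chrom, "gene", mod$start, mod$end, mod$strand, ga))
    for (tx in names(mod$transcripts)) {
      ex <- mod$transcripts[[tx]]
      ta <- sprintf('gene_id "%s"; transcript_id "%s";', mod$gene_id, tx)
      lines <- c(lines,
                 fmt(mod$chrom, "transcript", min(ex$start), max(ex$end),
                     mod$strand, ta),
                 fmt(mod$chrom, "exon", ex$start, ex$end, mod$strand, ta))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
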