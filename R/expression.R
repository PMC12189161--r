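# FPKM quantification, a labeled threshold-based differential-expression
# stand-in, and 2^-ddCt relative quantification.

#' FPKM quantification
#'
#' `fpkm(g, s) = counts(g, s) * 1e9 / (library_size(s) * exonic_length(g))`
#' with gene length taken as the exon-union length.
#'
#' @param counts genes x samples count matrix (rownames = gene ids).
#' @param models list of `GeneModel` covering every row.
#' @return numeric matrix of FPKM values, same dimensions.
#' @export
compute_fpkm <- function(counts, models) {
  abort_if(any(!rownames(counts) %in% names(models)),
           "count matrix contains genes absent from the annotation")
  len <- vapply(models[rownames(counts)], function(m) m$exonic_length,
                numeric(1))
  abort_if(any(len <= 0), "exonic_length must be > 0 for all genes")
  lib <- colSums(counts)
  abort_if(any(lib == 0), "zero library size for sample: ",
           paste(colnames(counts)[lib == 0], collapse = ", "))
  sweep(sweep(counts * 1e9, 2, lib, "/"), 1, len, "/")
}

#' Median-of-ratios size factors
#'
#' DESeq-style: per-sample median of count ratios to the per-gene geometric
#' mean, computed over genes positive in all samples.
#'
#' @param counts genes x samples count matrix.
#' @return named numeric vector of size factors.
#' @export
size_factors <- function(counts) {
  log_gm <- rowMeans(log(counts))
  use <- is.finite(log_gm)
  abort_if(!any(use), "no gene is positive in every sample")
  apply(counts, 2, function(col) exp(stats::median(log(col[use]) -
                                                     log_gm[use])))
}

#' Threshold differential expression (stand-in)
#'
#' A deliberately simple replacement for an NB-GLM engine, labeled as such in
#' the `method` attribute: median-of-ratios normalization, log2 fold change
#' of group means with pseudocount 1, Welch t test on log2 normalized counts,
#' BH adjustment, and the published flagging thresholds
#' (padj < `alpha` and |log2FC| > `lfc_cut`).
#'
#' @param counts genes x samples count matrix with a `groups` attribute, or
#'   pass `groups` explicitly (named sample -> group, two groups; group order
#'   follows first appearance: fold changes are group 2 vs group 1).
#' @param groups optional group map overriding the attribute.
#' @param alpha adjusted-p cutoff.
#' @param lfc_cut |log2FC| cutoff.
#' @param var_equal `TRUE` (default) uses the pooled-variance Student's t:
#'   at 2-3 replicates per group Welch's Satterthwaite degrees of freedom
#'   collapse toward 2 and cost roughly a third of the power, which is why
#'   the established count engines pool or shrink variance instead of
#'   testing per-gene unequal variances. `FALSE` gives Welch's t.
#' @return data.frame per gene: base means, log2fc, p_value, padj, de_flag
#'   (`up` / `down` / `none`); attribute `method`.
#' @export
differential_expression <- function(counts, groups = NULL, alpha = 0.05,
                                    lfc_cut = 1, var_equal = TRUE) {
  groups <- groups %||% attr(counts, "groups")
  abort_if(is.null(groups), "no group map supplied")
  groups <- groups[colnames(counts)]
  lev <- unique(unname(groups))
  abort_if(length(lev) != 2L, "need exactly two groups")
  i1 <- which(groups == lev[1L]); i2 <- which(groups == lev[2L])
  abort_if(length(i1) < 2L || length(i2) < 2L,
           "need >= 2 samples per group")
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  lg <- log2(norm + 1)
  m1 <- rowMeans(norm[, i1, drop = FALSE])
  m2 <- rowMeans(norm[, i2, drop = FALSE])
  log2fc <- log2((m2 + 1) / (m1 + 1))
  stats_ <- lapply(seq_len(nrow(lg)), function(i) {
    two_sample_t(lg[i, i2], lg[i, i1], var_equal)
  })
  p <- vapply(stats_, function(s) s$p, numeric(1))
  tstat <- vapply(stats_, function(s) s$t, numeric(1))
  # zero variance in both groups with equal means: no evidence, not a test
  skip <- vapply(seq_len(nrow(lg)), function(i) {
    stats::var(lg[i, i1]) == 0 && stats::var(lg[i, i2]) == 0 &&
      isTRUE(all.equal(mean(lg[i, i1]), mean(lg[i, i2])))
  }, logical(1))
  p[skip] <- NA_real_
  padj <- rep(NA_real_, length(p))
  padj[!is.na(p)] <- bh_fdr(p[!is.na(p)])
  de_flag <- rep("none", length(p))
  de_flag[!is.na(padj) & padj < alpha & log2fc > lfc_cut] <- "up"
  de_flag[!is.na(padj) & padj < alpha & log2fc < -lfc_cut] <- "down"
  res <- data.frame(gene_id = rownames(counts),
                    base_mean_1 = m1, base_mean_2 = m2,
                    log2fc = log2fc, t_statistic = tstat,
                    p_value = p, padj = padj, de_flag = de_flag,
                    row.names = NULL)
  attr(res, "method") <- "threshold DE (stand-in)"
  res
}

#' Relative expression by the 2^-ddCt method
#'
#' `dCt = Ct_target - Ct_reference` per condition;
#' `ddCt = dCt_treated - dCt_control`; returns `2^-ddCt`.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   finite Ct values (vectorized).
#' @return relative expression (> 0).
#' @export
ddct <- function(ct_target_treated, ct_ref_treated,
                 ct_target_control, ct_ref_control) {
  all_ct <- c(ct_target_treated, ct_ref_treated, ct_target_control,
              ct_ref_control)
  abort_if(any(!is.finite(all_ct)), "Ct values must be finite")
  dct_t <- ct_target_treated - ct_ref_treated
  dct_c <- ct_target_control - ct_ref_control
  2^-(dct_t - dct_c)
}
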