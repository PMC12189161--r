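# mRNA decay kinetics: half-life estimation from actinomycin-D chase
# time courses by log-linear least squares.

#' Fit an exponential decay to one time course
#'
#' Ordinary least squares of `log(rel_abundance)` on time, with a free
#' intercept to absorb t = 0 normalization noise. `k = -slope`,
#' `half_life = ln(2) / k`. A non-negative slope is reported as status
#' `"no decay detected"` with infinite half-life.
#'
#' @param time time points (>= 3 distinct values).
#' @param abundance relative abundances (> 0).
#' @return list: `k`, `half_life`, `fit_r2`, `status`.
#' @export
fit_decay_one <- function(time, abundance) {
  abort_if(length(unique(time)) < 3L, "need >= 3 distinct time points")
  abort_if(any(abundance <= 0), "abundances must be > 0")
  fit <- stats::lm(log(abundance) ~ time)
  slope <- unname(stats::coef(fit)[2L])
  y <- log(abundance)
  ss_tot <- sum((y - mean(y))^2)
  # manual R^2: summary.lm warns on (near-)perfect noiseless fits
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else
    NA_real_
  if (slope >= 0) {
    return(list(k = -slope, half_life = Inf, fit_r2 = r2,
                status = "no decay detected"))
  }
  k <- -slope
  list(k = k, half_life = log(2) / k, fit_r2 = r2, status = "ok")
}

#' Fit decay kinetics per condition
#'
#' Each replicate's series is normalized to its own t = 0 value, then fitted
#' by [fit_decay_one()]. With `pooling = "per-replicate"` the per-replicate
#' estimates are averaged; `"pooled"` fits one regression to all normalized
#' points of the condition.
#'
#' @param decay decay table (see [read_decay_table()]): columns condition,
#'   replicate, time_min, rel_abundance.
#' @param pooling `"per-replicate"` or `"pooled"`.
#' @return data.frame per condition: n_reps, k, half_life_min, fit_r2,
#'   status; attribute `replicate_fits` keeps the per-replicate estimates.
#' @export
fit_decay <- function(decay, pooling = c("per-replicate", "pooled")) {
  pooling <- match.arg(pooling)
  decay <- data.table::as.data.table(decay)
  rep_rows <- list()
  out <- list()
  for (cond in unique(decay$condition)) {
    sub <- decay[decay$condition == cond, ]
    reps <- unique(sub$replicate)
    fits <- lapply(reps, function(r) {
      s <- sub[sub$replicate == r, ]
      a0 <- s$rel_abundance[s$time_min == 0][1L]
      fit_decay_one(s$time_min, s$rel_abundance / a0)
    })
    rep_rows[[cond]] <- data.frame(
      condition = cond, replicate = reps,
      k = vapply(fits, `[[`, numeric(1), "k"),
      half_life = vapply(fits, `[[`, numeric(1), "half_life"),
      fit_r2 = vapply(fits, `[[`, numeric(1), "fit_r2"),
      status = vapply(fits, `[[`, character(1), "status"))
    if (pooling == "pooled") {
      norm <- sub[, list(time_min,
                         rel = rel_abundance /
                           rel_abundance[time_min == 0][1L]),
                  by = "replicate"]
      f <- fit_decay_one(norm$time_min, norm$rel)
      out[[cond]] <- data.frame(condition = cond, n_reps = length(reps),
                                k = f$k, half_life_min = f$half_life,
                                fit_r2 = f$fit_r2, status = f$status)
    } else {
      ks <- rep_rows[[cond]]$k
      hl <- rep_rows[[cond]]$half_life
      status <- if (all(rep_rows[[cond]]$status == "ok")) "ok" else
        "no decay detected"
      out[[cond]] <- data.frame(
        condition = cond, n_reps = length(reps), k = mean(ks),
        half_life_min = if (status == "ok") mean(hl) else Inf,
        fit_r2 = mean(rep_rows[[cond]]$fit_r2), status = status)
    }
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  attr(res, "replicate_fits") <- do.call(rbind, c(rep_rows,
                                                  make.row.names = FALSE))
  res
}

#' Compare half-lives between two conditions
#'
#' Reports the two half-lives, their difference and ratio, and a bootstrap
#' percentile interval on the difference obtained by resampling replicates
#' with replacement.
#'
#' @param decay decay table containing both conditions.
#' @param cond_a,cond_b condition labels; the difference is `H_b - H_a`.
#' @param n_boot bootstrap draws.
#' @param conf interval coverage.
#' @param seed RNG seed for the bootstrap.
#' @return list: `half_life_a`, `half_life_b`, `delta` (b - a), `ratio`,
#'   `ci` (length-2), `status` (`"ok"` or `"indeterminate"`).
#' @export
compare_half_lives <- function(decay, cond_a, cond_b, n_boot = 1000L,
                               conf = 0.95, seed = 1L) {
  fits <- fit_decay(decay)
  reps <- attr(fits, "replicate_fits")
  ha <- fits$half_life_min[fits$condition == cond_a]
  hb <- fits$half_life_min[fits$condition == cond_b]
  abort_if(length(ha) != 1L || length(hb) != 1L, "condition not found")
  if (!is.finite(ha) || !is.finite(hb)) {
    return(list(half_life_a = ha, half_life_b = hb, delta = NA_real_,
                ratio = NA_real_, ci = c(NA_real_, NA_real_),
                status = "indeterminate"))
  }
  ra <- reps$half_life[reps$condition == cond_a]
  rb <- reps$half_life[reps$condition == cond_b]
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    mean(sample(rb, replace = TRUE)) - mean(sample(ra, replace = TRUE))
  }, numeric(1))
  alpha <- (1 - conf) / 2
  list(half_life_a = ha, half_life_b = hb, delta = hb - ha,
       ratio = hb / ha,
       ci = unname(stats::quantile(boots, c(alpha, 1 - alpha))),
       status = "ok")
}
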