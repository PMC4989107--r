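# Recombination-rate overlay: per-interval cM/Mb from a genetic map, the
# proportion of nonsynonymous SNPs called deleterious in each interval, and
# the interval-level Pearson correlation plus a SNP-level logistic
# regression quantifying the association.

#' Per-interval recombination rates from a genetic map
#'
#' Rate = delta cM / (delta bp / 1e6) between consecutive markers within a
#' chromosome. Intervals with negative rates or rates above `max_rate`
#' (default 20 cM/Mb) are excluded as likely marker-placement errors; the
#' exclusion ledger is returned so interval counts reconcile.
#'
#' @param map A `genetic_map` from [read_genetic_map()].
#' @param max_rate Upper bound on plausible cM/Mb (default 20).
#' @return List with `intervals` (data.frame chrom, start, end, cM_start,
#'   cM_end, rate) and `excluded` (same shape plus `reason`). Chromosomes
#'   with fewer than two markers are skipped with a warning.
#' @export
interval_rates <- function(map, max_rate = 20) {
  keep <- list(); drop <- list()
  for (ch in unique(map$chrom)) {
    d <- map[map$chrom == ch, , drop = FALSE]
    if (nrow(d) < 2L) {
      warning("interval_rates: chromosome ", ch, " has < 2 markers; skipped")
      next
    }
    n <- nrow(d)
    iv <- data.frame(chrom = ch, start = d$bp[-n], end = d$bp[-1],
                     cM_start = d$cM[-n], cM_end = d$cM[-1])
    iv$rate <- (iv$cM_end - iv$cM_start) / ((iv$end - iv$start) / 1e6)
    bad <- iv$rate < 0 | iv$rate > max_rate
    if (any(bad)) {
      ex <- iv[bad, , drop = FALSE]
      ex$reason <- ifelse(ex$rate < 0, "negative_rate", "rate_above_max")
      drop[[ch]] <- ex
      ds_log("interval_rates: %s: excluded %d interval(s)", ch, sum(bad))
    }
    keep[[ch]] <- iv[!bad, , drop = FALSE]
  }
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), cM_start = numeric(0),
                      cM_end = numeric(0), rate = numeric(0))
  list(intervals = if (length(keep)) do.call(rbind, c(keep, make.row.names = FALSE)) else empty,
       excluded = if (length(drop)) do.call(rbind, c(drop, make.row.names = FALSE)) else
         cbind(empty, reason = character(0)))
}

#' Overlay deleterious proportions onto map intervals
#'
#' Each nonsynonymous SNP is assigned to exactly one interval, half-open
#' [start, end) at bp resolution; SNPs before the first or after the last
#' marker of a chromosome are out-of-map and reported, never silently
#' dropped. Intervals without nonsynonymous SNPs carry an undefined
#' proportion (NA) and are excluded from the correlation.
#'
#' @param intervals data.frame from [interval_rates()]`$intervals`.
#' @param snps data.frame with `variant_id`, `chrom`, `pos`, and logical
#'   `deleterious` — one row per nonsynonymous SNP.
#' @return List with `intervals` (plus n_nonsyn, n_deleterious, proportion),
#'   `snp_interval` (per-SNP interval assignment with the interval rate, NA
#'   when out of map), and `n_out_of_map`.
#' @export
overlay_deleterious <- function(intervals, snps) {
  iv <- intervals
  iv$n_nonsyn <- 0L; iv$n_deleterious <- 0L
  assign_idx <- rep(NA_integer_, nrow(snps))
  for (k in seq_len(nrow(snps))) {
    hit <- which(iv$chrom == snps$chrom[k] & snps$pos[k] >= iv$start &
                   snps$pos[k] < iv$end)
    if (length(hit) == 0) next
    hit <- hit[1]
    assign_idx[k] <- hit
    iv$n_nonsyn[hit] <- iv$n_nonsyn[hit] + 1L
    iv$n_deleterious[hit] <- iv$n_deleterious[hit] + snps$deleterious[k]
  }
  iv$proportion <- ifelse(iv$n_nonsyn > 0, iv$n_deleterious / iv$n_nonsyn,
                          NA_real_)
  n_out <- sum(is.na(assign_idx))
  if (n_out > 0)
    ds_log("overlay_deleterious: %d SNP(s) outside map bounds", n_out)
  snp_interval <- data.frame(variant_id = snps$variant_id,
                             interval = assign_idx,
                             rate = iv$rate[assign_idx],
                             deleterious = snps$deleterious)
  list(intervals = iv, snp_interval = snp_interval, n_out_of_map = n_out)
}

#' Pearson correlation between recombination rate and deleterious proportion
#'
#' @param intervals data.frame from [overlay_deleterious()]`$intervals`.
#' @return List `r`, `r_squared`, `p` (two-sided, via the t transform) and
#'   `n` intervals used.
#' @export
correlate_rate_proportion <- function(intervals) {
  d <- intervals[!is.na(intervals$proportion), , drop = FALSE]
  if (nrow(d) < 3L) stop("correlate_rate_proportion: need >= 3 intervals")
  if (stats::sd(d$proportion) == 0 || stats::sd(d$rate) == 0)
    stop("correlate_rate_proportion: zero variance")
  ct <- stats::cor.test(d$rate, d$proportion, method = "pearson")
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p = ct$p.value, n = nrow(d))
}

#' Logistic regression of the per-SNP deleterious indicator on rate
#'
#' Maximum-likelihood logit fit (iteratively reweighted least squares via
#' `glm`), Wald p-value for the slope.
#'
#' @param snp_table data.frame with logical/0-1 `deleterious` and numeric
#'   `rate` (SNPs without an interval rate are dropped).
#' @return List `intercept`, `slope`, `slope_se`, `p`, `n`.
#' @export
logistic_fit <- function(snp_table) {
  d <- snp_table[!is.na(snp_table$rate), , drop = FALSE]
  y <- as.integer(d$deleterious)
  if (length(unique(y)) < 2L)
    stop("logistic_fit: both outcome classes must be present")
  fit <- stats::glm(y ~ rate, data = d, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) stop("logistic_fit: IRLS did not converge")
  co <- summary(fit)$coefficients
  if (any(abs(co[, "Estimate"]) > 20))
    stop("logistic_fit: complete or quasi-complete separation suspected")
  list(intercept = co[1, 1], slope = co[2, 1], slope_se = co[2, 2],
       p = co[2, 4], n = nrow(d))
}
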