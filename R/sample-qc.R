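# Per-sample quality control: summary statistics of the raw copy-number
# signal in control regions, the printed exclusion thresholds, and a
# reproducible surrogate for visual copy-number-PCA outlier screening.

#' Per-sample QC statistics
#'
#' Computes, for one sample: the standard deviation of raw copy number in
#' its diploid control windows; the one-sample Kolmogorov-Smirnov statistic
#' of the control raw CN against a Normal fitted to it (a normality score);
#' the Pearson correlation between neighboring windows (within chromosomes;
#' residual spatial autocorrelation signals artifacts); and the mean raw
#' depth of coverage.
#'
#' @param raw raw copy-number vector for the sample.
#' @param control integer indices of the sample's control windows (>= 2).
#' @param depth raw depth vector for the sample (same windows).
#' @param chrom chromosome of each window (neighbor pairs never straddle a
#'   chromosome boundary).
#' @return a one-row data frame: `sd_control`, `ks_stat`, `neighbor_corr`,
#'   `mean_raw_coverage`, `degenerate` (TRUE when the control signal is
#'   constant and sd/correlation are reported as 0).
#' @export
qc_stats <- function(raw, control, depth, chrom = rep("chr1", length(raw))) {
  if (length(control) < 2L) stop("need at least 2 control windows")
  x <- raw[control]
  degenerate <- sd(x) == 0
  sd_control <- sd(x)
  ks_stat <- if (degenerate) 0 else {
    unname(suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))$statistic)
  }
  same <- chrom[-length(chrom)] == chrom[-1L]
  a <- raw[-length(raw)][same]
  b <- raw[-1L][same]
  neighbor_corr <- if (degenerate || sd(a) == 0 || sd(b) == 0) 0 else cor(a, b)
  data.frame(sd_control = sd_control, ks_stat = ks_stat,
             neighbor_corr = neighbor_corr,
             mean_raw_coverage = mean(depth),
             degenerate = degenerate)
}

#' Apply sample-exclusion thresholds
#'
#' A sample fails when its control-region standard deviation exceeds
#' `sd_max`, its KS normality statistic is below `ks_min`, its
#' neighboring-window correlation exceeds `corr_max`, or its mean raw
#' coverage is below `cov_min`. The KS direction is implemented exactly as
#' published (exclude *low* statistics); set `ks_direction = "high"` to
#' invert it.
#'
#' @param report one-row data frame from [qc_stats()] (or several rows).
#' @param sd_max,ks_min,corr_max,cov_min thresholds (defaults 0.5, 0.03,
#'   0.15, 11.7).
#' @param ks_direction `"low"` (default; exclude ks < ks_min, as published)
#'   or `"high"` (exclude ks > ks_min).
#' @return the report with added `pass` (logical) and `reasons` (character;
#'   `""` when passing, otherwise comma-separated violated rules).
#' @export
apply_qc_thresholds <- function(report, sd_max = 0.5, ks_min = 0.03,
                                corr_max = 0.15, cov_min = 11.7,
                                ks_direction = c("low", "high")) {
  ks_direction <- match.arg(ks_direction)
  reasons <- character(nrow(report))
  for (i in seq_len(nrow(report))) {
    r <- character(0)
    if (report$sd_control[i] > sd_max)
      r <- c(r, sprintf("sd>%.3g", sd_max))
    ks_bad <- if (ks_direction == "low") report$ks_stat[i] < ks_min
              else report$ks_stat[i] > ks_min
    if (ks_bad)
      r <- c(r, sprintf("ks%s%.3g", if (ks_direction == "low") "<" else ">", ks_min))
    if (report$neighbor_corr[i] > corr_max)
      r <- c(r, sprintf("corr>%.3g", corr_max))
    if (report$mean_raw_coverage[i] < cov_min)
      r <- c(r, sprintf("coverage<%.3g", cov_min))
    reasons[i] <- paste(r, collapse = ",")
  }
  report$pass <- reasons == ""
  report$reasons <- reasons
  report
}

#' Copy-number PCA outlier flagging
#'
#' A deterministic surrogate for visual inspection of copy-number PCA:
#' in each of (at most) `n_rounds` rounds, samples are projected on the
#' first two principal components of the samples-by-windows copy-number
#' matrix, their distance from the component-wise median is computed, and
#' samples farther than `median + mad_factor * MAD` are flagged and removed
#' before the next round. Flags are returned; exclusion remains the user's
#' decision.
#'
#' @param cn samples-by-windows copy-number matrix (>= 3 samples).
#' @param n_rounds PCA rounds (default 2).
#' @param mad_factor robust distance cutoff in MADs (default 6).
#' @return list with `outlier` (named logical), `round` (0 = never flagged),
#'   and `scores` (per-round PC1/PC2 coordinates).
#' @export
cn_pca_outliers <- function(cn, n_rounds = 2L, mad_factor = 6) {
  stopifnot(nrow(cn) >= 3L)
  samples <- rownames(cn)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(cn)))
  outlier <- setNames(rep(FALSE, nrow(cn)), samples)
  round_flagged <- setNames(rep(0L, nrow(cn)), samples)
  keep <- seq_len(nrow(cn))
  scores <- vector("list", n_rounds)
  for (r in seq_len(n_rounds)) {
    if (length(keep) < 3L) break
    x <- cn[keep, , drop = FALSE]
    x <- x[, apply(x, 2L, sd) > 0, drop = FALSE]
    if (ncol(x) == 0L) break
    pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = 2L)
    sc <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
    ctr <- apply(sc, 2L, median)
    d <- sqrt(rowSums(sweep(sc, 2L, ctr)^2))
    cut <- median(d) + mad_factor * mad(d)
    flag <- d > cut & mad(d) > 0
    scores[[r]] <- data.frame(sample = samples[keep], round = r,
                              PC1 = sc[, 1L],
                              PC2 = if (ncol(sc) > 1L) sc[, 2L] else 0,
                              dist = d, stringsAsFactors = FALSE)
    if (!any(flag)) break
    outlier[keep[flag]] <- TRUE
    round_flagged[keep[flag]] <- r
    keep <- keep[!flag]
  }
  list(outlier = outlier, round = round_flagged,
       scores = do.call(rbind, scores))
}
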