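# Scaling window read depth to a continuous "raw" copy number: diploid
# control regions are found by iterative outlier trimming, GC bias is removed
# by binned median scaling, and depth is rescaled so that control regions
# average copy number 2. All of this is per sample: each sample is normalized
# against its own control set.

#' Select diploid control windows for one sample
#'
#' Iteratively removes windows with outlier depth (outside mean +/- `trim_sd`
#' standard deviations), recomputing the moments each round, until either no
#' window is removed or the index of dispersion (variance/mean) of the
#' retained depths stabilizes. The retained windows approximate the
#' Poisson-like depth distribution expected of diploid sequence and serve as
#' the copy-number-2 reference.
#'
#' @param depths numeric vector of window depths for one sample (>= 100
#'   windows).
#' @param trim_sd trimming threshold in standard deviations (default 3).
#' @param max_iter maximum trimming rounds (default 50).
#' @param tol stop when the index of dispersion changes by less than this
#'   (default 1e-3).
#' @param max_removed_frac abort if more than this fraction of windows is
#'   trimmed (default 0.9): such a sample is degenerate.
#' @return integer vector of retained window indices.
#' @export
select_control_regions <- function(depths, trim_sd = 3, max_iter = 50L,
                                   tol = 1e-3, max_removed_frac = 0.9) {
  n <- length(depths)
  if (n < 100L) stop("need at least 100 windows to select control regions")
  keep <- seq_len(n)
  disp_old <- Inf
  for (iter in seq_len(max_iter)) {
    x <- depths[keep]
    m <- mean(x)
    s <- sd(x)
    disp <- if (m > 0) var(x) / m else 0
    inlier <- abs(x - m) <= trim_sd * s
    if (!any(inlier)) break
    no_removal <- all(inlier)
    converged <- is.finite(disp_old) && abs(disp - disp_old) < tol
    if (no_removal || converged) break
    keep <- keep[inlier]
    disp_old <- disp
    if (length(keep) < (1 - max_removed_frac) * n) {
      stop("degenerate sample: more than ", round(100 * max_removed_frac),
           "% of windows trimmed during control-region selection")
    }
  }
  keep
}

gc_bin_of <- function(gc, bin_width) {
  nbins <- ceiling(1 / bin_width)
  pmin(floor(gc / bin_width), nbins - 1L) + 1L
}

#' Correct GC bias by binned median scaling
#'
#' Windows are binned by GC fraction (default 2% bins); within each bin the
#' median depth of the sample's control windows is compared to the global
#' control median and every window in the bin is scaled by the ratio. Bins
#' with fewer than `min_bin` control windows inherit the factor of the
#' nearest populated bin, so no window is left uncorrected.
#'
#' @param depths numeric vector of window depths for one sample.
#' @param gc_fraction per-window GC fraction (same length).
#' @param control integer indices of the sample's control windows.
#' @param bin_width GC bin width (default 0.02).
#' @param min_bin minimum control windows per bin (default 20).
#' @return corrected depth vector.
#' @export
gc_correct <- function(depths, gc_fraction, control, bin_width = 0.02,
                       min_bin = 20L) {
  stopifnot(length(depths) == length(gc_fraction))
  nbins <- ceiling(1 / bin_width)
  bin <- gc_bin_of(gc_fraction, bin_width)
  ctrl_bin <- bin[control]
  ctrl_depth <- depths[control]
  global_med <- median(ctrl_depth)
  bin_n <- tabulate(ctrl_bin, nbins)
  bin_med <- rep(NA_real_, nbins)
  for (b in which(bin_n >= min_bin)) {
    bin_med[b] <- median(ctrl_depth[ctrl_bin == b])
  }
  populated <- which(!is.na(bin_med) & bin_med > 0)
  if (length(populated) == 0L) return(depths)  # nothing to anchor on
  factor_of <- rep(NA_real_, nbins)
  factor_of[populated] <- global_med / bin_med[populated]
  for (b in seq_len(nbins)) {
    if (is.na(factor_of[b])) {
      nearest <- populated[which.min(abs(populated - b))]
      factor_of[b] <- factor_of[nearest]
    }
  }
  depths * factor_of[bin]
}

#' Scale depth to raw copy number
#'
#' The mean depth over a sample's diploid control windows is taken as the
#' depth of copy number 2, and every window's depth is rescaled accordingly:
#' `raw = 2 * depth / mean(control depth)`.
#'
#' @param depths (GC-corrected) window depths for one sample.
#' @param control integer indices of control windows.
#' @return numeric vector of continuous raw copy numbers.
#' @export
raw_copy_number <- function(depths, control) {
  if (length(control) == 0L) stop("empty control set")
  m <- mean(depths[control])
  if (!is.finite(m) || m <= 0) stop("control mean depth is zero")
  2 * depths / m
}

#' Standard deviation of raw copy number in control regions
#'
#' This is the noise scale (sigma_CR) that parameterizes the HMM emission
#' widths (sigma_N = sigma_CR * N / 2).
#'
#' @param raw raw copy-number vector for one sample.
#' @param control integer indices of control windows (>= 2).
#' @return numeric scalar.
#' @export
control_sigma <- function(raw, control) {
  if (length(control) < 2L) stop("need at least 2 control windows")
  sd(raw[control])
}

#' Depth matrix to raw copy-number matrix
#'
#' Per-sample convenience wrapper: selects control regions, applies GC
#' correction, rescales to raw copy number and measures sigma_CR.
#'
#' @param depth_matrix windows-by-samples depth matrix.
#' @param grid window grid (for `gc_fraction`).
#' @param gc_bin_width,min_bin,trim_sd,max_iter passed to the per-sample steps.
#' @return list with `raw` (windows-by-samples matrix), `control` (list of
#'   index vectors per sample), `sigma` (named numeric vector of sigma_CR).
#' @export
depth_to_raw_cn <- function(depth_matrix, grid, gc_bin_width = 0.02,
                            min_bin = 20L, trim_sd = 3, max_iter = 50L) {
  samples <- colnames(depth_matrix)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(depth_matrix)))
  raw <- matrix(NA_real_, nrow = nrow(depth_matrix), ncol = ncol(depth_matrix),
                dimnames = list(NULL, samples))
  control <- vector("list", length(samples))
  names(control) <- samples
  sigma <- setNames(numeric(length(samples)), samples)
  for (j in seq_along(samples)) {
    d <- depth_matrix[, j]
    ctrl <- select_control_regions(d, trim_sd = trim_sd, max_iter = max_iter)
    d_corr <- gc_correct(d, grid$gc_fraction, ctrl, bin_width = gc_bin_width,
                         min_bin = min_bin)
    r <- raw_copy_number(d_corr, ctrl)
    raw[, j] <- r
    control[[j]] <- ctrl
    sigma[j] <- control_sigma(r, ctrl)
  }
  list(raw = raw, control = control, sigma = sigma)
}
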