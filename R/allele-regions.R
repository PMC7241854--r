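# Window-level copy-number allele calling from per-sample 99% copy-number
# intervals, classification of windows into diploid / FD / CNV (gain, loss,
# gain-loss) / unclassified, and merging of consecutive same-category
# windows into regions.

#' Call copy-number alleles at one window
#'
#' Groups the per-sample integer copy-number intervals of one window into
#' alleles by the iterated majority procedure:
#' 1. among unassigned samples, find the most common integer copy number
#'    across their intervals (ties: the lowest integer);
#' 2. seed the allele with every unassigned sample whose interval contains
#'    that integer;
#' 3. assign the allele interval: all integers shared by at least
#'    `share_frac` (default 90%) of the seeded samples (kept contiguous
#'    around the seeding integer);
#' 4. absorb any remaining unassigned sample whose interval overlaps the
#'    allele interval;
#' 5. repeat with the remaining samples until all are assigned.
#'
#' @param intervals data frame with columns `sample`, `lo`, `hi` (integer
#'   copy-number interval per sample, inclusive).
#' @param share_frac sharing fraction for the allele interval (default 0.9;
#'   the comparison is `count >= share_frac * n_seeded`, so 18/20 qualifies).
#' @return an object of class `window_alleles`: list with `alleles` (each a
#'   list with `members`, `interval`, `seed_cn`, `step1_count`, `seeded`,
#'   `absorbed`), `intervals` (the input), `n_samples`.
#' @export
call_alleles <- function(intervals, share_frac = 0.9) {
  stopifnot(is.data.frame(intervals), nrow(intervals) >= 1L,
            all(c("sample", "lo", "hi") %in% names(intervals)),
            all(intervals$lo <= intervals$hi))
  lo <- as.integer(intervals$lo)
  hi <- as.integer(intervals$hi)
  n <- nrow(intervals)
  unassigned <- seq_len(n)
  alleles <- list()
  while (length(unassigned) > 0L) {
    cand <- min(lo[unassigned]):max(hi[unassigned])
    counts <- vapply(cand, function(x) {
      sum(lo[unassigned] <= x & hi[unassigned] >= x)
    }, integer(1L))
    seed_cn <- cand[which.max(counts)]          # first max = lowest integer
    step1_count <- max(counts)
    seeded <- unassigned[lo[unassigned] <= seed_cn & hi[unassigned] >= seed_cn]
    ns <- length(seeded)
    shared <- vapply(cand, function(x) {
      sum(lo[seeded] <= x & hi[seeded] >= x)
    }, integer(1L))
    ok <- shared >= share_frac * ns - 1e-9
    # contiguous run of qualifying integers containing the seed
    i <- match(seed_cn, cand)
    a <- i
    while (a > 1L && ok[a - 1L]) a <- a - 1L
    b <- i
    while (b < length(cand) && ok[b + 1L]) b <- b + 1L
    allele_int <- c(cand[a], cand[b])
    rest <- setdiff(unassigned, seeded)
    absorbed <- rest[lo[rest] <= allele_int[2L] & hi[rest] >= allele_int[1L]]
    members <- c(seeded, absorbed)
    alleles[[length(alleles) + 1L]] <- list(
      members = members, interval = allele_int, seed_cn = seed_cn,
      step1_count = step1_count, seeded = seeded, absorbed = absorbed)
    unassigned <- setdiff(unassigned, members)
  }
  structure(list(alleles = alleles, intervals = intervals, n_samples = n),
            class = "window_alleles")
}

#' @export
print.window_alleles <- function(x, ...) {
  cat(length(x$alleles), "allele(s) over", x$n_samples, "samples\n")
  for (i in seq_along(x$alleles)) {
    al <- x$alleles[[i]]
    cat(sprintf("  Allele %d: interval [%d,%d], %d member(s) (seed CN %d)\n",
                i, al$interval[1L], al$interval[2L], length(al$members),
                al$seed_cn))
  }
  invisible(x)
}

interval_width <- function(lo, hi, rule = c("n_integers", "range")) {
  rule <- match.arg(rule)
  if (rule == "n_integers") hi - lo + 1L else hi - lo
}

#' Classify a window from its allele call
#'
#' Windows with more than one allele are CNV; the subtype compares each
#' allele interval to the diploid copy number 2 as a whole: gain if some
#' allele lies entirely above 2, loss if entirely below, gain-loss if both
#' (alleles whose interval contains 2 count as reference-like).
#' Single-allele windows are diploid when the allele interval contains 2;
#' otherwise FD (fixed duplication, or fixed loss - see attribute
#' `fd_subtype`) when no individual interval spans more than `max_span`
#' copy numbers, and unclassified when intervals are too wide to trust.
#'
#' @param wa a `window_alleles` object.
#' @param max_span widest individual interval compatible with an FD call
#'   (default 3; with `span_rule = "n_integers"` an interval `[3,5]`
#'   containing 3 integers is allowed, `[3,6]` is not).
#' @param span_rule how to measure interval span: number of integers
#'   contained (`"n_integers"`, default) or range difference (`"range"`).
#' @return one of `"diploid"`, `"FD"`, `"CNV_gain"`, `"CNV_loss"`,
#'   `"CNV_gain_loss"`, `"unclassified"`; FD calls carry an attribute
#'   `fd_subtype` (`"gain"` or `"loss"`).
#' @export
classify_window <- function(wa, max_span = 3L,
                            span_rule = c("n_integers", "range")) {
  stopifnot(inherits(wa, "window_alleles"))
  span_rule <- match.arg(span_rule)
  ints <- lapply(wa$alleles, `[[`, "interval")
  if (length(ints) > 1L) {
    above <- any(vapply(ints, function(x) x[1L] > 2L, logical(1L)))
    below <- any(vapply(ints, function(x) x[2L] < 2L, logical(1L)))
    if (above && below) return("CNV_gain_loss")
    if (above) return("CNV_gain")
    if (below) return("CNV_loss")
    # all alleles contain 2: unreachable under contiguous allele intervals,
    # kept as a defensive fallback
    return("unclassified")
  }
  al <- ints[[1L]]
  if (al[1L] <= 2L && al[2L] >= 2L) return("diploid")
  widths <- interval_width(wa$intervals$lo, wa$intervals$hi, span_rule)
  if (all(widths <= max_span)) {
    sub <- if (al[2L] < 2L) "loss" else "gain"
    return(structure("FD", fd_subtype = sub))
  }
  "unclassified"
}

#' Call and classify every window of a panel
#'
#' @param lo,hi windows-by-samples integer matrices of copy-number interval
#'   bounds (from [confidence_intervals()]).
#' @param share_frac,max_span,span_rule passed to [call_alleles()] /
#'   [classify_window()].
#' @return character vector of per-window categories.
#' @export
window_categories <- function(lo, hi, share_frac = 0.9, max_span = 3L,
                              span_rule = "n_integers") {
  samples <- colnames(lo)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(lo)))
  vapply(seq_len(nrow(lo)), function(w) {
    wa <- call_alleles(data.frame(sample = samples, lo = lo[w, ], hi = hi[w, ],
                                  stringsAsFactors = FALSE),
                       share_frac = share_frac)
    as.character(classify_window(wa, max_span = max_span, span_rule = span_rule))
  }, character(1L))
}

#' Merge consecutive same-category windows into regions
#'
#' Maximal runs of windows with equal category and consecutive indices
#' within one chromosome become a region spanning from the first window's
#' start to the last window's end. Diploid runs are dropped by default, so
#' the output is the map of non-diploid regions.
#'
#' @param categories per-window category vector (aligned with `grid`).
#' @param grid window grid.
#' @param drop_diploid drop regions of category `"diploid"` (default TRUE).
#' @return data frame `chrom`, `start`, `end`, `category`, `n_windows`.
#' @export
merge_regions <- function(categories, grid, drop_diploid = TRUE) {
  stopifnot(length(categories) == nrow(grid))
  out <- list()
  for (ch in unique(grid$chrom)) {
    rows <- which(grid$chrom == ch)
    r <- rle(categories[rows])
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1L
    for (k in seq_along(r$values)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        start = grid$start[rows[starts[k]]],
        end = grid$end[rows[stops[k]]],
        category = r$values[k],
        n_windows = r$lengths[k],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  if (drop_diploid) out <- out[out$category != "diploid", , drop = FALSE]
  rownames(out) <- NULL
  out
}
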