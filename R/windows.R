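# Coordinates are 0-based half-open (BED convention) throughout the package.

as_dna <- function(sequences) {
  if (is(sequences, "DNAStringSet")) return(sequences)
  if (is.character(sequences)) {
    if (is.null(names(sequences))) {
      names(sequences) <- paste0("chr", seq_along(sequences))
    }
    return(Biostrings::DNAStringSet(sequences))
  }
  stop("`sequences` must be a named character vector or a DNAStringSet")
}

empty_mask <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

#' Normalize a mask track
#'
#' Sorts intervals, merges overlapping/adjacent ones and drops empty ones.
#' Masks are BED-style data frames with columns `chrom`, `start`, `end`
#' (0-based half-open).
#'
#' @param mask a mask data frame.
#' @return a normalized mask data frame.
#' @export
normalize_mask <- function(mask) {
  stopifnot(all(c("chrom", "start", "end") %in% names(mask)))
  mask <- mask[mask$end > mask$start, , drop = FALSE]
  if (nrow(mask) == 0L) return(empty_mask())
  out <- lapply(split(mask, mask$chrom), function(m) {
    ir <- IRanges::reduce(IRanges::IRanges(start = m$start + 1L, end = m$end))
    data.frame(chrom = m$chrom[1L], start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Mask over-represented k-mers
#'
#' Slides a k-mer window over each chromosome, counts exact placements of
#' every k-mer on both strands across the whole sequence set, and masks each
#' position covered by a k-mer with more than `max_placements` placements.
#' This reproduces mappability masking by exact k-mer multiplicity: a k-mer
#' occurring 21 or more times (forward plus reverse-complement occurrences)
#' is masked, one occurring exactly 20 times is kept.
#'
#' @param sequences named character vector or `DNAStringSet`.
#' @param k k-mer length in bp (default 78).
#' @param max_placements placements allowed before masking (default 20;
#'   strictly-greater counts are masked).
#' @return a normalized mask data frame (`chrom`, `start`, `end`).
#' @export
mask_kmers <- function(sequences, k = 78L, max_placements = 20L) {
  sequences <- as_dna(sequences)
  if (length(sequences) == 0L) stop("empty sequence set")
  if (k > min(Biostrings::width(sequences)))
    stop("k exceeds the shortest chromosome")
  chroms <- names(sequences)
  fwd <- lapply(seq_along(sequences), function(i) {
    s <- as.character(sequences[[i]])
    n <- nchar(s) - k + 1L
    substring(s, seq_len(n), seq_len(n) + k - 1L)
  })
  tab <- table(unlist(fwd, use.names = FALSE))
  kmers <- names(tab)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  rc_counts <- as.integer(tab[rc])
  rc_counts[is.na(rc_counts)] <- 0L
  total <- as.integer(tab) + rc_counts
  names(total) <- kmers
  res <- lapply(seq_along(sequences), function(i) {
    bad <- which(total[fwd[[i]]] > max_placements)
    if (length(bad) == 0L) return(NULL)
    ir <- IRanges::reduce(IRanges::IRanges(start = bad, width = k))
    data.frame(chrom = chroms[i], start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) return(empty_mask())
  normalize_mask(res)
}

#' Extend masked intervals by a flank
#'
#' Each masked interval grows by `flank` bp on both sides (clipped at the
#' chromosome bounds) and the track is re-normalized. Mirrors the masking of
#' the bases flanking repeat-masked regions so that windows adjacent to
#' masked sequence do not underestimate copy number.
#'
#' @param mask a mask data frame.
#' @param flank flank size in bp (default 78).
#' @param seqlengths optional named vector of chromosome lengths used to clip
#'   the right ends.
#' @return a normalized mask data frame.
#' @export
flank_mask <- function(mask, flank = 78L, seqlengths = NULL) {
  mask <- normalize_mask(mask)
  if (nrow(mask) == 0L) return(mask)
  mask$start <- pmax(0L, mask$start - as.integer(flank))
  mask$end <- mask$end + as.integer(flank)
  if (!is.null(seqlengths)) {
    mask$end <- pmin(mask$end, as.integer(seqlengths[mask$chrom]))
  }
  normalize_mask(mask)
}

mask_logical <- function(mask, chrom, len) {
  m <- rep(FALSE, len)
  sel <- mask[mask$chrom == chrom, , drop = FALSE]
  if (nrow(sel)) {
    for (i in seq_len(nrow(sel))) {
      m[(sel$start[i] + 1L):min(sel$end[i], len)] <- TRUE
    }
  }
  m
}

#' Build fixed-unmasked-size windows
#'
#' Scans each chromosome left to right, accumulating unmasked bases; a window
#' closes once `window_unmasked` unmasked bases (default 1000) have been
#' collected, so a window may span masked stretches and be longer than its
#' unmasked content. A trailing remainder shorter than `window_unmasked`
#' unmasked bp emits no window. GC fraction is computed over the unmasked
#' bases of each window.
#'
#' @param sequences named character vector or `DNAStringSet`.
#' @param mask a mask data frame (may be empty).
#' @param window_unmasked unmasked bp per window (default 1000).
#' @return a window-grid data frame with columns `chrom`, `start`, `end`,
#'   `unmasked_bp`, `gc_fraction`, `index` (dense, 1-based per chromosome).
#' @export
build_windows <- function(sequences, mask = empty_mask(), window_unmasked = 1000L) {
  sequences <- as_dna(sequences)
  mask <- normalize_mask(mask)
  out <- lapply(seq_along(sequences), function(i) {
    chrom <- names(sequences)[i]
    len <- Biostrings::width(sequences)[i]
    masked <- mask_logical(mask, chrom, len)
    pos <- which(!masked)
    nwin <- length(pos) %/% window_unmasked
    if (nwin == 0L) return(NULL)
    base <- strsplit(as.character(sequences[[i]]), "", fixed = TRUE)[[1L]]
    is_gc <- base %in% c("G", "C", "g", "c")
    idx <- matrix(pos[seq_len(nwin * window_unmasked)], nrow = window_unmasked)
    data.frame(
      chrom = chrom,
      start = idx[1L, ] - 1L,
      end = idx[window_unmasked, ],
      unmasked_bp = window_unmasked,
      gc_fraction = colMeans(matrix(is_gc[idx], nrow = window_unmasked)),
      index = seq_len(nwin),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      unmasked_bp = integer(), gc_fraction = numeric(),
                      index = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Aggregate per-base depth into window means
#'
#' Averages per-base read depth over the unmasked positions of each window;
#' masked positions inside a gap-spanning window are excluded from the mean.
#'
#' @param depth named list mapping chromosome to a per-base depth vector
#'   (positions 1..chrom length), or to a positions-by-samples matrix.
#' @param grid a window grid from [build_windows()].
#' @param mask the mask used to build the grid (default empty).
#' @return a windows-by-samples numeric matrix (one column for vector input).
#' @export
aggregate_depth <- function(depth, grid, mask = empty_mask()) {
  mask <- normalize_mask(mask)
  depth <- lapply(depth, function(d) if (is.matrix(d)) d else matrix(d, ncol = 1L))
  nsamp <- ncol(depth[[1L]])
  if (any(vapply(depth, function(d) anyNA(d), logical(1L))))
    stop("depth contains missing values")
  out <- matrix(NA_real_, nrow = nrow(grid), ncol = nsamp)
  colnames(out) <- colnames(depth[[1L]])
  for (chrom in unique(grid$chrom)) {
    d <- depth[[chrom]]
    if (is.null(d)) stop("no depth for chromosome ", chrom)
    masked <- mask_logical(mask, chrom, nrow(d))
    rows <- which(grid$chrom == chrom)
    for (r in rows) {
      p <- (grid$start[r] + 1L):grid$end[r]
      p <- p[!masked[p]]
      out[r, ] <- colMeans(d[p, , drop = FALSE])
    }
  }
  out
}
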