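# Gene copy-number profiling: overlap of protein-coding exons with FD / CNV
# / unclassified regions, the 90% "within" rule, the half-the-samples
# constant-pattern rule, gene-level allele calling, and the resulting
# category lattice diploid -> partial -> composite -> complete.

GENE_CATEGORIES <- c("diploid", "partial_FD", "partial_CNV", "composite_FD",
                     "composite_CNV", "complete_FD", "complete_CNV",
                     "nondiploid_unclassified")

region_class_of <- function(category) {
  ifelse(category == "FD", "FD",
         ifelse(category %in% c("CNV_gain", "CNV_loss", "CNV_gain_loss"),
                "CNV",
                ifelse(category == "unclassified", "unclassified", "diploid")))
}

overlap_bp <- function(exons, regions) {
  # exons, regions: data frames with chrom/start/end (0-based half-open)
  total <- 0L
  for (ch in unique(exons$chrom)) {
    e <- exons[exons$chrom == ch, , drop = FALSE]
    r <- regions[regions$chrom == ch, , drop = FALSE]
    if (nrow(r) == 0L) next
    ei <- IRanges::IRanges(start = e$start + 1L, end = e$end)
    ri <- IRanges::reduce(IRanges::IRanges(start = r$start + 1L, end = r$end))
    total <- total + sum(IRanges::width(IRanges::intersect(ei, ri)))
  }
  total
}

#' Coding overlap fractions with region types
#'
#' Fraction of a gene's protein-coding bases overlapping FD, CNV and
#' unclassified regions (CNV subtypes are pooled).
#'
#' @param exons exon table of one gene: `chrom`, `start`, `end` (0-based
#'   half-open, non-overlapping).
#' @param regions region table from [merge_regions()].
#' @return named numeric vector `c(FD=, CNV=, unclassified=)`.
#' @export
coding_overlap <- function(exons, regions) {
  coding_bp <- sum(exons$end - exons$start)
  stopifnot(coding_bp > 0)
  cls <- region_class_of(regions$category)
  vapply(c(FD = "FD", CNV = "CNV", unclassified = "unclassified"),
         function(k) {
           overlap_bp(exons, regions[cls == k, , drop = FALSE]) / coding_bp
         }, numeric(1L))
}

gene_windows <- function(exons, grid) {
  # windows overlapping >= 1 exonic bp (window span, which may include
  # masked gap bases, judged against exon intervals)
  hit <- logical(nrow(grid))
  for (ch in unique(exons$chrom)) {
    e <- exons[exons$chrom == ch, , drop = FALSE]
    rows <- which(grid$chrom == ch)
    if (length(rows) == 0L) next
    wi <- IRanges::IRanges(start = grid$start[rows] + 1L, end = grid$end[rows])
    ei <- IRanges::IRanges(start = e$start + 1L, end = e$end)
    hit[rows] <- IRanges::overlapsAny(wi, ei)
  }
  which(hit)
}

#' Gene-level allele calling
#'
#' Runs the window allele-calling algorithm ([call_alleles()]) on per-sample
#' gene-level copy-number intervals (the intersection of each constant
#' sample's window intervals across the gene).
#'
#' @param intervals data frame `sample`, `lo`, `hi` of gene-level intervals.
#' @param share_frac sharing fraction (default 0.9).
#' @return a `window_alleles` object.
#' @export
gene_allele_call <- function(intervals, share_frac = 0.9) {
  if (nrow(intervals) == 0L) stop("no constant samples to call gene alleles on")
  call_alleles(intervals, share_frac = share_frac)
}

#' Classify one gene's copy-number profile
#'
#' Applies the gene taxonomy: genes without any coding-bp overlap with
#' non-diploid regions are diploid; genes overlapping FD or CNV regions by
#' less than `within_frac` of their coding length are partial; genes with at
#' least `within_frac` (default 90%) of their coding length within FD/CNV
#' regions are candidates for completeness: when at least `constancy_frac`
#' (default half) of the samples have a constant copy-number pattern along
#' the gene (a non-empty intersection of their window intervals), the gene
#' allele call on those intersections decides - one gene allele is a
#' complete FD gene, more than one a complete CNV gene; otherwise the gene
#' is composite. Genes whose only non-diploid overlap is with unclassified
#' regions are non-diploid unclassified.
#'
#' @param exons exon table of the gene (`chrom`, `start`, `end`).
#' @param regions region table from [merge_regions()].
#' @param lo,hi windows-by-samples interval-bound matrices aligned with
#'   `grid`.
#' @param grid window grid.
#' @param within_frac coding fraction for "within" (default 0.9).
#' @param constancy_frac fraction of samples that must be constant (default
#'   0.5).
#' @param share_frac sharing fraction for gene allele calling (default 0.9).
#' @return list: `category`, `fractions`, `n_gene_alleles` (NA unless
#'   complete), `n_constant`, `n_windows`.
#' @export
classify_gene <- function(exons, regions, lo, hi, grid, within_frac = 0.9,
                          constancy_frac = 0.5, share_frac = 0.9) {
  fr <- coding_overlap(exons, regions)
  res <- list(fractions = fr, n_gene_alleles = NA_integer_,
              n_constant = NA_integer_, n_windows = NA_integer_)
  if (all(fr == 0)) {
    res$category <- "diploid"
    return(res)
  }
  within_fd <- fr[["FD"]] >= within_frac
  within_cnv <- fr[["CNV"]] >= within_frac
  if (within_fd || within_cnv) {
    # pick the dominating type; ties favor CNV (conservative for fixation)
    type <- if (within_fd && within_cnv) {
      if (fr[["FD"]] > fr[["CNV"]]) "FD" else "CNV"
    } else if (within_fd) "FD" else "CNV"
    gw <- gene_windows(exons, grid)
    res$n_windows <- length(gw)
    glo <- apply(lo[gw, , drop = FALSE], 2L, max)
    ghi <- apply(hi[gw, , drop = FALSE], 2L, min)
    constant <- glo <= ghi
    res$n_constant <- sum(constant)
    if (sum(constant) >= constancy_frac * ncol(lo)) {
      ga <- gene_allele_call(
        data.frame(sample = colnames(lo)[constant], lo = glo[constant],
                   hi = ghi[constant], stringsAsFactors = FALSE),
        share_frac = share_frac)
      res$n_gene_alleles <- length(ga$alleles)
      res$category <- if (length(ga$alleles) > 1L) "complete_CNV" else "complete_FD"
    } else {
      res$category <- paste0("composite_", type)
    }
    return(res)
  }
  if (fr[["FD"]] > 0 || fr[["CNV"]] > 0) {
    type <- if (fr[["FD"]] > fr[["CNV"]]) "FD"
            else if (fr[["CNV"]] > fr[["FD"]]) "CNV"
            else "CNV"
    res$category <- paste0("partial_", type)
    return(res)
  }
  res$category <- "nondiploid_unclassified"
  res
}

#' Profile every gene of an annotation
#'
#' @param exon_table exon table for all genes: `gene`, `chrom`, `strand`,
#'   `start`, `end` (GFF-like TSV layout; exon order irrelevant).
#' @param regions region table from [merge_regions()].
#' @param lo,hi windows-by-samples interval matrices.
#' @param grid window grid.
#' @param ... passed to [classify_gene()].
#' @return data frame: `gene`, `category`, `f_FD`, `f_CNV`,
#'   `f_unclassified`, `n_gene_alleles`, `n_constant`.
#' @export
gene_profiles <- function(exon_table, regions, lo, hi, grid, ...) {
  genes <- unique(exon_table$gene)
  rows <- lapply(genes, function(g) {
    ex <- exon_table[exon_table$gene == g, , drop = FALSE]
    cl <- classify_gene(ex, regions, lo, hi, grid, ...)
    data.frame(gene = g, category = cl$category,
               f_FD = unname(cl$fractions[["FD"]]),
               f_CNV = unname(cl$fractions[["CNV"]]),
               f_unclassified = unname(cl$fractions[["unclassified"]]),
               n_gene_alleles = cl$n_gene_alleles,
               n_constant = cl$n_constant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
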