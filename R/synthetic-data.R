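# Seeded synthetic-data generator: toy reference sequences with planted
# repeats, population copy-number truth with 1-3 copy-number alleles per
# locus, noisy depth matrices matching the Normal-emission regime of the
# HMM, annotation fixtures (genes, orthologs, disease table), and the
# 30-sample worked example of the allele-calling procedure.

#' Simulation specification
#'
#' Bundles and validates the parameters of a synthetic panel. Defaults
#' emulate a high-coverage short-read panel: ~30x mean coverage and a raw
#' copy-number noise of sigma_CR = 0.3 in diploid regions.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param repeat_insertions list of `c(motif_length, copies)` pairs; each
#'   motif is planted `copies` times to exercise k-mer masking.
#' @param loci list of loci, each a list with `chrom`, `start`, `end` (bp,
#'   0-based half-open), `cn` (integer allele copy numbers) and `freq`
#'   (allele frequencies summing to 1). Loci must not overlap within a
#'   chromosome.
#' @param n_samples number of samples.
#' @param mean_coverage mean depth of coverage (reads per base equivalent).
#' @param sigma_cr target standard deviation of raw copy number in diploid
#'   windows.
#' @param gc_bias_amplitude amplitude of the multiplicative quadratic GC
#'   bias (0 = none).
#' @param batch_offsets per-sample coverage multipliers (default all 1).
#' @param seed integer RNG seed.
#' @return an object of class `sim_spec`.
#' @export
sim_spec <- function(n_chromosomes = 2L, chrom_length = 60000L,
                     repeat_insertions = list(), loci = list(),
                     n_samples = 100L, mean_coverage = 30,
                     sigma_cr = 0.3, gc_bias_amplitude = 0,
                     batch_offsets = NULL, seed = 1L) {
  stopifnot(n_chromosomes >= 1L, chrom_length >= 1L, n_samples >= 1L,
            mean_coverage > 0, sigma_cr > 0, gc_bias_amplitude >= 0)
  if (is.null(batch_offsets)) batch_offsets <- rep(1, n_samples)
  stopifnot(length(batch_offsets) == n_samples, all(batch_offsets > 0))
  for (loc in loci) {
    stopifnot(all(c("chrom", "start", "end", "cn", "freq") %in% names(loc)),
              loc$start < loc$end,
              length(loc$cn) == length(loc$freq),
              all(loc$cn >= 0),
              abs(sum(loc$freq) - 1) < 1e-8)
  }
  # non-overlap within chromosomes
  if (length(loci) > 1L) {
    df <- data.frame(chrom = vapply(loci, `[[`, character(1L), "chrom"),
                     start = vapply(loci, function(l) as.numeric(l$start), numeric(1L)),
                     end = vapply(loci, function(l) as.numeric(l$end), numeric(1L)))
    for (ch in unique(df$chrom)) {
      d <- df[df$chrom == ch, , drop = FALSE]
      d <- d[order(d$start), , drop = FALSE]
      if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)]))
        stop("overlapping loci on ", ch)
    }
  }
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = as.integer(chrom_length),
                 repeat_insertions = repeat_insertions, loci = loci,
                 n_samples = as.integer(n_samples),
                 mean_coverage = mean_coverage, sigma_cr = sigma_cr,
                 gc_bias_amplitude = gc_bias_amplitude,
                 batch_offsets = batch_offsets, seed = as.integer(seed)),
            class = "sim_spec")
}

#' Generate reference sequences with planted repeats
#'
#' Draws uniform random A/C/G/T chromosomes, then overwrites each repeat
#' motif at randomly chosen non-overlapping placements across the genome.
#' Placements are recorded as the truth repeat mask.
#'
#' @param spec a `sim_spec`.
#' @return list: `sequences` (`DNAStringSet`), `repeat_mask` (BED-style
#'   data frame of planted placements).
#' @export
generate_reference <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  chroms <- paste0("chr", seq_len(spec$n_chromosomes))
  seqs <- lapply(chroms, function(ch) {
    sample(c("A", "C", "G", "T"), spec$chrom_length, replace = TRUE)
  })
  names(seqs) <- chroms
  mask <- empty_mask()
  for (rep_spec in spec$repeat_insertions) {
    len <- as.integer(rep_spec[1L])
    copies <- as.integer(rep_spec[2L])
    if (len > spec$chrom_length) stop("repeat motif longer than chromosome")
    motif <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    placed <- 0L
    guard <- 0L
    while (placed < copies) {
      guard <- guard + 1L
      if (guard > 100L * copies) stop("cannot place repeat copies without overlap")
      ch <- sample(chroms, 1L)
      start <- sample.int(spec$chrom_length - len + 1L, 1L) - 1L  # 0-based
      sel <- mask[mask$chrom == ch, , drop = FALSE]
      if (nrow(sel) && any(start < sel$end & start + len > sel$start)) next
      seqs[[ch]][(start + 1L):(start + len)] <- motif
      mask <- rbind(mask, data.frame(chrom = ch, start = start,
                                     end = start + len,
                                     stringsAsFactors = FALSE))
      placed <- placed + 1L
    }
  }
  sequences <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1L),
                                               collapse = ""))
  list(sequences = sequences,
       repeat_mask = if (nrow(mask)) mask[order(mask$chrom, mask$start), ,
                                          drop = FALSE] else mask)
}

locus_windows <- function(grid, loc) {
  which(grid$chrom == loc$chrom & grid$start < loc$end & grid$end > loc$start)
}

truth_category_of <- function(cn, freq) {
  if (length(cn) == 1L) {
    if (cn == 2L) "diploid" else "FD"
  } else {
    above <- any(cn > 2L)
    below <- any(cn < 2L)
    if (above && below) "CNV_gain_loss" else if (above) "CNV_gain" else "CNV_loss"
  }
}

#' Draw population copy-number truth
#'
#' Each sample's copy number at each locus is drawn from the locus's allele
#' distribution (alleles are total window copy-number states); windows
#' outside loci are copy number 2 for every sample. Per-window truth
#' categories follow from the allele structure: a single allele different
#' from 2 is FD, multiple alleles are CNV (gain / loss / gain-loss vs 2),
#' a single allele equal to 2 is diploid.
#'
#' @param grid window grid.
#' @param spec a `sim_spec` (loci must fall inside the grid span).
#' @return list (`truth_set`): `truth_cn` (windows-by-samples integer
#'   matrix), `truth_category` (per-window), `loci` (the spec's loci).
#' @export
generate_population_truth <- function(grid, spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed + 1L)
  samples <- paste0("S", seq_len(spec$n_samples))
  truth_cn <- matrix(2L, nrow = nrow(grid), ncol = spec$n_samples,
                     dimnames = list(NULL, samples))
  truth_category <- rep("diploid", nrow(grid))
  for (loc in spec$loci) {
    rows <- locus_windows(grid, loc)
    if (length(rows) == 0L) next
    cn_alleles <- as.integer(loc$cn)
    draws <- cn_alleles[sample.int(length(cn_alleles), spec$n_samples,
                                   replace = TRUE, prob = loc$freq)]
    truth_cn[rows, ] <- matrix(rep(draws, each = length(rows)),
                               nrow = length(rows))
    truth_category[rows] <- truth_category_of(as.integer(loc$cn), loc$freq)
  }
  list(truth_cn = truth_cn, truth_category = truth_category,
       loci = spec$loci)
}

#' Quadratic GC bias factor
#'
#' Smooth multiplicative coverage bias peaking at mid GC: `1 + amplitude *
#' (1 - ((gc - 0.5) / 0.5)^2)`, i.e. 1 at the GC extremes and
#' `1 + amplitude` at GC 0.5.
#'
#' @param gc_fraction GC fraction in `[0, 1]`.
#' @param amplitude bias amplitude.
#' @return multiplicative factor.
#' @export
gc_bias_factor <- function(gc_fraction, amplitude) {
  1 + amplitude * (1 - ((gc_fraction - 0.5) / 0.5)^2)
}

#' Simulate a window depth matrix from copy-number truth
#'
#' `depth(s, w) = offset_s * coverage * (cn / 2) * gc_factor(w) + noise`,
#' with Gaussian noise whose standard deviation is chosen so that the raw
#' copy number recovered in diploid windows has standard deviation
#' `sigma_cr` (i.e. `sd = sigma_cr * offset_s * coverage * gc_factor(w) /
#' 2`). Depths are floored at 0.
#'
#' @param truth truth set from [generate_population_truth()].
#' @param grid window grid.
#' @param spec a `sim_spec`.
#' @return windows-by-samples depth matrix.
#' @export
simulate_depth_matrix <- function(truth, grid, spec) {
  stopifnot(inherits(spec, "sim_spec"),
            nrow(truth$truth_cn) == nrow(grid))
  set.seed(spec$seed + 2L)
  gcf <- gc_bias_factor(grid$gc_fraction, spec$gc_bias_amplitude)
  nw <- nrow(grid)
  ns <- spec$n_samples
  mu <- truth$truth_cn / 2 * spec$mean_coverage
  mu <- sweep(mu, 1L, gcf, `*`)
  mu <- sweep(mu, 2L, spec$batch_offsets, `*`)
  sd_mat <- outer(gcf, spec$batch_offsets) * spec$mean_coverage * spec$sigma_cr / 2
  depth <- mu + rnorm(nw * ns, sd = sd_mat)
  depth <- pmax(depth, 0)
  dimnames(depth) <- dimnames(truth$truth_cn)
  depth
}

#' Generate annotation fixtures with known expected gene profiles
#'
#' Places multi-exon gene models relative to the truth loci so each gene has
#' a construction-expected profile: one gene spanning a locus interior
#' (expected complete FD / complete CNV by locus type), one gene straddling
#' a locus edge (expected partial), and diploid genes in between. Also
#' returns an ortholog table pairing each gene with a mirrored gene id of a
#' second species and a disease table in which disease status is enriched
#' among expected-non-diploid genes by `disease_enrichment` (1 = null).
#'
#' @param grid window grid.
#' @param truth truth set from [generate_population_truth()].
#' @param seed RNG seed.
#' @param disease_enrichment enrichment factor for disease status among
#'   expected non-diploid genes (default 1: independent).
#' @param disease_rate baseline disease-annotation probability (default
#'   0.1).
#' @return list: `exons` (gene exon table), `expected` (gene,
#'   expected_category), `orthologs`, `disease` (gene, source, score).
#' @export
generate_annotation_fixtures <- function(grid, truth, seed = 1L,
                                         disease_enrichment = 1,
                                         disease_rate = 0.1) {
  stopifnot(nrow(grid) >= 1L)
  set.seed(seed)
  exons <- list()
  expected <- list()
  add_gene <- function(id, chrom, start, end, expect, n_exons = 3L) {
    # exons tile [start, end) with small introns
    len <- end - start
    cuts <- round(seq(start, end, length.out = 2L * n_exons))
    ex <- data.frame(gene = id, chrom = chrom, strand = "+",
                     start = cuts[seq(1L, 2L * n_exons - 1L, by = 2L)],
                     end = cuts[seq(2L, 2L * n_exons, by = 2L)],
                     stringsAsFactors = FALSE)
    ex <- ex[ex$end > ex$start, , drop = FALSE]
    exons[[length(exons) + 1L]] <<- ex
    expected[[length(expected) + 1L]] <<-
      data.frame(gene = id, expected_category = expect,
                 stringsAsFactors = FALSE)
  }
  gid <- 0L
  next_id <- function() {
    gid <<- gid + 1L
    sprintf("gene%03d", gid)
  }
  for (loc in truth$loci) {
    rows <- locus_windows(grid, loc)
    if (length(rows) < 3L) next
    cls <- region_class_of(truth$truth_category[rows[1L]])
    span_start <- grid$start[rows[1L]]
    span_end <- grid$end[rows[length(rows)]]
    # gene well inside the locus: expected complete
    pad <- max(1L, (span_end - span_start) %/% 20L)
    add_gene(next_id(), loc$chrom, span_start + pad, span_end - pad,
             paste0("complete_", cls))
    # gene straddling the left edge: roughly half inside, expected partial
    out_len <- span_end - span_start
    g_start <- max(0L, span_start - out_len %/% 2L)
    if (span_start - g_start > 0L) {
      add_gene(next_id(), loc$chrom, g_start,
               span_start + out_len %/% 2L, paste0("partial_", cls))
    }
  }
  # diploid genes: the first stretch of consecutive diploid windows per
  # chromosome
  nondip <- truth$truth_category != "diploid"
  for (ch in unique(grid$chrom)) {
    ok <- which(grid$chrom == ch & !nondip)
    if (length(ok) >= 4L) {
      # find 3 consecutive diploid windows
      d <- which(diff(ok) == 1L)
      if (length(d) >= 3L) {
        w <- ok[d[1L]]
        add_gene(next_id(), ch, grid$start[w] + 100L,
                 grid$end[min(w + 2L, nrow(grid))] - 100L, "diploid")
      }
    }
  }
  exons <- do.call(rbind, exons)
  expected <- do.call(rbind, expected)
  orthologs <- data.frame(gene_a = expected$gene,
                          gene_b = paste0(expected$gene, "_spB"),
                          one_to_one = TRUE, stringsAsFactors = FALSE)
  p <- ifelse(expected$expected_category == "diploid", disease_rate,
              pmin(1, disease_rate * disease_enrichment))
  is_disease <- runif(nrow(expected)) < p
  disease <- data.frame(gene = expected$gene[is_disease],
                        source = rep("DisGeNET", sum(is_disease)),
                        score = round(runif(sum(is_disease), 0.06, 0.8), 3),
                        stringsAsFactors = FALSE)
  list(exons = exons, expected = expected, orthologs = orthologs,
       disease = disease)
}

#' Worked-example fixture: 30 copy-number intervals for one window
#'
#' The canonical 30-sample toy input of the allele-calling procedure:
#' samples 1-17 have interval `[3,4]`, sample 18 `[2,4]`, sample 19 `[4,4]`,
#' sample 20 `[4,5]`, sample 21 `[2,3]`, samples 22-26 `[2,2]`, sample 27
#' `[1,2]` and samples 28-30 `[5,6]`. Running [call_alleles()] on it yields
#' three alleles: samples 1-21 with allele interval `[3,4]`, samples 22-27
#' with allele interval `[2,2]`, and samples 28-30 with allele interval
#' `[5,6]`.
#'
#' @return data frame `sample`, `lo`, `hi` (30 rows).
#' @export
fixture_s28 <- function() {
  data.frame(
    sample = 1:30,
    lo = c(rep(3L, 17), 2L, 4L, 4L, 2L, rep(2L, 5), 1L, rep(5L, 3)),
    hi = c(rep(4L, 17), 4L, 4L, 5L, 3L, rep(2L, 5), 2L, rep(6L, 3))
  )
}
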