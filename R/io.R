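# Plain-text serialization: BED (0-based half-open) for masks, window grids
# and region maps; TSV for depth/CN matrices (windows as rows, sample-ID
# header), interval tables, gene exon tables and ortholog/disease tables;
# YAML-style key-value files for simulation parameters.

#' Write a mask or region track as BED
#'
#' Columns beyond `chrom`, `start`, `end` (e.g. `category`) are written in
#' the BED name field.
#'
#' @param track data frame with `chrom`, `start`, `end` and optionally a
#'   name-like column.
#' @param path output path.
#' @param name_col optional column written as the BED name field.
#' @export
write_bed <- function(track, path, name_col = NULL) {
  out <- track[, c("chrom", "start", "end")]
  if (!is.null(name_col)) out$name <- track[[name_col]]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED3/BED4 file
#'
#' @param path input path.
#' @return data frame `chrom`, `start`, `end` (+ `name` when present).
#' @export
read_bed <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(tab)[1:3] <- c("chrom", "start", "end")
  if (ncol(tab) >= 4L) names(tab)[4L] <- "name"
  tab
}

#' Write a window grid as BED-style TSV
#'
#' @param grid window grid.
#' @param path output path.
#' @export
write_window_grid <- function(grid, path) {
  write.table(grid, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_window_grid
#' @export
read_window_grid <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write a windows-by-samples matrix as TSV
#'
#' Windows are rows, prefixed by the grid's `chrom`, `start`, `end`; the
#' header row carries the sample IDs.
#'
#' @param m windows-by-samples numeric matrix.
#' @param grid window grid aligned with the rows.
#' @param path output path.
#' @export
write_matrix_tsv <- function(m, grid, path) {
  out <- cbind(grid[, c("chrom", "start", "end")], as.data.frame(m))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @return for the reader: list with `grid` (chrom/start/end) and `matrix`.
#' @export
read_matrix_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -(1:3), drop = FALSE])
  list(grid = tab[, 1:3], matrix = m)
}

#' Write per-sample copy-number intervals as TSV
#'
#' Long format: `chrom`, `start`, `end`, `sample`, `lo`, `hi`.
#'
#' @param lo,hi windows-by-samples interval matrices.
#' @param grid window grid.
#' @param path output path.
#' @export
write_intervals_tsv <- function(lo, hi, grid, path) {
  samples <- colnames(lo)
  out <- data.frame(
    chrom = rep(grid$chrom, times = ncol(lo)),
    start = rep(grid$start, times = ncol(lo)),
    end = rep(grid$end, times = ncol(lo)),
    sample = rep(samples, each = nrow(lo)),
    lo = as.vector(lo), hi = as.vector(hi), stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene exon table
#'
#' GFF-like TSV with columns `gene`, `chrom`, `strand`, `start`, `end`
#' (0-based half-open exon intervals of the main isoform).
#'
#' @param path input path.
#' @return exon data frame.
#' @export
read_gene_models <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(tab)))
  tab
}

#' Read an ortholog-pair table
#'
#' TSV with columns `gene_a`, `gene_b`, `one_to_one`.
#'
#' @param path input path.
#' @return data frame.
#' @export
read_ortholog_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_a", "gene_b") %in% names(tab)))
  tab
}

#' Read a simulation spec from a YAML-style config
#'
#' Key-value file with the fields of [sim_spec()]; `repeat_insertions` is a
#' list of `[motif_length, copies]` pairs and `loci` a list of mappings
#' with `chrom`, `start`, `end`, `cn`, `freq`.
#'
#' @param path config path.
#' @return a `sim_spec`.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  loci <- lapply(cfg$loci, function(l) {
    l$cn <- as.integer(unlist(l$cn))
    l$freq <- as.numeric(unlist(l$freq))
    l
  })
  reps <- lapply(cfg$repeat_insertions, function(r) as.integer(unlist(r)))
  sim_spec(
    n_chromosomes = cfg$n_chromosomes %||% 2L,
    chrom_length = cfg$chrom_length %||% 60000L,
    repeat_insertions = reps, loci = loci,
    n_samples = cfg$n_samples %||% 100L,
    mean_coverage = cfg$mean_coverage %||% 30,
    sigma_cr = cfg$sigma_cr %||% 0.3,
    gc_bias_amplitude = cfg$gc_bias_amplitude %||% 0,
    batch_offsets = cfg$batch_offsets,
    seed = cfg$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
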