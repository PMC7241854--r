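# End-to-end orchestration: depth matrix -> raw copy number -> trained HMM
# -> population-prior re-genotyping -> 99% copy-number intervals; and from
# intervals -> window categories -> region map.

#' Genotype a panel from a window depth matrix
#'
#' Runs the full per-sample copy-number inference: control-region selection,
#' GC correction and raw copy-number scaling; Baum-Welch training of the
#' transition matrix on `train_n` randomly drawn held-out samples (excluded
#' from downstream calls); forward-backward posterior decoding per
#' chromosome; local population-prior re-genotyping; and 99% copy-number
#' confidence intervals.
#'
#' @param depth_matrix windows-by-samples depth matrix.
#' @param grid window grid aligned with the matrix rows.
#' @param train_n held-out training samples (default 5).
#' @param seed seed for the training-sample draw.
#' @param level confidence level (default 0.99).
#' @param span population-prior window span (default 5).
#' @param regenotype apply the population-prior correction (default TRUE).
#' @param states state space (default [cn_states()]).
#' @param bw_max_iter,bw_tol Baum-Welch controls.
#' @return list: `grid`, `samples` (genotyped), `training_samples`, `raw`,
#'   `sigma`, `transitions`, `probs` (windows x states x samples array of
#'   final probabilities), `lo`, `hi`, `confidence` (windows-by-samples).
#' @export
genotype_panel <- function(depth_matrix, grid, train_n = 5L, seed = 1L,
                           level = 0.99, span = 5L, regenotype = TRUE,
                           states = cn_states(), bw_max_iter = 30L,
                           bw_tol = 1e-3) {
  stopifnot(nrow(depth_matrix) == nrow(grid))
  rawres <- depth_to_raw_cn(depth_matrix, grid)
  samples <- colnames(rawres$raw)
  set.seed(seed)
  train_n <- min(train_n, length(samples) - 1L)
  training <- if (train_n > 0L) sample(samples, train_n) else character(0)
  keep <- setdiff(samples, training)
  chroms <- unique(grid$chrom)
  track_rows <- lapply(chroms, function(ch) which(grid$chrom == ch))
  transitions <- NULL
  if (length(training) > 0L) {
    tracks <- list()
    models <- list()
    for (s in training) {
      for (rows in track_rows) {
        tracks[[length(tracks) + 1L]] <- rawres$raw[rows, s]
        models[[length(models) + 1L]] <-
          emission_model(rawres$sigma[s], states)
      }
    }
    transitions <- train_transitions(tracks, models = models,
                                     max_iter = bw_max_iter, tol = bw_tol)
  } else {
    S <- nrow(states)
    transitions <- matrix(0.1 / (S - 1L), S, S)
    diag(transitions) <- 0.9
  }
  S <- nrow(states)
  probs <- array(NA_real_, dim = c(nrow(grid), S, length(keep)),
                 dimnames = list(NULL, states$label, keep))
  for (s in keep) {
    m <- emission_model(rawres$sigma[s], states)
    for (rows in track_rows) {
      probs[rows, , s] <- posterior_decode(rawres$raw[rows, s], transitions, m)
    }
  }
  if (regenotype && length(keep) > 0L) {
    prior <- population_prior(probs, grid$chrom, span = span)
    for (s in keep) {
      probs[, , s] <- bayes_regenotype(probs[, , s], prior)
    }
  }
  ci <- confidence_intervals(probs, states, level = level)
  list(grid = grid, samples = keep, training_samples = training,
       raw = rawres$raw, sigma = rawres$sigma, control = rawres$control,
       transitions = transitions, probs = probs,
       lo = ci$lo, hi = ci$hi, confidence = ci$confidence)
}

#' Classify windows and build the region map from a genotyped panel
#'
#' @param fit result of [genotype_panel()].
#' @param share_frac,max_span,span_rule passed to the allele caller /
#'   window classifier.
#' @return list: `categories` (per window), `regions` (non-diploid region
#'   table).
#' @export
call_regions <- function(fit, share_frac = 0.9, max_span = 3L,
                         span_rule = "n_integers") {
  categories <- window_categories(fit$lo, fit$hi, share_frac = share_frac,
                                  max_span = max_span, span_rule = span_rule)
  list(categories = categories,
       regions = merge_regions(categories, fit$grid))
}
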