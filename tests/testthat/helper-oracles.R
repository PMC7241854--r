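# Independent oracles and shared fixtures.

# Brute-force HMM smoothing by exhaustive path enumeration: for short tracks
# and small state spaces, sums the joint probability of every state path and
# marginalizes per window. Independent of the forward-backward code path.
brute_force_posteriors <- function(logE, A, pi) {
  T_ <- nrow(logE)
  S <- ncol(logE)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), T_)))
  logp <- apply(paths, 1L, function(st) {
    lp <- log(pi[st[1L]]) + logE[1L, st[1L]]
    if (T_ > 1L) {
      for (t in 2:T_) {
        lp <- lp + log(A[st[t - 1L], st[t]]) + logE[t, st[t]]
      }
    }
    lp
  })
  w <- exp(logp - max(logp))
  w <- w / sum(w)
  post <- matrix(0, T_, S)
  for (t in seq_len(T_)) {
    for (s in seq_len(S)) {
      post[t, s] <- sum(w[paths[, t] == s])
    }
  }
  post
}

random_stochastic_matrix <- function(S) {
  A <- matrix(runif(S * S, 0.05, 1), S, S)
  A / rowSums(A)
}

# A tiny emission model over integer states 0..(S-1) for oracle tests.
small_states <- function(S) {
  data.frame(label = as.character(0:(S - 1L)), lo = 0:(S - 1L),
             hi = 0:(S - 1L), is_interval = FALSE, stringsAsFactors = FALSE)
}

# Shared small population simulation: two chromosomes, one {2,4} CNV locus
# and one fixed CN-4 locus, at a realistic (~8%) non-diploid window
# fraction.
small_panel_sim <- function(n_samples = 30L, seed = 42L, sigma_cr = 0.3,
                            coverage = 30) {
  loci <- list(
    list(chrom = "chr1", start = 100000, end = 110000,
         cn = c(2L, 4L), freq = c(0.5, 0.5)),
    list(chrom = "chr2", start = 100000, end = 110000, cn = 4L, freq = 1))
  spec <- sim_spec(n_chromosomes = 2L, chrom_length = 250000L, loci = loci,
                   n_samples = n_samples, mean_coverage = coverage,
                   sigma_cr = sigma_cr, seed = seed)
  ref <- generate_reference(spec)
  grid <- build_windows(ref$sequences)
  truth <- generate_population_truth(grid, spec)
  depth <- simulate_depth_matrix(truth, grid, spec)
  list(spec = spec, ref = ref, grid = grid, truth = truth, depth = depth)
}

# Direct grid construction (no sequence) for moment-level simulations.
flat_grid <- function(n_windows, chrom = "chr1", gc = 0.5) {
  data.frame(chrom = chrom, start = (seq_len(n_windows) - 1L) * 1000L,
             end = seq_len(n_windows) * 1000L, unmasked_bp = 1000L,
             gc_fraction = gc, index = seq_len(n_windows),
             stringsAsFactors = FALSE)
}
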