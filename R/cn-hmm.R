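# Integer copy-number inference: an HMM whose observations are per-window
# raw copy numbers, whose hidden states are integer copy numbers 0..20 plus
# three high-copy interval states, with Normal emissions of width
# sigma_N = sigma_CR * N / 2. Transitions are Baum-Welch trained on held-out
# samples; smoothing posteriors come from the forward-backward algorithm; a
# local population prior re-genotypes each window; and each sample-window is
# summarised as the smallest contiguous integer interval with >= 99%
# cumulative posterior.

#' Copy-number state space
#'
#' Integer states 0..`max_integer` plus interval states for high copy
#' numbers, where copy number and noise are too entangled to resolve single
#' integers. Defaults: integers 0-20 and intervals 21-100, 101-500, 501-1000
#' (24 states).
#'
#' @param max_integer largest single-integer state (default 20).
#' @param intervals list of `c(lo, hi)` interval states.
#' @return data frame with columns `label`, `lo`, `hi`, `is_interval`.
#' @export
cn_states <- function(max_integer = 20L,
                      intervals = list(c(21L, 100L), c(101L, 500L), c(501L, 1000L))) {
  ints <- data.frame(label = as.character(0:max_integer),
                     lo = 0:max_integer, hi = 0:max_integer,
                     is_interval = FALSE, stringsAsFactors = FALSE)
  iv <- do.call(rbind, lapply(intervals, function(x) {
    data.frame(label = paste0(x[1], "-", x[2]), lo = x[1], hi = x[2],
               is_interval = TRUE, stringsAsFactors = FALSE)
  }))
  rbind(ints, iv)
}

#' Emission model for the copy-number HMM
#'
#' Integer state N >= 1 emits `Normal(N, sigma_cr * N / 2)`; state 0, where
#' the formula degenerates to zero width, uses the floor `sigma_cr / 2`
#' (the smallest nonzero width in the family). Interval states emit a
#' mixture of their member integers' Normals; weights default to uniform and
#' may be supplied (e.g. re-estimated from a genome-wide raw-CN histogram).
#'
#' @param sigma_cr standard deviation of raw copy number in control regions
#'   (> 0).
#' @param states state space from [cn_states()].
#' @param interval_weights optional list (one element per interval state) of
#'   mixture weights over member integers; each must sum to 1.
#' @return an object of class `cn_emission`.
#' @export
emission_model <- function(sigma_cr, states = cn_states(),
                           interval_weights = NULL) {
  stopifnot(sigma_cr > 0)
  iv_idx <- which(states$is_interval)
  if (is.null(interval_weights)) {
    interval_weights <- lapply(iv_idx, function(i) {
      m <- states$hi[i] - states$lo[i] + 1L
      rep(1 / m, m)
    })
  }
  stopifnot(length(interval_weights) == length(iv_idx))
  for (w in interval_weights) {
    stopifnot(abs(sum(w) - 1) < 1e-8)
  }
  structure(list(sigma_cr = sigma_cr, states = states,
                 interval_weights = interval_weights),
            class = "cn_emission")
}

state_sigma <- function(n, sigma_cr) {
  ifelse(n == 0, sigma_cr / 2, sigma_cr * n / 2)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Emission log-density
#'
#' Log density of observed raw copy numbers under each HMM state.
#'
#' @param raw numeric vector of raw copy numbers (one track).
#' @param model a `cn_emission` object.
#' @return a length(raw)-by-states matrix of log densities.
#' @export
emission_logprob <- function(raw, model) {
  stopifnot(inherits(model, "cn_emission"))
  st <- model$states
  out <- matrix(-Inf, nrow = length(raw), ncol = nrow(st))
  colnames(out) <- st$label
  for (j in which(!st$is_interval)) {
    out[, j] <- dnorm(raw, mean = st$lo[j],
                      sd = state_sigma(st$lo[j], model$sigma_cr), log = TRUE)
  }
  iv_idx <- which(st$is_interval)
  for (k in seq_along(iv_idx)) {
    j <- iv_idx[k]
    members <- st$lo[j]:st$hi[j]
    w <- model$interval_weights[[k]]
    # T x members matrix of log(w_m) + logNormal(raw; m, sigma_m),
    # collapsed by a vectorized log-sum-exp over members
    sig <- state_sigma(members, model$sigma_cr)
    comp <- outer(raw, members, function(x, m) x - m) /
      rep(sig, each = length(raw))
    comp <- -0.5 * comp^2 -
      rep(log(sig) - log(w), each = length(raw)) - 0.5 * log(2 * pi)
    rmx <- do.call(pmax, as.data.frame(comp))
    out[, j] <- rmx + log(rowSums(exp(comp - rmx)))
  }
  out
}

# Scaled forward-backward. logE: T x S emission log-densities; A: S x S row
# stochastic; pi: initial distribution. Returns per-window smoothing
# posteriors (gamma), total log-likelihood, and (optionally) expected
# transition counts (xi summed over t) for Baum-Welch.
forward_backward_core <- function(logE, A, pi, want_xi = FALSE) {
  T_ <- nrow(logE)
  S <- ncol(logE)
  rmax <- apply(logE, 1L, max)
  if (any(!is.finite(rmax))) stop("window with zero likelihood under every state")
  E <- exp(logE - rmax)  # row-rescaled emissions; FB posteriors invariant
  alpha <- matrix(0, T_, S)
  cvec <- numeric(T_)
  a <- pi * E[1L, ]
  cvec[1L] <- sum(a)
  if (cvec[1L] <= 0) stop("zero likelihood at first window")
  alpha[1L, ] <- a / cvec[1L]
  if (T_ > 1L) {
    for (t in 2:T_) {
      a <- as.numeric(alpha[t - 1L, ] %*% A) * E[t, ]
      cvec[t] <- sum(a)
      if (cvec[t] <= 0) stop("zero likelihood at window ", t)
      alpha[t, ] <- a / cvec[t]
    }
  }
  beta <- matrix(0, T_, S)
  beta[T_, ] <- 1
  if (T_ > 1L) {
    for (t in (T_ - 1L):1L) {
      b <- as.numeric(A %*% (E[t + 1L, ] * beta[t + 1L, ]))
      beta[t, ] <- b / cvec[t + 1L]
    }
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  ll <- sum(log(cvec)) + sum(rmax)
  xi <- NULL
  if (want_xi && T_ > 1L) {
    xi <- matrix(0, S, S)
    for (t in seq_len(T_ - 1L)) {
      x <- (alpha[t, ] %o% (E[t + 1L, ] * beta[t + 1L, ])) * A
      xi <- xi + x / sum(x)
    }
  }
  list(gamma = gamma, loglik = ll, xi = xi)
}

#' Forward-backward posterior decoding
#'
#' Exact HMM smoothing: per-window posterior probabilities over the state
#' space for one raw copy-number track, under a uniform initial state
#' distribution.
#'
#' @param raw numeric vector of raw copy numbers (one chromosome track of
#'   one sample).
#' @param transitions S-by-S row-stochastic transition matrix.
#' @param model a `cn_emission` object.
#' @return a length(raw)-by-states posterior matrix (rows sum to 1) with the
#'   track log-likelihood in attribute `"loglik"`.
#' @export
posterior_decode <- function(raw, transitions, model) {
  stopifnot(length(raw) >= 1L)
  logE <- emission_logprob(raw, model)
  S <- ncol(logE)
  stopifnot(nrow(transitions) == S, ncol(transitions) == S)
  fb <- forward_backward_core(logE, transitions, rep(1 / S, S))
  structure(fb$gamma, loglik = fb$loglik)
}

#' Baum-Welch training of the transition matrix
#'
#' EM re-estimation of the transition matrix only (emissions stay fixed at
#' the Normal family above), on one or more held-out training tracks, until
#' the log-likelihood gain falls below `tol` or `max_iter` is reached. Rows
#' with no expected transitions keep their previous values.
#'
#' @param tracks list of raw copy-number tracks (numeric vectors); if models
#'   differ per track (per-sample sigma_CR), pass a list of `cn_emission`
#'   objects of the same length via `models`.
#' @param model a `cn_emission` used for all tracks (ignored if `models`
#'   given).
#' @param models optional per-track emission models.
#' @param max_iter maximum EM iterations (default 50).
#' @param tol log-likelihood convergence tolerance (default 1e-4).
#' @param init optional initial transition matrix; default is
#'   diagonal-dominant (0.9 self-transition, remainder uniform).
#' @return transition matrix with attribute `"loglik"`: the vector of
#'   per-iteration total log-likelihoods (non-decreasing).
#' @export
train_transitions <- function(tracks, model = NULL, models = NULL,
                              max_iter = 50L, tol = 1e-4, init = NULL) {
  if (!is.list(tracks)) tracks <- list(tracks)
  stopifnot(length(tracks) >= 1L)
  if (is.null(models)) {
    stopifnot(!is.null(model))
    models <- rep(list(model), length(tracks))
  }
  S <- nrow(models[[1L]]$states)
  logEs <- mapply(function(tr, m) emission_logprob(tr, m),
                  tracks, models, SIMPLIFY = FALSE)
  A <- init
  if (is.null(A)) {
    A <- matrix(0.1 / (S - 1L), S, S)
    diag(A) <- 0.9
  }
  pi <- rep(1 / S, S)
  ll_trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    xi_sum <- matrix(0, S, S)
    ll <- 0
    for (i in seq_along(logEs)) {
      fb <- tryCatch(forward_backward_core(logEs[[i]], A, pi, want_xi = TRUE),
                     error = function(e) stop("training track ", i,
                                              " has zero likelihood under the current model: ",
                                              conditionMessage(e)))
      ll <- ll + fb$loglik
      if (!is.null(fb$xi)) xi_sum <- xi_sum + fb$xi
    }
    ll_trace <- c(ll_trace, ll)
    if (iter > 1L && ll - ll_trace[iter - 1L] < tol) break
    rs <- rowSums(xi_sum)
    A_new <- A
    nz <- rs > 0
    A_new[nz, ] <- xi_sum[nz, , drop = FALSE] / rs[nz]
    A <- A_new
  }
  structure(A, loglik = ll_trace)
}

#' Local population prior
#'
#' For each window, the prior probability of each copy-number state is the
#' average posterior across all samples over (up to) `span` consecutive
#' windows centered on the window of interest, truncated at chromosome ends,
#' then renormalized.
#'
#' @param posteriors 3-d array windows x states x samples (or a list of
#'   per-sample posterior matrices).
#' @param chrom chromosome of each window (length = n windows); windows of a
#'   chromosome must be consecutive and ordered.
#' @param span window span (default 5).
#' @return windows-by-states prior matrix (rows sum to 1).
#' @export
population_prior <- function(posteriors, chrom, span = 5L) {
  if (is.list(posteriors)) {
    posteriors <- array(unlist(posteriors),
                        dim = c(nrow(posteriors[[1L]]), ncol(posteriors[[1L]]),
                                length(posteriors)))
  }
  stopifnot(length(dim(posteriors)) == 3L)
  half <- span %/% 2L
  T_ <- dim(posteriors)[1L]
  stopifnot(length(chrom) == T_)
  smean <- apply(posteriors, c(1L, 2L), mean)  # mean over samples
  prior <- matrix(NA_real_, T_, ncol(smean))
  for (ch in unique(chrom)) {
    rows <- which(chrom == ch)
    n <- length(rows)
    cs <- rbind(0, apply(smean[rows, , drop = FALSE], 2L, cumsum))
    for (k in seq_len(n)) {
      a <- max(1L, k - half)
      b <- min(n, k + half)
      prior[rows[k], ] <- (cs[b + 1L, ] - cs[a, ]) / (b - a + 1L)
    }
  }
  prior / rowSums(prior)
}

#' Bayesian population re-genotyping
#'
#' Corrects one sample's posterior with the local population prior via
#' Bayes' theorem. Since the decoding posterior was obtained under a uniform
#' state prior, it is proportional to the likelihood, so the corrected
#' probability is the renormalized product `posterior * prior`. If the
#' product vanishes everywhere in a window (prior and posterior supported on
#' disjoint states) the uncorrected posterior is kept and a warning raised.
#'
#' @param posterior windows-by-states posterior matrix for one sample.
#' @param prior windows-by-states prior matrix from [population_prior()].
#' @return corrected windows-by-states probability matrix.
#' @export
bayes_regenotype <- function(posterior, prior) {
  stopifnot(all(dim(posterior) == dim(prior)))
  prod <- posterior * prior
  rs <- rowSums(prod)
  bad <- rs <= 0 | !is.finite(rs)
  if (any(bad)) {
    warning(sum(bad), " window(s) with vanishing posterior-prior product; ",
            "keeping uncorrected posterior there")
    prod[bad, ] <- posterior[bad, , drop = FALSE]
    rs[bad] <- rowSums(posterior[bad, , drop = FALSE])
  }
  prod / rs
}

#' 99% copy-number confidence interval
#'
#' Starting from the most probable state, the contiguous state interval is
#' grown one neighbor at a time - always toward the adjacent state with the
#' higher probability, ties toward the lower copy number - until the
#' cumulative probability reaches `level` (e.g. (3) to (3-4) to (3-5)).
#' High-copy interval states absorb as their upper bound.
#'
#' @param p probability vector over the state space (sums to 1).
#' @param states state space from [cn_states()].
#' @param level confidence level (default 0.99).
#' @return list with integer `lo`, `hi` and achieved `confidence`.
#' @export
confidence_interval <- function(p, states = cn_states(), level = 0.99) {
  stopifnot(length(p) == nrow(states))
  i0 <- which.max(p)  # ties: lowest state
  lo <- hi <- i0
  cum <- p[i0]
  S <- length(p)
  while (cum < level && (lo > 1L || hi < S)) {
    pl <- if (lo > 1L) p[lo - 1L] else -Inf
    ph <- if (hi < S) p[hi + 1L] else -Inf
    if (pl >= ph) {           # ties go to the lower copy number
      lo <- lo - 1L
      cum <- cum + p[lo]
    } else {
      hi <- hi + 1L
      cum <- cum + p[hi]
    }
  }
  list(lo = states$lo[lo], hi = states$hi[hi], confidence = unname(cum))
}

#' Confidence intervals for a probability array
#'
#' @param probs 3-d array windows x states x samples of (re-genotyped)
#'   probabilities.
#' @param states state space.
#' @param level confidence level (default 0.99).
#' @return list of windows-by-samples integer matrices `lo` and `hi` and a
#'   numeric matrix `confidence`.
#' @export
confidence_intervals <- function(probs, states = cn_states(), level = 0.99) {
  T_ <- dim(probs)[1L]
  n <- dim(probs)[3L]
  lo <- hi <- matrix(NA_integer_, T_, n)
  conf <- matrix(NA_real_, T_, n)
  for (j in seq_len(n)) {
    pj <- probs[, , j, drop = FALSE]
    for (w in seq_len(T_)) {
      ci <- confidence_interval(pj[w, , 1L], states, level)
      lo[w, j] <- ci$lo
      hi[w, j] <- ci$hi
      conf[w, j] <- ci$confidence
    }
  }
  dimnames(lo) <- dimnames(hi) <- dimnames(conf) <-
    list(NULL, dimnames(probs)[[3L]])
  list(lo = lo, hi = hi, confidence = conf)
}
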