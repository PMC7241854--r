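test_that("emission widths follow sigma_N = sigma_CR * N / 2 with a floor at 0", {
  m <- emission_model(0.4)
  st <- m$states
  # N = 2 has width exactly sigma_CR; N = 4 twice that; N = 0 the floor
  le <- emission_logprob(c(2, 4, 0), m)
  expect_equal(unname(le[1, "2"]), dnorm(2, 2, 0.4, log = TRUE))
  expect_equal(unname(le[2, "4"]), dnorm(4, 4, 0.8, log = TRUE))
  expect_equal(unname(le[3, "0"]), dnorm(0, 0, 0.2, log = TRUE))
  # at the mode the log density is -log(sigma_N * sqrt(2*pi))
  expect_equal(unname(le[1, "2"]), -log(0.4 * sqrt(2 * pi)))
  # interval-state mixture weights must sum to one
  expect_error(emission_model(0.4, interval_weights = list(c(1), c(1), c(0.5))))
})

test_that("forward-backward equals exhaustive path enumeration (<= 6 windows)", {
  set.seed(10)
  for (rep in 1:10) {
    S <- sample(2:4, 1)
    T_ <- sample(1:6, 1)
    logE <- matrix(log(runif(T_ * S, 0.01, 1)), T_, S)
    A <- random_stochastic_matrix(S)
    pi <- rep(1 / S, S)
    fb <- rdcnv:::forward_backward_core(logE, A, pi)
    bf <- brute_force_posteriors(logE, A, pi)
    expect_lt(max(abs(fb$gamma - bf)), 1e-9)
    expect_equal(rowSums(fb$gamma), rep(1, T_), tolerance = 1e-9)
  }
})

test_that("posterior decoding recovers noiseless integer tracks", {
  m <- emission_model(0.05)
  S <- nrow(m$states)
  A <- matrix(0.001 / (S - 1), S, S)
  diag(A) <- 0.999
  raw <- c(2, 2, 2, 4, 4, 2, 1, 1)
  post <- posterior_decode(raw, A, m)
  expect_equal(m$states$lo[apply(post, 1, which.max)], c(2, 2, 2, 4, 4, 2, 1, 1))
  expect_equal(rowSums(post), rep(1, length(raw)), tolerance = 1e-9)
})

test_that("Baum-Welch fixes self-transitions on constant data and is monotone", {
  m <- emission_model(0.2)
  A <- train_transitions(rep(2, 200), model = m, max_iter = 20)
  i2 <- which(m$states$label == "2")
  expect_lt(abs(A[i2, i2] - 1), 1e-3)
  ll <- attr(A, "loglik")
  expect_true(all(diff(ll) >= -1e-8))

  # a track with one CN-2 -> CN-4 breakpoint leaves a positive trained
  # 2 -> 4 transition
  set.seed(11)
  raw <- c(rnorm(100, 2, 0.2), rnorm(100, 4, 0.2))
  A2 <- train_transitions(raw, model = m, max_iter = 20)
  i4 <- which(m$states$label == "4")
  expect_gt(A2[i2, i4], 0)
  expect_true(all(diff(attr(A2, "loglik")) >= -1e-8))
  expect_equal(unname(rowSums(A2)), rep(1, nrow(A2)), tolerance = 1e-9)
})

test_that("population prior averages samples over a truncated 5-window span", {
  T_ <- 4L
  S <- 3L
  p1 <- matrix(c(1, 0, 0,
                 0, 1, 0,
                 0, 1, 0,
                 0, 0, 1), T_, S, byrow = TRUE)
  p2 <- matrix(c(0, 1, 0,
                 0, 1, 0,
                 1, 0, 0,
                 0, 0, 1), T_, S, byrow = TRUE)
  arr <- array(c(p1, p2), dim = c(T_, S, 2))
  prior <- population_prior(arr, chrom = rep("chr1", T_), span = 5L)
  # first window of the chromosome averages windows 1..3 only
  expect_equal(prior[1, ], colMeans(rbind(p1[1:3, ], p2[1:3, ])) /
                 sum(colMeans(rbind(p1[1:3, ], p2[1:3, ]))))
  expect_equal(rowSums(prior), rep(1, T_), tolerance = 1e-9)

  # consensus across samples concentrates the prior
  consensus <- array(0, dim = c(3, 3, 4))
  consensus[, 2, ] <- 1
  pr <- population_prior(consensus, chrom = rep("chr1", 3))
  expect_equal(pr[, 2], rep(1, 3))
})

test_that("Bayes re-genotyping multiplies by the prior and renormalizes", {
  post <- matrix(c(0.2, 0.3, 0.5), 1, 3)
  expect_equal(bayes_regenotype(post, matrix(1 / 3, 1, 3)), post)
  conc <- matrix(c(0, 1, 0), 1, 3)
  expect_equal(bayes_regenotype(post, conc), matrix(c(0, 1, 0), 1, 3))
  pri <- matrix(c(0.5, 0.3, 0.2), 1, 3)
  hand <- c(0.2 * 0.5, 0.3 * 0.3, 0.5 * 0.2)
  expect_equal(bayes_regenotype(post, pri), matrix(hand / sum(hand), 1, 3))
  # disjoint support falls back to the uncorrected posterior with a warning
  expect_warning(out <- bayes_regenotype(matrix(c(1, 0, 0), 1, 3),
                                         matrix(c(0, 0.5, 0.5), 1, 3)),
                 "vanishing")
  expect_equal(out, matrix(c(1, 0, 0), 1, 3))
  # when every sample agrees, the correction never changes the call
  set.seed(12)
  for (i in 1:20) {
    p <- runif(24)
    p <- p / sum(p)
    top <- which.max(p)
    prior <- rep(0.001, 24)
    prior[top] <- 1
    prior <- prior / sum(prior)
    corr <- bayes_regenotype(matrix(p, 1), matrix(prior, 1))
    expect_equal(which.max(corr), top)
  }
})

test_that("confidence intervals grow toward the heavier neighbor until 99%", {
  st <- cn_states()
  p <- rep(0, nrow(st))
  p[st$label == "2"] <- 1
  ci <- confidence_interval(p, st)
  expect_equal(c(ci$lo, ci$hi), c(2L, 2L))

  p <- rep(0, nrow(st))
  p[st$label == "3"] <- 0.97
  p[st$label == "4"] <- 0.02
  p[st$label == "2"] <- 0.01
  ci <- confidence_interval(p, st)
  expect_equal(c(ci$lo, ci$hi), c(3L, 4L))
  expect_gte(ci$confidence, 0.99)

  # (3) -> (3-4) -> (3-5) growth when 4 then 5 are the best extensions
  p <- rep(0, nrow(st))
  p[st$label == "3"] <- 0.60
  p[st$label == "4"] <- 0.30
  p[st$label == "5"] <- 0.095
  p[st$label == "2"] <- 0.005
  ci <- confidence_interval(p, st)
  expect_equal(c(ci$lo, ci$hi), c(3L, 5L))

  # ties extend toward the lower copy number
  p <- rep(0, nrow(st))
  p[st$label == "3"] <- 0.9
  p[st$label == "2"] <- 0.05
  p[st$label == "4"] <- 0.05
  ci <- confidence_interval(p, st, level = 0.95)
  expect_equal(c(ci$lo, ci$hi), c(2L, 3L))

  # high-copy interval states absorb as their upper bound
  p <- rep(0, nrow(st))
  p[st$label == "20"] <- 0.5
  p[st$label == "21-100"] <- 0.5
  ci <- confidence_interval(p, st)
  expect_equal(ci$hi, 100L)

  # the emitted interval always contains the top state
  set.seed(13)
  for (i in 1:50) {
    p <- runif(nrow(st))^3
    p <- p / sum(p)
    ci <- confidence_interval(p, st)
    top <- which.max(p)
    expect_true(st$lo[top] >= ci$lo && st$hi[top] <= ci$hi)
    expect_gte(ci$confidence, 0.99)
  }
})
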