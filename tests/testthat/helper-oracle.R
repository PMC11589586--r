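# Brute-force HMM oracle: exhaustive enumeration over all state paths.
# Kept deliberately independent of the package's forward-backward code —
# it builds dense transition matrices and sums over S^T paths.

oracle_transition <- function(rates, M, d) {
  S <- length(rates)
  p <- exp(-rates * d)
  A <- matrix(0, S, S)
  for (k in seq_len(S))
    for (l in seq_len(S))
      A[k, l] <- (if (k == l) p[k] else 0) + (1 - p[k]) * M[l]
  A
}

oracle_enumerate <- function(emis, rates, M, dist) {
  T_ <- nrow(emis); S <- ncol(emis)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), T_)))
  A <- lapply(seq_along(dist), function(t) oracle_transition(rates, M, dist[t]))
  w <- apply(paths, 1, function(pp) {
    pr <- M[pp[1]] * emis[1, pp[1]]
    if (T_ > 1)
      for (t in 2:T_)
        pr <- pr * A[[t - 1]][pp[t - 1], pp[t]] * emis[t, pp[t]]
    pr
  })
  lik <- sum(w)
  gamma <- matrix(0, T_, S)
  for (t in seq_len(T_))
    for (s in seq_len(S))
      gamma[t, s] <- sum(w[paths[, t] == s]) / lik
  list(gamma = gamma, loglik = log(lik),
       viterbi = paths[which.max(w), ], max_path_prob = max(w))
}

# probability of one specific state path (for tie-robust Viterbi checks)
oracle_path_prob <- function(pp, emis, rates, M, dist) {
  T_ <- nrow(emis)
  pr <- M[pp[1]] * emis[1, pp[1]]
  if (T_ > 1)
    for (t in 2:T_) {
      A <- oracle_transition(rates, M, dist[t - 1])
      pr <- pr * A[pp[t - 1], pp[t]] * emis[t, pp[t]]
    }
  pr
}

# small Hardy-Weinberg panel builder for unit tests
hwe_panel <- function(n, m, freqs = NULL, seed = 1, scaffold = "s1",
                      population = "P") {
  set.seed(seed)
  if (is.null(freqs)) freqs <- runif(m, 0.05, 0.95)
  X <- sapply(freqs, function(f) rbinom(n, 2, f))
  genotype_panel(X,
                 data.frame(scaffold = scaffold, pos = seq_len(m) * 1000,
                            gpos = seq_len(m) * 1000 * 2e-8),
                 data.frame(id = sprintf("i%03d", seq_len(n)),
                            population = population))
}

# simulate observations from the HBD HMM itself (for EM recovery tests)
simulate_hmm <- function(T_, rates, M, freqs, error, dist, seed = 1) {
  set.seed(seed)
  S <- length(rates)
  path <- integer(T_)
  path[1] <- sample.int(S, 1, prob = M)
  for (t in 2:T_) {
    stay <- exp(-rates[path[t - 1]] * dist[t - 1])
    path[t] <- if (runif(1) < stay) path[t - 1]
               else sample.int(S, 1, prob = M)
  }
  g <- integer(T_)
  nonhbd <- S
  for (t in seq_len(T_)) {
    f <- freqs[t]
    g[t] <- if (path[t] == nonhbd || runif(1) < error) rbinom(1, 2, f)
            else if (runif(1) < f) 2L else 0L
  }
  list(genotypes = g, path = path)
}
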