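# Independent brute-force oracles for the HMM recursions, plus small model
# generators shared across test files.

enumerate_paths <- function(k, n) {
  as.matrix(expand.grid(rep(list(seq_len(k)), n)))
}

path_log_prob <- function(model, y, s) {
  lp <- log(model$initial_distribution[s[1]]) +
    sum(dnorm(y, model$means[s], model$sds[s], log = TRUE))
  if (length(s) > 1) {
    lp <- lp + sum(log(model$transition_matrix[cbind(s[-length(s)], s[-1])]))
  }
  lp
}

# Exact marginal log-likelihood by exhaustive path enumeration.
oracle_loglik <- function(model, y) {
  paths <- enumerate_paths(model$k, length(y))
  lp <- apply(paths, 1, function(s) path_log_prob(model, y, s))
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

# Exact maximum-probability path by exhaustive enumeration.
oracle_viterbi <- function(model, y) {
  paths <- enumerate_paths(model$k, length(y))
  lp <- apply(paths, 1, function(s) path_log_prob(model, y, s))
  unname(paths[which.max(lp), ])
}

# Random valid Gaussian-emission HMM with well-conditioned parameters.
random_hmm <- function(k, seed) {
  fretfold::with_seed(seed, {
    P <- matrix(runif(k * k, 0.05, 1), k, k)
    P <- P / rowSums(P)
    pi0 <- runif(k, 0.1, 1)
    pi0 <- pi0 / sum(pi0)
    means <- sort(runif(k, 0.05, 0.95))
    if (k > 1) means <- means + seq(0, 0.02, length.out = k)  # avoid ties
    means <- pmin(means, 1)
    hmm_model(means, runif(k, 0.03, 0.12), P, pi0)
  })
}

# Per-molecule FRET tibble straight from simulator truth (no photophysics):
# exact Gaussian emissions around the state means.
noiseless_fret <- function(model, n_molecules, n_frames, seed) {
  purrr::map_dfr(seq_len(n_molecules), function(i) {
    path <- simulate_state_path(model, n_frames, seed * 1000 + i)
    eff <- with_seed(seed * 2000 + i, {
      pmin(pmax(rnorm(n_frames, model$emission_means[path],
                      model$emission_sds[path]), 0), 1)
    })
    tibble::tibble(molecule_id = sprintf("m%03d", i),
                   frame = seq_len(n_frames),
                   efficiency = eff, valid = TRUE,
                   true_state = path)
  })
}
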