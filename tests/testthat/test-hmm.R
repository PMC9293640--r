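# HMM machinery against brute-force oracles, EM behaviour, state-count
# selection, idealization.

test_that("forward likelihood equals the closed form for one state", {
  m <- hmm_model(0.5, 0.1, matrix(1, 1, 1), 1)
  y <- c(0.42, 0.55, 0.50, 0.61)
  expect_equal(forward_log_likelihood(m, y),
               sum(dnorm(y, 0.5, 0.1, log = TRUE)), tolerance = 1e-12)
})

test_that("forward likelihood matches exhaustive path enumeration", {
  for (r in 1:20) {
    k <- with_seed(r, sample(2:3, 1))
    n <- with_seed(r + 100, sample(2:8, 1))
    m <- random_hmm(k, seed = r)
    y <- with_seed(r + 200, runif(n))
    expect_equal(forward_log_likelihood(m, y, clamp = FALSE),
                 oracle_loglik(m, y), tolerance = 1e-9)
  }
})

test_that("state duplication never decreases the likelihood", {
  m <- random_hmm(2, seed = 5)
  y <- with_seed(6, runif(6))
  # split state 2's initial and incoming mass across two identical copies
  P3 <- rbind(cbind(m$transition_matrix[, 1],
                    m$transition_matrix[, 2] / 2,
                    m$transition_matrix[, 2] / 2),
              c(m$transition_matrix[2, 1], m$transition_matrix[2, 2] / 2,
                m$transition_matrix[2, 2] / 2))
  pi3 <- c(m$initial_distribution[1], m$initial_distribution[2] / 2,
           m$initial_distribution[2] / 2)
  m3 <- hmm_model(c(m$means[1], m$means[2], m$means[2] + 1e-9),
                  c(m$sds[1], m$sds[2], m$sds[2]), P3, pi3)
  expect_gte(forward_log_likelihood(m3, y, clamp = FALSE) + 1e-7,
             forward_log_likelihood(m, y, clamp = FALSE))
})

test_that("Viterbi matches the exhaustive argmax path", {
  for (r in 1:20) {
    k <- with_seed(r + 300, sample(2:3, 1))
    n <- with_seed(r + 400, sample(2:8, 1))
    m <- random_hmm(k, seed = r + 31)
    y <- with_seed(r + 500, runif(n))
    expect_identical(viterbi_decode(m, y, clamp = FALSE),
                     as.integer(oracle_viterbi(m, y)))
  }
})

test_that("Viterbi degenerate cases: one state, and on-mean observations", {
  m1 <- hmm_model(0.5, 0.1, matrix(1, 1, 1), 1)
  expect_equal(viterbi_decode(m1, runif(10)), rep(1L, 10))

  m <- hmm_model(c(0.2, 0.8), c(0.05, 0.05),
                 matrix(c(0.95, 0.05, 0.05, 0.95), 2, byrow = TRUE),
                 c(0.5, 0.5))
  expect_equal(viterbi_decode(m, rep(0.8, 20)), rep(2L, 20))
})

test_that("Baum-Welch recovers a single-state mean", {
  y <- with_seed(8, rnorm(2000, 0.6, 0.08))
  fit <- baum_welch_fit(y, k = 1, n_restarts = 1)
  se <- 0.08 / sqrt(2000)
  expect_lt(abs(fit$means - mean(pmin(pmax(y, 0), 1))), 1e-6)
  expect_lt(abs(fit$means - 0.6), 3 * se)
})

test_that("Baum-Welch recovers three-state emission means and transitions", {
  m <- atrg3_model(self_prob = 0.9)
  fr <- noiseless_fret(m, n_molecules = 60, n_frames = 200, seed = 3)
  fit <- baum_welch_fit(fr, k = 3, n_restarts = 2, seed = 1)
  expect_lt(max(abs(fit$means - c(0.32, 0.50, 0.74))), 0.02)
  expect_true(all(diff(fit$loglik_path) > -1e-8))
  # transition matrix recovery within 3 s.e. of binomial sampling error
  n_i <- tabulate(fr$true_state, 3) |> pmax(1)
  for (i in 1:3) for (j in 1:3) {
    p <- m$transition_matrix[i, j]
    se <- sqrt(p * (1 - p) / n_i[i])
    expect_lt(abs(fit$transition_matrix[i, j] - p), 3 * se + 0.01)
  }
})

test_that("EM log-likelihood is monotone across data sets and state counts", {
  for (r in 1:4) {
    m <- if (r %% 2) atrg3_model(0.9) else g4_model(0.9)
    fr <- noiseless_fret(m, n_molecules = 15, n_frames = 80, seed = r + 40)
    for (k in c(2, length(m$emission_means))) {
      fit <- baum_welch_fit(fr, k, n_restarts = 1, seed = r)
      expect_true(all(diff(fit$loglik_path) > -1e-8))
    }
  }
})

test_that("initial-permutation invariance: canonical order undoes relabeling", {
  fr <- noiseless_fret(atrg3_model(0.9), n_molecules = 30, n_frames = 120,
                       seed = 77)
  f1 <- baum_welch_fit(fr, 3, n_restarts = 1, seed = 1)
  f2 <- baum_welch_fit(fr, 3, n_restarts = 3, seed = 9)
  expect_equal(f1$means, f2$means, tolerance = 1e-3)
  expect_equal(f1$transition_matrix, f2$transition_matrix, tolerance = 5e-3)
})

test_that("BIC selects the generating state count", {
  fr1 <- noiseless_fret(
    folding_model(0.5, 0.06, matrix(1, 1, 1), 1), 20, 100, seed = 15)
  sel1 <- select_state_count(fr1, k_range = 1:3, n_restarts = 2)
  expect_equal(sel1$best_k, 1)

  fr3 <- noiseless_fret(atrg3_model(0.9), 40, 100, seed = 16)
  sel3 <- select_state_count(fr3, k_range = 1:5, n_restarts = 2)
  expect_equal(sel3$best_k, 3)
  expect_equal(sel3$summary$n_params, c(2, 7, 14, 23, 34))
})

test_that("idealization is run-length encoding of the Viterbi path", {
  m <- hmm_model(c(0.2, 0.8), c(0.05, 0.05),
                 matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE), c(0.5, 0.5))
  # observations pinned at the means give a deterministic path 1110011
  fr <- tibble::tibble(molecule_id = "m", frame = 1:7,
                       efficiency = c(0.2, 0.2, 0.2, 0.8, 0.8, 0.2, 0.2))
  seg <- idealize(m, fr)
  expect_equal(seg$start_frame, c(1, 4, 6))
  expect_equal(seg$end_frame, c(4, 6, 8))
  expect_equal(seg$state, c(1, 2, 1))
  expect_equal(seg$state_mean, c(0.2, 0.8, 0.2))
})

test_that("idealization recovers >= 90% of frames at 3-sigma state separation", {
  m <- atrg3_model(self_prob = 0.95)  # separations 0.18/0.24 at sd 0.06
  fr <- noiseless_fret(m, n_molecules = 30, n_frames = 150, seed = 19)
  true_model <- hmm_model(m$emission_means, m$emission_sds,
                          m$transition_matrix, m$initial_distribution)
  seg <- idealize(true_model, fr)
  decoded <- fr |>
    dplyr::group_by(molecule_id) |>
    dplyr::mutate(decoded = viterbi_decode(true_model, efficiency)) |>
    dplyr::ungroup()
  expect_gte(mean(decoded$decoded == decoded$true_state), 0.9)
  # segments cover the frames contiguously with alternating states
  for (mm in unique(seg$molecule_id)[1:5]) {
    s <- seg[seg$molecule_id == mm, ]
    expect_equal(s$start_frame[-1], s$end_frame[-nrow(s)])
    expect_true(all(diff(s$state) != 0))
  }
})

test_that("HMM models round-trip through JSON", {
  fr <- noiseless_fret(atrg3_model(0.9), 20, 80, seed = 23)
  fit <- baum_welch_fit(fr, 3, n_restarts = 1)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_hmm_json(fit, tmp)
  back <- read_hmm_json(tmp)
  expect_equal(back$means, fit$means, tolerance = 1e-12)
  expect_equal(back$transition_matrix, fit$transition_matrix,
               tolerance = 1e-12)
  expect_equal(glance(fit)$k, 3)
  expect_equal(nrow(tidy(fit)), 3)
})
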