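# Trace simulator: state paths, intensity emission, dataset assembly.

test_that("state path respects degenerate chains and the seed contract", {
  m <- folding_model(c(0.3, 0.7), 0.06, diag(2),
                     initial_distribution = c(1, 0))
  expect_equal(simulate_state_path(m, 50, seed = 3), rep(1L, 50))

  m2 <- folding_model(c(0.3, 0.7), 0.06,
                      matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE))
  p1 <- simulate_state_path(m2, 200, seed = 7)
  p2 <- simulate_state_path(m2, 200, seed = 7)
  expect_identical(p1, p2)
  expect_false(identical(p1, simulate_state_path(m2, 200, seed = 8)))
})

test_that("empirical occupancy and transition frequencies match the chain", {
  m <- g4_model(self_prob = 0.9)
  path <- simulate_state_path(m, 1e5, seed = 11)
  pi <- stationary_distribution(m$transition_matrix)
  occ <- tabulate(path, 4) / length(path)
  # 3 s.e. with s.e. ~ sqrt(p(1-p)/n_eff); sticky chains mix slowly, so use
  # an autocorrelation-inflated effective sample size (relaxation time of
  # the 0.9-sticky birth-death chain is ~50 frames)
  n_eff <- 1e5 * 0.02
  for (s in 1:4) {
    se <- sqrt(pi[s] * (1 - pi[s]) / n_eff)
    expect_lt(abs(occ[s] - pi[s]), 3 * se)
  }
  # conditional transition frequencies against matrix rows (iid given row)
  from <- path[-length(path)]; to <- path[-1]
  for (i in 1:4) {
    n_i <- sum(from == i)
    for (j in 1:4) {
      phat <- sum(from == i & to == j) / n_i
      se <- sqrt(m$transition_matrix[i, j] *
                   (1 - m$transition_matrix[i, j]) / n_i)
      expect_lt(abs(phat - m$transition_matrix[i, j]), 3 * max(se, 1e-4))
    }
  }
})

test_that("emission arithmetic: FRET partitions a fixed photon budget", {
  m <- folding_model(c(0.2, 0.5), 1e-9, diag(2),
                     initial_distribution = c(0, 1))
  phys <- photophysics(total_intensity = 1000, intensity_sd = 0,
                       background = 0, donor_bleach_prob = 0,
                       acceptor_bleach_prob = 0)
  tr <- emit_intensities(rep(2L, 10), m, phys, seed = 1)
  expect_equal(tr$donor, tr$acceptor, tolerance = 1e-5)
  expect_equal(tr$donor + tr$acceptor, rep(1000, 10), tolerance = 1e-6)
})

test_that("computed FRET recovers the generating state mean", {
  m <- folding_model(c(0.3, 0.74), 0.06, diag(2),
                     initial_distribution = c(0, 1))
  phys <- photophysics(donor_bleach_prob = 0, acceptor_bleach_prob = 0)
  tr <- emit_intensities(rep(2L, 1000), m, phys, seed = 5)
  e <- tr$acceptor / (tr$donor + tr$acceptor)
  se <- sd(e) / sqrt(length(e))
  expect_lt(abs(mean(e) - 0.74), 3 * se + 0.005)  # + clamp/ratio bias margin
})

test_that("acceptor bleach collapses FRET; donor bleach collapses both channels", {
  m <- folding_model(c(0.3, 0.74), 0.01, diag(2),
                     initial_distribution = c(0, 1))
  phys <- photophysics(intensity_sd = 0, background = 5,
                       donor_bleach_prob = 0, acceptor_bleach_prob = 0.02)
  tr <- emit_intensities(rep(2L, 400), m, phys, seed = 2)
  b <- attr(tr, "bleach")$acceptor
  expect_false(is.na(b))
  after <- tr$frame >= b
  expect_true(all(tr$acceptor[after] == 5))
  expect_true(all(tr$donor[after] == 1005))
  e_after <- tr$acceptor[after] / (tr$donor[after] + tr$acceptor[after])
  expect_true(all(e_after < 0.01))

  phys_d <- photophysics(intensity_sd = 0, background = 5,
                         donor_bleach_prob = 0.02, acceptor_bleach_prob = 0)
  tr_d <- emit_intensities(rep(2L, 400), m, phys_d, seed = 2)
  bd <- attr(tr_d, "bleach")$donor
  after_d <- tr_d$frame >= bd
  expect_true(all(tr_d$donor[after_d] == 5))
  expect_true(all(tr_d$acceptor[after_d] == 5))
})

test_that("dataset assembly composes per-molecule simulation deterministically", {
  m <- atrg3_model()
  phys <- photophysics()
  sim1 <- simulate_traces(m, n_molecules = 5, n_frames = 40, phys, seed = 9)
  sim2 <- simulate_traces(m, n_molecules = 5, n_frames = 40, phys, seed = 9)
  expect_identical(as.data.frame(sim1), as.data.frame(sim2))

  # trace i is independent of n_molecules, and equals the direct composition
  sim_big <- simulate_traces(m, n_molecules = 8, n_frames = 40, phys, seed = 9)
  one <- sim_big[sim_big$molecule_id == "mol0003", ]
  path <- simulate_state_path(m, 40, fretfold:::derive_seed(9, 3, 1L))
  tr <- emit_intensities(path, m, phys, fretfold:::derive_seed(9, 3, 2L))
  expect_equal(one$donor, tr$donor)
  expect_equal(one$acceptor, tr$acceptor)
  expect_equal(one$true_state, path)
})

test_that("pooled true-state occupancy matches the stationary distribution", {
  m <- g4_model(self_prob = 0.9)
  sim <- simulate_traces(m, n_molecules = 300, n_frames = 400,
                         photophysics(donor_bleach_prob = 0,
                                      acceptor_bleach_prob = 0),
                         seed = 4)
  pi <- stationary_distribution(m$transition_matrix)
  occ <- tabulate(sim$true_state, 4) / nrow(sim)
  # molecules are independent; the effective n is the molecule count times
  # the autocorrelation-adjusted per-trace effective frames
  n_eff <- 300 * 400 * 0.02
  for (s in 1:4) {
    se <- sqrt(pi[s] * (1 - pi[s]) / n_eff)
    expect_lt(abs(occ[s] - pi[s]), 3 * se)
  }
})

test_that("trace tables and truth sidecars round-trip through TSV", {
  sim <- simulate_traces(atrg3_model(), n_molecules = 3, n_frames = 30,
                         seed = 21)
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "traces.tsv")
  write_fret_traces(sim, f)
  back <- read_fret_traces(f)
  expect_equal(back$molecule_id, sim$molecule_id)
  expect_equal(back$frame, sim$frame)
  expect_equal(back$donor, sim$donor, tolerance = 1e-9)

  ft <- file.path(tmp, "truth.tsv")
  write_state_truth(sim, ft)
  tr <- read_state_truth(ft)
  expect_equal(tr$truth$true_state, sim$true_state)
  expect_equal(tr$header$seed, 21)
  expect_equal(tr$header$model$emission_means, c(0.32, 0.50, 0.74))

  fm <- file.path(tmp, "manifest.json")
  write_manifest(list(K100 = list(trace_file = "traces.tsv", kcl_mM = 100)),
                 fm)
  man <- read_manifest(fm)
  expect_equal(man$K100$kcl_mM, 100)
})
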