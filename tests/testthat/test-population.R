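# Histograms, Gaussian mixture decomposition, state fractions, titration and
# condition comparison.

test_that("histogram binning conserves mass with half-open bins", {
  h <- build_histogram(c(0.5), bin_width = 0.02)
  expect_equal(sum(h$count), 1)
  expect_equal(h$count[h$bin_lo <= 0.5 & h$bin_hi > 0.5], 1)

  x <- with_seed(3, runif(5000))
  h2 <- build_histogram(x, bin_width = 0.02)
  expect_equal(sum(h2$count), 5000)
  expect_equal(attr(h2, "n_samples"), 5000)
  # boundary conventions: 1.0 falls in the last (closed) bin
  h3 <- build_histogram(c(0, 0.02, 1), bin_width = 0.02)
  expect_equal(sum(h3$count), 3)
  expect_equal(h3$count[length(h3$count)], 1)
  expect_error(build_histogram(numeric(0)), "no samples")
})

test_that("histogram of normal draws centres at the generating mean", {
  x <- with_seed(9, rnorm(1e4, 0.5, 0.06))
  h <- build_histogram(x)
  mids <- (h$bin_lo + h$bin_hi) / 2
  mu_hat <- sum(mids * h$count) / sum(h$count)
  expect_lt(abs(mu_hat - 0.5), 3 * 0.06 / sqrt(1e4) + 0.01)
})

test_that("single-component fit recovers the sample mean", {
  x <- with_seed(12, rnorm(2000, 0.32, 0.05))
  fit <- fit_gaussian_mixture(x, k = 1)
  expect_lt(abs(fit$components$center - 0.32), 0.01)
  expect_equal(fit$components$area, 1)
  expect_equal(state_fractions(fit)$fraction, 1)
})

test_that("three-component fit recovers the ATRG3 state means", {
  m <- atrg3_model(self_prob = 0.9)
  fr <- noiseless_fret(m, n_molecules = 100, n_frames = 60, seed = 31)
  fit <- fit_gaussian_mixture(fr, k = 3, seed = 1)
  expect_lt(max(abs(fit$components$center - c(0.32, 0.50, 0.74))), 0.02)
  expect_equal(sum(fit$components$area), 1, tolerance = 1e-9)
})

test_that("mixture agrees with an independent EM implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))  # Mclust resolves helpers by attachment
  x <- with_seed(14, c(rnorm(1500, 0.35, 0.05), rnorm(1500, 0.7, 0.05)))
  x <- pmin(pmax(x, 0), 1)
  fit <- fit_gaussian_mixture(x, k = 2, seed = 2)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(fit$components$center, sort(as.numeric(mc$parameters$mean)),
               tolerance = 5e-3)
  expect_equal(fit$components$area,
               mc$parameters$pro[order(mc$parameters$mean)],
               tolerance = 2e-2)
})

test_that("symmetric two-component mixture splits areas evenly", {
  x <- with_seed(17, c(rnorm(2500, 0.3, 0.05), rnorm(2500, 0.7, 0.05)))
  fit <- fit_gaussian_mixture(x, k = 2, seed = 1)
  expect_lt(abs(fit$components$area[1] - 0.5), 3 * sqrt(0.25 / 5000) + 0.01)
})

test_that("state fractions normalize areas and label the extremes", {
  fit <- structure(
    list(components = tibble::tibble(state = 1:4,
                                     center = c(0.32, 0.5, 0.74, 0.92),
                                     width = 0.06, area = c(1, 1, 1, 1) / 4),
         k = 4L, n = 400L, loglik = 0, bic = 0, n_iter = 1L,
         data = tibble::tibble(molecule_id = "m", efficiency = 0.5)),
    class = "fret_mixture")
  fr <- state_fractions(fit)
  expect_equal(fr$fraction, rep(0.25, 4))
  expect_equal(sum(fr$fraction), 1, tolerance = 1e-9)
  expect_equal(fr$label,
               c("unfolded", "intermediate_1", "intermediate_2", "folded"))
})

test_that("folded fraction rises between low- and high-K+ simulations", {
  lo <- potassium_model(5, "3G", emission_sds = 0.05)
  hi <- potassium_model(150, "3G", emission_sds = 0.05)
  fr_lo <- noiseless_fret(lo, 80, 60, seed = 41)
  fr_hi <- noiseless_fret(hi, 80, 60, seed = 42)
  pooled_means <- c(0.32, 0.50, 0.74, 0.92)
  f_lo <- fit_gaussian_mixture(fr_lo, 4, init_means = pooled_means,
                               constrain = TRUE, seed = 1)
  f_hi <- fit_gaussian_mixture(fr_hi, 4, init_means = pooled_means,
                               constrain = TRUE, seed = 1)
  expect_gt(state_fractions(f_hi)$fraction[4],
            state_fractions(f_lo)$fraction[4])
  expect_gt(state_fractions(f_lo)$fraction[1],
            state_fractions(f_lo)$fraction[4])
})

test_that("titration assembly is deterministic and ordered by concentration", {
  m <- atrg3_model(0.9)
  fr <- noiseless_fret(m, 40, 60, seed = 51)
  samples <- dplyr::bind_rows(
    dplyr::mutate(fr, kcl_mM = 10,
                  molecule_id = paste0("a", molecule_id)),
    dplyr::mutate(fr, kcl_mM = 100,
                  molecule_id = paste0("b", molecule_id))
  )
  t1 <- titration_curve(samples, k = 3, n_boot = 25, seed = 5)
  t2 <- titration_curve(samples, k = 3, n_boot = 25, seed = 5)
  expect_equal(as.data.frame(t1), as.data.frame(t2))
  # identical data at both labels -> identical fractions
  expect_equal(t1$folded[1], t1$folded[2], tolerance = 1e-6)
  expect_equal(t1$kcl_mM, c(10, 100))
  expect_true(all(t1$folded_lo <= t1$folded & t1$folded <= t1$folded_hi))
})

test_that("comparing a decomposition with itself gives zero deltas", {
  fr <- noiseless_fret(atrg3_model(0.9), 40, 60, seed = 61)
  fit <- fit_gaussian_mixture(fr, 3, seed = 1)
  cmp <- compare_conditions(fit, fit, n_boot = 20, seed = 2)
  expect_equal(cmp$delta, rep(0, 3), tolerance = 1e-9)
  expect_true(all(cmp$delta_lo <= 0 & cmp$delta_hi >= 0))
  fit2 <- fit_gaussian_mixture(fr, 2, seed = 1)
  expect_error(compare_conditions(fit, fit2), "different numbers")
})

test_that("bootstrap CIs cover the generating fractions", {
  # scaled-down coverage check: 25 replicate experiments, 3-state chain
  m <- atrg3_model(self_prob = 0.9)
  truth <- stationary_distribution(m$transition_matrix)
  covered <- 0L
  n_rep <- 25L
  for (r in seq_len(n_rep)) {
    fr <- noiseless_fret(m, 40, 50, seed = 700 + r)
    fit <- fit_gaussian_mixture(fr, 3, init_means = m$emission_means,
                                constrain = TRUE, seed = r)
    boots <- with_seed(r, fretfold:::.boot_mat(
      60, 3, function() fretfold:::.boot_fractions(fit$data, fit)))
    lo <- apply(boots, 2, quantile, 0.025, na.rm = TRUE)
    hi <- apply(boots, 2, quantile, 0.975, na.rm = TRUE)
    if (truth[3] >= lo[3] && truth[3] <= hi[3]) covered <- covered + 1L
  }
  expect_gte(covered / n_rep, 0.85)
})
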