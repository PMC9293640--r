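# Population analysis: FRET histograms, multi-peak Gaussian decomposition,
# peak-area state fractions, potassium titrations and before/after condition
# comparisons.

#' Build a population FRET histogram
#'
#' Fixed-width binning on `[0, 1]` with half-open bins `[lo, hi)` and the
#' last bin closed.  Deterministic: the same samples always give the same
#' counts.
#'
#' @param samples A numeric vector of FRET efficiencies, or a data frame
#'   with an `efficiency` column (and optionally `molecule_id`, used for the
#'   molecule count).
#' @param bin_width Bin width in FRET units (default 0.02, resolving peaks
#'   separated by >= 0.08).
#' @param range Histogram range (default `c(0, 1)`).
#' @return A tibble of class `fret_histogram` with columns `bin_lo`,
#'   `bin_hi`, `count` and attributes `n_samples`, `n_molecules`.
#' @export
build_histogram <- function(samples, bin_width = 0.02, range = c(0, 1)) {
  n_mol <- NA_integer_
  if (is.data.frame(samples)) {
    if ("molecule_id" %in% names(samples)) {
      n_mol <- length(unique(samples$molecule_id))
    }
    samples <- samples$efficiency
  }
  samples <- samples[!is.na(samples)]
  if (!length(samples)) stop("no samples to histogram", call. = FALSE)
  stopifnot(bin_width > 0, length(range) == 2, range[2] > range[1])
  edges <- seq(range[1], range[2], by = bin_width)
  if (edges[length(edges)] < range[2]) edges <- c(edges, range[2])
  idx <- findInterval(samples, edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(edges) - 1L)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  out <- tibble::tibble(bin_lo = edges[-length(edges)],
                        bin_hi = edges[-1L],
                        count = counts)
  attr(out, "n_samples") <- length(samples)
  attr(out, "n_molecules") <- n_mol
  class(out) <- c("fret_histogram", class(out))
  out
}

# Single EM run for a 1-D Gaussian mixture with bounded widths and optional
# box constraints on the centers.
.gmm_em <- function(x, k, w, mu, sigma, sd_bounds, mu_lo = NULL, mu_hi = NULL,
                    tol = 1e-8, max_iter = 500) {
  n <- length(x)
  ll_path <- numeric(0)
  for (it in seq_len(max_iter)) {
    lg <- vapply(seq_len(k),
                 function(j) log(w[j]) + dnorm(x, mu[j], sigma[j], log = TRUE),
                 numeric(n))
    lg <- matrix(lg, n, k)
    m <- rowmax(lg)
    lse <- m + log(rowSums(exp(lg - m)))
    ll <- sum(lse)
    ll_path <- c(ll_path, ll)
    if (it > 1L && ll - ll_path[it - 1L] < tol) break
    r <- exp(lg - lse)
    Nk <- colSums(r)
    # components a condition does not populate keep their (constrained)
    # centers and widths at vanishing weight instead of aborting the fit:
    # a shared-K titration legitimately empties states at the extremes
    upd <- Nk > 1e-3
    if (!any(upd)) return(list(ok = FALSE, ll_path = ll_path))
    w <- pmax(Nk / n, 1e-10)
    w <- w / sum(w)
    m1 <- colSums(r * x)[upd] / Nk[upd]
    mu_new <- mu
    mu_new[upd] <- m1
    if (!is.null(mu_lo)) mu_new <- pmin(pmax(mu_new, mu_lo), mu_hi)
    m2 <- colSums(r * x^2)[upd] / Nk[upd]
    v <- m2 - 2 * mu_new[upd] * m1 + mu_new[upd]^2
    sigma[upd] <- pmin(pmax(sqrt(pmax(v, 0)), sd_bounds[1]), sd_bounds[2])
    mu <- mu_new
  }
  list(ok = TRUE, w = w, mu = mu, sigma = sigma,
       loglik = ll_path[length(ll_path)], ll_path = ll_path)
}

#' Decompose a FRET population into Gaussian components
#'
#' Maximum-likelihood K-component Gaussian mixture fitted to the raw pooled
#' samples by EM with seed-controlled restarts.  Component widths are
#' bounded (default `[0.01, 0.15]` FRET units) so no single broad component
#' swallows the histogram, and centers may optionally be pinned near
#' reference values (e.g. fitted HMM means) to stabilize 4-component fits.
#' Components are reported in ascending-center order; component weights are
#' the peak-area fractions.
#'
#' @param samples A numeric vector, or a data frame with `efficiency` (and
#'   ideally `molecule_id`, kept for molecule-level bootstraps).
#' @param k Number of components (>= 1); pooled samples must number at
#'   least `20 * k`.
#' @param init_means Optional starting centers (e.g. HMM means).
#' @param constrain If `TRUE`, centers are constrained to
#'   `init_means +/- constraint_tol`.
#' @param constraint_tol Half-width of the center constraint box.
#' @param sd_bounds Length-2 bounds on component s.d.
#' @param n_restarts EM restarts (jittered starts after the first).
#' @param seed Integer seed for restart jitter.
#' @param max_iter,tol EM controls.
#' @return An object of class `fret_mixture`: a list with `components`
#'   (tibble `state`, `center`, `width`, `area`), `loglik`, `bic`, `n`,
#'   `k`, and the samples used (`data`).
#' @export
#' @examples
#' x <- with_seed(1, rnorm(500, 0.32, 0.05))
#' fit_gaussian_mixture(x, k = 1)$components
fit_gaussian_mixture <- function(samples, k, init_means = NULL,
                                 constrain = FALSE, constraint_tol = 0.05,
                                 sd_bounds = c(0.01, 0.15), n_restarts = 5,
                                 seed = 1L, max_iter = 500, tol = 1e-8) {
  data <- if (is.data.frame(samples)) samples else
    tibble::tibble(molecule_id = "pooled", efficiency = as.numeric(samples))
  x <- data$efficiency
  x <- x[!is.na(x)]
  x <- pmin(pmax(x, 0), 1)
  stopifnot(k >= 1)
  if (length(x) < 20 * k) {
    stop("need at least 20 samples per component", call. = FALSE)
  }
  base_mu <- if (!is.null(init_means)) sort(init_means) else
    quantile(x, probs = (2 * seq_len(k) - 1) / (2 * k), names = FALSE)
  if (length(base_mu) != k) stop("init_means must have length k", call. = FALSE)
  mu_lo <- if (constrain && !is.null(init_means)) base_mu - constraint_tol
  mu_hi <- if (constrain && !is.null(init_means)) base_mu + constraint_tol
  best <- NULL
  for (r in seq_len(n_restarts)) {
    mu <- if (r == 1L) base_mu else with_seed(
      derive_seed(seed, r, 19L), sort(base_mu + rnorm(k, 0, 0.03)))
    sigma <- rep(max(min(sd(x), sd_bounds[2]), sd_bounds[1]), k)
    fit <- .gmm_em(x, k, w = rep(1 / k, k), mu = mu, sigma = sigma,
                   sd_bounds = sd_bounds, mu_lo = mu_lo, mu_hi = mu_hi,
                   tol = tol, max_iter = max_iter)
    if (!fit$ok) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) {
    stop("mixture fit failed: component collapse in every restart",
         call. = FALSE)
  }
  ord <- order(best$mu)
  comps <- tibble::tibble(
    state = seq_len(k),
    center = best$mu[ord],
    width = best$sigma[ord],
    area = best$w[ord]
  )
  structure(
    list(components = comps, k = k, n = length(x),
         loglik = best$loglik,
         bic = -2 * best$loglik + (3 * k - 1) * log(length(x)),
         n_iter = length(best$ll_path),
         data = data),
    class = "fret_mixture"
  )
}

#' @export
print.fret_mixture <- function(x, ...) {
  cat("<fret_mixture> ", x$k, " components on ", x$n, " samples\n", sep = "")
  print(as.data.frame(dplyr::mutate(x$components,
                                    dplyr::across(dplyr::where(is.numeric),
                                                  ~ round(.x, 4)))),
        row.names = FALSE)
  invisible(x)
}

#' @rdname fit_gaussian_mixture
#' @param x A `fret_mixture`.
#' @param ... Unused.
#' @export
tidy.fret_mixture <- function(x, ...) {
  dplyr::mutate(x$components, fraction = .data$area / sum(.data$area))
}

#' @rdname fit_gaussian_mixture
#' @export
glance.fret_mixture <- function(x, ...) {
  tibble::tibble(k = x$k, loglik = x$loglik, bic = x$bic, n = x$n,
                 n_iter = x$n_iter)
}

#' Peak-area state fractions of a decomposition
#'
#' Fractions are peak areas normalized to 1.  The lowest-center component is
#' labelled `unfolded` (ssRNA), the highest `folded` (the well-folded
#' quadruplex), and interior components `intermediate_i` (G-hairpin,
#' G-triplex).
#'
#' @param decomposition A [fit_gaussian_mixture()] result.
#' @return A tibble `state`, `center`, `fraction`, `label`; fractions sum
#'   to 1.
#' @export
state_fractions <- function(decomposition) {
  stopifnot(inherits(decomposition, "fret_mixture"))
  comps <- decomposition$components
  k <- nrow(comps)
  labels <- if (k == 1L) "single" else c(
    "unfolded",
    if (k > 2L) paste0("intermediate_", seq_len(k - 2L)),
    "folded"
  )
  tibble::tibble(
    state = comps$state,
    center = comps$center,
    fraction = comps$area / sum(comps$area),
    label = labels
  )
}

# Refit fractions on a molecule-level bootstrap resample, starting from the
# point-estimate parameters (single start: the resample is a small
# perturbation of the original sample).
.boot_fractions <- function(data, fit, sd_bounds = c(0.01, 0.15)) {
  mols <- unique(data$molecule_id)
  take <- sample(mols, length(mols), replace = TRUE)
  x <- unlist(lapply(take, function(m)
    data$efficiency[data$molecule_id == m]), use.names = FALSE)
  x <- pmin(pmax(x[!is.na(x)], 0), 1)
  em <- .gmm_em(x, fit$k, w = fit$components$area, mu = fit$components$center,
                sigma = fit$components$width, sd_bounds = sd_bounds,
                mu_lo = fit$components$center - 0.1,
                mu_hi = fit$components$center + 0.1,
                tol = 1e-6, max_iter = 200)
  if (!em$ok) return(rep(NA_real_, fit$k))
  em$w[order(em$mu)]
}

.boot_mat <- function(n_boot, k, f) {
  out <- matrix(NA_real_, n_boot, k)
  for (b in seq_len(n_boot)) out[b, ] <- f()
  out
}

#' Potassium titration of folded/unfolded fractions
#'
#' For each KCl concentration, fits a K-component mixture to that
#' condition's pooled histogram frames (centers constrained near a pooled
#' all-condition fit, so components correspond across conditions) and
#' reports the extreme-component fractions with molecule-level bootstrap
#' confidence intervals.
#'
#' @param samples A data frame with columns `kcl_mM`, `molecule_id`,
#'   `efficiency` (e.g. histogram frames from a [simulate_titration()] run
#'   processed by [process_traces()]).
#' @param k Number of mixture components shared across conditions.
#' @param n_boot Bootstrap replicates (default 200).
#' @param conf Confidence level.
#' @param seed Integer seed.
#' @param ... Passed to [fit_gaussian_mixture()].
#' @return A tibble of class `fret_titration`: per condition `kcl_mM`,
#'   `folded`, `folded_lo`, `folded_hi`, `unfolded`, `unfolded_lo`,
#'   `unfolded_hi`, `n_molecules`, `fit_ok`.
#' @export
titration_curve <- function(samples, k, n_boot = 200, conf = 0.95,
                            seed = 1L, ...) {
  stopifnot(all(c("kcl_mM", "molecule_id", "efficiency") %in% names(samples)))
  concs <- sort(unique(samples$kcl_mM))
  if (length(concs) < 2) stop("need at least 2 conditions", call. = FALSE)
  pooled <- fit_gaussian_mixture(samples, k, seed = seed, ...)
  alpha <- (1 - conf) / 2
  rows <- purrr::map(concs, function(conc) {
    sub <- samples[samples$kcl_mM == conc, ]
    fit <- tryCatch(
      fit_gaussian_mixture(sub, k, init_means = pooled$components$center,
                           constrain = TRUE, seed = seed, ...),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      return(tibble::tibble(kcl_mM = conc, folded = NA_real_,
                            folded_lo = NA_real_, folded_hi = NA_real_,
                            unfolded = NA_real_, unfolded_lo = NA_real_,
                            unfolded_hi = NA_real_,
                            n_molecules = length(unique(sub$molecule_id)),
                            fit_ok = FALSE))
    }
    fr <- state_fractions(fit)
    boots <- with_seed(derive_seed(seed, round(conc * 1000) %% 1e6, 23L), {
      .boot_mat(n_boot, k, function() .boot_fractions(fit$data, fit))
    })
    folded_b <- boots[, k]
    unfolded_b <- boots[, 1L]
    tibble::tibble(
      kcl_mM = conc,
      folded = fr$fraction[k],
      folded_lo = quantile(folded_b, alpha, na.rm = TRUE, names = FALSE),
      folded_hi = quantile(folded_b, 1 - alpha, na.rm = TRUE, names = FALSE),
      unfolded = fr$fraction[1L],
      unfolded_lo = quantile(unfolded_b, alpha, na.rm = TRUE, names = FALSE),
      unfolded_hi = quantile(unfolded_b, 1 - alpha, na.rm = TRUE, names = FALSE),
      n_molecules = length(unique(sub$molecule_id)),
      fit_ok = TRUE
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("fret_titration", class(out))
  out
}

#' Compare state fractions between two conditions
#'
#' Per-state fraction changes (after minus before) with molecule-level
#' bootstrap confidence intervals, e.g. a quadruplex population before and
#' after helicase + ATP injection.  Both decompositions must share the same
#' number of components; components are matched by their canonical
#' ascending-center order.  Unwinding shows as `delta < 0` for the folded
#' state and `delta > 0` for the unfolded state.
#'
#' @param before,after [fit_gaussian_mixture()] results with the same `k`.
#' @param n_boot Bootstrap replicates.
#' @param conf Confidence level.
#' @param seed Integer seed.
#' @return A tibble of class `condition_comparison`: `state`, `label`,
#'   `fraction_before`, `fraction_after`, `delta`, `delta_lo`, `delta_hi`.
#' @export
compare_conditions <- function(before, after, n_boot = 200, conf = 0.95,
                               seed = 1L) {
  stopifnot(inherits(before, "fret_mixture"), inherits(after, "fret_mixture"))
  if (before$k != after$k) {
    stop("decompositions have different numbers of components (",
         before$k, " vs ", after$k, ")", call. = FALSE)
  }
  k <- before$k
  fr_b <- state_fractions(before)
  fr_a <- state_fractions(after)
  boots_b <- with_seed(derive_seed(seed, 1L, 29L),
                       .boot_mat(n_boot, k,
                                 function() .boot_fractions(before$data, before)))
  boots_a <- with_seed(derive_seed(seed, 2L, 29L),
                       .boot_mat(n_boot, k,
                                 function() .boot_fractions(after$data, after)))
  deltas <- boots_a - boots_b
  alpha <- (1 - conf) / 2
  out <- tibble::tibble(
    state = fr_b$state,
    label = fr_b$label,
    fraction_before = fr_b$fraction,
    fraction_after = fr_a$fraction,
    delta = fr_a$fraction - fr_b$fraction,
    delta_lo = apply(deltas, 2, quantile, probs = alpha, na.rm = TRUE),
    delta_hi = apply(deltas, 2, quantile, probs = 1 - alpha, na.rm = TRUE)
  )
  class(out) <- c("condition_comparison", class(out))
  out
}
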