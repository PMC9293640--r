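# Gaussian-emission hidden Markov machinery for folding-state identification
# and trace idealization.  One shared model is fitted across all traces of a
# condition (traces enter the likelihood as independent sequences); the
# forward-backward recursions are vectorized across traces for speed.

#' Construct/validate a Gaussian-emission HMM
#'
#' @param means Per-state emission means (FRET units); stored in ascending
#'   (canonical) order.
#' @param sds Per-state emission s.d.; floored at `sd_floor`.
#' @param transition_matrix K x K row-stochastic matrix.
#' @param initial_distribution Length-K probability vector.
#' @param sd_floor Lower bound on emission s.d. (default 0.01 FRET units,
#'   preventing variance collapse onto single observations).
#' @return An object of class `fret_hmm`.
#' @export
hmm_model <- function(means, sds, transition_matrix, initial_distribution,
                      sd_floor = 0.01) {
  k <- length(means)
  sds <- pmax(rep_len(sds, k), sd_floor)
  .check_stochastic(transition_matrix, tol = 1e-10)
  stopifnot(nrow(transition_matrix) == k,
            length(initial_distribution) == k,
            all(initial_distribution >= 0),
            abs(sum(initial_distribution) - 1) < 1e-10)
  ord <- order(means)
  structure(
    list(k = k, means = as.numeric(means[ord]), sds = as.numeric(sds[ord]),
         transition_matrix = unname(transition_matrix[ord, ord, drop = FALSE]),
         initial_distribution = as.numeric(initial_distribution[ord])),
    class = "fret_hmm"
  )
}

#' @export
print.fret_hmm <- function(x, ...) {
  cat("<fret_hmm> ", x$k, " Gaussian-emission states\n", sep = "")
  print(data.frame(state = seq_len(x$k), mean = round(x$means, 4),
                   sd = round(x$sds, 4),
                   initial = round(x$initial_distribution, 4)),
        row.names = FALSE)
  if (!is.null(x$loglik)) {
    cat("log-likelihood ", format(x$loglik), " (", length(x$loglik_path),
        " EM iterations)\n", sep = "")
  }
  invisible(x)
}

# Coerce observations to a list of clamped numeric vectors.
.as_obs_list <- function(x, clamp = TRUE) {
  obs <- if (is.data.frame(x)) {
    stopifnot(all(c("molecule_id", "efficiency") %in% names(x)))
    x <- x[!is.na(x$efficiency), ]
    split(x$efficiency, factor(x$molecule_id, levels = unique(x$molecule_id)))
  } else if (is.list(x)) {
    x
  } else {
    list(as.numeric(x))
  }
  obs <- obs[lengths(obs) > 0]
  if (!length(obs)) stop("no observations", call. = FALSE)
  if (clamp) obs <- lapply(obs, function(v) pmin(pmax(v, 0), 1))
  obs
}

# Traces are sorted by length (descending) so that the set of traces still
# active at frame t is always a prefix of the batch.
.obs_matrix <- function(obs) {
  len <- lengths(obs)
  ord <- order(len, decreasing = TRUE)
  obs <- obs[ord]
  len <- len[ord]
  n <- length(obs)
  Y <- matrix(NA_real_, n, max(len))
  for (i in seq_len(n)) Y[i, seq_len(len[i])] <- obs[[i]]
  Y0 <- Y
  Y0[is.na(Y0)] <- 0
  list(Y = Y, Y0 = Y0, len = len,
       nact = colSums(outer(len, seq_len(max(len)), ">=")))
}

# Scaled forward(-backward) across a batch of traces.  Emission densities are
# computed for the whole batch up front and shifted per (trace, frame) by
# their maximum in log space before exponentiation, so arbitrarily unlikely
# observations cannot underflow; the shift is absorbed into the per-trace
# log-likelihood.  `om` comes from .obs_matrix (lengths non-increasing).
.fb_batch <- function(om, means, sds, P, pi0, smoothed = TRUE) {
  Y0 <- om$Y0; len <- om$len; nact <- om$nact
  n <- nrow(Y0); Tm <- ncol(Y0); k <- length(means)
  LB <- array(0, c(n, Tm, k))
  for (j in seq_len(k)) LB[, , j] <- dnorm(Y0, means[j], sds[j], log = TRUE)
  M <- LB[, , 1L]
  if (k > 1L) for (j in 2:k) M <- pmax(M, LB[, , j])
  BS <- exp(LB - as.vector(M))          # n x Tm x k, recycled over k
  A <- array(0, c(n, k, Tm))
  Cs <- matrix(1, n, Tm)
  ll <- numeric(n)
  for (t in seq_len(Tm)) {
    na <- nact[t]
    idx <- seq_len(na)
    eb <- matrix(BS[idx, t, ], na, k)
    a <- if (t == 1L) eb * rep(pi0, each = na)
         else (matrix(A[idx, , t - 1L], na, k) %*% P) * eb
    cc <- pmax(.rowSums(a, na, k), 1e-300)
    A[idx, , t] <- a / cc
    Cs[idx, t] <- cc
    ll[idx] <- ll[idx] + log(cc)
  }
  active <- outer(len, seq_len(Tm), ">=")
  ll <- ll + .rowSums(M * active, n, Tm)
  out <- list(loglik = ll, A = A, BS = BS, Cs = Cs)
  if (!smoothed) return(out)
  Bh <- array(0, c(n, k, Tm))
  for (i in seq_len(n)) Bh[i, , len[i]] <- 1
  tP <- t(P)
  if (Tm > 1L) {
    for (t in seq.int(Tm - 1L, 1L)) {
      na <- nact[t + 1L]
      if (na == 0L) next
      idx <- seq_len(na)
      w <- matrix(BS[idx, t + 1L, ], na, k) * matrix(Bh[idx, , t + 1L], na, k)
      Bh[idx, , t] <- (w %*% tP) / Cs[idx, t + 1L]
    }
  }
  out$Bh <- Bh
  out
}

#' Forward log-likelihood of observations under an HMM
#'
#' Exact log marginal likelihood by the scaled forward recursion; numerically
#' safe for traces of arbitrary length.  Multiple traces are treated as
#' independent and their log-likelihoods summed.
#'
#' @param model A [hmm_model()].
#' @param observations A numeric vector, a list of numeric vectors, or a
#'   data frame with `molecule_id`/`efficiency` columns.
#' @param clamp Clamp observations to `[0, 1]` first (the emission-domain
#'   contract of the pipeline).  Set `FALSE` for raw likelihoods.
#' @return Total log-likelihood (scalar).
#' @export
forward_log_likelihood <- function(model, observations, clamp = TRUE) {
  stopifnot(inherits(model, "fret_hmm"))
  obs <- .as_obs_list(observations, clamp = clamp)
  om <- .obs_matrix(obs)
  sum(.fb_batch(om, model$means, model$sds,
                model$transition_matrix, model$initial_distribution,
                smoothed = FALSE)$loglik)
}

.hmm_init <- function(pooled, k, sticky = 0.95, jitter_sd = 0, seed = NULL) {
  qs <- quantile(pooled, probs = (2 * seq_len(k) - 1) / (2 * k), names = FALSE)
  if (jitter_sd > 0) {
    qs <- with_seed(seed, qs + rnorm(k, 0, jitter_sd))
  }
  qs <- sort(pmin(pmax(qs, 0), 1))
  # break exact ties so states stay distinct
  for (j in seq_len(k)[-1]) if (qs[j] <= qs[j - 1]) qs[j] <- qs[j - 1] + 1e-3
  P0 <- if (k == 1L) matrix(1, 1, 1) else {
    diag(sticky, k) + (1 - sticky) / (k - 1) * (1 - diag(k))
  }
  list(means = qs,
       sds = rep(max(sd(pooled) / k, 0.02), k),
       P = P0,
       pi0 = rep(1 / k, k))
}

.baum_welch_once <- function(om, k, init, tol, max_iter, sd_floor) {
  Y0 <- om$Y0; len <- om$len; nact <- om$nact
  n <- nrow(Y0); Tm <- ncol(Y0)
  n_obs <- sum(len)
  means <- init$means; sds <- pmax(init$sds, sd_floor)
  P <- init$P; pi0 <- init$pi0
  ll_path <- numeric(0)
  collapsed <- FALSE
  for (it in seq_len(max_iter)) {
    fb <- .fb_batch(om, means, sds, P, pi0, smoothed = TRUE)
    ll <- sum(fb$loglik)
    ll_path <- c(ll_path, ll)
    if (it > 1L && ll - ll_path[it - 1L] < tol) break
    G <- fb$A * fb$Bh                     # n x k x Tm; zero beyond len
    S0 <- numeric(k); S1 <- numeric(k); S2 <- numeric(k)
    for (j in seq_len(k)) {
      Gj <- G[, j, ]
      S0[j] <- sum(Gj)
      S1[j] <- sum(Gj * Y0)
      S2[j] <- sum(Gj * Y0 * Y0)
    }
    if (any(S0 < 1e-6)) { collapsed <- TRUE; break }
    Xi <- matrix(0, k, k)
    if (Tm > 1L) {
      for (t in seq_len(Tm - 1L)) {
        na <- nact[t + 1L]
        if (na == 0L) next
        idx <- seq_len(na)
        w <- matrix(fb$BS[idx, t + 1L, ], na, k) *
          matrix(fb$Bh[idx, , t + 1L], na, k) / fb$Cs[idx, t + 1L]
        At <- matrix(fb$A[idx, , t], na, k)
        Xi <- Xi + P * crossprod(At, w)
      }
    }
    pi0 <- colMeans(matrix(G[, , 1L], n, k))
    pi0 <- pmax(pi0, 0); pi0 <- pi0 / sum(pi0)
    rs <- rowSums(Xi)
    Pnew <- P
    ok <- rs > 0
    Pnew[ok, ] <- Xi[ok, , drop = FALSE] / rs[ok]
    P <- Pnew / rowSums(Pnew)
    means <- S1 / S0
    v <- S2 / S0 - means^2
    sds <- pmax(sqrt(pmax(v, 0)), sd_floor)
  }
  final_ll <- sum(.fb_batch(om, means, sds, P, pi0,
                            smoothed = FALSE)$loglik)
  list(means = means, sds = sds, P = P, pi0 = pi0,
       loglik = final_ll, loglik_path = ll_path,
       collapsed = collapsed, n_obs = n_obs,
       converged = !collapsed &&
         (length(ll_path) < max_iter ||
            diff(tail_two(ll_path)) < tol))
}

tail_two <- function(x) if (length(x) >= 2) x[c(length(x) - 1L, length(x))] else c(0, 0)

#' Fit a shared Gaussian-emission HMM by Baum-Welch EM
#'
#' Maximum-likelihood EM over all traces jointly (one shared model,
#' independent forward-backward per trace).  Initial means sit at evenly
#' spaced quantiles of the pooled observations with seed-controlled jitter
#' across restarts; transitions start sticky (self-probability `sticky`).
#' The fitted model is returned in canonical ascending-mean order, and the
#' per-iteration log-likelihood sequence is non-decreasing (an EM
#' guarantee, asserted in the test suite).
#'
#' @param observations As in [forward_log_likelihood()].
#' @param k Number of states (>= 1).
#' @param n_restarts Number of EM restarts (restart 1 uses the unjittered
#'   quantile initialization).
#' @param tol Stop when the log-likelihood improves by less than this.
#' @param max_iter Maximum EM iterations per restart.
#' @param sticky Initial self-transition probability.
#' @param sd_floor Emission s.d. floor (default 0.01).
#' @param seed Seed controlling restart jitter.
#' @return A [hmm_model()] with extra fields `loglik`, `loglik_path`,
#'   `n_obs`, `bic`, `converged`.
#' @export
baum_welch_fit <- function(observations, k, n_restarts = 5, tol = 1e-6,
                           max_iter = 200, sticky = 0.95, sd_floor = 0.01,
                           seed = 1L) {
  stopifnot(k >= 1)
  obs <- .as_obs_list(observations)
  pooled <- unlist(obs, use.names = FALSE)
  if (length(pooled) < 10 * k) {
    stop("need at least 10 observations per state", call. = FALSE)
  }
  om <- .obs_matrix(obs)
  best <- NULL
  attempts <- 0L
  for (r in seq_len(n_restarts)) {
    init <- .hmm_init(pooled, k, sticky = sticky,
                      jitter_sd = if (r == 1L) 0 else 0.03,
                      seed = derive_seed(seed, r, 11L))
    fit <- .baum_welch_once(om, k, init, tol, max_iter, sd_floor)
    attempts <- attempts + 1L
    retry <- 0L
    while (fit$collapsed && retry < 3L) {
      retry <- retry + 1L
      init <- .hmm_init(pooled, k, sticky = sticky, jitter_sd = 0.05,
                        seed = derive_seed(seed, 100L * r + retry, 13L))
      fit <- .baum_welch_once(om, k, init, tol, max_iter, sd_floor)
    }
    if (fit$collapsed) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) {
    stop("Baum-Welch failed: a state's responsibility mass collapsed in ",
         attempts, " restart(s)", call. = FALSE)
  }
  model <- hmm_model(best$means, best$sds, best$P, best$pi0,
                     sd_floor = sd_floor)
  model$loglik <- best$loglik
  model$loglik_path <- best$loglik_path
  model$n_obs <- best$n_obs
  model$bic <- -2 * best$loglik + (k^2 + 2 * k - 1) * log(best$n_obs)
  model$converged <- best$converged
  model
}

#' Most probable state path (Viterbi)
#'
#' Maximum-probability decoding in log space; ties break toward the lower
#' state index.
#'
#' @param model A [hmm_model()].
#' @param observations A single numeric observation vector.
#' @param clamp Clamp to `[0, 1]` first.
#' @return Integer vector of 1-based state indices.
#' @export
viterbi_decode <- function(model, observations, clamp = TRUE) {
  stopifnot(inherits(model, "fret_hmm"))
  y <- as.numeric(observations)
  if (!length(y)) stop("observations must be non-empty", call. = FALSE)
  if (clamp) y <- pmin(pmax(y, 0), 1)
  k <- model$k
  n <- length(y)
  logP <- log(model$transition_matrix)
  lb <- vapply(seq_len(k),
               function(j) dnorm(y, model$means[j], model$sds[j], log = TRUE),
               numeric(n))
  lb <- matrix(lb, n, k)
  delta <- log(model$initial_distribution) + lb[1L, ]
  psi <- matrix(0L, n, k)
  if (n > 1L) {
    for (t in 2:n) {
      m <- delta + logP  # m[i, j] = delta[i] + logP[i, j]
      arg <- integer(k); val <- numeric(k)
      for (j in seq_len(k)) {
        arg[j] <- which.max(m[, j])
        val[j] <- m[arg[j], j]
      }
      psi[t, ] <- arg
      delta <- val + lb[t, ]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  if (n > 1L) for (t in seq.int(n - 1L, 1L)) path[t] <- psi[t + 1L, path[t + 1L]]
  path
}

#' Choose the number of folding states by BIC
#'
#' Fits [baum_welch_fit()] for each candidate K and computes
#' `BIC = -2 logL + p log(n)` with `p = K^2 + 2K - 1` free parameters and
#' `n` the pooled frame count; the K minimizing BIC is selected.  State
#' counts asserted by eye from histogram peaks are replaced here by an
#' explicit information criterion.
#'
#' @param observations As in [baum_welch_fit()].
#' @param k_range Candidate state counts (default 1:5).
#' @param tol EM convergence tolerance.  The default is looser than
#'   [baum_welch_fit()]'s: BIC differences between state counts dwarf the
#'   flat tail of the likelihood climb, so late EM iterations cannot change
#'   the selection.
#' @param n_restarts,seed,... Passed to [baum_welch_fit()].
#' @return A list of class `state_count_selection`: `best_k`, `best_fit`,
#'   and `summary` (tibble of k, loglik, n_params, bic, converged).
#' @export
select_state_count <- function(observations, k_range = 1:5, n_restarts = 5,
                               tol = 1e-4, seed = 1L, ...) {
  stopifnot(length(k_range) >= 1)
  fits <- list()
  rows <- list()
  for (k in k_range) {
    fit <- tryCatch(
      baum_welch_fit(observations, k, n_restarts = n_restarts, tol = tol,
                     seed = derive_seed(seed, k, 17L), ...),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      rows[[as.character(k)]] <- tibble::tibble(
        k = k, loglik = NA_real_, n_params = k^2 + 2 * k - 1,
        bic = NA_real_, converged = FALSE, error = conditionMessage(fit))
      next
    }
    fits[[as.character(k)]] <- fit
    rows[[as.character(k)]] <- tibble::tibble(
      k = k, loglik = fit$loglik, n_params = k^2 + 2 * k - 1,
      bic = fit$bic, converged = fit$converged, error = NA_character_)
  }
  summary <- dplyr::bind_rows(rows)
  if (all(is.na(summary$bic))) {
    stop("all candidate state counts failed to fit", call. = FALSE)
  }
  best_k <- summary$k[which.min(summary$bic)]
  structure(list(best_k = best_k, best_fit = fits[[as.character(best_k)]],
                 summary = summary),
            class = "state_count_selection")
}

#' @export
print.state_count_selection <- function(x, ...) {
  cat("<state_count_selection> best K =", x$best_k, "\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' Idealize FRET traces into state segments
#'
#' Viterbi-decodes each molecule and compresses the path to contiguous
#' constant-state segments (the piecewise-constant idealization drawn over
#' raw traces in transition analysis).  Dwell times are
#' `(end_frame - start_frame) * frame_interval_s`.
#'
#' @param model A [hmm_model()].
#' @param fret Accepted FRET traces (`molecule_id`, `frame`, `efficiency`).
#' @return A tibble of class `idealized_traces`: `molecule_id`,
#'   `start_frame`, `end_frame` (half-open, in the trace's own frame
#'   numbering), `state`, `state_mean`.
#' @export
idealize <- function(model, fret) {
  stopifnot(inherits(model, "fret_hmm"))
  per_mol <- function(df) {
    df <- df[order(df$frame), ]
    path <- viterbi_decode(model, df$efficiency)
    r <- rle(path)
    ends <- cumsum(r$lengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    tibble::tibble(
      molecule_id = df$molecule_id[1L],
      start_frame = df$frame[starts],
      end_frame = df$frame[ends] + 1L,
      state = r$values,
      state_mean = model$means[r$values]
    )
  }
  out <- fret |>
    dplyr::group_by(.data$molecule_id) |>
    dplyr::group_split() |>
    purrr::map(per_mol) |>
    dplyr::bind_rows()
  class(out) <- c("idealized_traces", class(out))
  attr(out, "state_means") <- model$means
  out
}

#' @rdname baum_welch_fit
#' @param x A fitted `fret_hmm`.
#' @param ... Unused.
#' @export
tidy.fret_hmm <- function(x, ...) {
  tibble::tibble(
    state = seq_len(x$k),
    mean = x$means,
    sd = x$sds,
    initial_prob = x$initial_distribution,
    self_prob = diag(x$transition_matrix)
  )
}

#' @rdname baum_welch_fit
#' @export
glance.fret_hmm <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    loglik = x$loglik %||% NA_real_,
    bic = x$bic %||% NA_real_,
    n_obs = x$n_obs %||% NA_integer_,
    n_iter = length(x$loglik_path %||% integer(0)),
    converged = x$converged %||% NA
  )
}

#' Serialize / restore an HMM as JSON
#'
#' @param model A [hmm_model()].
#' @param path Output file.
#' @export
write_hmm_json <- function(model, path) {
  stopifnot(inherits(model, "fret_hmm"))
  x <- list(k = model$k, means = model$means, sds = model$sds,
            transition_matrix = model$transition_matrix,
            initial_distribution = model$initial_distribution,
            loglik = model$loglik %||% NULL,
            bic = model$bic %||% NULL)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_hmm_json
#' @export
read_hmm_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- hmm_model(x$means, x$sds, as.matrix(x$transition_matrix),
                 x$initial_distribution)
  m$loglik <- x$loglik
  m$bic <- x$bic
  m
}
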