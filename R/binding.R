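# Microscale thermophoresis (MST) analysis: normalized fluorescence from
# thermophoresis time windows, Hill dose-response fitting of Fnorm vs ligand
# concentration, and EC50-based affinity ranking across substrates.

#' Simulate an MST capillary trace
#'
#' Simple thermophoresis kinetics: constant fluorescence before the IR laser
#' switches on, exponential depletion to a plateau while it is on, and
#' exponential back-diffusion after it switches off.
#'
#' @param f0 Initial (cold) fluorescence level, counts.
#' @param plateau Hot-region fluorescence as a fraction of `f0` (e.g. 0.85
#'   for 15% depletion).
#' @param tau_s Depletion/recovery time constant in seconds.
#' @param t_before_s Seconds of cold baseline before laser-on (default 5).
#' @param laser_s Laser-on duration (default 30 s).
#' @param t_after_s Seconds recorded after laser-off (default 5).
#' @param dt_s Sampling interval.
#' @param noise_sd Additive Gaussian noise s.d., counts.
#' @param seed Integer seed (used when `noise_sd > 0`).
#' @return A tibble `time_s`, `fluorescence`, with attributes `laser_on_s`
#'   and `laser_off_s` (absolute switch times).
#' @export
simulate_mst_trace <- function(f0 = 1000, plateau = 0.85, tau_s = 2,
                               t_before_s = 5, laser_s = 30, t_after_s = 5,
                               dt_s = 0.05, noise_sd = 0, seed = 1L) {
  stopifnot(f0 > 0, plateau >= 0, tau_s > 0, dt_s > 0)
  t_on <- t_before_s
  t_off <- t_before_s + laser_s
  tt <- seq(0, t_before_s + laser_s + t_after_s, by = dt_s)
  f <- rep(f0, length(tt))
  on <- tt >= t_on & tt < t_off
  f[on] <- f0 * (plateau + (1 - plateau) * exp(-(tt[on] - t_on) / tau_s))
  after <- tt >= t_off
  f_off <- f0 * (plateau + (1 - plateau) * exp(-laser_s / tau_s))
  f[after] <- f0 - (f0 - f_off) * exp(-(tt[after] - t_off) / tau_s)
  if (noise_sd > 0) {
    f <- with_seed(seed, f + rnorm(length(f), 0, noise_sd))
  }
  out <- tibble::tibble(time_s = tt, fluorescence = pmax(f, 0))
  attr(out, "laser_on_s") <- t_on
  attr(out, "laser_off_s") <- t_off
  out
}

#' Normalized fluorescence (Fnorm) of an MST trace
#'
#' `Fnorm = 1000 * mean(F in hot window) / mean(F in cold window)`, in
#' per-mil, following the instrument convention.  By default the cold window
#' is the final second before laser-on and the hot window the final second
#' of the laser-on phase.
#'
#' @param data A tibble `time_s`, `fluorescence` (e.g. from
#'   [simulate_mst_trace()]).
#' @param laser_on_s,laser_off_s Laser switch times in seconds; taken from
#'   the trace attributes when omitted.
#' @param cold_window_s,hot_window_s Window lengths in seconds.
#' @return Fnorm in per-mil (scalar).
#' @export
#' @examples
#' tr <- simulate_mst_trace(plateau = 0.9, tau_s = 0.5)
#' compute_fnorm(tr)  # ~900
compute_fnorm <- function(data, laser_on_s = NULL, laser_off_s = NULL,
                          cold_window_s = 1, hot_window_s = 1) {
  stopifnot(all(c("time_s", "fluorescence") %in% names(data)))
  if (is.unsorted(data$time_s, strictly = TRUE)) {
    stop("time_s must be strictly ascending", call. = FALSE)
  }
  laser_on_s <- laser_on_s %||% attr(data, "laser_on_s")
  laser_off_s <- laser_off_s %||% attr(data, "laser_off_s")
  if (is.null(laser_on_s) || is.null(laser_off_s)) {
    stop("laser window times are required", call. = FALSE)
  }
  tt <- data$time_s
  span <- range(tt)
  if (laser_on_s - cold_window_s < span[1] || laser_off_s > span[2] + 1e-9) {
    stop("windows fall outside the recorded trace", call. = FALSE)
  }
  cold <- tt >= laser_on_s - cold_window_s & tt < laser_on_s
  hot <- tt >= laser_off_s - hot_window_s & tt < laser_off_s
  if (!any(cold) || !any(hot)) {
    stop("empty cold or hot window", call. = FALSE)
  }
  mc <- mean(data$fluorescence[cold])
  if (abs(mc) < .Machine$double.eps) {
    stop("cold-window mean fluorescence is zero", call. = FALSE)
  }
  1000 * mean(data$fluorescence[hot]) / mc
}

#' Simulate a binding (dose-response) curve
#'
#' Hill-model Fnorm values over a concentration series, optionally with
#' Gaussian noise; the generating ground truth for fit-recovery tests.
#'
#' @param concentrations Ligand concentrations (molar), strictly positive.
#' @param ec50 Half-maximal concentration (molar).
#' @param hill Hill coefficient.
#' @param baseline Fnorm at zero binding (per-mil).
#' @param amplitude Fnorm change at saturation (per-mil).
#' @param noise_sd Additive noise s.d. on Fnorm.
#' @param seed Integer seed.
#' @return A tibble `concentration`, `fnorm`.
#' @export
simulate_binding_curve <- function(concentrations, ec50, hill = 1,
                                   baseline = 850, amplitude = 60,
                                   noise_sd = 0, seed = 1L) {
  stopifnot(all(concentrations > 0), ec50 > 0)
  f <- baseline + amplitude * concentrations^hill /
    (ec50^hill + concentrations^hill)
  if (noise_sd > 0) {
    f <- with_seed(seed, f + rnorm(length(f), 0, noise_sd))
  }
  tibble::tibble(concentration = as.numeric(concentrations), fnorm = f)
}

#' Fit a Hill dose-response model to a binding curve
#'
#' Least-squares fit of
#' `Fnorm(c) = baseline + amplitude * c^h / (EC50^h + c^h)` with
#' multi-start on EC50 across the tested concentration range
#' (log-spaced starts) and residual-bootstrap confidence intervals.
#' Smaller EC50 means tighter binding.
#'
#' @param data A tibble `concentration`, `fnorm` with >= 5 concentrations
#'   spanning at least two decades.
#' @param fix_hill Fix the Hill coefficient at this value (e.g. 1 for
#'   mass-action-like binding); `NULL` (default) leaves it free.
#' @param n_starts Number of EC50 starting values.
#' @param n_boot Residual-bootstrap replicates (default 200).
#' @param conf Confidence level.
#' @param seed Integer seed.
#' @return An object of class `mst_fit`: list with `estimates` (tibble
#'   `term`, `estimate`, `conf_low`, `conf_high`), `ec50`, `hill`, `sigma`,
#'   `flags` (character: `"no_binding_signal"`, `"ec50_outside_range"` when
#'   applicable), `data`, `fitted`.
#' @export
fit_dose_response <- function(data, fix_hill = NULL, n_starts = 8,
                              n_boot = 200, conf = 0.95, seed = 1L) {
  stopifnot(all(c("concentration", "fnorm") %in% names(data)))
  conc <- data$concentration
  y <- data$fnorm
  if (length(conc) < 5) stop("need at least 5 concentrations", call. = FALSE)
  if (any(conc <= 0)) stop("concentrations must be > 0", call. = FALSE)
  if (diff(log10(range(conc))) < 2) {
    stop("concentrations must span at least two decades", call. = FALSE)
  }
  flags <- character(0)
  if (sd(y) < 1e-10) {
    warning("no binding signal: flat Fnorm curve", call. = FALSE)
    return(structure(list(estimates = NULL, ec50 = NA_real_, hill = NA_real_,
                          sigma = 0, flags = "no_binding_signal",
                          data = data, fitted = NULL),
                     class = "mst_fit"))
  }
  df <- data.frame(conc = conc, y = y)
  starts <- 10^seq(log10(min(conc)), log10(max(conc)), length.out = n_starts)
  amp0 <- y[which.max(conc)] - y[which.min(conc)]
  base0 <- y[which.min(conc)]
  fit_once <- function(d, ec50_start, hill_start = 1) {
    tryCatch({
      if (is.null(fix_hill)) {
        minpack.lm::nlsLM(
          y ~ baseline + amplitude * conc^h / (ec50^h + conc^h), data = d,
          start = list(baseline = base0, amplitude = amp0,
                       ec50 = ec50_start, h = hill_start),
          lower = c(-Inf, -Inf, min(conc) / 1e4, 0.2),
          upper = c(Inf, Inf, max(conc) * 1e4, 6),
          control = nls.control(maxiter = 200, warnOnly = TRUE))
      } else {
        h <- fix_hill
        minpack.lm::nlsLM(
          y ~ baseline + amplitude * conc^h / (ec50^h + conc^h), data = d,
          start = list(baseline = base0, amplitude = amp0, ec50 = ec50_start),
          lower = c(-Inf, -Inf, min(conc) / 1e4),
          upper = c(Inf, Inf, max(conc) * 1e4),
          control = nls.control(maxiter = 200, warnOnly = TRUE))
      }
    }, error = function(e) NULL)
  }
  fits <- purrr::compact(purrr::map(starts, ~ fit_once(df, .x)))
  if (!length(fits)) {
    stop("dose-response fit failed to converge from any start", call. = FALSE)
  }
  rss <- vapply(fits, function(f) sum(resid(f)^2), numeric(1))
  best <- fits[[which.min(rss)]]
  cf <- coef(best)
  ec50_hat <- unname(cf["ec50"])
  hill_hat <- if (is.null(fix_hill)) unname(cf["h"]) else fix_hill
  sigma <- sqrt(min(rss) / max(length(y) - length(cf), 1))
  if (abs(unname(cf["amplitude"])) < 2 * sigma) {
    flags <- c(flags, "no_binding_signal")
    warning("fitted amplitude indistinguishable from noise", call. = FALSE)
  }
  if (ec50_hat < min(conc) || ec50_hat > max(conc)) {
    flags <- c(flags, "ec50_outside_range")
    warning("EC50 estimate lies outside the tested concentration range",
            call. = FALSE)
  }
  yhat <- fitted(best)
  res <- resid(best)
  boot <- if (n_boot > 0) {
    with_seed(derive_seed(seed, 1L, 31L), {
      vapply(seq_len(n_boot), function(b) {
        yb <- yhat + sample(res, length(res), replace = TRUE)
        fb <- fit_once(data.frame(conc = conc, y = yb), ec50_hat,
                       hill_start = hill_hat)
        if (is.null(fb)) NA_real_ else unname(coef(fb)["ec50"])
      }, numeric(1))
    })
  } else numeric(0)
  alpha <- (1 - conf) / 2
  ci <- if (length(boot) && any(!is.na(boot))) {
    q <- quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
    c(min(q[1], ec50_hat), max(q[2], ec50_hat))  # CI always covers the estimate
  } else c(NA_real_, NA_real_)
  terms <- names(cf)
  estimates <- tibble::tibble(
    term = terms,
    estimate = unname(cf),
    conf_low = ifelse(terms == "ec50", ci[1], NA_real_),
    conf_high = ifelse(terms == "ec50", ci[2], NA_real_)
  )
  structure(
    list(estimates = estimates, ec50 = ec50_hat, hill = hill_hat,
         ec50_ci = ci, sigma = sigma, flags = flags,
         data = data, fitted = yhat, boot_ec50 = boot),
    class = "mst_fit"
  )
}

#' @export
print.mst_fit <- function(x, ...) {
  cat("<mst_fit>\n")
  if (is.null(x$estimates)) {
    cat("  no binding signal\n")
    return(invisible(x))
  }
  cat("  EC50 =", format(x$ec50, digits = 4),
      " [", format(x$ec50_ci[1], digits = 4), ",",
      format(x$ec50_ci[2], digits = 4), "]\n")
  cat("  Hill =", format(x$hill, digits = 3), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname fit_dose_response
#' @param x An `mst_fit`.
#' @param ... Unused.
#' @export
tidy.mst_fit <- function(x, ...) {
  x$estimates %||% tibble::tibble(term = character(0), estimate = numeric(0),
                                  conf_low = numeric(0),
                                  conf_high = numeric(0))
}

#' @rdname fit_dose_response
#' @export
glance.mst_fit <- function(x, ...) {
  tibble::tibble(ec50 = x$ec50, hill = x$hill, sigma = x$sigma,
                 n = nrow(x$data),
                 flags = paste(x$flags, collapse = ";"))
}

#' Rank substrates by binding affinity
#'
#' Ascending EC50 order (descending affinity).  A substrate pair is flagged
#' indistinguishable when their bootstrap confidence intervals overlap.
#'
#' @param fits A named list of [fit_dose_response()] results (names =
#'   substrate labels).
#' @return A tibble `substrate`, `ec50`, `ec50_lo`, `ec50_hi`, `rank`,
#'   `distinct_from_prev` (is this substrate's CI disjoint from the
#'   previous, tighter-binding one?).
#' @export
rank_substrates <- function(fits) {
  stopifnot(length(fits) >= 2, !is.null(names(fits)))
  tab <- purrr::imap(fits, function(f, nm) {
    tibble::tibble(substrate = nm, ec50 = f$ec50,
                   ec50_lo = if (!is.null(f$ec50_ci)) f$ec50_ci[1] else NA_real_,
                   ec50_hi = if (!is.null(f$ec50_ci)) f$ec50_ci[2] else NA_real_)
  }) |> dplyr::bind_rows()
  tab <- dplyr::arrange(tab, .data$ec50)
  tab$rank <- seq_len(nrow(tab))
  tab$distinct_from_prev <- c(
    NA,
    vapply(seq_len(nrow(tab))[-1], function(i) {
      isTRUE(tab$ec50_lo[i] > tab$ec50_hi[i - 1])
    }, logical(1))
  )
  tab
}
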