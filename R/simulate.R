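# Synthetic smFRET trace generation: Markov state paths, donor/acceptor
# intensity emission with photobleaching, and whole-dataset assembly with
# ground truth.  Stands in for raw microscope recordings, which are not
# publicly available for these experiments.

#' Photophysics configuration for intensity emission
#'
#' Camera/dye-level settings used by [emit_intensities()].  Intensities are
#' in arbitrary detector units; the total (donor + acceptor) photon budget
#' per frame is roughly constant while FRET partitions it between channels.
#'
#' @param total_intensity Mean summed photon count per frame (> 0).
#' @param intensity_sd Additive Gaussian noise s.d. per channel.
#' @param frame_interval_s Seconds per frame (default 0.1, i.e. 100 ms
#'   exposure).
#' @param donor_bleach_prob,acceptor_bleach_prob Per-frame single-step
#'   irreversible bleaching probabilities, in `[0, 1]`.
#' @param background Per-channel baseline offset.
#' @param blink_prob Per-frame probability of the acceptor entering a
#'   reversible dark state.  0 by default: experiments use an oxygen
#'   scavenger plus Trolox, which suppresses blinking.
#' @param blink_recovery_prob Per-frame probability of leaving the dark
#'   state, when blinking is enabled.
#' @return An object of class `photophysics`.
#' @export
photophysics <- function(total_intensity = 1000, intensity_sd = 20,
                         frame_interval_s = 0.1,
                         donor_bleach_prob = 5e-4,
                         acceptor_bleach_prob = 5e-4,
                         background = 10,
                         blink_prob = 0, blink_recovery_prob = 0.5) {
  probs <- c(donor_bleach_prob, acceptor_bleach_prob, blink_prob,
             blink_recovery_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("bleach/blink probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (total_intensity <= 0) stop("total_intensity must be > 0", call. = FALSE)
  if (frame_interval_s <= 0) stop("frame_interval_s must be > 0", call. = FALSE)
  if (intensity_sd < 0) stop("intensity_sd must be >= 0", call. = FALSE)
  structure(
    list(total_intensity = total_intensity, intensity_sd = intensity_sd,
         frame_interval_s = frame_interval_s,
         donor_bleach_prob = donor_bleach_prob,
         acceptor_bleach_prob = acceptor_bleach_prob,
         background = background,
         blink_prob = blink_prob,
         blink_recovery_prob = blink_recovery_prob),
    class = "photophysics"
  )
}

#' Simulate a Markov state path
#'
#' Draws a state sequence from a [folding_model()]'s Markov chain: the first
#' state from the initial distribution, each later state from the transition
#' row of its predecessor.
#'
#' @param model A [folding_model()].
#' @param n_frames Number of frames (>= 1).
#' @param seed Integer RNG seed; the caller's RNG state is untouched.
#' @return Integer vector of 1-based state indices, length `n_frames`.
#' @export
simulate_state_path <- function(model, n_frames, seed = 1L) {
  stopifnot(inherits(model, "folding_model"), n_frames >= 1)
  P <- model$transition_matrix
  k <- nrow(P)
  cum <- t(apply(P, 1, cumsum))
  cum0 <- cumsum(model$initial_distribution)
  with_seed(seed, {
    u <- runif(n_frames)
    s <- integer(n_frames)
    s[1L] <- findInterval(u[1L], cum0) + 1L
    if (n_frames > 1L) {
      for (t in 2:n_frames) {
        s[t] <- findInterval(u[t], cum[s[t - 1L], ]) + 1L
      }
    }
    pmin(s, k)
  })
}

#' Emit donor/acceptor intensities along a state path
#'
#' Per frame, a latent FRET value is drawn as
#' `Normal(mean(state), sd(state))` clamped to `[0, 1]`, then partitioned
#' into acceptor `= total * E + noise + background` and donor
#' `= total * (1 - E) + noise + background`.  Photobleaching is single-step
#' and irreversible: after an acceptor bleach the acceptor falls to
#' background and the donor rises to the full photon budget; after a donor
#' bleach both channels fall to background.
#'
#' @param path Integer state path from [simulate_state_path()].
#' @param model The generating [folding_model()].
#' @param phys A [photophysics()] configuration.
#' @param seed Integer RNG seed.
#' @return A tibble with columns `frame` (1-based), `donor`, `acceptor`, and
#'   attributes `bleach` (list with `donor`/`acceptor` bleach frames, `NA` if
#'   none within the trace) and `frame_interval_s`.
#' @export
emit_intensities <- function(path, model, phys = photophysics(), seed = 1L) {
  stopifnot(inherits(model, "folding_model"), length(path) >= 1)
  if (any(path < 1 | path > length(model$emission_means))) {
    stop("path contains state indices outside the model", call. = FALSE)
  }
  n <- length(path)
  with_seed(seed, {
    estar <- rnorm(n, model$emission_means[path], model$emission_sds[path])
    estar <- pmin(pmax(estar, 0), 1)
    d_bleach <- if (phys$donor_bleach_prob > 0) {
      rgeom(1L, phys$donor_bleach_prob) + 1L
    } else Inf
    a_bleach <- if (phys$acceptor_bleach_prob > 0) {
      rgeom(1L, phys$acceptor_bleach_prob) + 1L
    } else Inf
    dark <- rep(FALSE, n)
    if (phys$blink_prob > 0 && n > 1L) {
      state <- FALSE
      for (t in seq_len(n)) {
        state <- if (state) runif(1) >= phys$blink_recovery_prob
                 else runif(1) < phys$blink_prob
        dark[t] <- state
      }
    }
    frames <- seq_len(n)
    acc_sig <- phys$total_intensity * estar
    don_sig <- phys$total_intensity * (1 - estar)
    acc_off <- frames >= a_bleach | dark
    acc_sig[acc_off] <- 0
    don_sig[acc_off] <- phys$total_intensity
    don_off <- frames >= d_bleach
    acc_sig[don_off] <- 0
    don_sig[don_off] <- 0
    donor <- don_sig + rnorm(n, 0, phys$intensity_sd) + phys$background
    acceptor <- acc_sig + rnorm(n, 0, phys$intensity_sd) + phys$background
    out <- tibble::tibble(frame = frames, donor = donor, acceptor = acceptor)
    attr(out, "bleach") <- list(
      donor = if (is.finite(d_bleach) && d_bleach <= n) as.integer(d_bleach) else NA_integer_,
      acceptor = if (is.finite(a_bleach) && a_bleach <= n) as.integer(a_bleach) else NA_integer_
    )
    attr(out, "frame_interval_s") <- phys$frame_interval_s
    out
  })
}

#' Simulate a full smFRET dataset with ground truth
#'
#' Generates `n_molecules` independent intensity traces from a
#' [folding_model()].  Each molecule's path and emission seeds are derived
#' deterministically from the master seed and the molecule index, so trace
#' `i` is identical regardless of `n_molecules` and the whole dataset is
#' reproducible from `(model, phys, seed)`.
#'
#' @param model A [folding_model()].
#' @param n_molecules Number of molecules (default 300, a typical field
#'   size per condition).
#' @param n_frames Frames per trace.
#' @param phys A [photophysics()] configuration.
#' @param condition Free-form condition label (e.g. `"K100"`).
#' @param seed Master integer seed.
#' @return A tibble of class `fret_sim` with columns `molecule_id`, `frame`
#'   (1-based), `donor`, `acceptor`, `true_state` (1-based generating state).
#'   Attributes: `model`, `phys`, `condition`, `seed`, and `bleach` (tibble
#'   of per-molecule bleach frames).
#' @export
#' @examples
#' sim <- simulate_traces(atrg3_model(), n_molecules = 3, n_frames = 50)
#' head(sim)
simulate_traces <- function(model, n_molecules = 300, n_frames = 500,
                            phys = photophysics(),
                            condition = NA_character_, seed = 1L) {
  stopifnot(n_molecules >= 1, n_frames >= 1)
  ids <- sprintf("mol%04d", seq_len(n_molecules))
  bleach <- vector("list", n_molecules)
  parts <- vector("list", n_molecules)
  for (i in seq_len(n_molecules)) {
    path <- simulate_state_path(model, n_frames, derive_seed(seed, i, 1L))
    tr <- emit_intensities(path, model, phys, derive_seed(seed, i, 2L))
    bl <- attr(tr, "bleach")
    bleach[[i]] <- tibble::tibble(molecule_id = ids[i],
                                  donor_bleach = bl$donor,
                                  acceptor_bleach = bl$acceptor)
    tr$molecule_id <- ids[i]
    tr$true_state <- path
    parts[[i]] <- tr[, c("molecule_id", "frame", "donor", "acceptor",
                         "true_state")]
  }
  out <- dplyr::bind_rows(parts)
  attr(out, "model") <- model
  attr(out, "phys") <- phys
  attr(out, "condition") <- condition
  attr(out, "seed") <- as.integer(seed)
  attr(out, "bleach") <- dplyr::bind_rows(bleach)
  class(out) <- c("fret_sim", class(out))
  out
}

#' Simulate a KCl titration series
#'
#' Runs [simulate_traces()] once per KCl concentration, with the transition
#' matrix (and its stationary initial occupancy) rebuilt per concentration by
#' [potassium_model()].  Emulates the titration experiments in which rising
#' K+ shifts the FRET distribution toward the folded, high-FRET states.
#'
#' @param kcl_mM Numeric vector of KCl concentrations (mM).
#' @param n_molecules,n_frames,phys,seed As in [simulate_traces()].
#' @param construct,emission_sds,... Passed to [potassium_model()].
#' @return A tibble binding the per-condition `fret_sim` tables with an extra
#'   `kcl_mM` column.
#' @export
simulate_titration <- function(kcl_mM, n_molecules = 300, n_frames = 100,
                               construct = "3G", emission_sds = 0.06,
                               phys = photophysics(), seed = 1L, ...) {
  stopifnot(length(kcl_mM) >= 1, all(kcl_mM >= 0))
  parts <- purrr::imap(kcl_mM, function(conc, j) {
    model <- potassium_model(conc, construct = construct,
                             emission_sds = emission_sds, ...)
    sim <- simulate_traces(model, n_molecules, n_frames, phys,
                           condition = paste0("K", conc),
                           seed = derive_seed(seed, j, 3L))
    sim$kcl_mM <- conc
    sim$molecule_id <- paste0("K", conc, "_", sim$molecule_id)
    sim
  })
  dplyr::bind_rows(parts)
}
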