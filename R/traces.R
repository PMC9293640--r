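# Trace processing: raw donor/acceptor intensities -> QC-filtered FRET
# efficiency traces and the per-molecule frame selections pooled into
# population histograms.

#' Compute FRET efficiency from donor/acceptor intensities
#'
#' The proximity ratio `E = I_A / (I_D + I_A)` per frame, after clamping each
#' channel at zero.  Frames whose summed intensity falls below `floor` are
#' marked invalid rather than divided (they carry no signal, e.g. after a
#' donor bleach).  No gamma or leakage corrections are applied: the raw
#' proximity ratio is the reported FRET scale.
#'
#' @param data A data frame with columns `molecule_id`, `frame`, `donor`,
#'   `acceptor` (e.g. from [simulate_traces()] or [read_fret_traces()]).
#' @param floor Minimum summed intensity for a frame to be valid.  The
#'   default 100 corresponds to 10% of the default photon budget of
#'   [photophysics()].
#' @return A tibble `molecule_id`, `frame`, `efficiency` (in `[0, 1]`, `NA`
#'   when invalid), `valid`.
#' @export
#' @examples
#' df <- tibble::tibble(molecule_id = "m1", frame = 1:2,
#'                      donor = c(100, 26), acceptor = c(100, 74))
#' compute_fret(df)$efficiency
compute_fret <- function(data, floor = 100) {
  stopifnot(all(c("molecule_id", "frame", "donor", "acceptor") %in% names(data)),
            nrow(data) > 0, floor > 0)
  d <- pmax(data$donor, 0)
  a <- pmax(data$acceptor, 0)
  tot <- d + a
  valid <- tot >= floor
  eff <- ifelse(valid, a / tot, NA_real_)
  tibble::tibble(molecule_id = data$molecule_id, frame = data$frame,
                 efficiency = eff, valid = valid)
}

# Significant downward steps in one signal: for each interior frame compare
# flanking window means against z_threshold * frame-noise s.e.; greedily pick
# non-overlapping minima.
.step_drops <- function(x, window, z_threshold) {
  n <- length(x)
  if (n <= 2L * window) return(integer(0))
  noise <- mad(diff(x)) / sqrt(2)
  noise <- max(noise, 1e-8 * max(1, max(abs(x))))
  cs <- cumsum(c(0, x))
  t <- seq.int(window + 1L, n - window + 1L)
  left <- (cs[t] - cs[t - window]) / window
  right <- (cs[t + window] - cs[t]) / window
  z <- (right - left) / (noise * sqrt(2 / window))
  hits <- integer(0)
  cand <- which(z < -z_threshold)
  while (length(cand)) {
    best <- cand[which.min(z[cand])]
    hits <- c(hits, t[best])
    cand <- cand[abs(t[cand] - t[best]) > 2L * window]
  }
  sort(hits)
}

#' Detect single-step photobleaching events
#'
#' Locates change points where a fluorophore bleaches, comparing flanking
#' window means against `z_threshold` times the frame-noise standard error.
#' A donor bleach drops both channels (total intensity collapses to
#' background); an acceptor bleach drops the acceptor while the donor rises,
#' leaving the total roughly constant.  Detection therefore runs on the
#' total for donor events and on the acceptor channel (away from total
#' events) for acceptor events.
#'
#' @param data Intensity traces as in [compute_fret()].
#' @param window Flanking window half-width in frames.
#' @param z_threshold Detection threshold in standard errors.
#' @param level_frac A candidate step only counts as a bleach if the signal
#'   after the step falls below this fraction of its level just before it:
#'   folding transitions also step the acceptor channel, but only a bleach
#'   collapses it to background.
#' @return A tibble `molecule_id`, `frame` (first frame after the step),
#'   `channel` (`"donor"` or `"acceptor"`).  Traces shorter than
#'   `2 * window + 1` contribute no events.
#' @export
detect_bleach <- function(data, window = 5L, z_threshold = 4,
                          level_frac = 0.15) {
  stopifnot(window >= 1, z_threshold > 0)
  per_mol <- function(df) {
    df <- df[order(df$frame), ]
    tot <- df$donor + df$acceptor
    n <- length(tot)
    is_bleach <- function(x, f) {
      before <- mean(x[max(1L, f - window):(f - 1L)])
      after <- mean(x[f:min(f + window - 1L, n)])
      before > 0 && after < level_frac * before
    }
    don_ev <- .step_drops(tot, window, z_threshold)
    don_ev <- don_ev[vapply(don_ev, function(f)
      is_bleach(tot, f), logical(1))]
    acc_ev <- .step_drops(df$acceptor, window, z_threshold)
    acc_ev <- acc_ev[vapply(acc_ev, function(f)
      is_bleach(df$acceptor, f), logical(1))]
    if (length(don_ev)) {
      acc_ev <- acc_ev[vapply(acc_ev, function(f)
        all(abs(f - don_ev) > window), logical(1))]
    }
    tibble::tibble(
      molecule_id = df$molecule_id[1L],
      frame = df$frame[c(don_ev, acc_ev)],
      channel = rep(c("donor", "acceptor"),
                    c(length(don_ev), length(acc_ev)))
    )
  }
  data |>
    dplyr::group_by(.data$molecule_id) |>
    dplyr::group_split() |>
    purrr::map(per_mol) |>
    dplyr::bind_rows()
}

#' Truncate FRET traces at the first bleach and apply QC
#'
#' Each molecule's FRET trace is truncated just before its first bleach
#' event; molecules are rejected when the usable stretch is shorter than
#' `min_frames` (default 30, matching the histogram frame-selection rule),
#' when a channel shows more than one bleach step (multi-fluorophore
#' labelling), or when no frame is valid.
#'
#' @param fret A tibble from [compute_fret()].
#' @param bleach_events A tibble from [detect_bleach()].
#' @param min_frames Minimum usable frames for acceptance.
#' @return The accepted rows of `fret` (truncated, valid frames only), with
#'   attribute `qc` — a tibble `molecule_id`, `status`
#'   (`"accepted"`/`"rejected"`), `reason`, `n_usable` — retrievable with
#'   [qc_report()].
#' @export
truncate_and_filter <- function(fret, bleach_events, min_frames = 30L) {
  per_mol <- function(df) {
    df <- df[order(df$frame), ]
    ev <- bleach_events[bleach_events$molecule_id == df$molecule_id[1L], ]
    multi <- any(table(ev$channel) > 1L)
    cut <- if (nrow(ev)) min(ev$frame) else Inf
    keep <- df[df$frame < cut & df$valid, ]
    reason <- if (multi) "multistep_bleach"
      else if (nrow(keep) == 0L) "all_invalid"
      else if (nrow(keep) < min_frames) "too_short"
      else NA_character_
    list(
      accepted = if (is.na(reason)) keep else keep[0, ],
      qc = tibble::tibble(
        molecule_id = df$molecule_id[1L],
        status = if (is.na(reason)) "accepted" else "rejected",
        reason = reason,
        n_usable = nrow(keep)
      )
    )
  }
  parts <- fret |>
    dplyr::group_by(.data$molecule_id) |>
    dplyr::group_split() |>
    purrr::map(per_mol)
  out <- dplyr::bind_rows(purrr::map(parts, "accepted"))
  attr(out, "qc") <- dplyr::bind_rows(purrr::map(parts, "qc"))
  out
}

#' QC report of a processed trace set
#'
#' @param x The result of [truncate_and_filter()] or [process_traces()].
#' @return A tibble of per-molecule QC decisions.
#' @export
qc_report <- function(x) {
  if (is.list(x) && !is.data.frame(x) && !is.null(x$qc)) return(x$qc)
  attr(x, "qc")
}

#' Select per-molecule frames for the population histogram
#'
#' Takes the earliest `n_max` usable frames of each accepted molecule
#' (30-50 by default), so every molecule contributes a comparable number of
#' samples and none dominates the histogram.  Molecules with fewer than
#' `n_min` usable frames are excluded.
#'
#' @param fret Accepted FRET trace tibble (e.g. from
#'   [truncate_and_filter()]).
#' @param n_min,n_max Minimum/maximum frames per molecule (defaults 30/50).
#' @return A tibble `molecule_id`, `frame`, `efficiency` with at most
#'   `n_max` rows per molecule.
#' @export
select_histogram_frames <- function(fret, n_min = 30L, n_max = 50L) {
  stopifnot(n_min >= 1, n_max >= n_min)
  if ("valid" %in% names(fret)) fret <- dplyr::filter(fret, .data$valid)
  fret |>
    dplyr::group_by(.data$molecule_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::filter(dplyr::n() >= n_min) |>
    dplyr::slice_head(n = n_max) |>
    dplyr::ungroup() |>
    dplyr::select("molecule_id", "frame", "efficiency")
}

#' Full trace-processing stage
#'
#' Runs [compute_fret()], [detect_bleach()], [truncate_and_filter()] and
#' [select_histogram_frames()] in sequence.
#'
#' @param data Intensity traces (`molecule_id`, `frame`, `donor`,
#'   `acceptor`).
#' @param floor Invalid-frame intensity floor, see [compute_fret()].
#' @param window,z_threshold Bleach detection settings, see
#'   [detect_bleach()].
#' @param min_frames,n_max QC and histogram frame-selection settings.
#' @return A list with elements `fret` (accepted FRET traces),
#'   `histogram_frames` (pooled per-molecule selections), `qc` (QC report),
#'   `bleach_events`.
#' @export
process_traces <- function(data, floor = 100, window = 5L, z_threshold = 4,
                           min_frames = 30L, n_max = 50L) {
  fret <- compute_fret(data, floor = floor)
  ev <- detect_bleach(data, window = window, z_threshold = z_threshold)
  acc <- truncate_and_filter(fret, ev, min_frames = min_frames)
  list(
    fret = acc,
    histogram_frames = select_histogram_frames(acc, n_min = min_frames,
                                               n_max = n_max),
    qc = qc_report(acc),
    bleach_events = ev
  )
}
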