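# Transition density plots and transition-count matrices from idealized
# traces.  Clusters in the (FRET before, FRET after) plane reveal which
# folding states interconvert; on a birth-death pathway only adjacent-state
# clusters should carry mass, and at equilibrium the plot is symmetric about
# the diagonal.

#' Extract state transitions from idealized traces
#'
#' One pair per segment boundary, using the model means of the flanking
#' states (idealized coordinates give crisp clusters; raw pre/post frame
#' values would smear them by emission noise).  Single-segment traces
#' contribute nothing.
#'
#' @param idealized An [idealize()] result (segments tibble).
#' @return A tibble `molecule_id`, `frame` (first frame of the new state),
#'   `state_from`, `state_to`, `e_before`, `e_after`.
#' @export
extract_transitions <- function(idealized) {
  stopifnot(all(c("molecule_id", "start_frame", "state", "state_mean")
                %in% names(idealized)))
  idealized |>
    dplyr::group_by(.data$molecule_id) |>
    dplyr::arrange(.data$start_frame, .by_group = TRUE) |>
    dplyr::mutate(
      state_from = dplyr::lag(.data$state),
      e_before = dplyr::lag(.data$state_mean)
    ) |>
    dplyr::filter(!is.na(.data$state_from)) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      molecule_id = .data$molecule_id,
      frame = .data$start_frame,
      state_from = .data$state_from,
      state_to = .data$state,
      e_before = .data$e_before,
      e_after = .data$state_mean
    )
}

#' Transition density on the (E before, E after) plane
#'
#' 2D histogram of transition pairs on `[0, 1]^2`, optionally smoothed with
#' a separable Gaussian kernel, optionally normalized to integrate to 1 over
#' the plane.
#'
#' @param pairs A tibble from [extract_transitions()] (needs `e_before`,
#'   `e_after`).
#' @param n_bins Grid size per axis (default 50).
#' @param bandwidth Gaussian kernel s.d. in FRET units (0 = no smoothing;
#'   default 0.02).
#' @param normalize If `TRUE`, scale so the density integrates to 1.
#' @return An object of class `fret_tdp`: list with `density` (matrix,
#'   rows = E before), `edges`, `total_transitions`, `normalized`.
#' @export
transition_density <- function(pairs, n_bins = 50, bandwidth = 0.02,
                               normalize = TRUE) {
  if (nrow(pairs) == 0) stop("no transitions to bin", call. = FALSE)
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- function(v) pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE),
                               1L), n_bins)
  i <- bin(pairs$e_before)
  j <- bin(pairs$e_after)
  D <- matrix(0, n_bins, n_bins)
  for (t in seq_along(i)) D[i[t], j[t]] <- D[i[t], j[t]] + 1
  if (bandwidth > 0) {
    h <- bandwidth / (edges[2] - edges[1])  # bandwidth in bin units
    half <- max(1L, ceiling(3 * h))
    kx <- dnorm(seq(-half, half), sd = h)
    kx <- kx / sum(kx)
    Km <- matrix(0, n_bins, n_bins)
    for (a in seq_len(n_bins)) {
      lo <- max(1L, a - half); hi <- min(n_bins, a + half)
      w <- kx[(lo - a + half + 1L):(hi - a + half + 1L)]
      Km[a, lo:hi] <- w / sum(w)
    }
    D <- t(Km) %*% D %*% Km
  }
  total <- nrow(pairs)
  if (normalize) {
    bin_area <- (edges[2] - edges[1])^2
    D <- D / (sum(D) * bin_area)
  }
  structure(list(density = D, edges = edges, total_transitions = total,
                 normalized = normalize),
            class = "fret_tdp")
}

#' @export
print.fret_tdp <- function(x, ...) {
  cat("<fret_tdp> ", nrow(x$density), "x", ncol(x$density), " grid, ",
      x$total_transitions, " transitions",
      if (x$normalized) " (normalized)", "\n", sep = "")
  invisible(x)
}

#' Transition-count matrix
#'
#' `n[i, j]` counts i -> j segment boundaries across all idealized traces;
#' the diagonal is zero by construction (consecutive segments differ).
#'
#' @param x An [idealize()] result or an [extract_transitions()] tibble.
#' @param k Number of states (indices above `k` are an error).
#' @return A `k x k` integer matrix with zero diagonal.
#' @export
transition_counts <- function(x, k) {
  pairs <- if (all(c("state_from", "state_to") %in% names(x))) x
           else extract_transitions(x)
  stopifnot(k >= 1)
  if (nrow(pairs) && max(pairs$state_from, pairs$state_to) > k) {
    stop("state index exceeds k", call. = FALSE)
  }
  M <- matrix(0L, k, k)
  for (t in seq_len(nrow(pairs))) {
    M[pairs$state_from[t], pairs$state_to[t]] <-
      M[pairs$state_from[t], pairs$state_to[t]] + 1L
  }
  M
}

#' Detailed-balance asymmetry scores
#'
#' For each state pair, `z = (n_ij - n_ji) / sqrt(n_ij + n_ji)`.  At
#' equilibrium the expected i->j and j->i counts balance, so populated pairs
#' should satisfy `|z| <= ~3`; systematic asymmetry indicates a driven
#' (non-equilibrium) process such as helicase unwinding.
#'
#' @param counts A transition-count matrix from [transition_counts()].
#' @return A tibble `from`, `to` (`from < to`), `n_forward`, `n_backward`,
#'   `z` (`NA` for unpopulated pairs).
#' @export
detailed_balance_score <- function(counts) {
  k <- nrow(counts)
  stopifnot(k >= 2, ncol(counts) == k)
  rows <- list()
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      nf <- counts[i, j]; nb <- counts[j, i]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        from = i, to = j, n_forward = nf, n_backward = nb,
        z = if (nf + nb > 0) (nf - nb) / sqrt(nf + nb) else NA_real_
      )
    }
  }
  dplyr::bind_rows(rows)
}
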