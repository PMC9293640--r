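# End-to-end orchestration: raw intensity traces -> QC -> shared HMM ->
# idealization -> population histogram -> Gaussian decomposition -> state
# fractions -> transition density.

#' Analyze one smFRET condition end to end
#'
#' Runs the full folding-state pipeline on a set of intensity traces:
#' [process_traces()] (FRET + bleach QC + histogram frame selection), a
#' shared [baum_welch_fit()] across all accepted traces (state count chosen
#' by [select_state_count()] when `n_states` is `NULL`), [idealize()],
#' [build_histogram()], [fit_gaussian_mixture()] seeded at the HMM means,
#' [state_fractions()], and the transition-density stage.  Deterministic
#' given `(data, settings, seed)`.
#'
#' @param data Intensity traces (`molecule_id`, `frame`, `donor`,
#'   `acceptor`).
#' @param n_states Number of folding states; `NULL` selects by BIC over
#'   `k_range`.
#' @param k_range Candidate state counts when selecting.
#' @param floor,window,z_threshold,min_frames,n_max QC settings, see
#'   [process_traces()].
#' @param bin_width Histogram bin width.
#' @param hmm_restarts,mixture_restarts EM restarts for the two fits.
#' @param seed Integer seed.
#' @return A list of class `fret_analysis`: `qc`, `hmm`, `selection` (when
#'   BIC ran), `idealized`, `histogram`, `mixture`, `fractions`,
#'   `transitions`, `transition_counts`, `tdp`, `balance`, `settings`.
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_traces(atrg3_model(), n_molecules = 40, n_frames = 120)
#' res <- analyze_fret_experiment(sim, n_states = 3)
#' res$fractions
#' }
analyze_fret_experiment <- function(data, n_states = NULL, k_range = 1:5,
                                    floor = 100, window = 5L, z_threshold = 4,
                                    min_frames = 30L, n_max = 50L,
                                    bin_width = 0.02, hmm_restarts = 5,
                                    mixture_restarts = 3, seed = 1L) {
  proc <- process_traces(data, floor = floor, window = window,
                         z_threshold = z_threshold, min_frames = min_frames,
                         n_max = n_max)
  if (nrow(proc$fret) == 0) {
    stop("no traces passed QC", call. = FALSE)
  }
  selection <- NULL
  if (is.null(n_states)) {
    selection <- select_state_count(proc$fret, k_range = k_range,
                                    n_restarts = hmm_restarts, seed = seed)
    hmm <- selection$best_fit
    n_states <- selection$best_k
  } else {
    hmm <- baum_welch_fit(proc$fret, n_states, n_restarts = hmm_restarts,
                          seed = seed)
  }
  ideal <- idealize(hmm, proc$fret)
  histogram <- build_histogram(proc$histogram_frames, bin_width = bin_width)
  mixture <- fit_gaussian_mixture(proc$histogram_frames, n_states,
                                  init_means = hmm$means, constrain = TRUE,
                                  n_restarts = mixture_restarts, seed = seed)
  fractions <- state_fractions(mixture)
  pairs <- extract_transitions(ideal)
  counts <- transition_counts(pairs, n_states)
  tdp <- if (nrow(pairs)) transition_density(pairs) else NULL
  balance <- if (n_states >= 2) detailed_balance_score(counts) else NULL
  structure(
    list(qc = proc$qc, hmm = hmm, selection = selection, idealized = ideal,
         histogram = histogram, mixture = mixture, fractions = fractions,
         transitions = pairs, transition_counts = counts, tdp = tdp,
         balance = balance,
         settings = list(n_states = n_states, floor = floor, window = window,
                         z_threshold = z_threshold, min_frames = min_frames,
                         n_max = n_max, bin_width = bin_width,
                         hmm_restarts = hmm_restarts,
                         mixture_restarts = mixture_restarts, seed = seed)),
    class = "fret_analysis"
  )
}

#' @export
print.fret_analysis <- function(x, ...) {
  n_acc <- sum(x$qc$status == "accepted")
  cat("<fret_analysis>\n")
  cat("  molecules:", nrow(x$qc), "(", n_acc, "accepted )\n")
  cat("  states:", x$settings$n_states,
      if (!is.null(x$selection)) "(BIC-selected)", "\n")
  cat("  state fractions:\n")
  print(as.data.frame(dplyr::mutate(x$fractions,
                                    dplyr::across(dplyr::where(is.numeric),
                                                  ~ round(.x, 3)))),
        row.names = FALSE)
  cat("  transitions:", nrow(x$transitions), "\n")
  invisible(x)
}

#' Write the artifacts of a full analysis to a directory
#'
#' Emits the QC report (JSON), fitted HMM (JSON), idealized segments (TSV),
#' histogram (TSV), decomposition (JSON) and fractions (TSV).
#'
#' @param analysis A [analyze_fret_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  stopifnot(inherits(analysis, "fret_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_qc_json(analysis$qc, file.path(dir, "qc.json"))
  write_hmm_json(analysis$hmm, file.path(dir, "hmm.json"))
  write_segments_tsv(analysis$idealized, file.path(dir, "segments.tsv"))
  write_histogram_tsv(analysis$histogram, file.path(dir, "histogram.tsv"))
  write_decomposition_json(analysis$mixture,
                           file.path(dir, "decomposition.json"))
  readr::write_tsv(analysis$fractions, file.path(dir, "fractions.tsv"))
  invisible(dir)
}
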