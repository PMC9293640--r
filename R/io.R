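# Plain-text interchange: tab-separated trace tables, truth sidecars with a
# JSON model header, condition manifests, and result writers.  Files use the
# 0-based frame/state indexing conventional for trace interchange; tibbles in
# R use 1-based indices throughout, and the readers/writers convert.

#' Write / read an intensity trace table
#'
#' Long-format TSV with columns `molecule_id`, `frame` (0-based in the
#' file), `donor`, `acceptor`; one file per condition.
#'
#' @param data A trace tibble (`molecule_id`, `frame`, `donor`, `acceptor`).
#' @param path Output file.
#' @export
write_fret_traces <- function(data, path) {
  out <- tibble::tibble(
    molecule_id = data$molecule_id,
    frame = as.integer(data$frame) - 1L,
    donor = data$donor,
    acceptor = data$acceptor
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_fret_traces
#' @return `read_fret_traces()`: a tibble with 1-based `frame`.
#' @export
read_fret_traces <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           molecule_id = readr::col_character(),
                           frame = readr::col_integer(),
                           donor = readr::col_double(),
                           acceptor = readr::col_double()))
  out$frame <- out$frame + 1L
  out
}

#' Write / read the ground-truth sidecar of a simulated dataset
#'
#' TSV with `molecule_id`, `frame`, `true_state` (both 0-based in the file)
#' plus a JSON header recording the generating model and seed.
#'
#' @param sim A [simulate_traces()] result.
#' @param path Sidecar TSV path.
#' @param header_path JSON header path (default: `path` with `.json`
#'   appended).
#' @export
write_state_truth <- function(sim, path, header_path = paste0(path, ".json")) {
  stopifnot(all(c("molecule_id", "frame", "true_state") %in% names(sim)))
  out <- tibble::tibble(
    molecule_id = sim$molecule_id,
    frame = as.integer(sim$frame) - 1L,
    true_state = as.integer(sim$true_state) - 1L
  )
  readr::write_tsv(out, path)
  model <- attr(sim, "model")
  hdr <- list(seed = attr(sim, "seed"),
              condition = attr(sim, "condition"))
  if (!is.null(model)) {
    hdr$model <- list(
      state_labels = model$state_labels,
      emission_means = model$emission_means,
      emission_sds = model$emission_sds,
      transition_matrix = model$transition_matrix,
      initial_distribution = model$initial_distribution
    )
  }
  jsonlite::write_json(hdr, header_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_state_truth
#' @return `read_state_truth()`: a list with `truth` (tibble, 1-based
#'   indices) and `header`.
#' @export
read_state_truth <- function(path, header_path = paste0(path, ".json")) {
  truth <- readr::read_tsv(path, show_col_types = FALSE)
  truth$frame <- truth$frame + 1L
  truth$true_state <- truth$true_state + 1L
  header <- if (file.exists(header_path)) {
    jsonlite::read_json(header_path, simplifyVector = TRUE)
  }
  list(truth = truth, header = header)
}

#' Write / read a condition manifest
#'
#' JSON mapping condition label to its trace file and condition metadata
#' (KCl concentration or protein/ATP condition).
#'
#' @param manifest A named list: each entry a list with at least
#'   `trace_file` and either `kcl_mM` or `condition`.
#' @param path Output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(is.list(manifest), !is.null(names(manifest)))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Write idealized trace segments as TSV
#'
#' Columns `molecule_id`, `start_frame`, `end_frame` (half-open, 0-based in
#' the file), `state` (0-based), `state_mean`.
#'
#' @param idealized An [idealize()] result.
#' @param path Output TSV path.
#' @export
write_segments_tsv <- function(idealized, path) {
  out <- tibble::tibble(
    molecule_id = idealized$molecule_id,
    start_frame = as.integer(idealized$start_frame) - 1L,
    end_frame = as.integer(idealized$end_frame) - 1L,
    state = as.integer(idealized$state) - 1L,
    state_mean = idealized$state_mean
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write a FRET histogram as TSV
#'
#' @param histogram A [build_histogram()] result.
#' @param path Output TSV path.
#' @export
write_histogram_tsv <- function(histogram, path) {
  readr::write_tsv(tibble::as_tibble(histogram), path)
  invisible(path)
}

#' Write a mixture decomposition as JSON
#'
#' @param decomposition A [fit_gaussian_mixture()] result.
#' @param path Output JSON path.
#' @export
write_decomposition_json <- function(decomposition, path) {
  x <- list(k = decomposition$k, n = decomposition$n,
            loglik = decomposition$loglik, bic = decomposition$bic,
            components = decomposition$components)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a QC report as JSON
#'
#' Counts of accepted molecules and of each rejection reason.
#'
#' @param qc A QC tibble from [qc_report()].
#' @param path Output JSON path.
#' @export
write_qc_json <- function(qc, path) {
  counts <- table(ifelse(qc$status == "accepted", "accepted", qc$reason))
  jsonlite::write_json(
    list(n_molecules = nrow(qc), counts = as.list(counts)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
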