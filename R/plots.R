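# ggplot2 views of the result types.

#' Plot a population FRET histogram
#'
#' @param object A [build_histogram()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fret_histogram <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                                   y = .data$count)) +
    ggplot2::geom_col(width = df$bin_hi[1] - df$bin_lo[1],
                      fill = "grey70", colour = "grey35", linewidth = 0.2) +
    ggplot2::labs(x = "FRET efficiency", y = "Frames") +
    ggplot2::theme_minimal()
}

#' Plot a Gaussian decomposition over its histogram
#'
#' @param object A [fit_gaussian_mixture()] result.
#' @param bin_width Histogram bin width for the backdrop.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fret_mixture <- function(object, bin_width = 0.02, ...) {
  x <- object$data$efficiency
  x <- pmin(pmax(x[!is.na(x)], 0), 1)
  hist <- build_histogram(x, bin_width = bin_width)
  grid <- seq(0, 1, length.out = 401)
  comp <- purrr::pmap(object$components, function(state, center, width, area) {
    tibble::tibble(state = factor(state), x = grid,
                   y = length(x) * bin_width * area * dnorm(grid, center, width))
  }) |> dplyr::bind_rows()
  total <- comp |>
    dplyr::summarise(y = sum(.data$y), .by = "x")
  autoplot(hist) +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$state),
                       inherit.aes = FALSE) +
    ggplot2::geom_line(data = total,
                       ggplot2::aes(x = .data$x, y = .data$y),
                       inherit.aes = FALSE, colour = "red") +
    ggplot2::labs(colour = "Component")
}

#' Plot a transition density heat map
#'
#' @param object A [transition_density()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fret_tdp <- function(object, ...) {
  n <- nrow(object$density)
  mids <- (object$edges[-1] + object$edges[-(n + 1)]) / 2
  df <- tidyr::expand_grid(e_before = mids, e_after = mids)
  df$density <- as.vector(t(object$density))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$e_before, y = .data$e_after,
                                   fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "FRET before", y = "FRET after") +
    ggplot2::theme_minimal()
}

#' Plot a potassium titration of folded/unfolded fractions
#'
#' @param object A [titration_curve()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fret_titration <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble::tibble(kcl_mM = object$kcl_mM, pool = "folded",
                   fraction = object$folded, lo = object$folded_lo,
                   hi = object$folded_hi),
    tibble::tibble(kcl_mM = object$kcl_mM, pool = "unfolded",
                   fraction = object$unfolded, lo = object$unfolded_lo,
                   hi = object$unfolded_hi)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$kcl_mM, y = .data$fraction,
                                     colour = .data$pool)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "KCl (mM)", y = "Population fraction",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an MST dose-response fit
#'
#' @param object An [fit_dose_response()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mst_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$concentration,
                                    y = .data$fnorm)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Concentration (M)", y = "Fnorm (per mil)") +
    ggplot2::theme_minimal()
  if (!is.null(object$estimates)) {
    cf <- setNames(object$estimates$estimate, object$estimates$term)
    h <- if ("h" %in% names(cf)) cf[["h"]] else object$hill
    grid <- 10^seq(log10(min(object$data$concentration)),
                   log10(max(object$data$concentration)), length.out = 200)
    curve <- tibble::tibble(
      concentration = grid,
      fnorm = cf[["baseline"]] + cf[["amplitude"]] * grid^h /
        (cf[["ec50"]]^h + grid^h))
    p <- p + ggplot2::geom_line(data = curve, colour = "red") +
      ggplot2::geom_vline(xintercept = object$ec50, linetype = 2,
                          colour = "grey50")
  }
  p
}

#' Plot a FRET trace with its idealization
#'
#' @param fret Accepted FRET traces (`molecule_id`, `frame`, `efficiency`).
#' @param idealized Optional [idealize()] result overlaying the state path.
#' @param molecule Molecule id to plot (default: the first).
#' @return A ggplot.
#' @export
plot_fret_trace <- function(fret, idealized = NULL, molecule = NULL) {
  molecule <- molecule %||% fret$molecule_id[1]
  df <- fret[fret$molecule_id == molecule, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$frame,
                                        y = .data$efficiency)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Frame", y = "FRET efficiency", title = molecule) +
    ggplot2::theme_minimal()
  if (!is.null(idealized)) {
    seg <- idealized[idealized$molecule_id == molecule, ]
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$start_frame, xend = .data$end_frame - 1,
                   y = .data$state_mean, yend = .data$state_mean),
      colour = "red", linewidth = 0.8, inherit.aes = FALSE)
  }
  p
}
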