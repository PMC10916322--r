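# ggplot2 convenience plots. Plots are presentation helpers, not part of
# the numerical contract.

#' Plot an NRE length distribution
#'
#' @param hist_tbl Tibble from [length_distribution()].
#' @return A ggplot.
#' @export
plot_length_distribution <- function(hist_tbl) {
  ggplot2::ggplot(hist_tbl,
                  ggplot2::aes(x = .data$bin_start, y = .data$count)) +
    ggplot2::geom_col(width = 1.8, fill = "steelblue") +
    ggplot2::facet_grid(kind ~ class_label, scales = "free_y") +
    ggplot2::labs(x = "NRE length (residues)", y = "segments") +
    ggplot2::theme_minimal()
}

#' @describeIn scaled_composition Line plot of per-position composition for
#'   selected letters.
#' @param object An `nre_scaled_profile`.
#' @param letters Letters to draw (default the residues with the largest
#'   overall frequency).
#' @param ... Unused.
#' @method autoplot nre_scaled_profile
#' @export
autoplot.nre_scaled_profile <- function(object, letters = NULL, ...) {
  freq <- object$freq
  if (is.null(letters)) {
    letters <- names(sort(colSums(freq), decreasing = TRUE))[1:6]
  }
  df <- tibble::as_tibble(freq[, letters, drop = FALSE]) |>
    dplyr::mutate(bin = dplyr::row_number()) |>
    tidyr::pivot_longer(-"bin", names_to = "letter", values_to = "frequency")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = 100 * .data$frequency,
                                   colour = .data$letter)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = sprintf("scaled position (1-%d)", object$bins),
                  y = "composition (%)", colour = "residue") +
    ggplot2::theme_minimal()
}

#' @describeIn terminal_logo Stacked information-content logo (letter
#'   heights are `freq * ic` in bits).
#' @param object An `nre_logo`.
#' @param ... Unused.
#' @method autoplot nre_logo
#' @export
autoplot.nre_logo <- function(object, ...) {
  df <- tibble::as_tibble(object$freq) |>
    dplyr::mutate(position = dplyr::row_number(),
                  ic = object$ic) |>
    tidyr::pivot_longer(cols = dplyr::all_of(colnames(object$freq)),
                        names_to = "letter", values_to = "freq") |>
    dplyr::mutate(bits = .data$freq * .data$ic) |>
    dplyr::filter(.data$bits > 0.01)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$bits,
                                   fill = .data$letter,
                                   label = .data$letter)) +
    ggplot2::geom_col(colour = "grey30", linewidth = 0.1) +
    ggplot2::labs(x = sprintf("position (%s-terminal window)", object$end),
                  y = "information (bits)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
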