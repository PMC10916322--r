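# broom-style tidiers for motif models.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a motif model
#'
#' One row per (position, letter) with the count, frequency and log-odds.
#'
#' @param x An `nre_motif`.
#' @param ... Unused.
#' @return A tibble `position, letter, count, freq, log_odds`.
#' @method tidy nre_motif
#' @export
tidy.nre_motif <- function(x, ...) {
  tibble::tibble(
    position = rep(seq_len(x$width), times = length(x$alphabet)),
    letter = rep(x$alphabet, each = x$width),
    count = as.numeric(x$counts),
    freq = as.numeric(x$freq),
    log_odds = as.numeric(x$log_odds)
  ) |>
    dplyr::arrange(.data$position, .data$letter)
}

#' One-row summary of a motif model
#'
#' @param x An `nre_motif`.
#' @param ... Unused.
#' @return A tibble `id, width, n_sites, consensus, llr, p_value, gamma`.
#' @method glance nre_motif
#' @export
glance.nre_motif <- function(x, ...) {
  ds <- x$discovery_stat
  tibble::tibble(
    id = x$id, width = x$width, n_sites = x$n_sites,
    consensus = x$consensus,
    llr = if (is.null(ds)) NA_real_ else ds$llr,
    p_value = if (is.null(ds)) NA_real_ else ds$p_value,
    gamma = if (is.null(ds)) NA_real_ else ds$gamma
  )
}
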