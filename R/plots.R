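#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the main result
#' types: per-residue accessible area profiles (`sasa_result`), interface
#' areas by label (`assembly_interface_map`), and the volume-contraction
#' deltas across entries (`comparative_report`).
#'
#' @param object A quatstab result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name quatstab-plots
NULL

#' @rdname quatstab-plots
#' @export
autoplot.sasa_result <- function(object, ...) {
  if (is.null(object$per_residue))
    abort("per-residue areas unavailable (atoms lacked residue columns)")
  ggplot2::ggplot(object$per_residue,
                  ggplot2::aes(x = .data$resno, y = .data$area,
                               colour = .data$chain)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = expression("accessible area (" *
                                                  ring(A)^2 * ")"),
                  colour = "chain") +
    ggplot2::theme_minimal()
}

#' @rdname quatstab-plots
#' @export
autoplot.assembly_interface_map <- function(object, ...) {
  d <- object$labels |>
    mutate(pair = paste(.data$chain1, .data$chain2, sep = "/"))
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$pair,
                                                     -.data$interface_area),
                                  y = .data$interface_area,
                                  fill = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "chain pair",
                  y = expression("interface area (" * ring(A)^2 * ")"),
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname quatstab-plots
#' @export
autoplot.comparative_report <- function(object, ...) {
  d <- object$rows |>
    tidyr::pivot_longer(c("delta2", "delta4"), names_to = "delta",
                        values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$entry_id, y = .data$value,
                                  fill = .data$delta)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL,
                  y = expression("volume contraction (" * ring(A)^3 * ")"),
                  fill = NULL) +
    ggplot2::theme_minimal()
}
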