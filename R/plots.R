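# ggplot2 views of the main result types.

#' Arc-strength diagnostic curve
#'
#' Empirical cumulative distribution of bootstrap arc strengths with the
#' retention threshold marked; the curve one inspects when choosing the
#' cutoff.
#'
#' @param object A `hen_arc_strength` table or a `hen_network`.
#' @param threshold Cutoff to mark (defaults to the network's own).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hen_arc_strength <- function(object, threshold = 0.6, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$strength)) +
    ggplot2::stat_ecdf(pad = TRUE) +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::labs(
      x = "arc strength (fraction of bootstrap replicates)",
      y = "cumulative fraction of arcs",
      title = "Arc-strength distribution"
    )
}

#' @rdname autoplot.hen_arc_strength
#' @export
autoplot.hen_network <- function(object, ...) {
  nodes <- object$nodes
  p <- length(nodes)
  theta <- 2 * pi * (seq_len(p) - 1) / p
  layout <- tibble(node = nodes, x = cos(theta), y = sin(theta))
  arcs <- object$arcs |>
    left_join(layout, by = c(from = "node")) |>
    rename(x0 = "x", y0 = "y") |>
    left_join(layout, by = c(to = "node")) |>
    rename(x1 = "x", y1 = "y")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = arcs,
      ggplot2::aes(
        x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
        alpha = .data$strength
      ),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))
    ) +
    ggplot2::geom_text(
      data = layout,
      ggplot2::aes(x = 1.08 * .data$x, y = 1.08 * .data$y, label = .data$node),
      size = 2.5
    ) +
    ggplot2::coord_equal(xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3)) +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Averaged network (circular layout)")
}

#' Plot sufficiency ratios per nutrient
#'
#' @param sufficiency Tibble from [sufficiency_ratio()] (columns `nutrient`,
#'   `ratio`).
#' @return A ggplot: one bar per nutrient with the sufficiency line at 1.
#' @export
plot_sufficiency <- function(sufficiency) {
  dat <- filter(as_tibble(sufficiency), !is.na(.data$ratio))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$nutrient, .data$ratio), y = .data$ratio
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "supply / population requirement")
}

#' Plot excess and deficit requirement-years
#'
#' @param headcount Tibble from [headcount_report()].
#' @return A ggplot with deficits and excesses on separate panels.
#' @export
plot_headcount <- function(headcount) {
  dat <- as_tibble(headcount) |>
    tidyr::pivot_longer(
      all_of(c("deficit_requirement_years", "excess_requirement_years")),
      names_to = "side", values_to = "requirement_years"
    ) |>
    mutate(side = if_else(
      .data$side == "deficit_requirement_years", "deficit", "excess"
    ))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$nutrient, .data$requirement_years),
    y = .data$requirement_years
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~side, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "requirement-years (persons)")
}
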