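#' Plot a colony map
#'
#' Static map figure: trees as triangles, nests as circles sized by
#' population and coloured by resource-flow category, trails as segments
#' (foraging trails green, internest trails grey).
#'
#' @param object A [colony_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot colony_map
#' @export
autoplot.colony_map <- function(object, ...) {
  flow <- suppressWarnings(suppressMessages(flow_betweenness(object)))
  nodes <- object$nodes |>
    left_join(flow |> select("node_id", "flow_category"), by = "node_id")
  pos <- nodes[, c("node_id", "x", "y")]
  segs <- object$trails |>
    left_join(pos |> rename(xa = "x", ya = "y"),
              by = c(endpoint_a = "node_id")) |>
    left_join(pos |> rename(xb = "x", yb = "y"),
              by = c(endpoint_b = "node_id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb, colour = .data$kind),
      linewidth = 0.4) +
    ggplot2::scale_colour_manual(
      values = c(internest = "grey50", foraging = "darkgreen"),
      name = "trail") +
    ggplot2::geom_point(
      data = nodes |> filter(.data$kind == "tree"),
      ggplot2::aes(.data$x, .data$y), shape = 17, colour = "darkgreen",
      size = 2) +
    ggplot2::geom_point(
      data = nodes |> filter(.data$kind == "nest"),
      ggplot2::aes(.data$x, .data$y, size = .data$population,
                   fill = .data$flow_category),
      shape = 21) +
    ggplot2::scale_fill_brewer(palette = "Oranges", name = "flow",
                               drop = FALSE) +
    ggplot2::scale_size_continuous(trans = "log10", guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0(object$colony_id, " @ ",
                                 object$timepoint),
                  x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' Plot a QAP null distribution with its observed statistic
#'
#' @param object A [qap_cox()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qap_cox
#' @export
autoplot.qap_cox <- function(object, ...) {
  ggplot2::ggplot(tibble(z = object$null_stats), ggplot2::aes(.data$z)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70",
                            colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_stat,
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(
      x = "null z statistic",
      y = "permutations",
      title = sprintf("%s: z = %.2f, p = %.4g (%s, B = %d)",
                      object$covariate, object$observed_stat,
                      object$p_value, object$tail, object$B_ok)) +
    ggplot2::theme_minimal()
}

#' Plot survival curves
#'
#' Step curves from [survival_curve()] output, one per covariate profile.
#'
#' @param curves Tibble (`profile`, `time`, `survival`).
#' @return A ggplot object.
#' @export
plot_survival_curves <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(.data$time, .data$survival,
                                       colour = .data$profile)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "mapping intervals since entry",
                  y = "S(t)", colour = "profile") +
    ggplot2::theme_minimal()
}
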