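#' Plot an entropy profile
#'
#' Bar chart of segmentation entropy against sub-segment length, with a
#' horizontal line at the tolerance threshold; admissible lengths are
#' filled.
#'
#' @param object An [entropy_profile()].
#' @param tolerance Entropy tolerance used for the threshold line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.entropy_profile <- function(object, tolerance = 0.9, ...) {
  adm <- admissible_lengths(object, tolerance)
  df <- dplyr::mutate(as_tibble(object), admissible = .data$n %in% adm)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$n), y = .data$entropy_bits,
                                   fill = .data$admissible)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = tolerance * max(df$entropy_bits),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = "sub-segment length n (units)",
                  y = "information entropy (bits)",
                  fill = sprintf(">= %d%% of max", round(100 * tolerance))) +
    ggplot2::theme_minimal()
}

#' Plot per-construct delta-Cq means with propagated error bars
#'
#' @param results Output of [delta_cq()].
#' @return A ggplot object.
#' @export
plot_delta_cq <- function(results) {
  df <- dplyr::mutate(as_tibble(results),
                      construct_id = factor(.data$construct_id,
                                            levels = .data$construct_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$construct_id,
                                   y = .data$delta_cq_mean,
                                   alpha = !.data$excluded)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$delta_cq_mean - .data$delta_cq_sd,
                                        ymax = .data$delta_cq_mean + .data$delta_cq_sd),
                           width = 0.3) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
                                guide = "none") +
    ggplot2::labs(x = "construct", y = expression(Delta * "Cq (cycles)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot per-unit hotspot support
#'
#' Step profile of the number of significant constructs covering each unit,
#' with called hotspot intervals shaded when supplied.
#'
#' @param support A [unit_support()] table.
#' @param hotspots Optional [call_hotspots()] result to shade.
#' @return A ggplot object.
#' @export
plot_unit_support <- function(support, hotspots = NULL) {
  df <- as_tibble(support)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$ord, y = .data$n_significant)) +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::labs(x = "unit (ordinal position)",
                  y = "significant constructs covering unit") +
    ggplot2::theme_minimal()
  if (!is.null(hotspots) && nrow(hotspots)) {
    p <- p + ggplot2::geom_rect(
      data = as_tibble(hotspots),
      ggplot2::aes(xmin = .data$start_ord - 0.5, xmax = .data$end_ord + 0.5,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "tomato", alpha = 0.15)
  }
  p
}
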