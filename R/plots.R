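#' Plot per-position read incidence across a hairpin
#'
#' Mirrors the standard mirtron deep-sequencing figure: coverage at each
#' hairpin position, coloured by region (5' arm / loop / 3' arm), from which
#' arm bias and end definition are visible at a glance.
#'
#' @param object An `arm_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.arm_profile <- function(object, ...) {
  df <- object$per_position
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$incidence,
                                   fill = .data$region)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_manual(values = c(arm5 = "#d7301f", loop = "grey70",
                                          arm3 = "#2b8cbe")) +
    ggplot2::labs(x = "hairpin position (nt)", y = "read incidence",
                  fill = NULL,
                  title = sprintf("arm fractions: 5' %.1f%% / 3' %.1f%%",
                                  100 * (object$arm5_fraction %||% NA),
                                  100 * (object$arm3_fraction %||% NA))) +
    ggplot2::theme_minimal()
}

#' Plot scored target sites along the transcript
#'
#' @param sites Tibble from [score_targets()].
#' @return A ggplot object: composite score by position, coloured by arm.
#' @export
plot_target_scores <- function(sites) {
  ggplot2::ggplot(sites, ggplot2::aes(x = .data$start, y = .data$composite,
                                      colour = .data$arm)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$start, yend = 0),
                          linewidth = 0.3) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::labs(x = "transcript position (nt)", y = "composite score",
                  colour = "guide arm") +
    ggplot2::theme_minimal()
}

#' Plot ranked insertion junctions along a transgene
#'
#' @param sites Tibble from [find_insertion_sites()].
#' @param top Label the best `top` junctions (default 3).
#' @return A ggplot object.
#' @export
plot_insertion_sites <- function(sites, top = 3) {
  lab <- head(sites, top)
  ggplot2::ggplot(sites, ggplot2::aes(x = .data$cds_position, y = .data$composite)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$cds_position, yend = 0),
                          linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_ese), colour = "#2b8cbe") +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$cds_position),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "CDS junction position (nt)", y = "composite score",
                  size = "ESE hits") +
    ggplot2::theme_minimal()
}
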