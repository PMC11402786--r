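#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ESS profile
#'
#' Stacked per-sample bars of the six length-normalized splicing
#' percentages.
#'
#' @param object an [ess_percentages()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ess_profile <- function(object, ...) {
  dat <- dplyr::filter(object, .data$in_model)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$sample_id,
                                    y = .data$percentage,
                                    fill = .data$isoform)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "percentage of splicing events",
                  fill = "isoform") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot per-embryo relative levels
#'
#' Tile map of the relative level of the metric among blastomeres of each
#' embryo (embryo maximum = 1).
#'
#' @param object a [relative_levels_within_embryo()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.embryo_summary <- function(object, ...) {
  dat <- dplyr::group_by(object, .data$embryo_id)
  dat <- dplyr::mutate(dat, slot = factor(dplyr::row_number()))
  dat <- dplyr::ungroup(dat)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$slot, y = .data$embryo_id,
                                    fill = .data$relative_level)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1), na.value = "grey85") +
    ggplot2::labs(x = "blastomere", y = NULL, fill = "relative level") +
    ggplot2::theme_minimal()
}

#' Plot an empirical structure null
#'
#' Histogram of the null f values with the left-tail threshold marked.
#'
#' @param object a [build_null()] result.
#' @param bins histogram bins (default 40).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.structure_null <- function(object, bins = 40, ...) {
  dat <- tibble(f = object$f_values)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$f)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", color = "grey40") +
    ggplot2::geom_vline(xintercept = object$threshold, color = "firebrick",
                        linetype = 2) +
    ggplot2::annotate("text", x = object$threshold, y = Inf,
                      label = sprintf("left %.3g%% = %g",
                                      100 * object$alpha, object$threshold),
                      vjust = 2, hjust = -0.05, color = "firebrick") +
    ggplot2::labs(x = "f value (tree edit distance)", y = "count") +
    ggplot2::theme_minimal()
}

#' Plot a pairwise f table as a heat map
#'
#' @param object a [pairwise_f_matrix()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.f_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fragment_b,
                                       y = .data$fragment_a,
                                       fill = .data$f)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = NULL, y = NULL, fill = "f") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1,
                                                       vjust = 0.5))
}
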