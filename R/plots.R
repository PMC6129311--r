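#' Bar chart of the top-weighted gene sets in a tissue
#'
#' @param sw A `set_weights` object.
#' @param tissue Tissue to profile.
#' @param k Number of sets to show (default 10).
#' @return A ggplot object.
#' @export
plot_tissue_profile <- function(sw, tissue, k = 10) {
  rep <- rank_sets_for_tissue(sw, tissue, k = k)
  ggplot2::ggplot(
    as_tibble(rep),
    ggplot2::aes(x = .data$weight,
                 y = stats::reorder(.data$set, .data$weight))
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "set weight (-log p)", y = NULL,
      title = paste0("Top gene sets: ", attr(rep, "tissue"))
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_tissue_profile
#' @param object A `ranked_report`.
#' @param ... Unused.
#' @method autoplot ranked_report
#' @export
autoplot.ranked_report <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$weight,
                 y = stats::reorder(.data$set, .data$weight))
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "set weight (-log p)", y = NULL,
      title = paste0("Top gene sets: ", attr(object, "tissue"))
    ) +
    ggplot2::theme_minimal()
}

#' Weighted vs. unweighted q-values
#'
#' Scatter of the BH q-values against the weighted (wFDR) q-values with the
#' discovery threshold marked; points below the diagonal gained from the
#' weighting.
#'
#' @param object A `wfdr_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wfdr_result
#' @export
autoplot.wfdr_result <- function(object, ...) {
  q <- attr(object, "q_threshold")
  ggplot2::ggplot(
    as_tibble(unclass_result(object)),
    ggplot2::aes(x = .data$q_bh, y = .data$q_wfdr)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_hline(yintercept = q, linetype = "dotted", colour = "red") +
    ggplot2::geom_vline(xintercept = q, linetype = "dotted", colour = "red") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "BH q-value (unweighted)", y = "wFDR q-value (weighted)") +
    ggplot2::theme_minimal()
}
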