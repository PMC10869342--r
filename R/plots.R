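# ggplot2 views of the main result types.

#' Volcano plot of a differential result
#'
#' @param result Tibble from [moderated_differential()] or
#'   [differential_node_strength()].
#' @return A ggplot object: effect vs -log10 adjusted p, significant
#'   features highlighted.
#' @export
plot_volcano <- function(result) {
  ggplot2::ggplot(result,
                  ggplot2::aes(x = .data$effect,
                               y = -log10(pmax(.data$padj, 1e-300)),
                               color = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "red3")) +
    ggplot2::labs(x = "effect", y = "-log10(adjusted p)", color = "significant") +
    ggplot2::theme_minimal()
}

#' Edge-weight density per method
#'
#' @param panels Named list of edge panels (one per method).
#' @param drop_zero Exclude absent (zero-weight) edges (default `TRUE`).
#' @return A ggplot density plot of nonzero edge weights, one facet per
#'   method.
#' @export
plot_edge_weight_density <- function(panels, drop_zero = TRUE) {
  long <- purrr::imap(panels, function(p, nm) {
    w <- as.vector(panel_weights(p))
    if (drop_zero) w <- w[w != 0]
    tibble::tibble(method = nm, weight = w)
  })
  ggplot2::ggplot(dplyr::bind_rows(long), ggplot2::aes(x = .data$weight)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~method, scales = "free") +
    ggplot2::theme_minimal()
}

#' Hub recurrence dot plot
#'
#' @param recurrence Tibble from [hub_recurrence()], optionally with the
#'   `specific` flag added via [subtype_specific_hubs()].
#' @return A ggplot object: recurrence counts per hub, faceted by group.
#' @export
plot_hub_recurrence <- function(recurrence) {
  ggplot2::ggplot(recurrence,
                  ggplot2::aes(x = .data$group, y = .data$count,
                               color = .data$regularly_recurring)) +
    ggplot2::geom_jitter(width = 0.2, height = 0, alpha = 0.5) +
    ggplot2::labs(x = "sample group", y = "hub recurrence",
                  color = "regular") +
    ggplot2::theme_minimal()
}

#' Boxplots of per-sample omics concordance by method
#'
#' @param concordance Tibble from [match_and_correlate()] rows (may combine
#'   several methods; needs a `method` column).
#' @return A ggplot object: per-sample correlation coefficients by method.
#' @export
plot_concordance <- function(concordance) {
  ggplot2::ggplot(concordance,
                  ggplot2::aes(x = .data$method, y = .data$r)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4) +
    ggplot2::labs(x = NULL, y = "per-sample Pearson r") +
    ggplot2::theme_minimal()
}
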