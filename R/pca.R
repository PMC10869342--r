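# PCA of node strengths: samples as observations, genes as features.

#' PCA of a node-strength matrix
#'
#' Transposes the strength matrix so rows are samples, centers columns, and
#' computes principal components without per-feature rescaling (strengths
#' from unit-scaled panels share a common scale, so variance-based feature
#' weighting is meaningful).
#'
#' @param strengths Node-strength table from [node_strength()].
#' @param groups Optional sample-group labels carried into the output.
#' @param n_components Number of components to return (default 2, at least).
#' @return An object of class `"ssnets_pca"`: list with `coords` (tibble of
#'   `sample`, `group`, `PC1`, `PC2`, ...) and `var_explained` (fraction per
#'   returned component; `var_explained_all` sums to 1 over all components).
#' @export
pca_node_strength <- function(strengths, groups = NULL, n_components = 2) {
  m <- t(as.matrix(strengths[, -1, drop = FALSE]))
  colnames(m) <- strengths$gene
  if (nrow(m) < 3) abort("PCA needs at least 3 samples")
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  ve_all <- pc$sdev^2 / sum(pc$sdev^2)
  k <- max(2, min(n_components, ncol(pc$x)))
  coords <- tibble::as_tibble(pc$x[, seq_len(k), drop = FALSE])
  coords <- dplyr::bind_cols(tibble::tibble(sample = rownames(m)), coords)
  if (!is.null(groups)) {
    g <- group_vector(groups)
    coords$group <- unname(g[coords$sample])
  }
  out <- list(
    coords = coords,
    var_explained = ve_all[seq_len(k)],
    var_explained_all = ve_all
  )
  class(out) <- "ssnets_pca"
  out
}

#' @export
print.ssnets_pca <- function(x, ...) {
  cat("PCA of node strengths:",
      nrow(x$coords), "samples,",
      length(x$var_explained_all), "components\n")
  cat("variance explained:",
      paste0(sprintf("PC%d %.1f%%", seq_along(x$var_explained),
                     100 * x$var_explained), collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn pca_node_strength Sample coordinates as a tibble.
#' @param x An `ssnets_pca` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ssnets_pca <- function(x, ...) x$coords

#' @describeIn pca_node_strength One-row summary with variance explained.
#' @exportS3Method generics::glance
glance.ssnets_pca <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$coords),
    pc1_var = x$var_explained[1],
    pc2_var = x$var_explained[2],
    n_components = length(x$var_explained_all)
  )
}

#' @describeIn pca_node_strength Scatter plot of the first two components,
#'   colored by group when available.
#' @param object An `ssnets_pca` object.
#' @exportS3Method ggplot2::autoplot
autoplot.ssnets_pca <- function(object, ...) {
  p <- ggplot2::ggplot(object$coords,
                       ggplot2::aes(x = .data$PC1, y = .data$PC2))
  p <- if ("group" %in% names(object$coords)) {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$group))
  } else {
    p + ggplot2::geom_point()
  }
  p +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])
    ) +
    ggplot2::theme_minimal()
}
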