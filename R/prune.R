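# Network pruning: background-edge restriction, per-sample top-k selection,
# and within-sample max-abs scaling into [-1, 1].

#' Restrict a network to background edges
#'
#' Retains exactly the edges whose unordered gene pair occurs in the
#' background network; retained edges keep their canonical (sorted) order.
#' Works on edge panels and aggregate networks alike.
#'
#' @param x Edge panel or aggregate network tibble.
#' @param background Background network tibble (`gene_a`, `gene_b`).
#' @return Same type as `x`, restricted to background edges.
#' @export
prune_to_background <- function(x, background) {
  bg <- dplyr::distinct(canonical_pairs(background$gene_a, background$gene_b))
  keep <- pair_key(x$gene_a, x$gene_b) %in% pair_key(bg$gene_a, bg$gene_b)
  if (!any(keep)) {
    abort("no edges left after background pruning; check that gene identifiers match")
  }
  out <- x[keep, , drop = FALSE]
  out <- out[pair_order(out$gene_a, out$gene_b), , drop = FALSE]
  attr(out, "binary") <- attr(x, "binary", exact = TRUE)
  attr(out, "unit_scaled") <- attr(x, "unit_scaled", exact = TRUE)
  out
}

#' Keep the k strongest edges per network
#'
#' For each sample (or once, for an aggregate network) the `k` edges with the
#' largest absolute weight are kept and all others set to 0 ("absent").
#' Boundary ties are broken by lexicographic edge identifier, so the
#' selection is deterministic.
#'
#' @param x Edge panel or aggregate network tibble.
#' @param k Number of edges to keep (default 25000); `k` larger than the
#'   edge count keeps everything.
#' @return Same type as `x` with non-selected weights zeroed.
#' @export
select_top_edges <- function(x, k = 25000) {
  stopifnot(k >= 1)
  r <- c_rank(x$gene_a, x$gene_b)
  tie_order <- order(r[[1]], r[[2]])
  tie_rank <- integer(length(tie_order))
  tie_rank[tie_order] <- seq_along(tie_order)
  pick_top <- function(w) {
    if (length(w) <= k) return(w)
    ord <- order(-abs(w), tie_rank)
    out <- numeric(length(w))
    sel <- ord[seq_len(k)]
    out[sel] <- w[sel]
    out
  }
  if (is_aggregate(x)) {
    x$weight <- pick_top(x$weight)
    return(x)
  }
  samples <- panel_samples(x)
  out <- x
  for (s in samples) out[[s]] <- pick_top(x[[s]])
  attr(out, "binary") <- attr(x, "binary", exact = TRUE)
  attr(out, "unit_scaled") <- attr(x, "unit_scaled", exact = TRUE)
  out
}

#' Scale edge weights into [-1, 1] within each sample
#'
#' Divides each sample's weights by that sample's maximum absolute weight.
#' Max-abs scaling preserves signs and zeros (absent edges stay absent),
#' unlike min-max scaling. Binary panels pass through unchanged.
#'
#' @param panel Edge panel.
#' @return The scaled panel, tagged with the `unit_scaled` provenance flag
#'   required by [differential_node_strength()].
#' @export
scale_weights_unit <- function(panel) {
  out <- panel
  if (!is_binary_panel(panel)) {
    for (s in panel_samples(panel)) {
      mx <- max(abs(panel[[s]]))
      if (mx == 0) abort(paste0("sample '", s, "' has only zero weights"))
      out[[s]] <- panel[[s]] / mx
    }
  }
  attr(out, "binary") <- attr(panel, "binary", exact = TRUE)
  attr(out, "unit_scaled") <- TRUE
  out
}
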