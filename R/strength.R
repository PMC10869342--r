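# Node strength: the sum of absolute weights of a node's retained edges.

#' Node strength matrix
#'
#' For each gene and sample, the sum of absolute weights of the gene's
#' nonzero edges. The gene universe is every gene appearing in the network's
#' edge list; genes with no retained edges in a sample have strength 0.
#'
#' @param x Edge panel or aggregate network tibble.
#' @return For a panel, a tibble with `gene` plus one column per sample; for
#'   an aggregate network, a tibble with `gene` and `strength`. Carries the
#'   `unit_scaled` provenance flag of the input panel.
#' @export
node_strength <- function(x) {
  genes <- sort_genes(unique(c(x$gene_a, x$gene_b)))
  ia <- match(x$gene_a, genes)
  ib <- match(x$gene_b, genes)
  accumulate <- function(w) {
    aw <- abs(w)
    s <- numeric(length(genes))
    s_a <- rowsum(aw, ia)
    s_b <- rowsum(aw, ib)
    s[as.integer(rownames(s_a))] <- s_a[, 1]
    s[as.integer(rownames(s_b))] <- s[as.integer(rownames(s_b))] + s_b[, 1]
    s
  }
  if (is_aggregate(x)) {
    return(tibble::tibble(gene = genes, strength = accumulate(x$weight)))
  }
  samples <- panel_samples(x)
  m <- vapply(samples, function(s) accumulate(x[[s]]), numeric(length(genes)))
  out <- dplyr::bind_cols(
    tibble::tibble(gene = genes),
    tibble::as_tibble(m, .name_repair = "minimal")
  )
  attr(out, "unit_scaled") <- attr(x, "unit_scaled", exact = TRUE)
  out
}
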