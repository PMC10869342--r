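# Topology summaries of the unweighted, undirected graph of retained
# (nonzero) edges. Negative weights preclude a distance interpretation, so
# all metrics are computed on the binarized graph; the declared gene universe
# (all genes in the edge list) contributes isolated vertices to density and
# component counts.

#' Summarize network topology
#'
#' Per network: average local clustering coefficient (0 for nodes of degree
#' < 2), edge density over the declared gene universe (no loops), mean node
#' and edge betweenness, diameter of the largest connected component, number
#' of connected components (isolated nodes included), and node/edge counts.
#'
#' @param x Edge panel (one summary row per sample) or aggregate network
#'   tibble (a single row with `sample = "aggregate"`).
#' @return A tibble with columns `sample`, `n_nodes`, `n_edges`, `density`,
#'   `clustering`, `mean_node_betweenness`, `mean_edge_betweenness`,
#'   `diameter`, `n_components`.
#' @export
topology_summary <- function(x) {
  genes <- sort_genes(unique(c(x$gene_a, x$gene_b)))
  summarize_one <- function(w, label) {
    present <- w != 0
    g <- igraph::graph_from_data_frame(
      data.frame(from = x$gene_a[present], to = x$gene_b[present]),
      directed = FALSE,
      vertices = genes
    )
    n_edges <- sum(present)
    cl <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
    if (is.nan(cl)) cl <- 0
    btw_n <- igraph::betweenness(g, directed = FALSE)
    btw_e <- if (n_edges > 0) igraph::edge_betweenness(g, directed = FALSE) else numeric(0)
    tibble::tibble(
      sample = label,
      n_nodes = length(genes),
      n_edges = n_edges,
      density = igraph::edge_density(g, loops = FALSE),
      clustering = cl,
      mean_node_betweenness = mean(btw_n),
      mean_edge_betweenness = if (n_edges > 0) mean(btw_e) else NA_real_,
      diameter = igraph::diameter(g, directed = FALSE, unconnected = TRUE),
      n_components = igraph::components(g)$no
    )
  }
  if (is_aggregate(x)) {
    return(summarize_one(x$weight, "aggregate"))
  }
  dplyr::bind_rows(lapply(panel_samples(x), function(s) summarize_one(x[[s]], s)))
}
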