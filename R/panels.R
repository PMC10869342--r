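# Edge panels: tibble with columns gene_a, gene_b (gene_a < gene_b
# lexicographically, C collation) and one numeric weight column per sample.
# A weight of exactly 0 after top-k selection means "edge absent in this
# sample's network". Binary panels (CSN) carry attr(panel, "binary") = TRUE;
# attr(panel, "unit_scaled") records that weights were scaled into [-1, 1]
# (provenance for differential node strength).

new_edge_panel <- function(gene_a, gene_b, weights, samples,
                           binary = FALSE, unit_scaled = binary) {
  stopifnot(length(gene_a) == length(gene_b), nrow(weights) == length(gene_a))
  colnames(weights) <- samples
  out <- dplyr::bind_cols(
    tibble::tibble(gene_a = gene_a, gene_b = gene_b),
    tibble::as_tibble(weights, .name_repair = "minimal")
  )
  attr(out, "binary") <- binary
  attr(out, "unit_scaled") <- unit_scaled
  out
}

#' Is an edge panel binary (CSN-style)?
#' @param panel An edge panel.
#' @return Logical flag.
#' @export
is_binary_panel <- function(panel) isTRUE(attr(panel, "binary", exact = TRUE))

panel_samples <- function(panel) {
  setdiff(names(panel), c("gene_a", "gene_b", "weight"))
}

panel_weights <- function(panel) {
  m <- as.matrix(panel[, panel_samples(panel), drop = FALSE])
  storage.mode(m) <- "double"
  m
}

is_aggregate <- function(x) {
  is.data.frame(x) && identical(names(x), c("gene_a", "gene_b", "weight"))
}

# C-collation rank of strings (radix order is locale-independent)
c_rank <- function(...) {
  vals <- c(...)
  u <- sort(unique(vals), method = "radix")
  lapply(list(...), match, table = u)
}

# canonical unordered pair: gene_a < gene_b
canonical_pairs <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  r <- c_rank(a, b)
  swap <- r[[1]] > r[[2]]
  tibble::tibble(
    gene_a = ifelse(swap, b, a),
    gene_b = ifelse(swap, a, b)
  )
}

# row order by (gene_a, gene_b)
pair_order <- function(gene_a, gene_b) {
  r <- c_rank(gene_a, gene_b)
  order(r[[1]], r[[2]])
}

pair_key <- function(gene_a, gene_b) paste(gene_a, gene_b, sep = "\r")

sort_genes <- function(genes) sort(genes, method = "radix")

# upper-triangle edge index over sorted genes: gene_a, gene_b and the flat
# index into a p x p matrix whose rows/cols follow `genes_sorted`
edge_index <- function(genes_sorted) {
  p <- length(genes_sorted)
  idx <- which(upper.tri(matrix(0, p, p)))
  i <- ((idx - 1L) %% p) + 1L
  j <- ((idx - 1L) %/% p) + 1L
  list(gene_a = genes_sorted[i], gene_b = genes_sorted[j], flat = idx)
}
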