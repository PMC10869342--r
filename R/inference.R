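# The aggregate Pearson network and the six single-sample inference methods.
# All methods share the same conventions: the cohort itself is the reference
# (no normal-tissue samples), Pearson correlation is the underlying network
# model, and the output is an edge panel with one weight column per sample.

# genes-by-samples matrix with genes in C-collation order, so that the upper
# triangle of any gene-by-gene matrix enumerates canonical gene_a < gene_b
# pairs
prepare_infer_matrix <- function(X, min_samples = 3) {
  m <- if (is.matrix(X)) X else expr_matrix(X)
  if (ncol(m) < min_samples) {
    abort(paste0("need at least ", min_samples, " samples"))
  }
  m[sort_genes(rownames(m)), , drop = FALSE]
}

# gene-gene Pearson matrix with the constant-gene policy applied
cor_genes <- function(m, constant_gene_policy = "zero") {
  s <- apply(m, 1, sd)
  if (any(s == 0)) {
    if (constant_gene_policy == "error") {
      abort(paste0("constant gene(s): ",
                   paste(head(rownames(m)[s == 0], 5), collapse = ", ")))
    }
    inform(paste0(sum(s == 0), " constant gene(s); their correlations set to 0"))
  }
  cc <- suppressWarnings(cor(t(m)))
  cc[!is.finite(cc)] <- 0
  cc
}

#' Aggregate Pearson coexpression network
#'
#' All-pairs Pearson correlation across the full cohort: the population-level
#' network that the single-sample methods perturb or interpolate against.
#'
#' @param X Expression table (typically scaled log2-CPM) or genes-by-samples
#'   matrix with at least 3 samples.
#' @param constant_gene_policy `"zero"` assigns weight 0 to edges of constant
#'   genes (with a message); `"error"` aborts.
#' @return A tibble with columns `gene_a`, `gene_b`, `weight` covering every
#'   unordered gene pair.
#' @export
pcc_aggregate <- function(X, constant_gene_policy = c("zero", "error")) {
  constant_gene_policy <- match.arg(constant_gene_policy)
  m <- prepare_infer_matrix(X)
  cc <- cor_genes(m, constant_gene_policy)
  ei <- edge_index(rownames(m))
  tibble::tibble(gene_a = ei$gene_a, gene_b = ei$gene_b, weight = cc[ei$flat])
}

# full-cohort and leave-one-out correlation vectors over canonical edges:
# list(all = edges vector, loo = edges x samples matrix)
loo_correlations <- function(m, constant_gene_policy) {
  ei <- edge_index(rownames(m))
  all_ut <- cor_genes(m, constant_gene_policy)[ei$flat]
  loo <- matrix(0, length(ei$flat), ncol(m))
  for (q in seq_len(ncol(m))) {
    loo[, q] <- cor_genes(m[, -q, drop = FALSE], constant_gene_policy)[ei$flat]
  }
  list(index = ei, all = all_ut, loo = loo)
}

#' SSN: leave-one-out correlation perturbation
#'
#' For each sample q, the edge weight is the difference between the Pearson
#' correlation over the full cohort (reference plus the sample of interest)
#' and the correlation over the cohort with q removed (the reference):
#' `delta_pcc = pcc(all) - pcc(all minus q)`. No edge significance testing is
#' applied.
#'
#' @inheritParams pcc_aggregate
#' @param X Expression table or matrix with at least 4 samples.
#' @return An edge panel (edges x samples).
#' @export
ssn_panel <- function(X, constant_gene_policy = c("zero", "error")) {
  constant_gene_policy <- match.arg(constant_gene_policy)
  m <- prepare_infer_matrix(X, min_samples = 4)
  lc <- loo_correlations(m, constant_gene_policy)
  new_edge_panel(lc$index$gene_a, lc$index$gene_b,
                 lc$all - lc$loo, colnames(m))
}

#' LIONESS: linear interpolation of leave-one-out networks
#'
#' `e_q = N * (e_all - e_without_q) + e_without_q` with `N` the total sample
#' count: the per-sample network recovered from the identity that the
#' all-sample network is the average of the single-sample networks.
#'
#' @inheritParams ssn_panel
#' @return An edge panel (edges x samples).
#' @export
lioness_panel <- function(X, constant_gene_policy = c("zero", "error")) {
  constant_gene_policy <- match.arg(constant_gene_policy)
  m <- prepare_infer_matrix(X, min_samples = 4)
  n <- ncol(m)
  lc <- loo_correlations(m, constant_gene_policy)
  w <- n * (lc$all - lc$loo) + lc$loo
  new_edge_panel(lc$index$gene_a, lc$index$gene_b, w, colnames(m))
}

#' SWEET: sample-weighted interpolation with a duplicated-sample perturbation
#'
#' The perturbed network adds a copy of sample q's profile to the cohort
#' (`n + 1` columns); the genome-wide sample weight
#' `W_q = (mu_q - min mu + x) / (max mu - min mu + x)` rescales the
#' perturbation, where `mu_q` is the mean correlation between sample q's
#' expression profile and each other sample's profile. The edge weight is
#' `e_q = W_q * n * K * (e_plus_q - e_all) + e_all`. The original z-test edge
#' filter is not applied; use [select_top_edges()] instead.
#'
#' @inheritParams ssn_panel
#' @param sweet_x Stabilizing constant in the sample-weight formula
#'   (default 0.01).
#' @param sweet_k Balance parameter scaling the perturbation (default 0.1).
#' @return An edge panel (edges x samples) carrying the per-sample weights
#'   `W_q` as the `sample_weights` attribute.
#' @export
sweet_panel <- function(X, sweet_x = 0.01, sweet_k = 0.1,
                        constant_gene_policy = c("zero", "error")) {
  constant_gene_policy <- match.arg(constant_gene_policy)
  m <- prepare_infer_matrix(X, min_samples = 4)
  n <- ncol(m)
  ei <- edge_index(rownames(m))
  # sample-to-sample correlations across genes
  cs <- suppressWarnings(cor(m))
  cs[!is.finite(cs)] <- 0
  mu <- (rowSums(cs) - 1) / (n - 1)
  w_sample <- (mu - min(mu) + sweet_x) / (max(mu) - min(mu) + sweet_x)
  e_all <- cor_genes(m, constant_gene_policy)[ei$flat]
  w <- matrix(0, length(ei$flat), n)
  for (q in seq_len(n)) {
    e_plus <- cor_genes(cbind(m, m[, q]), constant_gene_policy)[ei$flat]
    w[, q] <- w_sample[q] * n * sweet_k * (e_plus - e_all) + e_all
  }
  out <- new_edge_panel(ei$gene_a, ei$gene_b, w, colnames(m))
  attr(out, "sample_weights") <- setNames(w_sample, colnames(m))
  out
}

#' iENA: single-sample correlation from reference moments
#'
#' With per-gene reference mean `mu_i` and population variance
#' `var_i = mean((x_i - mu_i)^2)` taken over the whole cohort, the
#' single-sample weight is the normalized cross-deviation
#' `w(i, j | q) = (x_iq - mu_i) * (x_jq - mu_j) / sqrt(var_i * var_j)`.
#' Averaging these weights over samples recovers the aggregate Pearson
#' correlation exactly.
#'
#' @inheritParams pcc_aggregate
#' @return An edge panel (edges x samples).
#' @export
iena_panel <- function(X, constant_gene_policy = c("zero", "error")) {
  constant_gene_policy <- match.arg(constant_gene_policy)
  m <- prepare_infer_matrix(X)
  ctr <- m - rowMeans(m)
  v <- rowMeans(ctr^2)
  if (any(v == 0)) {
    if (constant_gene_policy == "error") {
      abort(paste0("constant gene(s): ",
                   paste(head(rownames(m)[v == 0], 5), collapse = ", ")))
    }
    inform(paste0(sum(v == 0), " constant gene(s); their edge weights set to 0"))
  }
  z <- ctr / sqrt(ifelse(v == 0, 1, v))
  z[v == 0, ] <- 0
  ei <- edge_index(rownames(m))
  p <- nrow(m)
  i <- ((ei$flat - 1L) %% p) + 1L
  j <- ((ei$flat - 1L) %/% p) + 1L
  w <- z[i, , drop = FALSE] * z[j, , drop = FALSE]
  new_edge_panel(ei$gene_a, ei$gene_b, w, colnames(m))
}

#' CSN: binary cell/sample-specific networks from local neighborhoods
#'
#' For each gene and sample the marginal neighborhood is the
#' `k = round(box_fraction * n)` *other* samples whose expression of that
#' gene is nearest to the sample's value (distance ties broken by smaller
#' sample index). Excluding the sample itself keeps the two neighborhoods
#' independent under the null, so the overlap count is exactly
#' hypergeometric. For a gene pair the test statistic
#' `rho = n_ij/n - (n_i/n) * (n_j/n)` measures the excess overlap of the two
#' neighborhoods over the independence expectation. Under independence the
#' overlap count is hypergeometric with mean `n_i n_j / n` and variance
#' `n_i n_j (n - n_i)(n - n_j) / (n^2 (n - 1))`, so
#' `z = rho * n^2 * sqrt(n - 1) / sqrt(n_i n_j (n - n_i)(n - n_j))` is the
#' standardized statistic; an edge is present (weight 1) when `z` exceeds the
#' upper-`alpha` normal quantile.
#'
#' @inheritParams pcc_aggregate
#' @param box_fraction Neighborhood size as a fraction of the cohort
#'   (default 0.1).
#' @param alpha Upper-tail significance level for edge calls (default 0.01).
#' @return A binary edge panel (edges x samples).
#' @export
csn_panel <- function(X, box_fraction = 0.1, alpha = 0.01,
                      constant_gene_policy = c("zero", "error")) {
  constant_gene_policy <- match.arg(constant_gene_policy)
  stopifnot(box_fraction > 0, box_fraction < 0.5, alpha > 0, alpha < 1)
  m <- prepare_infer_matrix(X)
  n <- ncol(m)
  p <- nrow(m)
  k <- round(box_fraction * n)
  if (k < 2) abort("box_fraction * n must be at least 2 samples")
  # neighborhood indicator per gene: nb[[g]] is n x n logical, row s flags
  # the k other samples nearest to sample s in gene g's expression
  nb <- vector("list", p)
  for (g in seq_len(p)) {
    x <- m[g, ]
    d <- abs(outer(x, x, "-"))
    diag(d) <- Inf
    sel <- matrix(FALSE, n, n)
    for (s in seq_len(n)) {
      ord <- order(d[s, ], seq_len(n))
      sel[s, ord[seq_len(k)]] <- TRUE
    }
    nb[[g]] <- sel
  }
  z_cut <- qnorm(1 - alpha)
  # overlap counts per sample via one p x p cross-product per sample
  ei <- edge_index(rownames(m))
  i <- ((ei$flat - 1L) %% p) + 1L
  j <- ((ei$flat - 1L) %/% p) + 1L
  w <- matrix(0, length(ei$flat), n)
  scale_z <- n^2 * sqrt(n - 1) / (k * (n - k))
  for (s in seq_len(n)) {
    bs <- matrix(0, p, n)
    for (g in seq_len(p)) bs[g, ] <- nb[[g]][s, ]
    nij <- tcrossprod(bs)
    rho <- nij / n - (k / n)^2
    z <- rho * scale_z
    w[, s] <- as.numeric(z[ei$flat] > z_cut)
  }
  new_edge_panel(ei$gene_a, ei$gene_b, w, colnames(m), binary = TRUE)
}

#' SSPGI: rank-based edge perturbation against a background network
#'
#' Genes are ranked within each sample (ascending, average ranks). For each
#' background edge `(i, j)` the delta rank is `delta_es = r_is - r_js`, the
#' benchmark is the cohort mean `delta_bar_e`, and the panel weight is the
#' perturbation `Delta_es = delta_es - delta_bar_e`. Only background edges
#' whose genes both occur in the expression data appear in the panel.
#'
#' @inheritParams pcc_aggregate
#' @param background Background network tibble (`gene_a`, `gene_b`), e.g.
#'   from [read_background()].
#' @param emulate_cap Refuse to run above `cap` genes, mirroring the
#'   scalability ceiling of the original tool (default `FALSE`: no limit).
#' @param cap Gene-count ceiling enforced when `emulate_cap = TRUE`.
#' @return An edge panel (edges x samples) restricted to background edges.
#' @export
sspgi_panel <- function(X, background, emulate_cap = FALSE, cap = 7800) {
  m <- prepare_infer_matrix(X, min_samples = 2)
  if (emulate_cap && nrow(m) > cap) {
    abort(paste0("gene count ", nrow(m), " exceeds the emulated cap of ", cap,
                 "; reduce with select_hvg(max_genes = ", cap, ")"))
  }
  if (nrow(background) == 0) abort("empty background network")
  pairs <- canonical_pairs(background$gene_a, background$gene_b)
  pairs <- dplyr::distinct(pairs)
  present <- pairs$gene_a %in% rownames(m) & pairs$gene_b %in% rownames(m)
  if (!all(present)) {
    inform(paste0("dropped ", sum(!present),
                  " background edge(s) with gene(s) absent from expression"))
    pairs <- pairs[present, , drop = FALSE]
  }
  if (nrow(pairs) == 0) abort("no background edges left after gene matching")
  pairs <- pairs[pair_order(pairs$gene_a, pairs$gene_b), , drop = FALSE]
  r <- apply(m, 2, rank)
  delta <- r[pairs$gene_a, , drop = FALSE] - r[pairs$gene_b, , drop = FALSE]
  w <- delta - rowMeans(delta)
  new_edge_panel(pairs$gene_a, pairs$gene_b, w, colnames(m))
}

#' Run one of the single-sample inference methods by name
#'
#' @inheritParams pcc_aggregate
#' @param method One of `"ssn"`, `"lioness"`, `"sweet"`, `"iena"`, `"csn"`,
#'   `"sspgi"`, or `"aggregate"`.
#' @param background Background network (required for `"sspgi"`).
#' @param params Named list overriding method parameters (`sweet_x`,
#'   `sweet_k`, `csn_box_fraction`, `csn_alpha`, `sspgi_emulate_cap`,
#'   `sspgi_cap`, `constant_gene_policy`).
#' @return An edge panel, or an aggregate network tibble for
#'   `method = "aggregate"`.
#' @export
infer_panel <- function(X, method, background = NULL, params = list()) {
  methods <- c("ssn", "lioness", "sweet", "iena", "csn", "sspgi", "aggregate")
  if (!method %in% methods) {
    abort(paste0("unknown method '", method, "'; valid methods: ",
                 paste(methods, collapse = ", ")))
  }
  cgp <- params$constant_gene_policy %||% "zero"
  switch(method,
    aggregate = pcc_aggregate(X, constant_gene_policy = cgp),
    ssn = ssn_panel(X, constant_gene_policy = cgp),
    lioness = lioness_panel(X, constant_gene_policy = cgp),
    sweet = sweet_panel(X, sweet_x = params$sweet_x %||% 0.01,
                        sweet_k = params$sweet_k %||% 0.1,
                        constant_gene_policy = cgp),
    iena = iena_panel(X, constant_gene_policy = cgp),
    csn = csn_panel(X, box_fraction = params$csn_box_fraction %||% 0.1,
                    alpha = params$csn_alpha %||% 0.01,
                    constant_gene_policy = cgp),
    sspgi = {
      if (is.null(background)) abort("sspgi requires a background network")
      sspgi_panel(X, background,
                  emulate_cap = isTRUE(params$sspgi_emulate_cap),
                  cap = params$sspgi_cap %||% 7800)
    }
  )
}
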