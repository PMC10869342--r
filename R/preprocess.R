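# Expression preprocessing: CPM-based low-count filtering, log2-CPM
# normalization, highly-variable-gene selection, per-gene scaling, and
# cluster-based outlier-sample removal.

#' Filter genes by counts-per-million
#'
#' Keeps genes with CPM above `cpm_threshold` in at least
#' `min_samples_expressed` samples. Library sizes are the column sums of the
#' matrix *before* filtering, so repeated application is stable.
#'
#' @param counts Counts-stage expression table.
#' @param cpm_threshold CPM cutoff (default 1).
#' @param min_samples_expressed Minimum number of samples above the cutoff
#'   (default 1).
#' @return A counts-stage expression table with the retained genes.
#' @export
filter_low_counts <- function(counts, cpm_threshold = 1, min_samples_expressed = 1) {
  check_stage(counts, "counts")
  m <- expr_matrix(counts)
  lib <- colSums(m)
  zero <- lib == 0
  if (any(zero)) {
    abort(paste0("sample(s) with zero library size: ",
                 paste(colnames(m)[zero], collapse = ", ")))
  }
  cpm <- sweep(m, 2, lib, "/") * 1e6
  keep <- rowSums(cpm > cpm_threshold) >= min_samples_expressed
  expr_rebuild(m[keep, , drop = FALSE], "counts")
}

#' Log2-CPM normalization
#'
#' Converts counts to counts-per-million and applies
#' `log2(cpm + pseudocount)`. The default pseudocount of 0.5 avoids minus
#' infinity at zero counts while perturbing expressed genes little.
#'
#' @param counts Counts-stage expression table.
#' @param pseudocount Value added to CPM before taking log2 (default 0.5).
#' @return A logcpm-stage expression table.
#' @export
normalize_log_cpm <- function(counts, pseudocount = 0.5) {
  check_stage(counts, "counts")
  m <- expr_matrix(counts)
  if (any(m < 0)) abort("negative counts in counts-stage input")
  lib <- colSums(m)
  zero <- lib == 0
  if (any(zero)) {
    abort(paste0("sample(s) with zero library size: ",
                 paste(colnames(m)[zero], collapse = ", ")))
  }
  cpm <- sweep(m, 2, lib, "/") * 1e6
  expr_rebuild(log2(cpm + pseudocount), "logcpm")
}

#' Select highly variable genes
#'
#' Keeps genes whose cross-sample variance (n - 1 denominator) strictly
#' exceeds `threshold`. With `max_genes` set, at most the top-variance
#' `max_genes` genes are retained (this emulates tools with a hard gene cap).
#'
#' @param logcpm Logcpm-stage expression table with at least 2 samples.
#' @param threshold Variance threshold (default 2.75).
#' @param max_genes Optional cap on the number of genes kept.
#' @return A logcpm-stage expression table restricted to the HVGs.
#' @export
select_hvg <- function(logcpm, threshold = 2.75, max_genes = NULL) {
  check_stage(logcpm, "logcpm")
  if (threshold < 0) abort("hvg variance threshold must be non-negative")
  m <- expr_matrix(logcpm)
  if (ncol(m) < 2) abort("variance needs at least 2 samples")
  v <- row_vars(m)
  keep <- which(v > threshold)
  if (!is.null(max_genes) && length(keep) > max_genes) {
    keep <- keep[order(v[keep], decreasing = TRUE)[seq_len(max_genes)]]
    keep <- sort(keep)
  }
  expr_rebuild(m[keep, , drop = FALSE], "logcpm")
}

#' Center and scale each gene
#'
#' Each gene row is transformed to mean 0 and sample standard deviation 1
#' (n - 1 denominator). Constant genes are an error; run [select_hvg()] with a
#' positive threshold first.
#'
#' @param x Logcpm-stage (or scaled-stage, for idempotence) expression table.
#' @return A scaled-stage expression table.
#' @export
scale_genes <- function(x) {
  m <- expr_matrix(x)
  s <- apply(m, 1, sd)
  if (any(s == 0)) {
    abort(paste0("constant gene(s) cannot be scaled: ",
                 paste(head(rownames(m)[s == 0], 5), collapse = ", ")))
  }
  expr_rebuild((m - rowMeans(m)) / s, "scaled")
}

#' Remove outlier samples by correlation clustering
#'
#' Samples are clustered by average-linkage agglomeration on the distance
#' `1 - Spearman correlation` between expression profiles; the tree is cut at
#' `cut_height_fraction` of its maximum merge height and clusters smaller
#' than `min_cluster_size` are dropped.
#'
#' @param x Expression table (any stage).
#' @param cut_height_fraction Fraction of the maximum merge height at which
#'   the tree is cut (default 0.95).
#' @param min_cluster_size Minimum cluster size to retain (default 3).
#' @return A list with `expression` (retained samples, same stage) and
#'   `removed` (character vector of dropped sample ids).
#' @export
remove_outlier_samples <- function(x, cut_height_fraction = 0.95,
                                   min_cluster_size = 3) {
  stopifnot(cut_height_fraction > 0, cut_height_fraction <= 1,
            min_cluster_size >= 1)
  m <- expr_matrix(x)
  if (ncol(m) < 2) abort("need at least 2 samples to cluster")
  d <- as.dist(1 - cor(m, method = "spearman"))
  hc <- hclust(d, method = "average")
  cl <- cutree(hc, h = cut_height_fraction * max(hc$height))
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_cluster_size]
  retained <- names(cl)[cl %in% keep]
  if (length(retained) == 0) {
    abort("all samples removed by outlier clustering; lower min_cluster_size")
  }
  removed <- setdiff(colnames(m), retained)
  list(
    expression = expr_rebuild(m[, retained, drop = FALSE],
                              expr_stage(x) %||% "logcpm"),
    removed = removed
  )
}

#' Two-group moderated differential test
#'
#' Fits a per-feature two-group comparison with an empirical-Bayes moderated
#' t-statistic (see [moderated_t_engine()]) and flags features passing both
#' the adjusted-p and effect-size cutoffs. For expression input the effect is
#' a log2 fold change; for node strengths it is the raw group-mean difference
#' on the same scale as the input.
#'
#' @param x Expression table, node-strength table, or features-by-samples
#'   numeric matrix.
#' @param groups Two-group sample labels: a `sample`/`group` data frame or a
#'   named vector.
#' @param p_cut Adjusted-p cutoff for the significance flag (default 0.05).
#' @param effect_cut Absolute effect cutoff (default 1).
#' @param d0_override Optional forced prior degrees of freedom (0 disables
#'   moderation; `Inf` forces complete shrinkage).
#' @return A tibble with `feature`, `effect`, `t`, `df_total`, `p`, `padj`,
#'   `significant`. The effect is `mean(group1) - mean(group2)` with group1
#'   the first level in sorted label order.
#' @export
moderated_differential <- function(x, groups, p_cut = 0.05, effect_cut = 1,
                                   d0_override = NULL) {
  m <- if (is.matrix(x)) x else expr_matrix(x)
  fit <- moderated_t_engine(m, groups, d0_override = d0_override)
  fit$padj <- bh_adjust(fit$p)
  fit$significant <- fit$padj <= p_cut & abs(fit$effect) >= effect_cut
  fit
}

check_stage <- function(x, expected) {
  st <- expr_stage(x)
  if (!is.null(st) && !identical(st, expected)) {
    abort(paste0("expected ", expected, "-stage expression, got ", st))
  }
  invisible(x)
}

row_vars <- function(m) {
  ctr <- m - rowMeans(m)
  rowSums(ctr^2) / (ncol(m) - 1)
}
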