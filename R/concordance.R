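# Concordance of node strengths with matched per-sample omics
# (proteomics, copy number).

#' Correlate node strengths with matched omics per sample
#'
#' For each sample shared between the strength matrix and the omics matrix,
#' computes the Pearson correlation across shared genes, excluding missing
#' omics entries pairwise. For an aggregate network (single `strength`
#' column) the same strength vector is correlated against every omics
#' sample.
#'
#' @param strengths Node-strength table from [node_strength()]; either a
#'   per-sample matrix or an aggregate `gene`/`strength` table.
#' @param omics Omics table from [read_omics()] (gene + sample columns,
#'   missing values allowed).
#' @param method Label recorded in the output `method` column (default
#'   `"single_sample"`, or `"aggregate"` when an aggregate strength table is
#'   supplied).
#' @param min_genes Minimum number of complete gene pairs for a reported
#'   correlation (default 3).
#' @param exclude_zero_strength Drop genes with strength exactly 0 from the
#'   correlation (default `FALSE`: absent genes participate with strength 0).
#' @return A tibble with `method`, `sample`, `r`, `n_genes`, `modality`.
#' @export
match_and_correlate <- function(strengths, omics, method = NULL,
                                min_genes = 3, exclude_zero_strength = FALSE) {
  modality <- attr(omics, "modality", exact = TRUE) %||% "omics"
  aggregate_mode <- identical(names(strengths), c("gene", "strength"))
  if (is.null(method)) method <- if (aggregate_mode) "aggregate" else "single_sample"
  shared_genes <- intersect(strengths$gene, omics$gene)
  if (length(shared_genes) < min_genes) {
    abort(paste0("fewer than ", min_genes, " shared genes"))
  }
  s_idx <- match(shared_genes, strengths$gene)
  o_idx <- match(shared_genes, omics$gene)
  omics_samples <- setdiff(names(omics), "gene")
  shared_samples <- if (aggregate_mode) {
    omics_samples
  } else {
    intersect(setdiff(names(strengths), "gene"), omics_samples)
  }
  if (length(shared_samples) == 0) abort("no shared samples")
  rows <- lapply(shared_samples, function(smp) {
    sv <- if (aggregate_mode) strengths$strength[s_idx] else strengths[[smp]][s_idx]
    ov <- omics[[smp]][o_idx]
    ok <- !is.na(ov)
    if (exclude_zero_strength) ok <- ok & sv != 0
    if (sum(ok) < min_genes) {
      return(tibble::tibble(method = method, sample = smp, r = NA_real_,
                            n_genes = sum(ok), modality = modality))
    }
    tibble::tibble(
      method = method, sample = smp,
      r = cor(sv[ok], ov[ok]),
      n_genes = sum(ok), modality = modality
    )
  })
  dplyr::bind_rows(rows)
}

#' Compare omics concordance across methods
#'
#' Kruskal-Wallis test with Dunn post hoc comparisons over the per-sample
#' correlation coefficients grouped by method; for each method-vs-aggregate
#' pair the adjusted p and the sign of the mean difference are reported.
#'
#' @param concordance Row-bound [match_and_correlate()] tables for two or
#'   more methods (including, typically, the aggregate baseline).
#' @param reference Method name to contrast every other method against in
#'   the `vs_reference` summary (default `"aggregate"`; skipped if absent).
#' @return A list of class `"concordance_comparison"`: the `kruskal_dunn`
#'   object plus `vs_reference`, a tibble with `method`, `mean_r`,
#'   `mean_diff`, `z`, `padj`.
#' @export
compare_concordance <- function(concordance, reference = "aggregate") {
  keep <- !is.na(concordance$r)
  kd <- kruskal_dunn(concordance$r[keep], concordance$method[keep])
  means <- tapply(concordance$r[keep], concordance$method[keep], mean)
  vs_ref <- NULL
  if (reference %in% names(means)) {
    pw <- kd$pairwise
    sel <- pw$group1 == reference | pw$group2 == reference
    pw <- pw[sel, , drop = FALSE]
    other <- ifelse(pw$group1 == reference, pw$group2, pw$group1)
    flip <- ifelse(pw$group1 == reference, -1, 1)
    vs_ref <- tibble::tibble(
      method = other,
      mean_r = unname(means[other]),
      mean_diff = unname(means[other] - means[reference]),
      z = flip * pw$z,
      padj = pw$padj
    )
  }
  out <- list(test = kd, means = means, vs_reference = vs_ref)
  class(out) <- "concordance_comparison"
  out
}

#' @export
print.concordance_comparison <- function(x, ...) {
  print(x$test)
  if (!is.null(x$vs_reference)) {
    cat("\nversus aggregate baseline:\n")
    print(x$vs_reference)
  }
  invisible(x)
}
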