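# Hypergeometric over-representation and Kruskal-Wallis with Dunn post hoc.

#' Hypergeometric gene-set enrichment
#'
#' One-sided over-representation test: the probability of observing at least
#' the given overlap between `hits` and `target` when `hits` are drawn
#' without replacement from `universe`. The target set is intersected with
#' the universe before testing.
#'
#' @param hits Character vector of selected genes (must lie in `universe`).
#' @param target Character vector of the gene set tested for enrichment.
#' @param universe Character vector of all eligible genes (the background).
#' @return A one-row tibble: `overlap_count`, `set_size` (target within
#'   universe), `draw_size`, `universe_size`, `p`, and `overlap_genes`
#'   (list-column).
#' @export
hypergeometric_enrichment <- function(hits, target, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("empty universe")
  hits <- unique(hits)
  outside <- setdiff(hits, universe)
  if (length(outside) > 0) {
    abort(paste0("hits outside the universe: ",
                 paste(head(outside, 5), collapse = ", ")))
  }
  target_u <- intersect(unique(target), universe)
  if (length(target_u) == 0) abort("empty target after intersection with universe")
  overlap <- intersect(hits, target_u)
  k <- length(overlap)
  # exact upper tail P(X >= k), X ~ Hypergeom(universe, target_u, hits)
  p <- phyper(k - 1, m = length(target_u),
              n = length(universe) - length(target_u),
              k = length(hits), lower.tail = FALSE)
  tibble::tibble(
    overlap_count = k,
    set_size = length(target_u),
    draw_size = length(hits),
    universe_size = length(universe),
    p = p,
    overlap_genes = list(sort_genes(overlap))
  )
}

#' Kruskal-Wallis test with Dunn post hoc comparisons
#'
#' Global rank test across `>= 2` groups (tie-corrected H) followed by Dunn's
#' pairwise z-tests on mean ranks, two-sided, with multiple-testing
#' adjustment across pairs.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length as `values`; every group needs at
#'   least 2 members.
#' @param p_adjust_method Adjustment for the pairwise p-values (default
#'   `"BH"`).
#' @return An object of class `"kruskal_dunn"`: a list with `h`, `df`, `p`
#'   (global test) and `pairwise`, a tibble with `group1`, `group2`, `z`,
#'   `p`, `padj`, `mean_rank_diff`.
#' @export
kruskal_dunn <- function(values, groups, p_adjust_method = "BH") {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]
  groups <- groups[ok]
  sizes <- table(groups)
  if (length(sizes) < 2) abort("need at least 2 groups")
  if (any(sizes < 2)) {
    abort(paste0("group(s) with < 2 members: ",
                 paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  kw <- kruskal.test(values, factor(groups))

  n <- length(values)
  r <- rank(values)
  mean_ranks <- tapply(r, groups, mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties)
  # Dunn's variance with tie correction
  sigma2_base <- n * (n + 1) / 12 - tie_term / (12 * (n - 1))
  lv <- sort_genes(names(sizes))
  pairs <- combn(lv, 2)
  z <- p_raw <- diffs <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]
    b <- pairs[2, i]
    se <- sqrt(sigma2_base * (1 / sizes[[a]] + 1 / sizes[[b]]))
    diffs[i] <- mean_ranks[[a]] - mean_ranks[[b]]
    z[i] <- diffs[i] / se
    p_raw[i] <- 2 * pnorm(-abs(z[i]))
  }
  out <- list(
    h = unname(kw$statistic),
    df = unname(kw$parameter),
    p = kw$p.value,
    pairwise = tibble::tibble(
      group1 = pairs[1, ], group2 = pairs[2, ],
      z = z, p = p_raw,
      padj = p.adjust(p_raw, method = p_adjust_method),
      mean_rank_diff = diffs
    ),
    p_adjust_method = p_adjust_method,
    group_sizes = as.integer(sizes)
  )
  class(out) <- "kruskal_dunn"
  out
}

#' @export
print.kruskal_dunn <- function(x, ...) {
  cat("Kruskal-Wallis: H =", format(x$h, digits = 4),
      "df =", x$df, "p =", format.pval(x$p, digits = 3), "\n")
  cat("Dunn post hoc (", x$p_adjust_method, "-adjusted):\n", sep = "")
  print(x$pairwise, ...)
  invisible(x)
}

#' @describeIn kruskal_dunn Pairwise Dunn comparisons as a tibble.
#' @param x A `kruskal_dunn` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.kruskal_dunn <- function(x, ...) x$pairwise

#' @describeIn kruskal_dunn One-row summary of the global test.
#' @exportS3Method generics::glance
glance.kruskal_dunn <- function(x, ...) {
  tibble::tibble(h = x$h, df = x$df, p = x$p,
                 n_groups = length(x$group_sizes), n = sum(x$group_sizes))
}
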