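# Hub identification, recurrence across sample groups, subtype-specific
# hubs, and driver-gene enrichment.

#' Identify hub genes per network
#'
#' Hubs are the `hub_n` most connected nodes of each network: nodes ranked
#' by degree (count of nonzero incident edges) descending, ties broken by
#' node strength descending and then gene id ascending. Only nodes with at
#' least one retained edge are eligible.
#'
#' @param x Edge panel or aggregate network tibble.
#' @param hub_n Number of hubs per network (default 200).
#' @return A tibble with `sample`, `rank`, `gene`, `degree`, `strength`
#'   (`sample = "aggregate"` for an aggregate network).
#' @export
identify_hubs <- function(x, hub_n = 200) {
  stopifnot(hub_n >= 1)
  genes <- sort_genes(unique(c(x$gene_a, x$gene_b)))
  ia <- match(x$gene_a, genes)
  ib <- match(x$gene_b, genes)
  hub_one <- function(w, label) {
    present <- w != 0
    deg <- tabulate(c(ia[present], ib[present]), nbins = length(genes))
    stren <- numeric(length(genes))
    aw <- abs(w[present])
    sa <- rowsum(aw, ia[present])
    sb <- rowsum(aw, ib[present])
    stren[as.integer(rownames(sa))] <- sa[, 1]
    stren[as.integer(rownames(sb))] <- stren[as.integer(rownames(sb))] + sb[, 1]
    eligible <- which(deg >= 1)
    ord <- eligible[order(-deg[eligible], -stren[eligible], eligible)]
    take <- head(ord, hub_n)
    tibble::tibble(
      sample = label,
      rank = seq_along(take),
      gene = genes[take],
      degree = deg[take],
      strength = stren[take]
    )
  }
  if (is_aggregate(x)) {
    return(hub_one(x$weight, "aggregate"))
  }
  dplyr::bind_rows(lapply(panel_samples(x), function(s) hub_one(x[[s]], s)))
}

#' Hub recurrence within sample groups
#'
#' Counts, for each gene and group, in how many of the group's networks the
#' gene appears as a hub. A hub is "regularly recurring" when it occurs in at
#' least `ceiling(recurrence_fraction * group size)` of the group's networks.
#'
#' @param hubs Hub table from [identify_hubs()].
#' @param groups Sample-group labels (`sample`/`group` data frame or named
#'   vector) covering every sample in `hubs`.
#' @param recurrence_fraction Fraction of a group's networks a hub must
#'   occur in to count as regularly recurring (default 0.75).
#' @return A tibble with `group`, `gene`, `count`, `fraction`,
#'   `regularly_recurring`.
#' @export
hub_recurrence <- function(hubs, groups, recurrence_fraction = 0.75) {
  samples <- unique(hubs$sample)
  g <- group_vector(groups)
  unlabeled <- setdiff(samples, names(g))
  if (length(unlabeled) > 0) {
    abort(paste0("unlabeled sample(s): ", paste(head(unlabeled, 5), collapse = ", ")))
  }
  sizes <- table(g[samples])
  hubs |>
    dplyr::mutate(group = unname(g[.data$sample])) |>
    dplyr::distinct(.data$group, .data$sample, .data$gene) |>
    dplyr::count(.data$group, .data$gene, name = "count") |>
    dplyr::mutate(
      group_size = as.integer(sizes[.data$group]),
      fraction = .data$count / .data$group_size,
      regularly_recurring =
        .data$count >= ceiling(recurrence_fraction * .data$group_size)
    ) |>
    dplyr::select(-"group_size") |>
    dplyr::arrange(.data$group, dplyr::desc(.data$count), .data$gene)
}

#' Subtype-specific regularly recurring hubs
#'
#' For each group, the regularly recurring hubs that are not regularly
#' recurring in any other group.
#'
#' @param recurrence Recurrence table from [hub_recurrence()].
#' @return A tibble with `group` and `gene`, one row per specific hub.
#' @export
subtype_specific_hubs <- function(recurrence) {
  regular <- recurrence[recurrence$regularly_recurring, c("group", "gene")]
  groups <- unique(recurrence$group)
  out <- lapply(groups, function(gp) {
    own <- regular$gene[regular$group == gp]
    other <- regular$gene[regular$group != gp]
    tibble::tibble(group = gp, gene = sort_genes(setdiff(own, other)))
  })
  dplyr::bind_rows(out)
}

#' Driver-gene enrichment of group hub sets
#'
#' Concatenates (unions) the hub lists of each group's networks and tests
#' the union for over-representation of the driver set against the network
#' gene universe with the exact hypergeometric tail.
#'
#' @param hubs Hub table from [identify_hubs()].
#' @param groups Sample-group labels.
#' @param drivers Character vector of driver genes.
#' @param universe Character vector of all genes in the network (the
#'   enrichment background).
#' @return A tibble with one row per group: the enrichment fields of
#'   [hypergeometric_enrichment()] plus `group`.
#' @export
driver_enrichment <- function(hubs, groups, drivers, universe) {
  g <- group_vector(groups)
  hubs <- dplyr::mutate(hubs, group = unname(g[.data$sample]))
  out <- lapply(sort_genes(unique(hubs$group)), function(gp) {
    hit_union <- intersect(unique(hubs$gene[hubs$group == gp]), universe)
    if (length(hit_union) == 0) abort(paste0("empty hub union for group ", gp))
    res <- hypergeometric_enrichment(hit_union, drivers, universe)
    dplyr::bind_cols(tibble::tibble(group = gp), res)
  })
  dplyr::bind_rows(out)
}

#' Differential node strength between two sample groups
#'
#' Applies the moderated two-group test to a node-strength matrix computed
#' from unit-scaled panels. Scaling edge weights into `[-1, 1]` first (see
#' [scale_weights_unit()]) makes strengths comparable across samples; the
#' provenance flag set by that function is checked here. The effect column
#' is the raw strength difference between group means (reported on the
#' LFC-compatible scale used for significance flags).
#'
#' @param strengths Node-strength table from [node_strength()] on a
#'   unit-scaled panel.
#' @param groups Two-group sample labels.
#' @param p_cut Adjusted-p cutoff (default 0.05).
#' @param effect_cut Absolute effect cutoff (default 1).
#' @param check_scaled Set `FALSE` to skip the unit-scaled provenance check.
#' @return A tibble as returned by [moderated_differential()].
#' @export
differential_node_strength <- function(strengths, groups, p_cut = 0.05,
                                       effect_cut = 1, check_scaled = TRUE) {
  if (check_scaled && !isTRUE(attr(strengths, "unit_scaled", exact = TRUE))) {
    abort(paste0(
      "strengths were not computed from a unit-scaled panel; ",
      "run scale_weights_unit() before node_strength(), ",
      "or pass check_scaled = FALSE"
    ))
  }
  m <- as.matrix(strengths[, -1, drop = FALSE])
  rownames(m) <- strengths$gene
  moderated_differential(m, groups, p_cut = p_cut, effect_cut = effect_cut)
}
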