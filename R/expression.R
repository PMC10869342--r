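# Expression tables: tibble with a `gene` column plus one numeric column per
# sample. The processing stage ("counts", "logcpm", "scaled") travels as the
# "stage" attribute so downstream verbs can check their preconditions.

#' Build an expression table
#'
#' Wraps a genes-by-samples numeric matrix (or a data frame with a `gene`
#' column) into the tibble layout used throughout the package: one row per
#' gene, one numeric column per sample, plus a `stage` attribute recording
#' whether values are raw counts, log2-CPM, or per-gene scaled values.
#'
#' @param x A numeric matrix with gene row names and sample column names, or a
#'   data frame whose first column holds gene identifiers.
#' @param stage One of `"counts"`, `"logcpm"`, `"scaled"`.
#' @return A tibble with columns `gene` and one column per sample.
#' @export
as_expression <- function(x, stage = c("counts", "logcpm", "scaled")) {
  stage <- match.arg(stage)
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      abort("expression matrix needs gene row names and sample column names")
    }
    tbl <- tibble::as_tibble(x, .name_repair = "minimal")
    tbl <- dplyr::bind_cols(tibble::tibble(gene = rownames(x)), tbl)
  } else {
    tbl <- tibble::as_tibble(x, .name_repair = "minimal")
    names(tbl)[1] <- "gene"
    tbl$gene <- as.character(tbl$gene)
  }
  validate_expression(tbl, stage)
  attr(tbl, "stage") <- stage
  tbl
}

#' Processing stage of an expression table
#' @param x An expression table created by [as_expression()] or a reader.
#' @return `"counts"`, `"logcpm"` or `"scaled"` (or `NULL` if untagged).
#' @export
expr_stage <- function(x) attr(x, "stage", exact = TRUE)

# genes-by-samples numeric matrix from an expression table
expr_matrix <- function(x) {
  stopifnot(is.data.frame(x), names(x)[1] == "gene")
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$gene
  m
}

# rebuild an expression tibble from a matrix, tagging the stage
expr_rebuild <- function(m, stage) {
  out <- dplyr::bind_cols(
    tibble::tibble(gene = rownames(m)),
    tibble::as_tibble(m, .name_repair = "minimal")
  )
  attr(out, "stage") <- stage
  out
}

validate_expression <- function(tbl, stage) {
  if (nrow(tbl) == 0L) abort("no data rows in expression input")
  if (ncol(tbl) < 2L) abort("expression input has no sample columns")
  dup_g <- unique(tbl$gene[duplicated(tbl$gene)])
  if (length(dup_g) > 0) {
    abort(paste0(
      "duplicate gene identifiers: ",
      paste(head(dup_g, 5), collapse = ", ")
    ))
  }
  samples <- names(tbl)[-1]
  if (anyDuplicated(samples)) {
    abort(paste0(
      "duplicate sample identifiers: ",
      paste(unique(samples[duplicated(samples)]), collapse = ", ")
    ))
  }
  m <- as.matrix(tbl[, -1, drop = FALSE])
  if (!is.numeric(m)) abort("non-numeric expression values")
  if (any(!is.finite(m))) abort("expression values must be finite")
  if (stage == "counts" && any(m < 0)) {
    abort("counts-stage expression values must be non-negative")
  }
  invisible(tbl)
}

# sample-group labels as a named character vector (sample -> group),
# accepting a two-column data frame (sample, group) or a named vector
group_vector <- function(groups, samples = NULL) {
  if (is.data.frame(groups)) {
    stopifnot(ncol(groups) >= 2)
    g <- setNames(as.character(groups[[2]]), as.character(groups[[1]]))
  } else {
    if (is.null(names(groups))) abort("groups must be named by sample id")
    g <- setNames(as.character(groups), names(groups))
  }
  if (!is.null(samples)) {
    missing <- setdiff(names(g), samples)
    if (length(missing) > 0) {
      abort(paste0(
        "labeled samples absent from the data: ",
        paste(head(missing, 5), collapse = ", ")
      ))
    }
    g <- g[intersect(samples, names(g))]
  }
  g
}
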