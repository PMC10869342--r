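# Readers and writers for the plain-text formats used throughout:
# genes-by-samples TSVs (expression, omics), HumanNet-style background edge
# lists, sample-group tables, gene sets (one-per-line or GMT), and the
# edges-by-samples panel TSV shared by all six inference methods.

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}

#' Read a genes-by-samples expression TSV
#'
#' Expects a header row of sample identifiers and gene identifiers in the
#' first column. Values must be finite; at the counts stage they must also be
#' non-negative. Duplicate gene or sample identifiers are an error.
#'
#' @param path Path to a tab-separated file.
#' @param stage Processing stage of the values: `"counts"` (raw counts),
#'   `"logcpm"` or `"scaled"`.
#' @return An expression table (see [as_expression()]).
#' @export
read_expression <- function(path, stage = c("counts", "logcpm", "scaled")) {
  stage <- match.arg(stage)
  tbl <- tryCatch(
    suppressWarnings(read_tsv_quiet(
      path,
      col_types = readr::cols(
        readr::col_character(),
        .default = readr::col_double()
      ),
      name_repair = "minimal"
    )),
    error = function(e) abort(paste0("cannot parse ", path, ": ", conditionMessage(e)))
  )
  if (nrow(tbl) == 0L) abort(paste0("no data rows in ", path))
  prob <- readr::problems(tbl)
  if (nrow(prob) > 0) {
    abort(paste0(
      "malformed numeric cell in ", path, " at row ", prob$row[1],
      ", column ", prob$col[1]
    ))
  }
  as_expression(tbl, stage = stage)
}

#' Write an expression table to TSV
#' @param x Expression table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read a background functional gene network
#'
#' Accepts HumanNet-style 2- or 3-column TSVs (`gene_a`, `gene_b`, optional
#' score), with or without a header. Pairs are canonicalized so that
#' `gene_a < gene_b`, self-loops are dropped (with a message), and duplicate
#' pairs are collapsed keeping the maximum score.
#'
#' @param path Path to the edge-list TSV.
#' @return A tibble with columns `gene_a`, `gene_b` and, when present in the
#'   input, `score`.
#' @export
read_background <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  if (length(first) == 0L) abort(paste0("no data rows in ", path))
  fields <- strsplit(first, "\t", fixed = TRUE)[[1]]
  has_header <- any(tolower(fields) %in%
                      c("gene_a", "gene_b", "gene1", "gene2", "score", "weight"))
  tbl <- read_tsv_quiet(path, col_names = has_header,
                        col_types = readr::cols(.default = readr::col_guess()))
  if (!has_header) names(tbl) <- c("gene_a", "gene_b", "score")[seq_len(ncol(tbl))]
  if (ncol(tbl) < 2) abort("background network needs at least 2 columns (gene_a, gene_b)")
  background_from_frame(tbl)
}

# canonicalize a raw edge frame into a background network tibble
background_from_frame <- function(tbl) {
  a <- as.character(tbl[[1]])
  b <- as.character(tbl[[2]])
  score <- if (ncol(tbl) >= 3) as.numeric(tbl[[3]]) else NULL
  loops <- a == b
  if (any(loops)) {
    inform(paste0("dropped ", sum(loops), " self-loop(s) from background network"))
    a <- a[!loops]
    b <- b[!loops]
    if (!is.null(score)) score <- score[!loops]
  }
  pairs <- canonical_pairs(a, b)
  out <- if (is.null(score)) {
    dplyr::distinct(pairs)
  } else {
    dplyr::summarise(
      dplyr::group_by(dplyr::mutate(pairs, score = score), .data$gene_a, .data$gene_b),
      score = max(.data$score),
      .groups = "drop"
    )
  }
  out[pair_order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Read sample-group labels
#'
#' @param path Two-column TSV (`sample`, `group`), with or without a header.
#' @return A tibble with columns `sample` and `group`.
#' @export
read_groups <- function(path) {
  first <- strsplit(readr::read_lines(path, n_max = 1), "\t")[[1]]
  has_header <- length(first) >= 2 && tolower(first[1]) %in% c("sample", "sample_id")
  tbl <- if (has_header) read_tsv_quiet(path) else read_tsv_quiet(path, col_names = FALSE)
  if (ncol(tbl) < 2) abort("group file needs 2 columns (sample, group)")
  tibble::tibble(sample = as.character(tbl[[1]]), group = as.character(tbl[[2]]))
}

#' Read gene sets from a plain list or GMT file
#'
#' A plain file (one gene per line) yields a single set named after the file;
#' a GMT file (set name, description, then genes, tab-separated) yields one
#' set per line.
#'
#' @param path Path to the gene-set file.
#' @return A named list of character vectors.
#' @export
read_gene_set <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(paste0("no data rows in ", path))
  if (any(grepl("\t", lines))) {
    sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
      genes <- unique(f[-c(1, 2)])
      genes[nzchar(genes)]
    })
    names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1)
    empty <- lengths(sets) == 0
    if (any(empty)) abort(paste0("empty gene set: ", names(sets)[empty][1]))
    sets
  } else {
    set <- list(unique(trimws(lines)))
    names(set) <- sub("\\.[^.]*$", "", basename(path))
    set
  }
}

#' Read a genes-by-samples omics matrix (proteomics or copy number)
#'
#' Duplicate gene rows are removed keeping the first occurrence; missing
#' values are allowed and are excluded pairwise at correlation time.
#'
#' @param path Path to the TSV (header of sample ids, gene ids in column 1).
#' @param modality `"proteomics"` or `"cnv"`.
#' @return A tibble with columns `gene` and one per sample, plus a
#'   `modality` attribute.
#' @export
read_omics <- function(path, modality = c("proteomics", "cnv")) {
  modality <- match.arg(modality)
  tbl <- read_tsv_quiet(path, col_types = readr::cols(
    readr::col_character(),
    .default = readr::col_double()
  ))
  if (nrow(tbl) == 0L) abort(paste0("no data rows in ", path))
  names(tbl)[1] <- "gene"
  dup <- duplicated(tbl$gene)
  if (any(dup)) {
    inform(paste0("removed ", sum(dup), " duplicate gene row(s) from ", modality))
    tbl <- tbl[!dup, , drop = FALSE]
  }
  attr(tbl, "modality") <- modality
  tbl
}

#' Write an edge panel as an edges-by-samples TSV
#'
#' The first column is the edge identifier `geneA<sep>geneB`; remaining
#' columns are per-sample weights. Binary panels are written as 0/1 integers.
#'
#' @param panel Edge panel.
#' @param path Output path.
#' @param sep Separator used inside the edge identifier (default `"_"`). An
#'   error is raised when a gene name already contains `sep`, since the file
#'   could then not be read back unambiguously.
#' @return `path`, invisibly.
#' @export
write_edge_panel <- function(panel, path, sep = "_") {
  genes <- unique(c(panel$gene_a, panel$gene_b))
  offending <- genes[grepl(sep, genes, fixed = TRUE)]
  if (length(offending) > 0) {
    abort(paste0(
      "gene name(s) contain the edge-id separator '", sep, "': ",
      paste(head(offending, 3), collapse = ", "),
      "; pass a custom `sep` not used in gene names"
    ))
  }
  out <- dplyr::bind_cols(
    tibble::tibble(edge = paste(panel$gene_a, panel$gene_b, sep = sep)),
    panel[, panel_samples(panel), drop = FALSE]
  )
  if (is_binary_panel(panel)) {
    out <- dplyr::mutate(out, dplyr::across(-"edge", as.integer))
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read an edge panel written by [write_edge_panel()]
#'
#' @param path Path to the panel TSV.
#' @param sep Edge-identifier separator used when writing.
#' @param binary Set `TRUE` to tag the result as a binary (CSN) panel.
#' @return An edge panel tibble.
#' @export
read_edge_panel <- function(path, sep = "_", binary = NULL) {
  tbl <- read_tsv_quiet(path, col_types = readr::cols(
    readr::col_character(),
    .default = readr::col_double()
  ))
  if (nrow(tbl) == 0L) abort(paste0("no data rows in ", path))
  parts <- strsplit(tbl[[1]], sep, fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) {
    abort(paste0("edge id not of the form geneA", sep, "geneB: ", tbl[[1]][which(bad)[1]]))
  }
  w <- as.matrix(tbl[, -1, drop = FALSE])
  if (is.null(binary)) binary <- all(w %in% c(0, 1))
  new_edge_panel(
    gene_a = vapply(parts, `[[`, "", 1),
    gene_b = vapply(parts, `[[`, "", 2),
    weights = w,
    samples = names(tbl)[-1],
    binary = binary
  )
}
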