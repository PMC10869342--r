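# Synthetic benchmark cohorts: two (optionally unbalanced) subtype groups,
# module-structured coexpression with group-restricted latent activities
# (the planted rewiring), a background network of true plus decoy edges,
# planted driver genes, negative-binomial counts, and linked proteomics and
# copy-number matrices.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate an unbalanced two-subtype bulk RNA-seq cohort: 40 vs 8
#' samples, six coexpression modules shared by all samples plus two modules
#' per group whose within-module correlation exists only in that group
#' (group-restricted latent activity, i.e. planted rewiring), negative
#' binomial counts with lognormal library sizes, and proteomics/copy-number
#' matrices derived from the same per-sample expression means.
#'
#' @param n_genes Total genes (default 300).
#' @param group_sizes Samples per group (default `c(40, 8)`).
#' @param n_shared_modules Modules active in all samples (default 6).
#' @param n_specific_modules_per_group Modules active in one group only
#'   (default 2 per group).
#' @param module_size Genes per module (default 15).
#' @param loading Latent-activity loading lambda on the log2 scale
#'   (default 1.2).
#' @param noise_sd Per-gene log2 noise sd (default 0.5).
#' @param nb_dispersion Negative-binomial dispersion (default 0.1).
#' @param libsize_lognormal_sd Lognormal sd of library-size factors
#'   (default 0.2).
#' @param decoy_edge_ratio Decoy edges per true (within-module) edge in the
#'   background network (default 1).
#' @param module_member_density Probability that a pair of non-hub module
#'   members is connected in the background network (default 0.3, in the
#'   range of within-pathway densities of integrated functional networks).
#'   Each module has one designated hub gene wired to every member; the
#'   hubs of group-specific modules are the planted drivers.
#' @param specific_activation_mean Magnitude of the mean latent activity of
#'   a group-specific module within its own group (default 2). Specific
#'   modules are subtype programs: stably up- or down-regulated in the
#'   matching subtype (alternating sign across a group's modules, mirroring
#'   the roughly even up/down split of real subtype DE genes), hence
#'   differentially expressed between groups and recurrently strong in that
#'   group's networks, rather than merely group-restricted fluctuation.
#' @param proteomics_noise_sd Noise sd added to log2 means for the
#'   proteomics matrix (default 0.7).
#' @param cnv_state_probs Marginal probabilities of copy-number states
#'   1/2/3/4 per gene and sample; the default is mildly amplification-biased,
#'   as is typical of tumor genomes.
#' @param driver_amplification_prob Probability that a planted driver is
#'   amplified (state 3 or 4) in a group-1 sample (default 0.6).
#' @param seed Random seed (default 1).
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_genes = 300,
                             group_sizes = c(40, 8),
                             n_shared_modules = 6,
                             n_specific_modules_per_group = 2,
                             module_size = 15,
                             loading = 1.2,
                             noise_sd = 0.5,
                             nb_dispersion = 0.1,
                             libsize_lognormal_sd = 0.2,
                             decoy_edge_ratio = 1,
                             module_member_density = 0.3,
                             specific_activation_mean = 2,
                             proteomics_noise_sd = 0.7,
                             cnv_state_probs = c(0.05, 0.80, 0.10, 0.05),
                             driver_amplification_prob = 0.6,
                             seed = 1) {
  n_groups <- length(group_sizes)
  n_modules <- n_shared_modules + n_groups * n_specific_modules_per_group
  if (n_modules * module_size > n_genes) {
    abort("module genes exceed n_genes; enlarge n_genes or shrink modules")
  }
  if (any(group_sizes < 4)) abort("each group needs at least 4 samples")
  stopifnot(length(cnv_state_probs) == 4, abs(sum(cnv_state_probs) - 1) < 1e-8)
  cfg <- as.list(environment())
  cfg$n_groups <- n_groups
  cfg$n_modules <- n_modules
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic benchmark cohort
#'
#' See [synthetic_config()] for the generative model. Per sample `s` and
#' module `m`, a latent activity `a[m, s] ~ N(0, 1)` drives all module genes
#' through `log2 mean = baseline + loading * a + log2(cnv / 2) + noise`; for
#' a group-specific module the shared activity is drawn only for that
#' group's samples and replaced by independent per-gene noise elsewhere, so
#' within-module correlation exists only in the matching group. Counts are
#' negative binomial around the log2 means scaled by lognormal library-size
#' factors; proteomics adds Gaussian noise to the log2 means; the
#' copy-number matrix holds the integer states themselves. The background
#' network contains all within-module pairs (true edges) plus uniformly
#' random decoy pairs; drivers are one designated hub gene per
#' group-specific module.
#'
#' @param config A [synthetic_config()].
#' @return A list with `counts`, `groups`, `background`, `drivers`
#'   (character vector), `proteomics`, `cnv`, and `truth` (module map,
#'   specific-module groups, true edges, latent activities, log2 means).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  n_genes <- config$n_genes
  sizes <- config$group_sizes
  n <- sum(sizes)
  genes <- sprintf("g%03d", seq_len(n_genes))
  samples <- sprintf("s%02d", seq_len(n))
  group_names <- paste0("grp", seq_along(sizes))
  group_of <- rep(group_names, sizes)

  # module layout: shared modules first, then per-group specific modules
  n_mod <- config$n_modules
  module_of <- rep(NA_integer_, n_genes)
  module_of[seq_len(n_mod * config$module_size)] <-
    rep(seq_len(n_mod), each = config$module_size)
  module_group <- c(
    rep(NA_character_, config$n_shared_modules),
    rep(group_names, each = config$n_specific_modules_per_group)
  )

  # latent activities: shared modules fluctuate around zero in every
  # sample; a group-specific module is a subtype program, up- or
  # down-regulated (mean +/- specific_activation_mean, alternating within
  # each group) in its own group's samples and NA elsewhere (its genes fall
  # back to independent per-gene noise there)
  activity <- matrix(rnorm(n_mod * n), n_mod, n,
                     dimnames = list(NULL, samples))
  program_rank <- 0
  for (m in seq_len(n_mod)) {
    if (!is.na(module_group[m])) {
      program_rank <- program_rank + 1
      sign_m <- if (program_rank %% 2 == 1) 1 else -1
      own <- group_of == module_group[m]
      activity[m, own] <- activity[m, own] +
        sign_m * config$specific_activation_mean
      activity[m, !own] <- NA_real_
    }
  }

  # copy-number states; planted drivers amplified in group 1
  cnv <- matrix(
    sample.int(4, n_genes * n, replace = TRUE, prob = config$cnv_state_probs),
    n_genes, n, dimnames = list(genes, samples)
  )
  specific_modules <- which(!is.na(module_group))
  drivers <- genes[vapply(specific_modules,
                          function(m) which(module_of == m)[1], 1L)]
  # each planted driver (the designated hub of a specific module) tends to
  # be amplified in the samples of the subtype it drives
  for (i in seq_along(drivers)) {
    d <- match(drivers[i], genes)
    own <- which(group_of == module_group[specific_modules[i]])
    amp <- rbinom(length(own), 1, config$driver_amplification_prob) == 1
    cnv[d, own[amp]] <- sample(c(3L, 4L), sum(amp), replace = TRUE)
  }

  baseline <- runif(n_genes, 3, 8)
  # copy-number dosage scales a gene's co-variation amplitude as well as
  # its level: an amplified gene transcribes more per unit of regulatory
  # input, a deleted one less
  dosage <- cnv / 2
  module_term <- matrix(0, n_genes, n)
  for (g in seq_len(n_genes)) {
    m <- module_of[g]
    if (is.na(m)) next
    a <- activity[m, ]
    miss <- is.na(a)
    a[miss] <- rnorm(sum(miss))
    module_term[g, ] <- config$loading * a * dosage[g, ]
  }
  logmean <- baseline + module_term + log2(dosage) +
    matrix(rnorm(n_genes * n, sd = config$noise_sd), n_genes, n)
  dimnames(logmean) <- list(genes, samples)

  lib_factor <- rlnorm(n, meanlog = 0, sdlog = config$libsize_lognormal_sd)
  mu <- sweep(2^logmean, 2, lib_factor, "*")
  counts <- matrix(
    rnbinom(n_genes * n, mu = mu, size = 1 / config$nb_dispersion),
    n_genes, n, dimnames = list(genes, samples)
  )

  proteomics <- logmean +
    matrix(rnorm(n_genes * n, sd = config$proteomics_noise_sd), n_genes, n)

  # background: hub-centered modules. Each module's designated hub is wired
  # to every member; the remaining member pairs are included with
  # probability module_member_density (functional networks are sparse
  # within pathways, and this is what makes the designated hubs the most
  # connected module genes). Decoys are uniform non-module pairs.
  module_hubs <- genes[vapply(seq_len(n_mod),
                              function(m) which(module_of == m)[1], 1L)]
  true_edges <- dplyr::bind_rows(lapply(seq_len(n_mod), function(m) {
    members <- genes[which(module_of == m)]
    hub <- members[1]
    spokes <- canonical_pairs(rep(hub, length(members) - 1), members[-1])
    others <- combn(members[-1], 2)
    keep <- runif(ncol(others)) < config$module_member_density
    dplyr::bind_rows(spokes,
                     canonical_pairs(others[1, keep], others[2, keep]))
  }))
  n_decoys <- round(config$decoy_edge_ratio * nrow(true_edges))
  decoys <- sample_decoy_pairs(genes, module_of, n_decoys, true_edges)
  background <- dplyr::distinct(dplyr::bind_rows(true_edges, decoys))
  background <- background[pair_order(background$gene_a, background$gene_b), ]

  omics_tbl <- function(m, modality) {
    out <- dplyr::bind_cols(tibble::tibble(gene = genes),
                            tibble::as_tibble(m, .name_repair = "minimal"))
    attr(out, "modality") <- modality
    out
  }
  list(
    counts = expr_rebuild(counts, "counts"),
    groups = tibble::tibble(sample = samples, group = group_of),
    background = background,
    drivers = drivers,
    proteomics = omics_tbl(proteomics, "proteomics"),
    cnv = omics_tbl(cnv, "cnv"),
    truth = list(
      module_of = setNames(module_of, genes),
      module_group = module_group,
      module_hubs = module_hubs,
      drivers = drivers,
      true_edges = true_edges,
      activity = activity,
      logmean = expr_rebuild(logmean, "logcpm"),
      baseline = setNames(baseline, genes)
    )
  )
}

# uniform pairs that are not within-module and not already true edges
sample_decoy_pairs <- function(genes, module_of, n_decoys, true_edges) {
  n_genes <- length(genes)
  got <- tibble::tibble(gene_a = character(0), gene_b = character(0))
  true_key <- pair_key(true_edges$gene_a, true_edges$gene_b)
  while (nrow(got) < n_decoys) {
    need <- n_decoys - nrow(got)
    i <- sample.int(n_genes, 2 * need, replace = TRUE)
    j <- sample.int(n_genes, 2 * need, replace = TRUE)
    ok <- i != j
    same_mod <- !is.na(module_of[i]) & !is.na(module_of[j]) &
      module_of[i] == module_of[j]
    ok <- ok & !same_mod
    cand <- canonical_pairs(genes[i[ok]], genes[j[ok]])
    cand <- cand[!pair_key(cand$gene_a, cand$gene_b) %in% true_key, ]
    got <- dplyr::distinct(dplyr::bind_rows(got, cand))
    got <- head(got, n_decoys)
  }
  got
}

#' Built-in tiny fixtures
#'
#' Deterministic miniature inputs used in examples and tests.
#'
#' @param name One of `"toy_expression_10x12"` (10-gene, 12-sample scaled
#'   expression table), `"toy_background"` (edge list over the toy genes),
#'   `"toy_ranks_4x3"` (4-gene, 3-sample matrix with hand-computable ranks),
#'   `"toy_triangle_panel"` (three-edge, one-sample panel with weights 0.5,
#'   -0.5, 1.0).
#' @return The fixture object (expression table, background tibble, or edge
#'   panel).
#' @export
small_fixture <- function(name) {
  fixtures <- c("toy_expression_10x12", "toy_background",
                "toy_ranks_4x3", "toy_triangle_panel")
  if (!name %in% fixtures) {
    abort(paste0("unknown fixture '", name, "'; available: ",
                 paste(fixtures, collapse = ", ")))
  }
  switch(name,
    toy_expression_10x12 = {
      old_seed <- get0(".Random.seed", envir = globalenv())
      on.exit({
        if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
      }, add = TRUE)
      set.seed(421)
      m <- matrix(rnorm(120), 10, 12,
                  dimnames = list(sprintf("g%02d", 1:10), sprintf("s%02d", 1:12)))
      expr_rebuild(m, "scaled")
    },
    toy_background = {
      tibble::tibble(
        gene_a = c("g01", "g01", "g02", "g03", "g05"),
        gene_b = c("g02", "g03", "g04", "g07", "g09")
      )
    },
    toy_ranks_4x3 = {
      m <- matrix(c(1.0, 3.0, 2.0, 4.0,
                    4.0, 1.0, 3.0, 2.0,
                    2.0, 4.0, 1.0, 3.0), 4, 3,
                  dimnames = list(c("gA", "gB", "gC", "gD"),
                                  c("s1", "s2", "s3")))
      expr_rebuild(m, "logcpm")
    },
    toy_triangle_panel = {
      new_edge_panel(
        gene_a = c("A", "A", "B"),
        gene_b = c("B", "C", "C"),
        weights = matrix(c(0.5, -0.5, 1.0), 3, 1),
        samples = "s1"
      )
    }
  )
}
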