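triangle <- small_fixture("toy_triangle_panel")

test_that("node strength sums absolute weights per node", {
  st <- node_strength(triangle)
  expect_equal(st$s1[st$gene == "A"], 1.0)
  expect_equal(st$s1[st$gene == "B"], 1.5)
  expect_equal(st$s1[st$gene == "C"], 1.5)

  # isolated gene: all incident weights zero
  p <- ssnets:::new_edge_panel(c("A", "B"), c("B", "C"),
                               matrix(c(1, 0), 2, 1), "s1")
  st2 <- node_strength(p)
  expect_equal(st2$s1[st2$gene == "C"], 0)

  # random panel equals an incidence-list brute force
  x <- rand_expr(8, 10, seed = 50)
  panel <- select_top_edges(lioness_panel(x), 12)
  st3 <- node_strength(panel)
  for (s in c("s03", "s07")) {
    for (g in st3$gene) {
      inc <- panel$gene_a == g | panel$gene_b == g
      expect_equal(st3[[s]][st3$gene == g], sum(abs(panel[[s]][inc])),
                   tolerance = 1e-12)
    }
  }

  # aggregate networks yield a single strength column
  agg <- pcc_aggregate(x)
  sta <- node_strength(agg)
  expect_named(sta, c("gene", "strength"))
})

test_that("topology summary matches hand values on canonical small graphs", {
  tri <- topology_summary(triangle)
  expect_equal(tri$clustering, 1)
  expect_equal(tri$density, 1)
  expect_equal(tri$diameter, 1)
  expect_equal(tri$n_components, 1)

  # 3-node path: average clustering 0, diameter 2
  path3 <- ssnets:::new_edge_panel(c("A", "B"), c("B", "C"),
                                   matrix(c(1, 1), 2, 1), "s1")
  ts <- topology_summary(path3)
  expect_equal(ts$clustering, 0)
  expect_equal(ts$diameter, 2)
  # middle node lies on one shortest path; mean over 3 nodes
  expect_equal(ts$mean_node_betweenness, 1 / 3)
})

test_that("topology metrics equal a brute-force oracle on random small graphs", {
  set.seed(60)
  for (rep in 1:30) {
    v <- sample(4:8, 1)
    genes <- sprintf("n%d", seq_len(v))
    all_pairs <- t(combn(seq_len(v), 2))
    n_edges <- sample(3:nrow(all_pairs), 1)
    sel <- all_pairs[sample(nrow(all_pairs), n_edges), , drop = FALSE]
    w <- runif(n_edges, 0.1, 1) * sample(c(-1, 1), n_edges, replace = TRUE)
    # zero one weight sometimes: the edge stays in the universe but is
    # absent from the graph (possibly isolating a node)
    zeroed <- integer(0)
    if (rep %% 3 == 0) {
      zeroed <- sample(n_edges, 1)
      w[zeroed] <- 0
    }
    panel <- ssnets:::new_edge_panel(
      genes[sel[, 1]], genes[sel[, 2]], matrix(w, n_edges, 1), "s1"
    )
    ts <- topology_summary(panel)

    # oracle over the declared universe: all genes named in the edge list
    verts <- sort(unique(c(sel)))
    relab <- match(seq_len(v), verts)
    present <- which(w != 0)
    A <- o_adjacency(cbind(relab[sel[present, 1]], relab[sel[present, 2]]),
                     length(verts))
    bt <- o_betweenness(A)
    expect_equal(ts$density, length(present) / choose(length(verts), 2),
                 tolerance = 1e-12)
    expect_equal(ts$clustering, mean(o_local_clustering(A)), tolerance = 1e-12)
    expect_equal(ts$mean_node_betweenness, mean(bt$node), tolerance = 1e-10)
    expect_equal(ts$mean_edge_betweenness,
                 sum(bt$edge) / length(present), tolerance = 1e-10)
    finite_d <- bt$D[is.finite(bt$D)]
    expect_equal(ts$diameter, max(finite_d), tolerance = 1e-12)
    expect_equal(ts$n_components, max(o_components(A)))
  }
})

test_that("hub identification ranks by degree, strength, then gene id", {
  # star: center has maximal degree
  star <- ssnets:::new_edge_panel(
    rep("hub", 4), c("a", "b", "c", "d"),
    matrix(c(0.1, 0.2, 0.3, 0.4), 4, 1), "s1"
  )
  h <- identify_hubs(star, hub_n = 3)
  expect_equal(h$gene[1], "hub")
  expect_equal(h$degree[1], 4)

  # degree ties broken by strength, then lexicographic gene id
  tie <- ssnets:::new_edge_panel(
    c("a", "c"), c("b", "d"),
    matrix(c(0.9, 0.9), 2, 1), "s1"
  )
  h2 <- identify_hubs(tie, hub_n = 4)
  expect_equal(h2$gene, c("a", "b", "c", "d"))

  # random panel equals a sort oracle
  x <- rand_expr(10, 8, seed = 61)
  panel <- select_top_edges(iena_panel(x), 18)
  h3 <- identify_hubs(panel, hub_n = 5)
  st <- node_strength(panel)
  for (s in c("s02", "s06")) {
    deg <- sapply(st$gene, function(g) {
      sum(panel[[s]][panel$gene_a == g | panel$gene_b == g] != 0)
    })
    ord <- order(-deg, -st[[s]], st$gene)
    ord <- ord[deg[ord] >= 1][1:5]
    expect_equal(h3$gene[h3$sample == s], st$gene[ord])
  }
})

test_that("hub recurrence counts and the 75% regularity rule", {
  hubs <- tibble::tibble(
    sample = rep(sprintf("s%02d", 1:10), each = 2),
    rank = rep(1:2, 10),
    gene = c(rep(c("g1", "g2"), 7), rep(c("g1", "g3"), 3)),
    degree = 5, strength = 1
  )
  groups <- tibble::tibble(sample = sprintf("s%02d", 1:10), group = "grpA")
  rec <- hub_recurrence(hubs, groups)
  expect_equal(rec$count[rec$gene == "g1"], 10L)
  expect_true(rec$regularly_recurring[rec$gene == "g1"])
  # 7 of 10 < ceiling(7.5) = 8: not regular
  expect_equal(rec$count[rec$gene == "g2"], 7L)
  expect_false(rec$regularly_recurring[rec$gene == "g2"])

  expect_error(hub_recurrence(hubs, groups[1:5, ]), "unlabeled")
})

test_that("subtype-specific hubs are the regular-set differences", {
  rec <- tibble::tibble(
    group = c("A", "A", "B", "B"),
    gene = c("X", "Y", "Y", "Z"),
    count = 10, fraction = 1,
    regularly_recurring = TRUE
  )
  sp <- subtype_specific_hubs(rec)
  expect_equal(sp$gene[sp$group == "A"], "X")
  expect_equal(sp$gene[sp$group == "B"], "Z")

  # disjoint regular sets: specific equals regular
  rec2 <- rec
  rec2$gene <- c("X", "Y", "W", "Z")
  sp2 <- subtype_specific_hubs(rec2)
  expect_setequal(sp2$gene[sp2$group == "A"], c("X", "Y"))
  expect_setequal(sp2$gene[sp2$group == "B"], c("W", "Z"))
})

test_that("driver enrichment delegates to the exact hypergeometric tail", {
  universe <- sprintf("u%02d", 1:40)
  hubs <- tibble::tibble(
    sample = rep(c("s1", "s2"), each = 10),
    rank = rep(1:10, 2),
    gene = rep(universe[1:20], length.out = 20),
    degree = 3, strength = 1
  )
  groups <- tibble::tibble(sample = c("s1", "s2"), group = "A")
  # hubs union is half the universe; drivers equal the hub union -> tiny p
  res <- driver_enrichment(hubs, groups, universe[1:20], universe)
  expect_lt(res$p, 0.01)
  # drivers equal the whole universe -> p = 1
  res2 <- driver_enrichment(hubs, groups, universe, universe)
  expect_equal(res2$p, 1)
  expect_error(driver_enrichment(hubs, groups, c("no1", "no2"), universe),
               "empty target")
})

test_that("differential node strength recovers planted shifts and respects provenance", {
  set.seed(70)
  genes <- sprintf("g%03d", 1:120)
  samples <- sprintf("s%02d", 1:20)
  m <- matrix(abs(rnorm(120 * 20, mean = 3, sd = 0.2)), 120, 20,
              dimnames = list(genes, samples))
  m[1:10, 1:10] <- m[1:10, 1:10] + 2
  strengths <- dplyr::bind_cols(tibble::tibble(gene = genes),
                                tibble::as_tibble(m))
  attr(strengths, "unit_scaled") <- TRUE
  groups <- setNames(rep(c("a", "b"), each = 10), samples)
  res <- differential_node_strength(strengths, groups)
  expect_gte(sum(res$significant[1:10]), 9)
  expect_equal(sum(res$significant[-(1:10)]), 0)

  # identical groups: nothing significant
  m0 <- matrix(rep(abs(rnorm(120, 3)), 20), 120, 20,
               dimnames = list(genes, samples))
  s0 <- dplyr::bind_cols(tibble::tibble(gene = genes), tibble::as_tibble(m0))
  attr(s0, "unit_scaled") <- TRUE
  suppressWarnings(res0 <- differential_node_strength(s0, groups))
  expect_equal(sum(res0$significant), 0)

  # provenance flag is enforced
  attr(s0, "unit_scaled") <- NULL
  expect_error(differential_node_strength(s0, groups), "unit-scaled")
})

test_that("pca of node strengths separates planted groups and normalizes variance", {
  set.seed(71)
  genes <- sprintf("g%03d", 1:50)
  samples <- sprintf("s%02d", 1:16)
  m <- matrix(rnorm(50 * 16), 50, 16, dimnames = list(genes, samples))
  m[, 9:16] <- m[, 9:16] + 4
  strengths <- dplyr::bind_cols(tibble::tibble(gene = genes),
                                tibble::as_tibble(abs(m)))
  groups <- tibble::tibble(sample = samples,
                           group = rep(c("a", "b"), each = 8))
  pc <- pca_node_strength(strengths, groups)
  expect_equal(sum(pc$var_explained_all), 1, tolerance = 1e-12)
  # a threshold on PC1 separates the groups perfectly
  coords <- pc$coords
  cut <- mean(tapply(coords$PC1, coords$group, mean))
  side <- coords$PC1 > cut
  expect_true(all(side == side[coords$group == coords$group[1]][1] |
                    coords$group != coords$group[1]))
  expect_equal(length(unique(side[coords$group == "a"])), 1L)
  expect_equal(length(unique(side[coords$group == "b"])), 1L)

  # duplicated sample gets identical coordinates
  strengths2 <- strengths
  strengths2$dup <- strengths2$s01
  pc2 <- pca_node_strength(strengths2)
  c1 <- unlist(pc2$coords[pc2$coords$sample == "s01", c("PC1", "PC2")])
  c2 <- unlist(pc2$coords[pc2$coords$sample == "dup", c("PC1", "PC2")])
  expect_equal(c1, c2, tolerance = 1e-10, ignore_attr = TRUE)

  p <- autoplot(pc)
  expect_s3_class(p, "ggplot")
})
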