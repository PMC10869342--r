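# Independent brute-force oracles. These are deliberately naive (explicit
# loops, textbook formulas) and share no code with the package internals.

# textbook Pearson correlation
o_pcc <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# genes-by-samples random fixture
rand_expr <- function(p, n, seed) {
  set.seed(seed)
  m <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("g%02d", seq_len(p)),
                              sprintf("s%02d", seq_len(n))))
  as_expression(m, stage = "scaled")
}

expr_mat <- function(x) {
  m <- as.matrix(x[, -1])
  rownames(m) <- x$gene
  m
}

# look up one weight in a panel
panel_w <- function(panel, a, b, s) {
  lo <- min(a, b); hi <- max(a, b)
  panel[[s]][panel$gene_a == lo & panel$gene_b == hi]
}

# brute-force single-sample panels, per (edge, sample) loops ---------------

o_ssn <- function(m, a, b, q) {
  o_pcc(m[a, ], m[b, ]) - o_pcc(m[a, -q], m[b, -q])
}

o_lioness <- function(m, a, b, q) {
  n <- ncol(m)
  e_all <- o_pcc(m[a, ], m[b, ])
  e_loo <- o_pcc(m[a, -q], m[b, -q])
  n * (e_all - e_loo) + e_loo
}

o_sweet <- function(m, a, b, q, x = 0.01, K = 0.1) {
  n <- ncol(m)
  mu <- sapply(seq_len(n), function(s) {
    mean(sapply(setdiff(seq_len(n), s), function(t) o_pcc(m[, s], m[, t])))
  })
  W <- (mu[q] - min(mu) + x) / (max(mu) - min(mu) + x)
  m_plus <- cbind(m, m[, q])
  e_all <- o_pcc(m[a, ], m[b, ])
  e_plus <- o_pcc(m_plus[a, ], m_plus[b, ])
  W * n * K * (e_plus - e_all) + e_all
}

o_iena <- function(m, a, b, q) {
  n <- ncol(m)
  mu_a <- mean(m[a, ]); mu_b <- mean(m[b, ])
  va <- sum((m[a, ] - mu_a)^2) / n
  vb <- sum((m[b, ] - mu_b)^2) / n
  (m[a, q] - mu_a) * (m[b, q] - mu_b) / sqrt(va * vb)
}

# CSN by explicit neighborhood sets
o_csn <- function(m, box_fraction = 0.1, alpha = 0.01) {
  n <- ncol(m)
  k <- round(box_fraction * n)
  neigh <- function(g, s) {
    d <- abs(m[g, ] - m[g, s])
    d[s] <- Inf
    order(d, seq_len(n))[1:k]
  }
  z_cut <- qnorm(1 - alpha)
  out <- list()
  genes <- rownames(m)
  for (i in seq_len(nrow(m) - 1)) {
    for (j in (i + 1):nrow(m)) {
      for (s in seq_len(n)) {
        nij <- length(intersect(neigh(i, s), neigh(j, s)))
        rho <- nij / n - (k / n)^2
        z <- rho * n^2 * sqrt(n - 1) / (k * (n - k))
        out[[length(out) + 1]] <- data.frame(
          a = genes[i], b = genes[j], s = colnames(m)[s],
          present = as.numeric(z > z_cut)
        )
      }
    }
  }
  do.call(rbind, out)
}

# SSPGI by explicit rank subtraction
o_sspgi <- function(m, edges) {
  r <- apply(m, 2, rank)
  out <- list()
  for (e in seq_len(nrow(edges))) {
    a <- edges$gene_a[e]; b <- edges$gene_b[e]
    delta <- r[a, ] - r[b, ]
    out[[e]] <- delta - mean(delta)
  }
  do.call(rbind, out)
}

# graph oracles on small graphs --------------------------------------------

# edges: two-column matrix of vertex indices (1..v)
o_adjacency <- function(edges, v) {
  A <- matrix(0, v, v)
  for (e in seq_len(nrow(edges))) {
    A[edges[e, 1], edges[e, 2]] <- 1
    A[edges[e, 2], edges[e, 1]] <- 1
  }
  A
}

o_local_clustering <- function(A) {
  v <- nrow(A)
  sapply(seq_len(v), function(i) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2) return(0)
    links <- sum(A[nb, nb]) / 2
    links / choose(length(nb), 2)
  })
}

o_shortest_paths <- function(A) {
  v <- nrow(A)
  D <- ifelse(A == 1, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(v)) {
    for (i in seq_len(v)) {
      for (j in seq_len(v)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# enumerate all shortest paths between s and t (vertex sequences)
o_all_shortest_paths <- function(A, D, s, t) {
  if (!is.finite(D[s, t])) return(list())
  if (s == t) return(list(s))
  paths <- list()
  grow <- function(path) {
    last <- path[length(path)]
    if (last == t) {
      paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    for (nxt in which(A[last, ] == 1)) {
      if (D[s, nxt] == length(path) && D[nxt, t] == D[s, t] - length(path)) {
        grow(c(path, nxt))
      }
    }
  }
  grow(s)
  paths
}

# node and edge betweenness (undirected: each unordered pair counted once)
o_betweenness <- function(A) {
  v <- nrow(A)
  D <- o_shortest_paths(A)
  node_b <- numeric(v)
  edge_b <- matrix(0, v, v)
  for (s in seq_len(v - 1)) {
    for (t in (s + 1):v) {
      paths <- o_all_shortest_paths(A, D, s, t)
      np <- length(paths)
      if (np == 0) next
      for (p in paths) {
        inner <- setdiff(p, c(s, t))
        node_b[inner] <- node_b[inner] + 1 / np
        for (i in seq_len(length(p) - 1)) {
          a <- min(p[i], p[i + 1]); b <- max(p[i], p[i + 1])
          edge_b[a, b] <- edge_b[a, b] + 1 / np
        }
      }
    }
  }
  list(node = node_b, edge = edge_b, D = D)
}

o_components <- function(A) {
  v <- nrow(A)
  comp <- rep(0, v)
  cur <- 0
  for (i in seq_len(v)) {
    if (comp[i] > 0) next
    cur <- cur + 1
    frontier <- i
    comp[i] <- cur
    while (length(frontier) > 0) {
      nxt <- unique(unlist(lapply(frontier, function(x) which(A[x, ] == 1))))
      nxt <- nxt[comp[nxt] == 0]
      comp[nxt] <- cur
      frontier <- nxt
    }
  }
  comp
}

# exhaustive hypergeometric tail: enumerate all possible draws
o_hyper_exhaustive <- function(universe, target, hits) {
  draws <- combn(universe, length(hits))
  obs <- length(intersect(hits, target))
  cnt <- apply(draws, 2, function(d) length(intersect(d, target)) >= obs)
  mean(cnt)
}

# BH step-up by hand
o_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in seq(n, 1)) {
    val <- min(prev, n / i * p[o[i]])
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# look up an aggregate-network weight
panel_w_agg <- function(agg, a, b) {
  lo <- min(a, b); hi <- max(a, b)
  agg$weight[agg$gene_a == lo & agg$gene_b == hi]
}
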