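# Independent brute-force oracles used to check the package implementations.
# Everything here is written from first principles (no igraph, no survival).

# two-group log-rank from the O/E/V definitions; `high` is a logical vector
oracle_logrank <- function(time, event, high) {
  ut <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (t in ut) {
    at <- time >= t
    n <- sum(at)
    n1 <- sum(at & high)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & high)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  p <- if (v > 0) pchisq((o1 - e1)^2 / v, 1, lower.tail = FALSE) else NA_real_
  list(p = p, o1 = o1, e1 = e1)
}

# brute-force optimal-cutoff scan over the percentile band
oracle_km_scan <- function(x, time, event, band = c(20, 80)) {
  ux <- sort(unique(x))
  pct <- vapply(ux, function(v) 100 * mean(x <= v), 0)
  cand <- ux[pct >= band[1] & pct <= band[2]]
  ps <- vapply(cand, function(cv) oracle_logrank(time, event, x > cv)$p, 0)
  best <- order(ps, cand)[1]
  list(cutoff = cand[best], p = ps[best])
}

# exhaustive enumeration of P(overlap >= k): A = first na universe elements,
# every size-nb subset of the universe equally likely
oracle_hypergeom <- function(na, nb, k, n_universe) {
  draws <- combn(n_universe, nb)
  mean(apply(draws, 2, function(d) sum(d <= na) >= k))
}

# BH step-up by the direct p * m / rank formula with cumulative minimum
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# all simple paths between s and t on an adjacency matrix
all_paths <- function(adj, s, t) {
  paths <- list()
  rec <- function(path) {
    last <- path[length(path)]
    if (last == t) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (nb in which(adj[last, ] > 0)) if (!(nb %in% path)) rec(c(path, nb))
  }
  rec(s)
  paths
}

# betweenness by enumerating every shortest path and splitting evenly
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in seq((s + 1), n)) {
    ps <- all_paths(adj, s, t)
    if (!length(ps)) next
    lens <- lengths(ps)
    sp <- ps[lens == min(lens)]
    for (v in setdiff(seq_len(n), c(s, t)))
      btw[v] <- btw[v] + mean(vapply(sp, function(p) v %in% p, TRUE))
  }
  btw
}

# BFS all-pairs distances (Inf when unreachable)
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    lvl <- 0
    while (length(frontier)) {
      d[s, frontier] <- pmin(d[s, frontier], lvl)
      nxt <- unique(unlist(lapply(frontier, function(v) which(adj[v, ] > 0))))
      frontier <- nxt[!is.finite(d[s, nxt])]
      lvl <- lvl + 1
    }
  }
  d
}

# Spearman as Pearson on mid-ranks, from the definition
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Newman modularity of a partition (vector of community ids per vertex)
oracle_modularity <- function(adj, memb) {
  m <- sum(adj) / 2
  deg <- rowSums(adj)
  q <- 0
  for (i in seq_len(nrow(adj))) for (j in seq_len(nrow(adj)))
    if (memb[i] == memb[j]) q <- q + adj[i, j] - deg[i] * deg[j] / (2 * m)
  q / (2 * m)
}

# all set partitions of 1..n (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(code, mx) {
    k <- length(code)
    if (k == n) {
      out[[length(out) + 1L]] <<- code
      return(invisible())
    }
    for (v in seq_len(mx + 1)) rec(c(code, v), max(mx, v))
  }
  rec(1L, 1L)
  out
}

# a random connected-ish sparse graph as an adjacency matrix, gene-labelled
random_adjacency <- function(n, p = 0.3) {
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, p)
  adj <- adj + t(adj)
  dimnames(adj) <- list(sprintf("G%02d", 1:n), sprintf("G%02d", 1:n))
  adj
}

# wrap an adjacency matrix as the package's gene_network container
network_from_adjacency <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  structure(list(graph = g, threshold = NA_real_, retention = NA_real_,
                 n_genes = nrow(adj), n_edges = igraph::ecount(g)),
            class = "gene_network")
}

# small synthetic survival instance with a prognostic covariate
random_survival_instance <- function(n, beta = 0) {
  x <- rlnorm(n, 1, 1)
  lp <- beta * as.numeric(scale(log1p(x)))
  t_true <- rexp(n, log(2) / 50 * exp(lp))
  cens <- runif(n, 0, 150)
  list(x = x, time = round(pmin(t_true, cens), 1) + 0.1,
       event = as.integer(t_true <= cens))
}
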