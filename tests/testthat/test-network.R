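test_that("Spearman matrix equals rank-then-Pearson and is monotone invariant", {
  x <- c(1, 2, 2, 4)
  y <- c(2, 1, 4, 3)
  m <- rbind(a = x, b = y)
  colnames(m) <- paste0("s", 1:4)
  sm <- spearman_matrix(m)
  expect_equal(sm["a", "b"], oracle_spearman(x, y), tolerance = 1e-12)

  z <- c(0.3, 1.1, 2.5, 7)
  m2 <- rbind(a = z, b = exp(z), c = -z)
  colnames(m2) <- paste0("s", 1:4)
  sm2 <- spearman_matrix(m2)
  expect_equal(sm2["a", "b"], 1)
  expect_equal(sm2["a", "c"], -1)
  expect_error(spearman_matrix(m2[, 1:2]), "3 samples")
})

test_that("edge retention count follows floor(fraction * n(n-1)/2) exactly", {
  set.seed(21)
  for (i in 1:12) {
    n <- sample(10:60, 1)
    frac <- sample(c(0.005, 0.02, 0.1, 0.5, 1), 1)
    m <- matrix(rnorm(n * 20), n, 20,
                dimnames = list(sprintf("G%03d", 1:n), NULL))
    k_exp <- as.integer(floor(frac * n * (n - 1) / 2))
    if (k_exp == 0L) {
      expect_warning(net <- build_gcn(spearman_matrix(m), frac), "no edges")
    } else {
      net <- build_gcn(spearman_matrix(m), frac)
    }
    expect_identical(net$n_edges, k_exp)
  }
  # 100 genes -> 4950 pairs -> floor(24.75) = 24 edges
  m <- matrix(rnorm(100 * 30), 100, 30,
              dimnames = list(sprintf("G%03d", 1:100), NULL))
  expect_identical(build_gcn(spearman_matrix(m), 0.005)$n_edges, 24L)
  expect_error(build_gcn(spearman_matrix(m), 0), "retention")
})

test_that("tied correlations are broken lexicographically and reproducibly", {
  # four perfectly correlated genes: all pair correlations equal 1
  base <- 1:10
  m <- rbind(Gd = base, Gc = base * 2, Gb = base + 5, Ga = base * 3)
  colnames(m) <- paste0("s", 1:10)
  n1 <- build_gcn(spearman_matrix(m), 0.5)   # floor(0.5*6) = 3 edges
  n2 <- build_gcn(spearman_matrix(m), 0.5)
  e1 <- igraph::as_data_frame(n1$graph)
  expect_identical(e1, igraph::as_data_frame(n2$graph))
  pid <- sort(paste(pmin(e1$from, e1$to), pmax(e1$from, e1$to), sep = "|"))
  expect_identical(pid, c("Ga|Gb", "Ga|Gc", "Ga|Gd"))  # first 3 pair ids
})

test_that("full retention yields the complete graph on non-degenerate genes", {
  set.seed(4)
  m <- matrix(rnorm(8 * 15), 8, 15, dimnames = list(letters[1:8], NULL))
  m[8, ] <- 3  # degenerate gene: undefined correlations, never an edge
  net <- build_gcn(spearman_matrix(m), 1)
  expect_identical(net$n_edges, as.integer(7 * 6 / 2))
  expect_false("h" %in% igraph::V(net$graph)$name)
})

test_that("Walktrap with modularity cut recovers planted communities", {
  clique_block <- function(ns) {
    adj <- matrix(0L, sum(ns), sum(ns))
    at <- cumsum(c(0, ns))
    for (b in seq_along(ns)) {
      ix <- (at[b] + 1):at[b + 1]
      adj[ix, ix] <- 1L
    }
    diag(adj) <- 0L
    dimnames(adj) <- list(sprintf("G%02d", seq_len(sum(ns))),
                          sprintf("G%02d", seq_len(sum(ns))))
    adj
  }
  # two disjoint 6-cliques
  adj <- clique_block(c(6, 6))
  mods <- detect_modules(network_from_adjacency(adj))
  expect_identical(length(unique(mods$module)), 2L)
  expect_identical(length(unique(mods$module[1:6])), 1L)

  # a single clique stays one community
  mods1 <- detect_modules(network_from_adjacency(clique_block(8)))
  expect_identical(length(unique(mods1$module)), 1L)

  # ring of four 5-cliques joined by single bridges -> the four cliques
  adj4 <- clique_block(c(5, 5, 5, 5))
  bridge <- cbind(c(5, 10, 15, 20), c(6, 11, 16, 1))
  adj4[bridge] <- 1L
  adj4[bridge[, 2:1]] <- 1L
  mods4 <- detect_modules(network_from_adjacency(adj4))
  expect_identical(length(unique(mods4$module)), 4L)
  for (b in 0:3)
    expect_identical(length(unique(mods4$module[b * 5 + 1:5])), 1L)
})

test_that("Walktrap modularity cut matches exhaustive partition search on a small graph", {
  # two 4-cliques joined by one bridge; all 4140 partitions of 8 nodes
  adj <- matrix(0L, 8, 8)
  adj[1:4, 1:4] <- 1L
  adj[5:8, 5:8] <- 1L
  diag(adj) <- 0L
  adj[4, 5] <- adj[5, 4] <- 1L
  dimnames(adj) <- list(sprintf("G%02d", 1:8), sprintf("G%02d", 1:8))
  parts <- all_partitions(8)
  qs <- vapply(parts, function(pp) oracle_modularity(adj, pp), 0)
  best <- parts[[which.max(qs)]]
  mods <- detect_modules(network_from_adjacency(adj))
  got <- as.integer(factor(mods$module, unique(mods$module)))
  expect_identical(got[order(mods$gene)],
                   as.integer(factor(best, unique(best))))
})

test_that("module detection is invariant to node relabeling", {
  set.seed(12)
  adj <- random_adjacency(15, 0.35)
  mods <- detect_modules(network_from_adjacency(adj))
  perm <- sample(15)
  adj2 <- adj[perm, perm]
  mods2 <- detect_modules(network_from_adjacency(adj2))
  m1 <- setNames(mods$module, mods$gene)
  m2 <- setNames(mods2$module, mods2$gene)
  shared <- intersect(names(m1), names(m2))
  # same partition up to label permutation
  expect_identical(length(unique(m1[shared])), length(unique(m2[shared])))
  tab <- table(m1[shared], m2[shared])
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("module filters apply the strict >20 nodes and >0.5 transitivity rules", {
  # 25-clique (kept), 30-path (transitivity 0), 20-clique (too small)
  n <- 25 + 30 + 20
  adj <- matrix(0L, n, n)
  adj[1:25, 1:25] <- 1L
  for (i in 26:54) adj[i, i + 1] <- adj[i + 1, i] <- 1L
  adj[56:75, 56:75] <- 1L
  diag(adj) <- 0L
  dimnames(adj) <- list(sprintf("G%03d", 1:n), sprintf("G%03d", 1:n))
  net <- network_from_adjacency(adj)
  mods <- data.frame(gene = rownames(adj),
                     module = rep(c("clique25", "path30", "clique20"),
                                  c(25, 30, 20)))
  st <- module_stats(net, mods)
  expect_equal(st$transitivity[st$module == "clique25"], 1)
  expect_equal(st$transitivity[st$module == "path30"], 0)
  kept <- filter_modules(net, mods)
  expect_identical(unique(kept$module), "clique25")
})

test_that("module centralities match closed forms and brute-force oracles", {
  # star K1,5
  adj <- matrix(0L, 6, 6)
  adj[1, 2:6] <- adj[2:6, 1] <- 1L
  dimnames(adj) <- list(sprintf("G%02d", 1:6), sprintf("G%02d", 1:6))
  net <- network_from_adjacency(adj)
  cent <- module_centralities(net, rownames(adj))
  expect_equal(cent$degree, c(5, rep(1, 5)))
  expect_equal(cent$betweenness, c(10, rep(0, 5)))
  # closeness: center (5/5)*(5/5)=1; leaf (5/5)*(5/9)
  expect_equal(cent$closeness, c(1, rep(5 / 9, 5)))

  # clique symmetry
  adjc <- matrix(1L, 5, 5); diag(adjc) <- 0L
  dimnames(adjc) <- list(letters[1:5], letters[1:5])
  cc <- module_centralities(network_from_adjacency(adjc), letters[1:5])
  expect_true(all(vapply(cc[, -1], function(v) diff(range(v)) == 0, TRUE)))

  # random graphs vs exhaustive path enumeration
  set.seed(31)
  for (i in 1:6) {
    adj <- random_adjacency(sample(8:12, 1), 0.3)
    net <- network_from_adjacency(adj)
    cent <- module_centralities(net, rownames(adj))
    ora_b <- oracle_betweenness(adj)
    expect_equal(cent$betweenness[match(rownames(adj), cent$gene)], ora_b,
                 tolerance = 1e-9)
    d <- oracle_distances(adj)
    n <- nrow(adj)
    ora_c <- vapply(seq_len(n), function(v) {
      dd <- d[v, -v]
      fin <- dd[is.finite(dd)]
      if (!length(fin) || sum(fin) == 0) return(0)
      (length(fin) / (n - 1)) * (length(fin) / sum(fin))
    }, 0)
    expect_equal(cent$closeness[match(rownames(adj), cent$gene)], ora_c,
                 tolerance = 1e-9)
  }
})
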