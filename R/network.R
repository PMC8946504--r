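#' Pairwise Spearman correlation matrix
#'
#' Spearman via mid-ranks (average ranks on ties) followed by Pearson on the
#' ranks. Genes with zero variance get `NA` correlations and can never be
#' retained as edges.
#'
#' @param expression gene x sample matrix with at least 3 samples.
#' @return symmetric gene x gene correlation matrix (diagonal is 1 but is
#'   never used as an edge).
#' @export
spearman_matrix <- function(expression) {
  stopifnot(is.matrix(expression))
  if (ncol(expression) < 3) stop("need at least 3 samples")
  suppressWarnings(stats::cor(t(expression), method = "spearman"))
}

#' Build a thresholded gene co-expression network
#'
#' Ranks all defined gene pairs by signed Spearman correlation (descending)
#' and keeps the top `floor(retention * n*(n-1)/2)` pairs as edges, where `n`
#' counts genes with at least one defined pair correlation. Ties at the
#' boundary are broken lexicographically by gene-pair id; isolated genes are
#' not part of the resulting graph.
#'
#' @param correlations symmetric correlation matrix from [spearman_matrix()].
#' @param retention fraction of pairs to keep, in (0, 1]; default 0.005.
#' @return object of class `gene_network`: list with `graph` (igraph, edge
#'   attribute `rho`), `threshold` (smallest retained correlation),
#'   `retention`, `n_genes` (genes entering the pair count) and `n_edges`.
#' @export
build_gcn <- function(correlations, retention = 0.005) {
  if (retention <= 0 || retention > 1) stop("retention must lie in (0, 1]")
  stopifnot(is.matrix(correlations),
            nrow(correlations) == ncol(correlations))
  g_names <- rownames(correlations)
  ut <- upper.tri(correlations)
  defined_gene <- rowSums(!is.na(correlations) & ut | t(!is.na(correlations) & ut)) > 0
  n <- sum(defined_gene)
  if (n < 2) stop("no defined pair correlations")
  idx <- which(ut & !is.na(correlations), arr.ind = TRUE)
  if (!nrow(idx)) stop("no defined pair correlations")
  rho <- correlations[idx]
  k <- floor(retention * n * (n - 1) / 2)
  if (k < 1) {
    warning("retention keeps no edges")
    return(structure(list(graph = igraph::make_empty_graph(0, directed = FALSE),
                          threshold = NA_real_, retention = retention,
                          n_genes = n, n_edges = 0L),
                     class = "gene_network"))
  }
  ga <- g_names[idx[, 1L]]
  gb <- g_names[idx[, 2L]]
  pair_id <- paste(pmin(ga, gb), pmax(ga, gb), sep = "|")
  ord <- order(-rho, pair_id)[seq_len(min(k, length(rho)))]
  edges <- data.frame(from = ga[ord], to = gb[ord], rho = rho[ord],
                      stringsAsFactors = FALSE)
  graph <- igraph::graph_from_data_frame(edges, directed = FALSE)
  structure(list(graph = graph,
                 threshold = min(edges$rho),
                 retention = retention,
                 n_genes = n,
                 n_edges = nrow(edges)),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat("Gene co-expression network:", igraph::vcount(x$graph), "genes,",
      x$n_edges, "edges (top", sprintf("%.3g%%", 100 * x$retention),
      "of pairs; realized threshold rho >=", signif(x$threshold, 4), ")\n")
  invisible(x)
}

#' Detect network modules with the Walktrap algorithm
#'
#' Random-walk agglomerative community detection (unweighted edges, walk
#' length `steps`), cut at the merge step maximizing modularity. Every node
#' belongs to exactly one module.
#'
#' @param network a [build_gcn()] result.
#' @param steps random-walk length (default 4).
#' @return data.frame: gene, module (ids `"M1"`, `"M2"`, ... by decreasing
#'   module size).
#' @export
detect_modules <- function(network, steps = 4L) {
  stopifnot(inherits(network, "gene_network"))
  g <- network$graph
  if (igraph::ecount(g) == 0) stop("network has no edges")
  wt <- igraph::cluster_walktrap(g, steps = steps, weights = NA)
  memb <- igraph::membership(wt)
  sizes <- sort(table(memb), decreasing = TRUE)
  relab <- stats::setNames(sprintf("M%d", seq_along(sizes)), names(sizes))
  data.frame(gene = names(memb), module = unname(relab[as.character(memb)]),
             row.names = NULL, stringsAsFactors = FALSE)
}

# induced unweighted subgraph on a module's genes
module_subgraph <- function(network, genes) {
  igraph::induced_subgraph(network$graph,
                           intersect(genes, igraph::V(network$graph)$name))
}

#' Per-module summary statistics
#'
#' @param network a [build_gcn()] result.
#' @param modules data.frame from [detect_modules()].
#' @return data.frame: module, size, transitivity (global transitivity of the
#'   module-induced subgraph).
#' @export
module_stats <- function(network, modules) {
  split_genes <- split(modules$gene, modules$module)
  data.frame(
    module = names(split_genes),
    size = lengths(split_genes),
    transitivity = vapply(split_genes, function(g) {
      tr <- igraph::transitivity(module_subgraph(network, g), type = "global")
      if (is.nan(tr)) 0 else tr
    }, 0),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter modules by size and transitivity
#'
#' Retains modules with strictly more than `min_nodes - 1` genes and global
#' transitivity strictly above `min_transitivity` (the "more than 20 nodes,
#' connectivity coefficient larger than 0.5" rule).
#'
#' @param network a [build_gcn()] result.
#' @param modules data.frame from [detect_modules()].
#' @param min_nodes minimum module size (default 21, i.e. > 20 nodes).
#' @param min_transitivity strict lower bound on transitivity (default 0.5).
#' @return the module table restricted to surviving modules, with the module
#'   statistics attached as attribute `"stats"`.
#' @export
filter_modules <- function(network, modules, min_nodes = 21L,
                           min_transitivity = 0.5) {
  st <- module_stats(network, modules)
  keep <- st$module[st$size >= min_nodes & st$transitivity > min_transitivity]
  out <- modules[modules$module %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "stats") <- st[st$module %in% keep, , drop = FALSE]
  out
}

#' Centralities of genes within a module
#'
#' Degree, shortest-path betweenness and closeness on the unweighted
#' module-induced subgraph. Closeness uses a per-component normalization:
#' `((r-1)/(n-1)) * ((r-1)/sum(d))` where `r` is the size of the gene's
#' connected component within the module, `n` the module size and `sum(d)`
#' the sum of distances to the other members of the component, keeping values
#' comparable across disconnected modules. Singleton modules get zeros.
#'
#' @param network a [build_gcn()] result.
#' @param genes the module's gene ids.
#' @return data.frame: gene, degree, betweenness, closeness.
#' @export
module_centralities <- function(network, genes) {
  if (!length(genes)) stop("module is empty")
  sub <- module_subgraph(network, genes)
  nm <- igraph::V(sub)$name
  n <- length(nm)
  missing <- setdiff(genes, nm)
  if (n <= 1 && length(genes) >= 1) {
    return(data.frame(gene = genes, degree = 0, betweenness = 0,
                      closeness = 0, row.names = NULL,
                      stringsAsFactors = FALSE))
  }
  deg <- igraph::degree(sub)
  btw <- igraph::betweenness(sub, weights = NA)
  dm <- igraph::distances(sub, weights = NA)
  clo <- vapply(seq_len(n), function(i) {
    dd <- dm[i, -i]
    fin <- dd[is.finite(dd)]
    r <- length(fin)                         # component size minus self
    if (r == 0 || sum(fin) == 0) return(0)
    (r / (n - 1)) * (r / sum(fin))
  }, 0)
  out <- data.frame(gene = c(nm, missing),
                    degree = c(unname(deg), rep(0, length(missing))),
                    betweenness = c(unname(btw), rep(0, length(missing))),
                    closeness = c(clo, rep(0, length(missing))),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[match(intersect(genes, out$gene), out$gene), , drop = FALSE]
}
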