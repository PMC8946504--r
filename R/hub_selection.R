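#' Top fraction of module genes by a centrality metric
#'
#' Sorts genes by the metric (descending) and returns exactly
#' `floor(fraction * module size)` genes; boundary ties are broken
#' lexicographically by gene id for determinism.
#'
#' @param centralities data.frame from [module_centralities()].
#' @param metric one of `"degree"`, `"betweenness"`, `"closeness"`.
#' @param fraction top fraction to keep (default 0.10).
#' @return character vector of gene ids.
#' @export
top_fraction <- function(centralities,
                         metric = c("degree", "betweenness", "closeness"),
                         fraction = 0.10) {
  metric <- match.arg(metric)
  k <- floor(fraction * nrow(centralities))
  if (k == 0) {
    warning("top fraction of a ", nrow(centralities),
            "-gene module is empty")
    return(character(0))
  }
  ord <- order(-centralities[[metric]], centralities$gene)
  centralities$gene[ord][seq_len(k)]
}

#' Hub genes shared between the two modules of a pair
#'
#' @param top_a,top_b per-module top-fraction gene lists.
#' @param universe shared gene universe for the significance test.
#' @return list: `genes` (sorted intersection), `p` (upper-tail
#'   hypergeometric p of the overlap).
#' @export
shared_hub_genes <- function(top_a, top_b, universe) {
  if (!length(universe)) stop("universe is empty")
  list(genes = sort(intersect(top_a, top_b)),
       p = hypergeometric_overlap(top_a, top_b, universe))
}

#' Candidate drug-target genes from per-metric shared hubs
#'
#' Intersects each metric's shared hub list with the SPGs and unions the
#' three intersections. The per-metric significance of the hub overlaps is
#' reported upstream but not used as a gate.
#'
#' @param shared_hubs named list (per metric) of shared hub gene vectors.
#' @param spg_genes SPG gene ids.
#' @return sorted character vector of candidate target genes (always a
#'   subset of the SPGs).
#' @export
candidate_targets <- function(shared_hubs, spg_genes) {
  sort(unique(unlist(lapply(shared_hubs, intersect, spg_genes),
                     use.names = FALSE)))
}

#' Filter candidate targets by gene essentiality
#'
#' Summarizes each gene's essentiality as the median score across cell lines
#' and keeps genes with summary strictly below `threshold` (knockout strongly
#' inhibits growth). Candidates absent from the table are excluded with a
#' warning.
#'
#' @param candidates candidate target gene ids.
#' @param essentiality gene x cell line score matrix.
#' @param threshold strict upper bound on the median score (default -1.5).
#' @return data.frame of class `target_gene_set`: gene, essentiality
#'   (median), keep; retained genes first, sorted by score.
#' @export
essentiality_filter <- function(candidates, essentiality, threshold = -1.5) {
  if (!length(candidates)) stop("no candidate genes")
  missing <- setdiff(candidates, rownames(essentiality))
  if (length(missing))
    warning("excluded candidate(s) absent from the essentiality table: ",
            paste(missing, collapse = ", "))
  present <- setdiff(candidates, missing)
  med <- apply(essentiality[present, , drop = FALSE], 1L, stats::median)
  out <- data.frame(gene = present, essentiality = unname(med),
                    keep = unname(med) < threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$keep, out$essentiality, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("target_gene_set", "data.frame")
  out
}
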