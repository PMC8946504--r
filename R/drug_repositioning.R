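#' Instance-level drug--shRNA signature correlations
#'
#' Spearman correlation over the shared landmark genes between every compound
#' instance signature and every shRNA instance whose target is among the
#' requested genes. Target genes with no shRNA in the dataset are dropped
#' with a message.
#'
#' @param dataset a `perturbation_dataset`.
#' @param target_genes genes whose knockdown signatures to match.
#' @return list of class `pert_correlations`: `cor` (compound instance x
#'   shRNA instance matrix), `compound_meta`, `shrna_meta`.
#' @export
drug_shrna_correlations <- function(dataset, target_genes) {
  stopifnot(inherits(dataset, "perturbation_dataset"))
  if (nrow(dataset$signatures) < 10)
    stop("fewer than 10 shared landmark genes")
  meta <- dataset$meta
  sh <- meta[meta$type == "shRNA" & meta$target %in% target_genes, ,
             drop = FALSE]
  absent <- setdiff(target_genes, sh$target)
  if (length(absent))
    message("no shRNA available for: ", paste(absent, collapse = ", "),
            " (excluded)")
  if (!nrow(sh)) stop("no shRNA instance for any requested target gene")
  cp <- meta[meta$type == "compound", , drop = FALSE]
  if (nrow(cp) < 2) stop("need at least 2 compound instances")
  m <- stats::cor(dataset$signatures[, cp$instance, drop = FALSE],
                  dataset$signatures[, sh$instance, drop = FALSE],
                  method = "spearman")
  structure(list(cor = m, compound_meta = cp, shrna_meta = sh),
            class = "pert_correlations")
}

#' Collapse dose/time instances to one row per compound
#'
#' For each (compound, shRNA) cell keeps the maximum correlation across the
#' compound's dose x time instances -- the strongest dose/time-responsive
#' connection. Ties are resolved deterministically (lowest dose, then
#' earliest time, then instance id), which fixes the recorded instance but
#' not the retained value, which is the maximum either way.
#'
#' @param correlations a [drug_shrna_correlations()] result.
#' @return list of class `drug_shrna_matrix`: `cor` (compound id x shRNA
#'   instance matrix), `shrna_targets` (named vector: shRNA instance ->
#'   target gene).
#' @export
collapse_dose_time <- function(correlations) {
  stopifnot(inherits(correlations, "pert_correlations"))
  cp <- correlations$compound_meta
  if (any(is.na(cp$compound_id))) stop("compound instance without compound id")
  ord <- order(cp$compound_id, cp$dose, cp$time, cp$instance)
  m <- correlations$cor[ord, , drop = FALSE]
  grp <- cp$compound_id[ord]
  ids <- unique(grp)                      # sorted order preserved
  collapsed <- do.call(rbind, lapply(split(seq_along(grp), factor(grp, ids)),
                                     function(ix)
                                       apply(m[ix, , drop = FALSE], 2L, max)))
  rownames(collapsed) <- ids
  structure(list(cor = collapsed,
                 shrna_targets = stats::setNames(
                   correlations$shrna_meta$target,
                   correlations$shrna_meta$instance)),
            class = "drug_shrna_matrix")
}

#' Prune shRNAs by cluster median correlation
#'
#' Hierarchically clusters all shRNA columns (average linkage, distance
#' `1 - Spearman` between columns over all compounds), cuts into two
#' clusters, and retains the cluster whose cells have the higher median
#' correlation (MdnCorr). A target gene losing every shRNA falls back to its
#' single highest-median-correlation shRNA (with a warning).
#'
#' @param dsm a [collapse_dose_time()] result.
#' @return list of class `shrna_selection`: `retained` (shRNA instance ids),
#'   `cluster` (named assignment), `median_correlation` (per cluster),
#'   `fallback` (genes rescued by the fallback rule).
#' @export
filter_shrna_clusters <- function(dsm) {
  stopifnot(inherits(dsm, "drug_shrna_matrix"))
  sh <- colnames(dsm$cor)
  if (length(sh) == 1L) {
    return(structure(list(retained = sh,
                          cluster = stats::setNames(1L, sh),
                          median_correlation = stats::median(dsm$cor),
                          fallback = character(0)),
                     class = "shrna_selection"))
  }
  cc <- suppressWarnings(stats::cor(dsm$cor, method = "spearman"))
  cc[is.na(cc)] <- 0
  cl <- stats::cutree(stats::hclust(stats::as.dist(1 - cc),
                                    method = "average"), k = 2L)
  med <- vapply(1:2, function(k)
    stats::median(dsm$cor[, cl == k, drop = FALSE]), 0)
  winner <- which.max(med)
  retained <- sh[cl == winner]
  fallback <- character(0)
  lost <- setdiff(unique(dsm$shrna_targets),
                  unique(dsm$shrna_targets[retained]))
  for (g in lost) {
    own <- sh[dsm$shrna_targets[sh] == g]
    best <- own[order(-vapply(own, function(s)
      stats::median(dsm$cor[, s]), 0), own)[1L]]
    retained <- c(retained, best)
    fallback <- c(fallback, g)
  }
  if (length(fallback))
    warning("cluster pruning removed every shRNA for: ",
            paste(fallback, collapse = ", "),
            "; kept their single best shRNA")
  structure(list(retained = sh[sh %in% retained],
                 cluster = cl,
                 median_correlation = stats::setNames(med, c("1", "2")),
                 fallback = fallback),
            class = "shrna_selection")
}

#' Rank drugs per shRNA and select top candidates per target gene
#'
#' Per retained shRNA column, drugs are ranked in ascending order of
#' correlation so the strongest correlation gets the largest rank; the top
#' set is the `floor(top_fraction * n_drugs)` largest ranks. A drug is a
#' candidate for a gene only if it sits in the top set of every retained
#' shRNA of that gene; candidates are scored by the median rank across those
#' shRNAs and the `n_select` highest-median-rank drugs are returned (ties:
#' higher mean correlation, then compound id).
#'
#' @param dsm a [collapse_dose_time()] result.
#' @param selection a [filter_shrna_clusters()] result.
#' @param top_fraction per-shRNA top rank fraction (default 0.05).
#' @param n_select drugs returned per gene (default 3).
#' @return data.frame of class `drug_candidates`: target, compound,
#'   median_rank, mean_correlation; the per-shRNA rank matrices are attached
#'   as attribute `"ranks"` (one matrix per gene).
#' @export
rank_and_select <- function(dsm, selection, top_fraction = 0.05,
                            n_select = 3L) {
  stopifnot(inherits(dsm, "drug_shrna_matrix"),
            inherits(selection, "shrna_selection"))
  m <- dsm$cor[, selection$retained, drop = FALSE]
  nd <- nrow(m)
  k <- floor(top_fraction * nd)
  if (k < 1) stop("top fraction keeps no drugs")
  ranks <- apply(m, 2L, rank, ties.method = "average")
  topset <- apply(m, 2L, function(v)
    rownames(m)[order(-v, rownames(m))[seq_len(k)]], simplify = FALSE)
  targets <- sort(unique(dsm$shrna_targets[selection$retained]))
  rank_store <- list()
  res <- lapply(targets, function(g) {
    own <- selection$retained[dsm$shrna_targets[selection$retained] == g]
    cand <- Reduce(intersect, topset[own])
    if (!length(cand)) {
      warning("no common top-fraction drug for ", g)
      return(NULL)
    }
    r <- ranks[cand, own, drop = FALSE]
    rank_store[[g]] <<- r
    med <- apply(r, 1L, stats::median)
    mc <- rowMeans(m[cand, own, drop = FALSE])
    ord <- order(-med, -mc, cand)[seq_len(min(n_select, length(cand)))]
    data.frame(target = g, compound = cand[ord], median_rank = med[ord],
               mean_correlation = mc[ord], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(target = character(0), compound = character(0),
                      median_rank = numeric(0), mean_correlation = numeric(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "ranks") <- rank_store
  class(out) <- c("drug_candidates", "data.frame")
  out
}
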