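#' Upper-tail hypergeometric overlap test
#'
#' Probability of observing at least the seen overlap between two gene sets
#' drawn from a finite universe: `P(X >= |A n B|)` for `X` hypergeometric
#' with population `|universe|`, successes `|A|`, draws `|B|`.
#'
#' @param a,b gene sets (character vectors), both subsets of `universe`.
#' @param universe the finite gene universe.
#' @return the p-value.
#' @export
hypergeometric_overlap <- function(a, b, universe) {
  a <- unique(a); b <- unique(b); universe <- unique(universe)
  if (!length(universe)) stop("universe is empty")
  if (!all(a %in% universe) || !all(b %in% universe))
    stop("sets must be contained in the universe")
  k <- length(intersect(a, b))
  stats::phyper(k - 1, length(a), length(universe) - length(a), length(b),
                lower.tail = FALSE)
}

#' Label a module by SPG enrichment
#'
#' A module is favorable when it overlaps the favorable SPGs more than
#' expected by chance (hypergeometric p < `alpha`), unfavorable analogously;
#' if both tests are significant the smaller p-value wins (reported via a
#' message); otherwise the module is non-prognostic.
#'
#' @param module_genes the module's gene set.
#' @param favorable,unfavorable SPG gene sets by direction.
#' @param universe gene universe (typically the GCN's node set).
#' @param alpha significance level on the raw p-value (default 0.05).
#' @return list: `label`, `p_favorable`, `p_unfavorable`.
#' @export
annotate_module_prognosis <- function(module_genes, favorable, unfavorable,
                                      universe, alpha = 0.05) {
  if (!length(favorable) && !length(unfavorable)) {
    warning("empty SPG sets: all modules non-prognostic")
    return(list(label = "non-prognostic", p_favorable = 1, p_unfavorable = 1))
  }
  p_f <- if (length(favorable))
    hypergeometric_overlap(module_genes, favorable, universe) else 1
  p_u <- if (length(unfavorable))
    hypergeometric_overlap(module_genes, unfavorable, universe) else 1
  label <- "non-prognostic"
  if (p_f < alpha && p_u < alpha) {
    label <- if (p_f <= p_u) "favorable" else "unfavorable"
    message("module significant for both directions; smaller p wins (",
            label, ")")
  } else if (p_f < alpha) label <- "favorable"
  else if (p_u < alpha) label <- "unfavorable"
  list(label = label, p_favorable = p_f, p_unfavorable = p_u)
}

#' Pair prognostic modules across cohorts by overlap
#'
#' Tests every (cohort A prognostic module) x (cohort B prognostic module)
#' pair for overlap with the upper-tail hypergeometric test on the shared
#' gene universe, adjusts with BH over exactly those tests, and returns pairs
#' with FDR below `alpha` sorted by FDR. The full tested table is attached as
#' attribute `"tested"`.
#'
#' @param modules_a,modules_b named lists of gene sets (prognostic modules).
#' @param universe genes present in both networks.
#' @param alpha FDR threshold (default 0.05).
#' @return data.frame: module_a, module_b, size_a, size_b, overlap, p, fdr.
#' @export
pair_modules_cross_cohort <- function(modules_a, modules_b, universe,
                                      alpha = 0.05) {
  if (!length(modules_a) || !length(modules_b)) {
    out <- data.frame(module_a = character(0), module_b = character(0),
                      size_a = integer(0), size_b = integer(0),
                      overlap = integer(0), p = numeric(0), fdr = numeric(0),
                      stringsAsFactors = FALSE)
    attr(out, "tested") <- out
    return(out)
  }
  modules_a <- lapply(modules_a, intersect, universe)
  modules_b <- lapply(modules_b, intersect, universe)
  grid <- expand.grid(module_a = names(modules_a), module_b = names(modules_b),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$size_a <- lengths(modules_a)[grid$module_a]
  grid$size_b <- lengths(modules_b)[grid$module_b]
  grid$overlap <- mapply(function(i, j)
    length(intersect(modules_a[[i]], modules_b[[j]])),
    grid$module_a, grid$module_b)
  grid$p <- mapply(function(i, j)
    hypergeometric_overlap(modules_a[[i]], modules_b[[j]], universe),
    grid$module_a, grid$module_b)
  grid$fdr <- benjamini_hochberg(grid$p)
  out <- grid[!is.na(grid$fdr) & grid$fdr < alpha, , drop = FALSE]
  out <- out[order(out$fdr, out$module_a, out$module_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tested") <- grid
  out
}
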