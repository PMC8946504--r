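#' Pipeline configuration
#'
#' All tunable thresholds of the screening / network / repositioning
#' pipeline, validated against their documented ranges. The defaults are the
#' conventional cutoffs of the method: mean FPKM >= 1, 20th--80th percentile
#' cutoff band, FDR 0.05, top 0.5% of correlations as edges, modules of more
#' than 20 nodes with transitivity above 0.5, top-10% hubs, essentiality
#' below -1.5, top-5% drug ranks, 3 drugs per target, Walktrap walk length 4.
#'
#' @param min_mean_fpkm expressed-gene mean FPKM threshold.
#' @param percentile_band KM candidate-cutoff percentile band.
#' @param fdr FDR / significance threshold used throughout.
#' @param edge_retention fraction of gene pairs kept as network edges.
#' @param module_min_nodes minimum module size (strictly more than
#'   `module_min_nodes - 1` genes).
#' @param module_min_transitivity strict transitivity lower bound.
#' @param hub_fraction per-metric top hub fraction.
#' @param essentiality_threshold strict upper bound on median essentiality.
#' @param drug_top_fraction per-shRNA top drug rank fraction.
#' @param n_select drugs selected per target gene.
#' @param walk_length Walktrap random-walk length.
#' @param seed integer seed recorded in run summaries.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_mean_fpkm = 1,
                            percentile_band = c(20, 80),
                            fdr = 0.05,
                            edge_retention = 0.005,
                            module_min_nodes = 21L,
                            module_min_transitivity = 0.5,
                            hub_fraction = 0.10,
                            essentiality_threshold = -1.5,
                            drug_top_fraction = 0.05,
                            n_select = 3L,
                            walk_length = 4L,
                            seed = 1L) {
  if (min_mean_fpkm < 0) stop("min_mean_fpkm must be non-negative")
  if (length(percentile_band) != 2 || percentile_band[1] < 0 ||
      percentile_band[2] > 100 || percentile_band[1] >= percentile_band[2])
    stop("percentile_band must be an increasing pair within [0,100]")
  if (fdr <= 0 || fdr >= 1) stop("fdr must lie in (0,1)")
  if (edge_retention <= 0 || edge_retention > 1)
    stop("edge_retention must lie in (0,1]")
  if (module_min_nodes < 1) stop("module_min_nodes must be positive")
  if (module_min_transitivity < 0 || module_min_transitivity > 1)
    stop("module_min_transitivity must lie in [0,1]")
  if (hub_fraction <= 0 || hub_fraction > 1)
    stop("hub_fraction must lie in (0,1]")
  if (drug_top_fraction <= 0 || drug_top_fraction > 1)
    stop("drug_top_fraction must lie in (0,1]")
  if (n_select < 1) stop("n_select must be positive")
  if (walk_length < 1) stop("walk_length must be positive")
  structure(list(min_mean_fpkm = min_mean_fpkm,
                 percentile_band = percentile_band,
                 fdr = fdr,
                 edge_retention = edge_retention,
                 module_min_nodes = as.integer(module_min_nodes),
                 module_min_transitivity = module_min_transitivity,
                 hub_fraction = hub_fraction,
                 essentiality_threshold = essentiality_threshold,
                 drug_top_fraction = drug_top_fraction,
                 n_select = as.integer(n_select),
                 walk_length = as.integer(walk_length),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration (JSON round-trip)
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = FALSE, digits = NA)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full screening / network / repositioning pipeline
#'
#' Executes all stages in order on a pair of expression cohorts, a
#' perturbation dataset and an essentiality table: expressed-gene filtering,
#' dual-cohort Cox + optimal-cutoff KM screening with BH correction and SPG
#' consensus, per-cohort co-expression networks with Walktrap modules,
#' module prognosis labels and cross-cohort module pairing, per-metric hub
#' extraction and candidate targets with essentiality filtering, and
#' drug--shRNA signature matching with top-drug selection.
#'
#' @param inputs list with `cohort_a`, `cohort_b` ([expression_cohort()]),
#'   `perturbation` (`perturbation_dataset`), `essentiality` (gene x cell
#'   line matrix).
#' @param config a [pipeline_config()].
#' @param outdir optional directory; when given, every intermediate table
#'   and a JSON run summary are written there.
#' @return list of class `gcn_pipeline`: all stage outputs plus `summary`
#'   (counts surviving each stage, thresholds, warnings).
#' @export
run_pipeline <- function(inputs, config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"),
            inherits(inputs$cohort_a, "expression_cohort"),
            inherits(inputs$cohort_b, "expression_cohort"))
  warn_log <- character(0)
  note <- function(...) warn_log <<- c(warn_log, paste0(...))
  wcall <- function(expr) withCallingHandlers(expr, warning = function(w) {
    note(conditionMessage(w)); invokeRestart("muffleWarning")
  })

  # 1. expressed genes, shared across cohorts
  filt <- stage("filter_expressed", {
    ea <- filter_expressed(inputs$cohort_a$expression, config$min_mean_fpkm)
    eb <- filter_expressed(inputs$cohort_b$expression, config$min_mean_fpkm)
    shared <- intersect(rownames(ea), rownames(eb))
    if (length(shared) < 10) stop("fewer than 10 shared expressed genes")
    list(a = ea[shared, , drop = FALSE], b = eb[shared, , drop = FALSE],
         shared = shared)
  })
  ca <- inputs$cohort_a; ca$expression <- filt$a
  cb <- inputs$cohort_b; cb$expression <- filt$b

  concordance <- stage("qc_concordance",
                       cohort_expression_concordance(ca, cb))

  # 2. survival screening and SPG consensus
  prog_a <- stage("screen_cohort_a",
                  screen_cohort(ca, band = config$percentile_band))
  prog_b <- stage("screen_cohort_b",
                  screen_cohort(cb, band = config$percentile_band))
  spgs <- stage("derive_spgs", derive_spgs(prog_a, prog_b, config$fdr))

  # 3. co-expression networks and modules
  make_net <- function(expr) {
    net <- build_gcn(spearman_matrix(expr), config$edge_retention)
    mods <- detect_modules(net, steps = config$walk_length)
    kept <- filter_modules(net, mods, config$module_min_nodes,
                           config$module_min_transitivity)
    list(net = net, modules = mods, kept = kept)
  }
  na <- stage("network_a", make_net(filt$a))
  nb <- stage("network_b", make_net(filt$b))

  # 4. module prognosis labels
  fav <- spgs$gene[spgs$direction == "favorable"]
  unf <- spgs$gene[spgs$direction == "unfavorable"]
  label_modules <- function(nw) {
    nodes <- igraph::V(nw$net$graph)$name
    sets <- split(nw$kept$gene, nw$kept$module)
    labs <- lapply(sets, function(g)
      wcall(annotate_module_prognosis(g, intersect(fav, nodes),
                                      intersect(unf, nodes), nodes,
                                      config$fdr)))
    data.frame(module = names(sets), size = lengths(sets),
               label = vapply(labs, `[[`, "", "label"),
               p_favorable = vapply(labs, `[[`, 0, "p_favorable"),
               p_unfavorable = vapply(labs, `[[`, 0, "p_unfavorable"),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  lab_a <- stage("label_modules_a", label_modules(na))
  lab_b <- stage("label_modules_b", label_modules(nb))

  # 5. cross-cohort pairing of prognostic modules
  pairs <- stage("pair_modules", {
    prog_mods <- function(nw, lab) {
      sets <- split(nw$kept$gene, nw$kept$module)
      sets[lab$module[lab$label != "non-prognostic"]]
    }
    shared_nodes <- intersect(igraph::V(na$net$graph)$name,
                              igraph::V(nb$net$graph)$name)
    pair_modules_cross_cohort(prog_mods(na, lab_a), prog_mods(nb, lab_b),
                              shared_nodes, config$fdr)
  })

  # 6. hubs and candidate targets (union over concordant pairs)
  hubs <- stage("hub_selection", {
    shared_nodes <- intersect(igraph::V(na$net$graph)$name,
                              igraph::V(nb$net$graph)$name)
    sets_a <- split(na$kept$gene, na$kept$module)
    sets_b <- split(nb$kept$gene, nb$kept$module)
    per_pair <- lapply(seq_len(nrow(pairs)), function(i) {
      cent_a <- module_centralities(na$net, sets_a[[pairs$module_a[i]]])
      cent_b <- module_centralities(nb$net, sets_b[[pairs$module_b[i]]])
      sh <- lapply(c(degree = "degree", betweenness = "betweenness",
                     closeness = "closeness"), function(mt)
        wcall(shared_hub_genes(top_fraction(cent_a, mt, config$hub_fraction),
                               top_fraction(cent_b, mt, config$hub_fraction),
                               shared_nodes)))
      list(pair = sprintf("%s-%s", pairs$module_a[i], pairs$module_b[i]),
           shared = lapply(sh, `[[`, "genes"),
           p = vapply(sh, `[[`, 0, "p"),
           candidates = candidate_targets(lapply(sh, `[[`, "genes"),
                                          spgs$gene))
    })
    list(per_pair = per_pair,
         candidates = sort(unique(unlist(lapply(per_pair, `[[`,
                                                "candidates")))))
  })

  targets <- stage("essentiality_filter", {
    if (!length(hubs$candidates)) {
      note("no candidate target genes; essentiality filter skipped")
      data.frame(gene = character(0), essentiality = numeric(0),
                 keep = logical(0), stringsAsFactors = FALSE)
    } else if (is.null(inputs$essentiality)) {
      note("no essentiality table supplied; candidates kept unfiltered")
      data.frame(gene = hubs$candidates, essentiality = NA_real_,
                 keep = TRUE, stringsAsFactors = FALSE)
    } else {
      wcall(essentiality_filter(hubs$candidates, inputs$essentiality,
                                config$essentiality_threshold))
    }
  })
  final_targets <- targets$gene[targets$keep]

  # 7. drug repositioning
  drugs <- stage("drug_repositioning", {
    if (!length(final_targets) || is.null(inputs$perturbation)) {
      note("repositioning skipped: no targets or no perturbation data")
      NULL
    } else {
      pc <- drug_shrna_correlations(inputs$perturbation, final_targets)
      dsm <- collapse_dose_time(pc)
      sel <- wcall(filter_shrna_clusters(dsm))
      cand <- wcall(rank_and_select(dsm, sel, config$drug_top_fraction,
                                    config$n_select))
      list(matrix = dsm, selection = sel, candidates = cand)
    }
  })

  summary <- list(
    seed = config$seed,
    thresholds = unclass(config),
    n_expressed_a = nrow(filter_expressed(inputs$cohort_a$expression,
                                          config$min_mean_fpkm)),
    n_expressed_b = nrow(filter_expressed(inputs$cohort_b$expression,
                                          config$min_mean_fpkm)),
    n_shared_expressed = length(filt$shared),
    expression_concordance = concordance,
    n_spgs = nrow(spgs),
    n_spgs_unfavorable = sum(spgs$direction == "unfavorable"),
    n_edges_a = na$net$n_edges, n_edges_b = nb$net$n_edges,
    n_modules_a = nrow(attr(na$kept, "stats")),
    n_modules_b = nrow(attr(nb$kept, "stats")),
    n_prognostic_modules_a = sum(lab_a$label != "non-prognostic"),
    n_prognostic_modules_b = sum(lab_b$label != "non-prognostic"),
    n_module_pairs = nrow(pairs),
    n_candidate_targets = length(hubs$candidates),
    n_final_targets = length(final_targets),
    n_shrna_retained = if (!is.null(drugs))
      length(drugs$selection$retained) else 0L,
    n_drug_candidates = if (!is.null(drugs)) nrow(drugs$candidates) else 0L,
    warnings = warn_log)

  result <- structure(list(
    config = config, spgs = spgs, prognosis_a = prog_a, prognosis_b = prog_b,
    network_a = na$net, network_b = nb$net,
    modules_a = na$kept, modules_b = nb$kept,
    module_labels_a = lab_a, module_labels_b = lab_b,
    module_pairs = pairs, hubs = hubs, targets = targets,
    final_targets = final_targets, drugs = drugs,
    summary = summary), class = "gcn_pipeline")

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(x, f) utils::write.table(x, file.path(outdir, f),
                                            sep = "\t", quote = FALSE,
                                            row.names = FALSE)
    wt(prog_a, "prognosis_a.tsv"); wt(prog_b, "prognosis_b.tsv")
    wt(spgs, "spgs.tsv")
    write_network_tsv(na$net, file.path(outdir, "network_a.tsv"))
    write_network_tsv(nb$net, file.path(outdir, "network_b.tsv"))
    wt(na$kept, "modules_a.tsv"); wt(nb$kept, "modules_b.tsv")
    wt(lab_a, "module_labels_a.tsv"); wt(lab_b, "module_labels_b.tsv")
    wt(pairs, "module_pairs.tsv")
    wt(targets, "targets.tsv")
    if (!is.null(drugs)) wt(drugs$candidates, "drug_candidates.tsv")
    jsonlite::write_json(summary, file.path(outdir, "run_summary.json"),
                         auto_unbox = TRUE, digits = 10)
  }
  result
}

#' Generate a synthetic study and run the pipeline on it
#'
#' @param spec a [synthetic_spec()]; the pipeline seed is taken from it.
#' @param config a [pipeline_config()].
#' @param outdir optional output directory, see [run_pipeline()].
#' @param n_cell_lines cell lines in the generated essentiality table.
#' @return a `gcn_pipeline` result with the generated `truth` attached.
#' @export
run_pipeline_synthetic <- function(spec, config = pipeline_config(seed = spec$seed),
                                   outdir = NULL, n_cell_lines = 16L) {
  pair <- generate_cohort_pair(spec)
  pert <- generate_perturbation_dataset(spec, pair$truth)
  ess <- generate_essentiality_table(rownames(pair$cohort_a$expression),
                                     n_cell_lines, pair$truth,
                                     seed = spec$seed + 2L)
  res <- run_pipeline(list(cohort_a = pair$cohort_a, cohort_b = pair$cohort_b,
                           perturbation = pert, essentiality = ess),
                      config, outdir)
  res$truth <- pair$truth
  res
}

#' @export
print.gcn_pipeline <- function(x, ...) {
  s <- x$summary
  cat("Co-expression network drug-repositioning run (seed ", s$seed, ")\n",
      sep = "")
  cat("  expressed genes (shared):", s$n_shared_expressed,
      " | expression concordance rho:", round(s$expression_concordance, 3), "\n")
  cat("  SPGs:", s$n_spgs, "(", s$n_spgs_unfavorable, "unfavorable )\n")
  cat("  modules kept A/B:", s$n_modules_a, "/", s$n_modules_b,
      "| prognostic:", s$n_prognostic_modules_a, "/",
      s$n_prognostic_modules_b, "| concordant pairs:", s$n_module_pairs, "\n")
  cat("  candidate targets:", s$n_candidate_targets,
      "| after essentiality filter:", s$n_final_targets, "\n")
  cat("  retained shRNAs:", s$n_shrna_retained,
      "| drug candidates:", s$n_drug_candidates, "\n")
  invisible(x)
}

#' @export
summary.gcn_pipeline <- function(object, ...) object$summary
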