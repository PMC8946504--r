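#' Specification for a synthetic drug-repositioning study
#'
#' Collects every parameter of the synthetic data generators in one validated
#' object: two expression cohorts with shared correlated gene blocks, survival
#' linked to planted prognostic genes, a perturbation signature dataset with
#' planted drug/shRNA mimicry, and a gene essentiality table.
#'
#' @param n_genes total number of genes per cohort.
#' @param n_samples samples per cohort; length 1 (both cohorts) or 2.
#' @param block_sizes sizes of the correlated gene blocks (first block is the
#'   planted unfavorable prognostic block, second -- if present -- favorable).
#' @param loading maximum within-block latent-factor loading, in [0,1].
#'   Within a block, the first ~10% of genes (the planted hubs) carry the
#'   full `loading` and the rest descend linearly from `0.9 * loading` to
#'   `0.7 * loading`; pairwise correlations approximate the product of the
#'   two genes' loadings, so each block has well-defined most-loaded hub
#'   genes.
#' @param effect_size log hazard ratio per standard deviation of log
#'   expression for a planted prognostic gene (approximately; exact for
#'   singleton blocks). 0 plants no prognostic genes.
#' @param censoring target fraction of right-censored samples, in [0,1).
#' @param n_landmark number of landmark genes in perturbation signatures.
#' @param n_drugs number of distinct compounds (matching drugs + decoys).
#' @param n_targets number of planted drug-target genes (taken from the most
#'   loaded genes of block 1); these also form the planted essential gene set.
#' @param drugs_per_target matching compounds planted per target gene.
#' @param shrna_per_target shRNA instances generated per target gene.
#' @param dose_levels,time_levels dose and time points per compound.
#' @param noise_sd standard deviation (z-score units) of the independent noise
#'   added to each planted signature instance.
#' @param seed integer seed; identical spec + seed gives identical output.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 1100L,
                           n_samples = c(300L, 300L),
                           block_sizes = c(50L, 50L, 50L),
                           loading = 0.9,
                           effect_size = 0.7,
                           censoring = 0.3,
                           n_landmark = 978L,
                           n_drugs = 600L,
                           n_targets = 5L,
                           drugs_per_target = 2L,
                           shrna_per_target = 3L,
                           dose_levels = 3L,
                           time_levels = 2L,
                           noise_sd = 0.5,
                           seed = 1L) {
  if (length(n_samples) == 1L) n_samples <- rep(n_samples, 2L)
  counts <- c(n_genes = n_genes, n_samples, block_sizes,
              n_landmark = n_landmark, n_drugs = n_drugs,
              n_targets = n_targets, drugs_per_target = drugs_per_target,
              shrna_per_target = shrna_per_target,
              dose_levels = dose_levels, time_levels = time_levels)
  if (any(counts <= 0) || any(counts != round(counts)))
    stop("all counts must be positive integers")
  if (sum(block_sizes) > n_genes)
    stop("block sizes sum to more than n_genes")
  if (!is.finite(effect_size)) stop("effect size must be finite")
  if (loading < 0 || loading > 1) stop("loading must lie in [0,1]")
  if (censoring < 0 || censoring >= 1) stop("censoring fraction must lie in [0,1)")
  if (noise_sd < 0) stop("noise sd must be non-negative")
  if (n_targets > block_sizes[1L])
    stop("n_targets exceeds the size of block 1")
  if (n_targets * drugs_per_target > n_drugs)
    stop("more matching compounds than compounds")
  structure(list(
    n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
    block_sizes = as.integer(block_sizes), loading = loading,
    effect_size = effect_size, censoring = censoring,
    n_landmark = as.integer(n_landmark), n_drugs = as.integer(n_drugs),
    n_targets = as.integer(n_targets),
    drugs_per_target = as.integer(drugs_per_target),
    shrna_per_target = as.integer(shrna_per_target),
    dose_levels = as.integer(dose_levels),
    time_levels = as.integer(time_levels),
    noise_sd = noise_sd, seed = as.integer(seed)), class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("Synthetic study spec:", x$n_genes, "genes;",
      paste(x$n_samples, collapse = "/"), "samples;",
      length(x$block_sizes), "blocks (",
      paste(x$block_sizes, collapse = ","), "); loading", x$loading,
      "; log-HR", x$effect_size, "; seed", x$seed, "\n")
  invisible(x)
}

gene_ids <- function(n) sprintf("G%04d", seq_len(n))

# per-gene latent-factor loadings: a plateau of hub genes at the full
# loading, then a linear gradient; the gap keeps the planted hubs' degree
# ranks above correlation sampling noise
block_loadings <- function(spec) {
  unlist(lapply(spec$block_sizes, function(s) {
    h <- max(1L, ceiling(0.1 * s))
    if (h >= s) return(rep(spec$loading, s))
    spec$loading * c(rep(1, h), seq(0.9, 0.7, length.out = s - h))
  }), use.names = FALSE)
}

#' Generate a pair of expression cohorts with planted ground truth
#'
#' Both cohorts share the gene list, block assignments and loadings (the
#' correlation structure is shared; samples are independent). Expression is
#' log-normal: `FPKM = exp(mu_g + z)` where `z` is a unit-variance Gaussian
#' with a single latent factor per block. Survival times are exponential
#' proportional hazards with log hazard linear in the planted prognostic
#' genes' standardized log expression (block 1 unfavorable, block 2
#' favorable); censoring is independent uniform, calibrated to hit the
#' requested fraction in expectation.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `cohort_a`, `cohort_b` (class
#'   `expression_cohort`) and `truth` (class `ground_truth`).
#' @export
generate_cohort_pair <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  genes <- gene_ids(spec$n_genes)
  nb <- length(spec$block_sizes)
  block <- rep(NA_integer_, spec$n_genes)
  block[seq_len(sum(spec$block_sizes))] <- rep(seq_len(nb), spec$block_sizes)
  load <- rep(0, spec$n_genes)
  load[!is.na(block)] <- block_loadings(spec)

  # baselines on log scale: block genes well-expressed, background spans the
  # mean-FPKM >= 1 filter boundary
  mu <- ifelse(is.na(block), stats::rnorm(spec$n_genes, 1.2, 1.2),
               stats::rnorm(spec$n_genes, 2.0, 0.5))

  prognostic <- character(0)
  if (spec$effect_size != 0) {
    prognostic <- c(stats::setNames(rep("unfavorable", spec$block_sizes[1L]),
                                    genes[block %in% 1L]),
                    if (nb >= 2L)
                      stats::setNames(rep("favorable", spec$block_sizes[2L]),
                                      genes[block %in% 2L]))
  }

  targets <- genes[which(block == 1L)[seq_len(spec$n_targets)]]
  cp_ids <- sprintf("CP%04d", seq_len(spec$n_drugs))
  matching <- stats::setNames(
    split(cp_ids[seq_len(spec$n_targets * spec$drugs_per_target)],
          rep(seq_len(spec$n_targets), each = spec$drugs_per_target)),
    targets)

  truth <- structure(list(
    prognostic_genes = prognostic,
    module_assignments = stats::setNames(block[!is.na(block)],
                                         genes[!is.na(block)]),
    matching_drugs = matching,
    essential_genes = targets,
    targets = targets,
    loadings = stats::setNames(load, genes)), class = "ground_truth")

  make_cohort <- function(id, n) {
    f <- matrix(stats::rnorm(n * nb), n, nb)          # latent block factors
    z <- matrix(stats::rnorm(n * spec$n_genes), n, spec$n_genes)
    inb <- !is.na(block)
    z[, inb] <- sweep(f[, block[inb], drop = FALSE], 2, load[inb], `*`) +
      sweep(z[, inb, drop = FALSE], 2, sqrt(1 - load[inb]^2), `*`)
    expr <- exp(sweep(z, 2, mu, `+`))                 # FPKM-like, samples x genes

    lp <- rep(0, n)
    if (spec$effect_size != 0) {
      # weights solve C w = effect for the block correlation matrix
      # C = diag(1 - l^2) + l l', so every planted gene's marginal
      # (univariable) log hazard ratio equals effect_size exactly
      bscore <- function(b) {
        ix <- which(block %in% b)
        l <- load[ix]
        C <- diag(1 - l^2, length(ix)) + outer(l, l)
        w <- spec$effect_size * solve(C, rep(1, length(ix)))
        drop(z[, ix, drop = FALSE] %*% w)
      }
      lp <- bscore(1L)
      if (nb >= 2L) lp <- lp - bscore(2L)
    }
    lambda <- log(2) / 730 * exp(lp)                  # baseline median ~2 years
    t_true <- stats::rexp(n, lambda)
    if (spec$censoring > 0) {
      cfrac <- function(u) mean((1 - exp(-lambda * u)) / (lambda * u))
      u <- stats::uniroot(function(u) cfrac(u) - spec$censoring,
                          c(1e-6, 1e9), tol = 1e-6)$root
      cens <- stats::runif(n, 0, u)
      time <- pmin(t_true, cens)
      event <- as.integer(t_true <= cens)
    } else {
      time <- t_true
      event <- rep(1L, n)
    }
    samples <- sprintf("%s_S%04d", id, seq_len(n))
    m <- t(expr)
    dimnames(m) <- list(genes, samples)
    expression_cohort(id, m,
                      data.frame(sample = samples, time = time, event = event,
                                 stringsAsFactors = FALSE))
  }

  list(cohort_a = make_cohort("A", spec$n_samples[1L]),
       cohort_b = make_cohort("B", spec$n_samples[2L]),
       truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Planted ground truth:", length(x$prognostic_genes), "prognostic genes,",
      length(unique(x$module_assignments)), "blocks,",
      length(x$targets), "drug targets,",
      length(unlist(x$matching_drugs)), "matching compounds\n")
  invisible(x)
}

#' Generate a perturbation signature dataset with planted drug--shRNA mimicry
#'
#' Each planted target gene gets a shared knockdown effect vector over the
#' landmark genes; its shRNA instances are that vector plus independent
#' Gaussian noise, and each matching compound gets one instance per dose/time
#' level equal to the effect vector scaled by `dose / max(dose)` plus noise
#' (so the strongest planted connection sits at the highest dose). Decoy
#' compounds are pure standard-normal noise at every dose/time level.
#'
#' @param spec a [synthetic_spec()].
#' @param truth ground truth from [generate_cohort_pair()].
#' @return object of class `perturbation_dataset`: list with `signatures`
#'   (landmark gene x instance matrix of moderated z-scores) and `meta`
#'   (instance metadata: type, target gene, compound id, dose, time).
#' @export
generate_perturbation_dataset <- function(spec, truth) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(truth, "ground_truth"))
  if (spec$n_landmark < 10)
    stop("n_landmark < 10: signatures too short for rank correlation")
  if (!length(truth$matching_drugs)) stop("truth$matching_drugs is empty")
  set.seed(spec$seed + 1L)

  landmarks <- sprintf("L%04d", seq_len(spec$n_landmark))
  targets <- names(truth$matching_drugs)
  effects <- matrix(stats::rnorm(spec$n_landmark * length(targets)),
                    spec$n_landmark, length(targets),
                    dimnames = list(landmarks, targets))

  doses <- signif(10 * (1 / 3)^((spec$dose_levels - 1):0), 3)
  times <- c(6L, 24L, 48L, 96L)[seq_len(spec$time_levels)]
  cp_ids <- sprintf("CP%04d", seq_len(spec$n_drugs))
  drug_of <- stats::setNames(rep(NA_character_, spec$n_drugs), cp_ids)
  for (g in targets) drug_of[truth$matching_drugs[[g]]] <- g

  grid <- expand.grid(dose = doses, time = times, compound = cp_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_cp <- nrow(grid)
  sig_cp <- matrix(stats::rnorm(spec$n_landmark * n_cp), spec$n_landmark, n_cp)
  planted <- !is.na(drug_of[grid$compound])
  if (any(planted)) {
    fac <- grid$dose[planted] / max(doses)
    sig_cp[, planted] <- effects[, drug_of[grid$compound[planted]], drop = FALSE] %*%
      diag(fac, sum(planted)) +
      matrix(stats::rnorm(spec$n_landmark * sum(planted), 0, spec$noise_sd),
             spec$n_landmark)
  }
  cp_names <- sprintf("%s_D%g_T%d", grid$compound, grid$dose, grid$time)

  n_sh <- length(targets) * spec$shrna_per_target
  sh_target <- rep(targets, each = spec$shrna_per_target)
  sig_sh <- effects[, sh_target, drop = FALSE] +
    matrix(stats::rnorm(spec$n_landmark * n_sh, 0, spec$noise_sd),
           spec$n_landmark)
  sh_names <- sprintf("SH_%s_%d", sh_target,
                      rep(seq_len(spec$shrna_per_target), length(targets)))

  signatures <- cbind(sig_cp, sig_sh)
  dimnames(signatures) <- list(landmarks, c(cp_names, sh_names))
  meta <- data.frame(
    instance = c(cp_names, sh_names),
    type = c(rep("compound", n_cp), rep("shRNA", n_sh)),
    target = c(rep(NA_character_, n_cp), sh_target),
    compound_id = c(grid$compound, rep(NA_character_, n_sh)),
    dose = c(grid$dose, rep(NA_real_, n_sh)),
    time = c(grid$time, rep(NA_integer_, n_sh)),
    stringsAsFactors = FALSE)
  structure(list(signatures = signatures, meta = meta),
            class = "perturbation_dataset")
}

#' @export
print.perturbation_dataset <- function(x, ...) {
  cat("Perturbation dataset:", nrow(x$signatures), "landmark genes x",
      ncol(x$signatures), "instances (",
      sum(x$meta$type == "shRNA"), "shRNA,",
      length(unique(stats::na.omit(x$meta$compound_id))), "compounds )\n")
  invisible(x)
}

#' Generate a gene essentiality score table
#'
#' Planted essential genes receive scores centered well below the -1.5
#' selection threshold; all other genes are centered near zero, emulating
#' CRISPR-screen gene effect scores across cell lines.
#'
#' @param genes gene ids (rows of the table).
#' @param n_cell_lines number of cell lines (columns).
#' @param truth ground truth carrying `essential_genes`.
#' @param seed integer seed.
#' @param essential_center,essential_sd score distribution of planted genes.
#' @param background_center,background_sd score distribution of other genes.
#' @return numeric matrix gene x cell line.
#' @export
generate_essentiality_table <- function(genes, n_cell_lines = 16L, truth,
                                        seed = 1L,
                                        essential_center = -2.0,
                                        essential_sd = 0.2,
                                        background_center = 0,
                                        background_sd = 0.3) {
  if (n_cell_lines < 1) stop("n_cell_lines must be at least 1")
  if (!all(truth$essential_genes %in% genes))
    stop("essential genes must be a subset of `genes`")
  set.seed(seed)
  center <- ifelse(genes %in% truth$essential_genes,
                   essential_center, background_center)
  sdv <- ifelse(genes %in% truth$essential_genes, essential_sd, background_sd)
  m <- matrix(stats::rnorm(length(genes) * n_cell_lines, center, sdv),
              length(genes), n_cell_lines,
              dimnames = list(genes, sprintf("CL%02d", seq_len(n_cell_lines))))
  m
}
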