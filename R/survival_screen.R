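#' Expression cohort container
#'
#' Pairs a non-negative gene x sample FPKM matrix with a survival table and
#' aligns them: expression columns and survival rows are restricted to their
#' common samples, and records with non-positive follow-up time are dropped.
#'
#' @param id cohort identifier.
#' @param expression numeric matrix, genes as rows, samples as columns.
#' @param survival data.frame with columns `sample`, `time` (days), `event`
#'   (0/1).
#' @return object of class `expression_cohort`.
#' @export
expression_cohort <- function(id, expression, survival) {
  stopifnot(is.matrix(expression), !is.null(rownames(expression)),
            !is.null(colnames(expression)),
            all(c("sample", "time", "event") %in% names(survival)))
  if (any(expression < 0)) stop("expression values must be non-negative")
  if (anyDuplicated(rownames(expression))) stop("duplicate gene ids")
  n_bad <- sum(survival$time <= 0)
  if (n_bad > 0) {
    message(id, ": dropped ", n_bad, " record(s) with time <= 0")
    survival <- survival[survival$time > 0, , drop = FALSE]
  }
  common <- intersect(colnames(expression), survival$sample)
  if (!length(common)) stop("no samples shared by expression and survival")
  lost <- setdiff(union(colnames(expression), survival$sample), common)
  if (length(lost))
    message(id, ": ", length(lost), " sample(s) without both expression ",
            "and survival dropped")
  survival <- survival[match(common, survival$sample), , drop = FALSE]
  rownames(survival) <- NULL
  structure(list(id = id,
                 expression = expression[, common, drop = FALSE],
                 survival = survival),
            class = "expression_cohort")
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat("Expression cohort", x$id, ":", nrow(x$expression), "genes x",
      ncol(x$expression), "samples;", sum(x$survival$event), "events\n")
  invisible(x)
}

#' Filter genes by mean expression
#'
#' Keeps genes whose arithmetic mean FPKM is at least `min_mean` (the
#' conventional "average FPKM no less than 1" expressed-gene rule); row order
#' is preserved.
#'
#' @param expression gene x sample matrix.
#' @param min_mean minimum mean FPKM (default 1).
#' @return the filtered matrix.
#' @export
filter_expressed <- function(expression, min_mean = 1) {
  if (!is.matrix(expression) || nrow(expression) == 0 || ncol(expression) == 0)
    stop("expression matrix is empty")
  expression[rowMeans(expression) >= min_mean, , drop = FALSE]
}

# single-gene univariable Cox fit; returns c(hr, p) or flags degeneracy
cox_gene_fit <- function(time, event, x) {
  if (stats::sd(x) == 0)
    return(list(hr = NA_real_, p = NA_real_, flag = "degenerate"))
  fit <- tryCatch(
    suppressWarnings(
      survival::coxph(survival::Surv(time, event) ~ x,
                      control = survival::coxph.control(iter.max = 50))),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$coefficients[1L]))
    return(list(hr = NA_real_, p = NA_real_, flag = "nonconverged"))
  s <- summary(fit)$coefficients
  list(hr = unname(s[1L, "exp(coef)"]), p = unname(s[1L, "Pr(>|z|)"]),
       flag = "ok")
}

#' Per-gene univariable Cox screen
#'
#' Fits a single-covariate proportional-hazards model for every gene. By
#' default the covariate is the per-gene standardized `log1p(FPKM)` so the
#' hazard ratio is per standard deviation of log expression; `"identity"`
#' uses raw FPKM. Genes with zero expression variance (or non-converging
#' fits) are flagged and excluded from multiple testing.
#'
#' @param cohort an [expression_cohort()].
#' @param transform covariate scale, `"log"` (default) or `"identity"`.
#' @return data.frame: gene, hr, p, flag.
#' @export
cox_screen <- function(cohort, transform = c("log", "identity")) {
  stopifnot(inherits(cohort, "expression_cohort"))
  transform <- match.arg(transform)
  if (sum(cohort$survival$event) < 2) stop("fewer than 2 events in cohort")
  time <- cohort$survival$time
  event <- cohort$survival$event
  res <- apply(cohort$expression, 1L, function(x) {
    if (transform == "log" && stats::sd(x) > 0)
      x <- as.numeric(scale(log1p(x)))
    cox_gene_fit(time, event, x)
  })
  data.frame(gene = rownames(cohort$expression),
             hr = vapply(res, `[[`, 0, "hr"),
             p = vapply(res, `[[`, 0, "p"),
             flag = vapply(res, `[[`, "", "flag"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Optimal-cutoff Kaplan--Meier screen for one gene
#'
#' Candidate cutoffs are the distinct observed expression values whose
#' empirical percentile lies in the given band (default 20th--80th). For each
#' candidate, samples split into high (> cutoff) and low (<= cutoff) groups
#' and a two-group log-rank statistic is computed; the cutoff with the
#' smallest p-value wins (ties go to the smaller cutoff). Direction is
#' favorable when the high group has fewer observed events than its log-rank
#' expectation.
#'
#' @param x expression values (FPKM).
#' @param time,event survival follow-up and event indicator.
#' @param band percentile band for candidate cutoffs, default `c(20, 80)`.
#' @return list with `cutoff`, `p`, `direction`, `observed_high`,
#'   `expected_high`, and `flag` (`"ok"` or `"degenerate"`).
#' @export
km_optimal_cutoff <- function(x, time, event, band = c(20, 80)) {
  stopifnot(length(x) == length(time), length(time) == length(event))
  flagged <- list(cutoff = NA_real_, p = NA_real_, direction = "none",
                  observed_high = NA_real_, expected_high = NA_real_,
                  flag = "degenerate")
  if (sum(event) < 1) return(flagged)
  n <- length(x)
  ux <- sort(unique(x))
  pct <- 100 * cumsum(tabulate(match(x, ux), length(ux))) / n
  cand <- ux[pct >= band[1L] & pct <= band[2L]]
  if (length(cand) < 1L) return(flagged)

  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]; x_s <- x[ord]
  ut <- unique(t_s[e_s == 1])                # event times, ascending
  pos <- match(ut, t_s)                      # first at-risk index per time
  n_risk <- n - pos + 1L

  H <- outer(x_s, cand, `>`) * 1             # n x k high-group membership
  revcs <- apply(H[n:1, , drop = FALSE], 2L, cumsum)[n:1, , drop = FALSE]
  n1 <- revcs[pos, , drop = FALSE]           # high-group at risk per event time
  ev <- which(e_s == 1)
  ft <- match(t_s[ev], ut)                   # event-time index per event
  d <- rowsum(e_s[ev], ft)[, 1L]             # total events per event time
  d1 <- rowsum(H[ev, , drop = FALSE], ft)    # high-group events per time

  frac <- n1 / n_risk
  e1 <- d * frac
  v <- d * frac * (1 - frac) *
    ifelse(n_risk > 1, (n_risk - d) / (n_risk - 1), 0)
  oe <- colSums(d1 - e1)
  vv <- colSums(v)
  p <- ifelse(vv > 0, stats::pchisq(oe^2 / vv, 1L, lower.tail = FALSE),
              NA_real_)
  if (all(is.na(p))) return(flagged)
  best <- order(p, cand)[1L]
  o_high <- sum(d1[, best])
  e_high <- sum(e1[, best])
  list(cutoff = cand[best], p = p[best],
       direction = if (o_high < e_high) "favorable" else "unfavorable",
       observed_high = o_high, expected_high = e_high, flag = "ok")
}

#' Benjamini--Hochberg adjusted p-values
#'
#' Standard BH step-up adjustment, clipped at 1, original order restored.
#' `NA` entries (genes excluded from the multiple-testing family) pass
#' through as `NA` and do not count toward the family size.
#'
#' @param p vector of p-values in [0,1].
#' @return adjusted values in the input order.
#' @export
benjamini_hochberg <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE) || !is.numeric(p))
    stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Screen one cohort with Cox and optimal-cutoff KM analyses
#'
#' Runs [cox_screen()] and [km_optimal_cutoff()] for every gene, adjusts both
#' p-value families with [benjamini_hochberg()] over the non-degenerate genes,
#' and assigns directions (Cox: unfavorable iff HR > 1; KM: from observed vs
#' expected events in the high group).
#'
#' @param cohort an [expression_cohort()] (already expression-filtered).
#' @param band percentile band for KM candidate cutoffs.
#' @param transform Cox covariate scale, see [cox_screen()].
#' @return data.frame of class `gene_prognosis`: gene, hr, cox_p, cox_fdr,
#'   cox_dir, km_cutoff, km_p, km_fdr, km_dir, flag.
#' @export
screen_cohort <- function(cohort, band = c(20, 80),
                          transform = c("log", "identity")) {
  cox <- cox_screen(cohort, transform = match.arg(transform))
  time <- cohort$survival$time
  event <- cohort$survival$event
  km <- apply(cohort$expression, 1L, km_optimal_cutoff,
              time = time, event = event, band = band)
  out <- data.frame(
    gene = cox$gene,
    hr = cox$hr,
    cox_p = cox$p,
    cox_fdr = benjamini_hochberg(cox$p),
    cox_dir = ifelse(cox$flag != "ok", "none",
                     ifelse(cox$hr > 1, "unfavorable", "favorable")),
    km_cutoff = vapply(km, `[[`, 0, "cutoff"),
    km_p = vapply(km, `[[`, 0, "p"),
    km_dir = vapply(km, `[[`, "", "direction"),
    flag = ifelse(cox$flag != "ok", cox$flag,
                  vapply(km, `[[`, "", "flag")),
    row.names = NULL, stringsAsFactors = FALSE)
  out$km_fdr <- benjamini_hochberg(out$km_p)
  out <- out[, c("gene", "hr", "cox_p", "cox_fdr", "cox_dir",
                 "km_cutoff", "km_p", "km_fdr", "km_dir", "flag")]
  n_deg <- sum(out$flag != "ok")
  if (n_deg > 0)
    message(cohort$id, ": ", n_deg,
            " degenerate gene(s) excluded from multiple testing")
  class(out) <- c("gene_prognosis", "data.frame")
  out
}

#' Derive signature prognostic genes (SPGs) from two cohorts
#'
#' A gene is an SPG when its BH FDR is below `alpha` in the Cox and the KM
#' analysis of both cohorts and all four direction calls agree.
#'
#' @param prognosis_a,prognosis_b per-cohort [screen_cohort()] tables.
#' @param alpha FDR threshold (default 0.05).
#' @return data.frame of class `spg_set`: gene, direction, and the four FDRs.
#' @export
derive_spgs <- function(prognosis_a, prognosis_b, alpha = 0.05) {
  if (!length(intersect(prognosis_a$gene, prognosis_b$gene)))
    stop("cohorts share no genes")
  m <- merge(prognosis_a, prognosis_b, by = "gene",
             suffixes = c("_a", "_b"))
  sig <- !is.na(m$cox_fdr_a) & !is.na(m$km_fdr_a) &
    !is.na(m$cox_fdr_b) & !is.na(m$km_fdr_b) &
    m$cox_fdr_a < alpha & m$km_fdr_a < alpha &
    m$cox_fdr_b < alpha & m$km_fdr_b < alpha
  agree <- m$cox_dir_a != "none" &
    m$cox_dir_a == m$km_dir_a &
    m$cox_dir_a == m$cox_dir_b &
    m$cox_dir_a == m$km_dir_b
  keep <- sig & agree
  out <- data.frame(gene = m$gene[keep], direction = m$cox_dir_a[keep],
                    cox_fdr_a = m$cox_fdr_a[keep], km_fdr_a = m$km_fdr_a[keep],
                    cox_fdr_b = m$cox_fdr_b[keep], km_fdr_b = m$km_fdr_b[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("spg_set", "data.frame")
  out
}
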