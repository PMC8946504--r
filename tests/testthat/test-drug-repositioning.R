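toy_perturbation <- function(n_landmark = 50, seed = 1) {
  # 5 compounds x 2 doses, 3 shRNAs over 2 target genes; hand-built metadata
  set.seed(seed)
  lm <- sprintf("L%03d", seq_len(n_landmark))
  cp <- expand.grid(dose = c(1, 10), compound = sprintf("D%d", 1:5),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  inst <- c(sprintf("%s_d%g", cp$compound, cp$dose),
            "sh_tA_1", "sh_tA_2", "sh_tB_1")
  sig <- matrix(rnorm(n_landmark * length(inst)), n_landmark,
                dimnames = list(lm, inst))
  meta <- data.frame(
    instance = inst,
    type = c(rep("compound", nrow(cp)), rep("shRNA", 3)),
    target = c(rep(NA, nrow(cp)), "tA", "tA", "tB"),
    compound_id = c(cp$compound, rep(NA, 3)),
    dose = c(cp$dose, rep(NA, 3)),
    time = c(rep(24, nrow(cp)), rep(NA, 3)),
    stringsAsFactors = FALSE)
  structure(list(signatures = sig, meta = meta),
            class = "perturbation_dataset")
}

test_that("instance correlations are Spearman over landmarks, with oracle agreement", {
  d <- toy_perturbation()
  d$signatures[, "D1_d10"] <- d$signatures[, "sh_tA_1"]          # identical
  d$signatures[, "D2_d10"] <- -d$signatures[, "sh_tA_1"]         # reversed
  pc <- drug_shrna_correlations(d, c("tA", "tB"))
  expect_equal(pc$cor["D1_d10", "sh_tA_1"], 1)
  expect_equal(pc$cor["D2_d10", "sh_tA_1"], -1)
  for (i in rownames(pc$cor)[1:5]) for (j in colnames(pc$cor))
    expect_equal(pc$cor[i, j],
                 oracle_spearman(d$signatures[, i], d$signatures[, j]),
                 tolerance = 1e-12)
  # unknown target gene excluded with a message
  expect_message(pc2 <- drug_shrna_correlations(d, c("tA", "tB", "tZ")),
                 "tZ")
  expect_identical(dim(pc2$cor), dim(pc$cor))
  expect_error(drug_shrna_correlations(toy_perturbation(n_landmark = 5),
                                       "tA"), "landmark")
})

test_that("dose/time collapse keeps the per-cell maximum deterministically", {
  d <- toy_perturbation(seed = 3)
  pc <- drug_shrna_correlations(d, c("tA", "tB"))
  dsm <- collapse_dose_time(pc)
  expect_identical(rownames(dsm$cor), sprintf("D%d", 1:5))
  for (cid in rownames(dsm$cor)) {
    own <- pc$compound_meta$instance[pc$compound_meta$compound_id == cid]
    expect_equal(dsm$cor[cid, ],
                 apply(pc$cor[own, , drop = FALSE], 2, max))
  }
  # single instance per compound: matrix unchanged
  d1 <- d
  keep <- d1$meta$type == "shRNA" | d1$meta$dose %in% 10
  d1$meta <- d1$meta[keep, ]
  d1$signatures <- d1$signatures[, d1$meta$instance]
  pc1 <- drug_shrna_correlations(d1, c("tA", "tB"))
  dsm1 <- collapse_dose_time(pc1)
  expect_equal(unname(dsm1$cor), unname(pc1$cor))
  # exact ties collapse to the same value, reproducibly
  d2 <- d
  d2$signatures[, "D3_d1"] <- d2$signatures[, "D3_d10"]
  pc2 <- drug_shrna_correlations(d2, c("tA", "tB"))
  expect_equal(collapse_dose_time(pc2)$cor["D3", ],
               pc2$cor["D3_d1", ])
})

test_that("shRNA cluster pruning keeps the structured half and falls back per gene", {
  # planted: 3 on-target shRNAs share strong drug correlations, 3 off-target
  # ones share only a weak background profile centred at zero
  set.seed(9)
  n_drug <- 60
  shared <- rnorm(n_drug)
  bg <- rnorm(n_drug)
  m <- cbind(matrix(shared + rnorm(n_drug * 3, 0, 0.3), n_drug, 3) + 0.5,
             matrix(bg + rnorm(n_drug * 3, 0, 0.3), n_drug, 3))
  dimnames(m) <- list(sprintf("D%02d", 1:n_drug),
                      c("sh_g1_1", "sh_g1_2", "sh_g2_1",
                        "sh_g2_2", "sh_g3_1", "sh_g3_2"))
  dsm <- structure(list(cor = m,
                        shrna_targets = setNames(
                          c("g1", "g1", "g2", "g2", "g3", "g3"),
                          colnames(m))), class = "drug_shrna_matrix")
  expect_warning(sel <- filter_shrna_clusters(dsm), "g3")
  expect_setequal(sel$retained[1:3], c("sh_g1_1", "sh_g1_2", "sh_g2_1"))
  expect_true(any(grepl("^sh_g3", sel$retained)))   # fallback rescue
  expect_identical(sel$fallback, "g3")

  # two shRNAs: each its own cluster, higher-median one kept
  m2 <- m[, c(1, 5)]
  dsm2 <- structure(list(cor = m2, shrna_targets = setNames(
    c("g1", "g3"), colnames(m2))), class = "drug_shrna_matrix")
  expect_warning(sel2 <- filter_shrna_clusters(dsm2), "g3")
  expect_identical(sel2$retained[1], "sh_g1_1")

  # a single shRNA is returned as-is
  dsm3 <- structure(list(cor = m[, 1, drop = FALSE],
                         shrna_targets = c(sh_g1_1 = "g1")),
                    class = "drug_shrna_matrix")
  expect_identical(filter_shrna_clusters(dsm3)$retained, "sh_g1_1")
})

test_that("rank-and-select applies the top-set intersection and median-rank rule", {
  # 20 drugs x 3 shRNAs of one gene, checked against a hand-applied rule chain
  set.seed(13)
  base <- runif(20, -1, 1)
  m <- matrix(base + rnorm(60, 0, 0.15), 20, 3,
              dimnames = list(sprintf("D%02d", 1:20),
                              c("s1", "s2", "s3")))
  dsm <- structure(list(cor = m, shrna_targets = setNames(rep("g", 3),
                                                          colnames(m))),
                   class = "drug_shrna_matrix")
  sel <- structure(list(retained = colnames(m)), class = "shrna_selection")
  got <- rank_and_select(dsm, sel, top_fraction = 0.25, n_select = 3)

  # oracle: ascending ranks, top floor(0.25*20)=5 per column, intersect,
  # median rank, take 3 best
  k <- 5
  ranks <- apply(m, 2, rank)
  tops <- lapply(1:3, function(j) rownames(m)[order(-m[, j])][1:k])
  cand <- Reduce(intersect, tops)
  med <- apply(ranks[cand, , drop = FALSE], 1, median)
  ord <- cand[order(-med, -rowMeans(m[cand, , drop = FALSE]), cand)]
  expect_identical(got$compound, ord[seq_len(min(3, length(ord)))])
  expect_equal(got$median_rank, unname(med[got$compound]))

  # a drug missing from one shRNA's top set is excluded no matter how strong
  m2 <- m
  m2["D01", ] <- c(1, 1, -1)     # huge on s1/s2, bottom on s3
  dsm2 <- dsm; dsm2$cor <- m2
  got2 <- rank_and_select(dsm2, sel, top_fraction = 0.25, n_select = 20)
  expect_false("D01" %in% got2$compound)

  # rank-invariance under strictly increasing transform of a column
  m3 <- m
  m3[, 2] <- tanh(2 * m3[, 2])
  dsm3 <- dsm; dsm3$cor <- m3
  got3 <- rank_and_select(dsm3, sel, top_fraction = 0.25, n_select = 3)
  expect_identical(got3$compound, got$compound)
  expect_equal(got3$median_rank, got$median_rank)

  # empty intersection warns and yields no candidates
  m4 <- cbind(s1 = c(rep(1, 5), rep(-1, 15)), s2 = c(rep(-1, 15), rep(1, 5)))
  rownames(m4) <- sprintf("D%02d", 1:20)
  dsm4 <- structure(list(cor = m4, shrna_targets = setNames(rep("g", 2),
                                                            colnames(m4))),
                    class = "drug_shrna_matrix")
  sel4 <- structure(list(retained = colnames(m4)), class = "shrna_selection")
  expect_warning(got4 <- rank_and_select(dsm4, sel4, top_fraction = 0.25),
                 "no common")
  expect_identical(nrow(got4), 0L)
})

test_that("planted matching drugs reach the top-3 through the whole chain", {
  spec <- synthetic_spec(seed = 101)
  pair <- generate_cohort_pair(spec)
  pert <- generate_perturbation_dataset(spec, pair$truth)
  pc <- drug_shrna_correlations(pert, pair$truth$targets)
  dsm <- collapse_dose_time(pc)
  sel <- suppressWarnings(filter_shrna_clusters(dsm))
  cand <- suppressWarnings(rank_and_select(dsm, sel))
  for (g in pair$truth$targets) {
    want <- pair$truth$matching_drugs[[g]]
    got <- cand$compound[cand$target == g]
    expect_true(all(want %in% got))
  }
})
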