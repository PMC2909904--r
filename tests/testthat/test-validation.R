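test_that("closeness adjustment equals recomputation from the reduced set", {
  w <- small_world()
  inter <- w$interactions
  g <- ensure_proteins(w$graph, inter$protein_id)
  phi <- suppressMessages(closeness_matrix(g, inter))
  multi <- names(which(table(inter$drug_id) >= 3))[1]
  targets <- inter$protein_id[inter$drug_id == multi]

  # remove all but one target; compare with building closeness from scratch
  keep <- targets[1]
  adjusted <- adjust_closeness_for_removed_targets(phi, multi,
                                                   setdiff(targets, keep))
  fresh <- suppressMessages(closeness_matrix(
    g, data.frame(drug_id = multi, protein_id = keep), drug_ids = multi))
  expect_equal(adjusted$values[, multi],
               fresh$values[rownames(adjusted$values), multi],
               tolerance = 1e-12)

  # removing a disconnected target changes nothing; empty set is identity
  expect_equal(adjust_closeness_for_removed_targets(phi, multi,
                                                    character()),
               phi)
  expect_warning(
    zeroed <- adjust_closeness_for_removed_targets(phi, multi, targets),
    "now zero")
  expect_true(all(zeroed$values[, multi] == 0))
})

test_that("oracle scorer yields perfect LOOCV precision, candidates number 20", {
  w <- small_world()
  phi <- suppressMessages(
    closeness_matrix(w$graph, w$interactions))
  rep <- loocv_precision("oracle", w$interactions, phi,
                         n_negatives = 19, n_repeats = 2, seed = 5)
  expect_equal(rep$precision, 1)
  expect_equal(rep$n_negatives, 19)
  expect_error(
    loocv_precision("oracle", w$interactions, phi,
                    n_negatives = 10000, n_repeats = 1, seed = 1),
    "smaller than the network")
})

test_that("LOOCV is seed-reproducible and seeds only change the stochastics", {
  w <- small_world()
  ts <- ts_matrix(w$drugs)
  cs <- cs_matrix(w$drugs)
  phi <- suppressMessages(
    closeness_matrix(w$graph, w$interactions, drug_ids = names(w$drugs)))
  r1 <- loocv_precision("CS", w$interactions, phi, ts, cs,
                        n_repeats = 2, seed = 7)
  r2 <- loocv_precision("CS", w$interactions, phi, ts, cs,
                        n_repeats = 2, seed = 7)
  expect_identical(r1$per_repeat, r2$per_repeat)
  expect_true(all(r1$per_repeat >= 0 & r1$per_repeat <= 1))
})

test_that("pooled ROC reproduces hand examples and the Mann-Whitney oracle", {
  make_result <- function(drug, proteins, scores) {
    ord <- order(-scores, proteins, method = "radix")
    res <- data.frame(protein_id = proteins[ord], score = scores[ord],
                      rank = seq_along(proteins))
    attr(res, "drug_id") <- drug
    class(res) <- c("concordance_result", "data.frame")
    res
  }
  proteins <- c("p1", "p2", "p3", "p4")
  res <- make_result("d", proteins, c(0.9, 0.8, 0.7, 0.6))
  gold <- data.frame(drug_id = "d", protein_id = c("p1", "p3"))
  roc <- pooled_rank_roc(list(res), gold)
  expect_equal(roc$auc, 0.75)
  expect_equal(roc$auc,
               mann_whitney_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)))

  # every gold target ranked first across drugs: AUC 1
  res2 <- make_result("e", proteins, c(0.9, 0.5, 0.4, 0.3))
  gold2 <- data.frame(drug_id = c("d", "e"), protein_id = c("p1", "p1"))
  expect_equal(pooled_rank_roc(list(res, res2), gold2)$auc, 1)

  # random single-drug instances against the pair-counting oracle
  set.seed(12)
  for (rep in 1:5) {
    scores <- stats::runif(30)
    labels <- stats::rbinom(30, 1, 0.3)
    if (sum(labels) == 0 || sum(labels) == 30) next
    ids <- sprintf("q%02d", 1:30)
    r <- make_result("d", ids, scores)
    g <- data.frame(drug_id = "d", protein_id = ids[labels == 1])
    expect_equal(pooled_rank_roc(list(r), g)$auc,
                 mann_whitney_auc(scores, labels), tolerance = 1e-12)
  }
  expect_error(pooled_rank_roc(list(res), gold[0, ]), "empty")
})

test_that("rank enrichment computes fold N / worst rank with an exact tail", {
  # worked example: five targets ranked 9, 12, 33, 267, 305 of 9981
  e1 <- rank_enrichment(c(9, 12, 33, 267, 305), 9981)
  expect_equal(e1$fold, 9981 / 305)
  expect_equal(round(e1$fold), 33)
  expect_equal(e1$cutoff, 305)
  # hypergeometric tail oracle: all 5 targets within the top 305
  expect_equal(e1$p_one_sided,
               prod((305 - 0:4) / (9981 - 0:4)), tolerance = 1e-12)

  e2 <- rank_enrichment(c(32, 103, 119), 9981)
  expect_equal(e2$fold, 9981 / 119)
  expect_equal(round(e2$fold), 84)

  # single target at the bottom: no enrichment
  expect_equal(rank_enrichment(500, 500)$fold, 1)
  expect_error(rank_enrichment(integer(), 100), "empty")
  expect_error(rank_enrichment(c(3, 3), 100), "distinct")
})

test_that("similarity-bin enrichment is flat under random target assignment", {
  set.seed(19)
  n <- 40
  ids <- sprintf("d%02d", 1:n)
  sim <- matrix(stats::runif(n * n), n, n, dimnames = list(ids, ids))
  sim[lower.tri(sim)] <- t(sim)[lower.tri(sim)]
  diag(sim) <- 1
  inter <- data.frame(
    drug_id = rep(ids, each = 2),
    protein_id = sample(sprintf("p%02d", 1:12), 2 * n, replace = TRUE))
  folds <- similarity_bin_enrichment(sim, inter, n_bins = 4)
  expect_equal(nrow(folds), 4)
  populated <- folds$n_pairs > 30
  expect_true(all(abs(folds$fold[populated] - 1) < 0.5))
  # single bin: normalization forces fold exactly 1
  one <- similarity_bin_enrichment(sim, inter, n_bins = 1)
  expect_equal(one$fold, 1)
})

test_that("high-similarity pairs are enriched in a planted world", {
  w <- generate_world(n_drugs = 30, n_proteins = 100, n_modules = 3,
                      seed = 8)
  cs <- cs_matrix(w$drugs)
  # two coarse bins: chemically similar pairs (same chemotype) vs the rest
  folds <- similarity_bin_enrichment(cs, w$interactions, n_bins = 2)
  expect_gt(folds$fold[2], 1)
  expect_gt(folds$fold[2], folds$fold[1])
})

test_that("Spearman correlation with permutation test matches a rank oracle", {
  set.seed(33)
  n <- 6
  ids <- sprintf("d%d", 1:n)
  sym <- function(m) { m[lower.tri(m)] <- t(m)[lower.tri(m)]; diag(m) <- 1; m }
  a <- sym(matrix(stats::runif(n * n), n, n, dimnames = list(ids, ids)))
  b <- sym(matrix(stats::runif(n * n), n, n, dimnames = list(ids, ids)))
  res <- correlation_with_permutation(a, b, n_perm = 200, seed = 4)
  # rank-transform-then-Pearson oracle on the upper triangle
  ut <- upper.tri(a)
  expect_equal(res$rho, stats::cor(rank(a[ut]), rank(b[ut])),
               tolerance = 1e-12)
  # self-correlation: rho 1 and the smallest attainable p (12 drugs, so a
  # label shuffle practically never reproduces the identity)
  ids12 <- sprintf("e%02d", 1:12)
  big <- sym(matrix(stats::runif(144), 12, 12,
                    dimnames = list(ids12, ids12)))
  self <- correlation_with_permutation(big, big, n_perm = 99, seed = 4)
  expect_equal(self$rho, 1)
  expect_equal(self$p_empirical, 1 / 100)
  expect_error(correlation_with_permutation(a, b, n_perm = 0), "at least 1")
})
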