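world_with_scores <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      w <- small_world()
      ts <- ts_matrix(w$drugs)
      cs <- cs_matrix(w$drugs)
      phi <- suppressMessages(
        closeness_matrix(w$graph, w$interactions, drug_ids = names(w$drugs)))
      cache <<- list(w = w, ts = ts, cs = cs, phi = phi)
    }
    cache
  }
})

test_that("the fingerprint map stacks per-drug MS score vectors", {
  ctx <- world_with_scores()
  fmap <- build_fingerprint_map(names(ctx$w$drugs)[1:3], ctx$ts, ctx$cs,
                                ctx$phi)
  expect_equal(dim(fmap$scores), c(3, nrow(ctx$phi$values)))
  for (d in rownames(fmap$scores)) {
    expect_equal(fmap$scores[d, ],
                 score_proteins(d, "MS", ctx$ts, ctx$cs,
                                values = ctx$phi$values))
  }
  expect_error(build_fingerprint_map(character(), ctx$ts, ctx$cs, ctx$phi),
               "empty")
})

test_that("unspecific proteins are filtered by score dispersion", {
  set.seed(3)
  scores <- matrix(stats::rnorm(5 * 40), 5, 40,
                   dimnames = list(paste0("d", 1:5), paste0("p", 1:40)))
  scores[, "p40"] <- 0.7                      # constant across all drugs
  fmap <- structure(list(scores = scores, model = "MS", filter_meta = NULL),
                    class = "fingerprint_map")
  filtered <- filter_unspecific_proteins(fmap, sd_quantile = 0.1)
  expect_false("p40" %in% colnames(filtered$scores))
  expect_equal(filtered$filter_meta$criterion, "sd_quantile")
  expect_equal(filtered$filter_meta$n_before, 40)
  # on dispersion-homogeneous noise the filter removes about the quantile
  expect_equal(filtered$filter_meta$n_after / 40, 0.9, tolerance = 0.06)
  # re-running on the filtered map removes (almost) nothing more than the
  # quantile dictates; zero-variance proteins are gone for good
  again <- filter_unspecific_proteins(filtered, sd_quantile = 0.0001)
  expect_equal(ncol(again$scores), ncol(filtered$scores) - 1)
  expect_error(filter_unspecific_proteins(fmap, sd_quantile = 1), "every")
})

test_that("activity resemblance is the cosine with hand-checked values", {
  expect_equal(activity_resemblance(c(1, 2, 2), c(2, 1, 2)), 8 / 9)
  expect_equal(activity_resemblance(c(1, 1), c(1, 1)), 1)
  expect_equal(activity_resemblance(c(1, 0), c(0, 1)), 0)
  expect_warning(z <- activity_resemblance(c(0, 0), c(1, 1)), "zero")
  expect_equal(z, 0)
  expect_error(activity_resemblance(1:3, 1:4), "mismatch")

  # symmetry and scale invariance on random rows
  set.seed(21)
  for (rep in 1:20) {
    f1 <- stats::rnorm(15); f2 <- stats::rnorm(15)
    expect_equal(activity_resemblance(f1, f2), activity_resemblance(f2, f1))
    expect_equal(activity_resemblance(3.7 * f1, f2),
                 activity_resemblance(f1, f2))
  }
})

test_that("the resemblance matrix agrees with pairwise cosines", {
  ctx <- world_with_scores()
  fmap <- build_fingerprint_map(names(ctx$w$drugs), ctx$ts, ctx$cs, ctx$phi)
  m <- resemblance_matrix(fmap)
  expect_equal(m, t(m))
  ids <- rownames(m)[1:4]
  for (a in ids) {
    for (b in ids) {
      expect_equal(m[a, b],
                   activity_resemblance(fmap$scores[a, ], fmap$scores[b, ]),
                   tolerance = 1e-12)
    }
  }
})

test_that("the significance threshold matches a sort-and-index oracle", {
  set.seed(9)
  scores <- matrix(stats::runif(20 * 30), 20, 30,
                   dimnames = list(sprintf("d%02d", 1:20), NULL))
  fmap <- structure(list(scores = scores, model = "MS", filter_meta = NULL),
                    class = "fingerprint_map")
  thr <- resemblance_threshold(fmap, alpha = 0.05)
  m <- resemblance_matrix(fmap)
  null_values <- sort(m[upper.tri(m)])
  expect_equal(thr, null_values[ceiling(0.95 * length(null_values))])
  # at most alpha of the null exceeds the threshold
  expect_lte(mean(null_values > thr), 0.05)
  # identical rows: the empirical null is all ones, so the threshold is 1
  same <- structure(list(scores = matrix(rep(stats::runif(10), each = 21),
                                         21, 10), model = "MS",
                         filter_meta = NULL),
                    class = "fingerprint_map")
  rownames(same$scores) <- sprintf("s%02d", 1:21)
  expect_equal(resemblance_threshold(same, alpha = 0.05), 1)
  # alpha -> 0: the threshold saturates at the null maximum
  expect_warning(limit <- resemblance_threshold(fmap, alpha = 1e-9),
                 "saturates")
  expect_equal(limit, max(null_values))
  tiny <- structure(list(scores = scores[1:2, ], model = "MS",
                         filter_meta = NULL), class = "fingerprint_map")
  expect_error(resemblance_threshold(tiny, alpha = 0.05), "too few")
})

test_that("unexpected relations require high resemblance and disjoint classes", {
  drugs <- list(
    n1 = drug_record("n1", atc_codes = "N05BA01"),
    n2 = drug_record("n2", atc_codes = "N02AA01"),
    c1 = drug_record("c1", atc_codes = "C01AA05", target_ids = "p1"),
    a1 = drug_record("a1", atc_codes = "A07AA01", target_ids = "p1"))
  scores <- rbind(n1 = c(1, 0, 0.5), n2 = c(1, 0.1, 0.5),
                  c1 = c(0.9, 0.1, 0.6), a1 = c(0.95, 0, 0.55))
  fmap <- structure(list(scores = scores, model = "MS", filter_meta = NULL),
                    class = "fingerprint_map")
  rel <- unexpected_relations(fmap, drugs, threshold = 0.95)
  # n1-n2 share main class N: excluded regardless of resemblance
  expect_false(any(rel$drug1 == "n1" & rel$drug2 == "n2"))
  # c1-a1: different classes, high cosine, shared target p1
  hit <- rel[(rel$drug1 == "a1" & rel$drug2 == "c1") |
               (rel$drug1 == "c1" & rel$drug2 == "a1"), ]
  expect_equal(nrow(hit), 1)
  expect_true(hit$shares_target)
  # reported pairs shrink as the threshold rises
  for (thr in c(0.9, 0.99, 1 + 1e-9)) {
    expect_lte(nrow(unexpected_relations(fmap, drugs, threshold = thr)),
               nrow(unexpected_relations(fmap, drugs, threshold = 0.9)))
  }
  expect_equal(nrow(unexpected_relations(fmap, drugs,
                                         threshold = 1 + 1e-9)), 0)
})
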