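test_that("single-model concordance is the guarded Pearson correlation", {
  ts_vec <- c(1, 0, 0.5, 0)
  expect_equal(concordance_ts(ts_vec, c(2, 0, 1, 0)), 1)   # proportional
  expect_equal(concordance_ts(ts_vec, c(3, 3, 3, 3)), 0)   # constant profile
  # textbook correlation oracle on the reversed profile
  phi_rev <- rev(c(2, 0, 1, 0))
  num <- sum((ts_vec - mean(ts_vec)) * (phi_rev - mean(phi_rev)))
  den <- sqrt(sum((ts_vec - mean(ts_vec))^2) * sum((phi_rev - mean(phi_rev))^2))
  expect_equal(concordance_ts(ts_vec, phi_rev), num / den)
  expect_equal(concordance_cs(ts_vec, phi_rev), num / den)
  expect_error(concordance_ts(ts_vec, c(1, 2)), "mismatch")
})

test_that("MS fit recovers exact linear combinations", {
  set.seed(2)
  ts_vec <- stats::runif(8)
  cs_vec <- stats::runif(8)
  phi <- 2 * ts_vec + 3 * cs_vec + 1
  fit <- fit_ms(ts_vec, cs_vec, phi)
  expect_equal(fit$a_prime, 2, tolerance = 1e-10)
  expect_equal(fit$b_prime, 3, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$residual_norm, 0, tolerance = 1e-10)
  expect_null(fit$fallback)
  expect_equal(concordance_ms(fit, ts_vec, cs_vec, phi), 1)
})

test_that("MS fit matches the normal-equations oracle on random instances", {
  set.seed(31)
  checked <- 0
  while (checked < 10) {
    ts_vec <- stats::runif(6)
    cs_vec <- stats::runif(6)
    phi <- 0.5 * ts_vec + 0.8 * cs_vec + stats::rnorm(6, sd = 0.05)
    beta <- normal_equations_fit(ts_vec, cs_vec, phi)
    if (beta[2] < 0 || beta[3] < 0) next    # oracle for the interior case
    fit <- fit_ms(ts_vec, cs_vec, phi)
    expect_equal(c(fit$intercept, fit$a_prime, fit$b_prime),
                 unname(beta), tolerance = 1e-8)
    checked <- checked + 1
  }
})

test_that("MS coefficients are never negative", {
  set.seed(17)
  for (rep in 1:50) {
    ts_vec <- stats::runif(10)
    cs_vec <- stats::runif(10)
    phi <- stats::rnorm(10)
    fit <- fit_ms(ts_vec, cs_vec, phi)
    expect_gte(fit$a_prime, 0)
    expect_gte(fit$b_prime, 0)
    # the constrained fit can never beat the unconstrained one
    beta <- normal_equations_fit(ts_vec, cs_vec, phi)
    unconstrained_rss <- sum((phi - cbind(1, ts_vec, cs_vec) %*% beta)^2)
    expect_gte(fit$residual_norm^2, unconstrained_rss - 1e-10)
  }
})

test_that("profiles orthogonal to both predictors get a null fit", {
  set.seed(8)
  ts_vec <- stats::runif(8)
  cs_vec <- stats::runif(8)
  # project a random profile onto the orthogonal complement of [1, ts, cs]
  X <- cbind(1, ts_vec, cs_vec)
  y <- stats::rnorm(8)
  phi <- as.numeric(y - X %*% solve(t(X) %*% X, t(X) %*% y))
  expect_lt(abs(stats::cor(ts_vec, phi)), 1e-10)
  fit <- fit_ms(ts_vec, cs_vec, phi)
  expect_equal(fit$a_prime, 0, tolerance = 1e-10)
  expect_equal(fit$b_prime, 0, tolerance = 1e-10)
  # degenerate: constant closeness profile scores zero under every model
  const <- rep(0.3, 8)
  expect_equal(concordance_ms(fit_ms(ts_vec, cs_vec, const),
                              ts_vec, cs_vec, const), 0)
})

test_that("collinear predictors trigger the flagged single-predictor fallback", {
  ts_vec <- c(0.1, 0.4, 0.2, 0.8, 0.5)
  cs_vec <- 2 * ts_vec
  phi <- 3 * ts_vec + 0.5
  fit <- fit_ms(ts_vec, cs_vec, phi)
  expect_false(is.null(fit$fallback))
  expect_equal(concordance_ms(fit, ts_vec, cs_vec, phi), 1)
})

test_that("MS concordance dominates single models when those are non-negative", {
  set.seed(13)
  for (rep in 1:100) {
    n <- 12
    ts_vec <- stats::runif(n)
    cs_vec <- stats::runif(n)
    phi <- stats::runif(1) * ts_vec + stats::runif(1) * cs_vec +
      stats::rnorm(n, sd = 0.3)
    s_ts <- concordance_ts(ts_vec, phi)
    s_cs <- concordance_cs(cs_vec, phi)
    fit <- fit_ms(ts_vec, cs_vec, phi)
    s_ms <- concordance_ms(fit, ts_vec, cs_vec, phi)
    if (s_ts >= 0 && s_cs >= 0) {
      expect_gte(s_ms, max(s_ts, s_cs) - 1e-10)
    }
    expect_gte(s_ms, -1e-12)
    expect_lte(s_ms, 1 + 1e-12)
  }
})

test_that("concordance is invariant under positive affine rescaling of phi", {
  set.seed(41)
  ts_vec <- stats::runif(10)
  cs_vec <- stats::runif(10)
  phi <- stats::runif(10)
  for (f in list(concordance_ts, concordance_cs)) {
    expect_equal(f(ts_vec, 5 * phi + 2), f(ts_vec, phi))
  }
  s1 <- concordance_ms(fit_ms(ts_vec, cs_vec, phi), ts_vec, cs_vec, phi)
  phi2 <- 5 * phi + 2
  s2 <- concordance_ms(fit_ms(ts_vec, cs_vec, phi2), ts_vec, cs_vec, phi2)
  expect_equal(s1, s2)
})

test_that("rank_proteins finds a planted optimum and breaks ties by id", {
  drugs <- c("d1", "d2", "d3", "d4")
  ts <- diag(1, 4); dimnames(ts) <- list(drugs, drugs)
  ts["d1", ] <- c(1, 0.8, 0.3, 0.1); ts[, "d1"] <- ts["d1", ]
  proteins <- c("pA", "pB", "pC", "pD", "pE")
  set.seed(6)
  phi <- matrix(stats::runif(20), 5, 4, dimnames = list(proteins, drugs))
  phi["pC", ] <- 2 * ts["d1", ] + 0.1         # planted proportional profile
  res <- rank_proteins("d1", "TS", ts = ts, phi = phi)
  expect_s3_class(res, "concordance_result")
  expect_equal(res$protein_id[1], "pC")
  expect_equal(res$score[1], 1)
  expect_equal(res$rank, 1:5)

  # all-tied scores: ranking follows lexicographic protein order
  flat <- matrix(1, 5, 4, dimnames = list(proteins, drugs))
  res2 <- rank_proteins("d1", "TS", ts = ts, phi = flat)
  expect_equal(res2$protein_id, sort(proteins))
  expect_true(all(res2$score == 0))
})

test_that("ranking equals the scalar-loop oracle and is deterministic", {
  w <- small_world()
  ts <- ts_matrix(w$drugs)
  cs <- cs_matrix(w$drugs)
  phi <- suppressMessages(
    closeness_matrix(w$graph, w$interactions, drug_ids = names(w$drugs)))
  d <- unique(w$interactions$drug_id)[1]
  for (model in c("TS", "CS", "MS")) {
    res <- rank_proteins(d, model, ts = ts, cs = cs, phi = phi)
    # independent scalar pass over every protein
    ts_vec <- ts[d, colnames(phi$values)]
    cs_vec <- cs[d, colnames(phi$values)]
    expected <- vapply(rownames(phi$values), function(p) {
      phi_vec <- phi$values[p, ]
      switch(model,
             TS = concordance_ts(ts_vec, phi_vec),
             CS = concordance_cs(cs_vec, phi_vec),
             MS = concordance_ms(fit_ms(ts_vec, cs_vec, phi_vec),
                                 ts_vec, cs_vec, phi_vec))
    }, 0)
    got <- res$score[match(rownames(phi$values), res$protein_id)]
    expect_equal(got, unname(expected), tolerance = 1e-10)
    expect_identical(res, rank_proteins(d, model, ts = ts, cs = cs,
                                        phi = phi))
    expect_true(all(res$score >= -1 - 1e-12 & res$score <= 1 + 1e-12))
  }
  expect_error(rank_proteins(d, "XX", ts = ts, cs = cs, phi = phi))
})
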