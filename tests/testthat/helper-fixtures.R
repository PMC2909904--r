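# Shared fixtures and independent oracles for the test suite.

# -- tiny graphs ------------------------------------------------------------

# path graph p1 - p2 - p3
path3_graph <- function() {
  igraph::graph_from_edgelist(cbind(c("p1", "p2"), c("p2", "p3")),
                              directed = FALSE)
}

# Erdos-Renyi graph over named proteins, reproducible
random_graph <- function(n, p = 0.12, seed = 1) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  idx <- utils::combn(n, 2)
  keep <- stats::runif(ncol(idx)) < p
  g <- igraph::graph_from_edgelist(
    cbind(ids[idx[1, keep]], ids[idx[2, keep]]), directed = FALSE)
  ensure_proteins(g, ids)
}

# -- independent oracles ----------------------------------------------------

# all-pairs shortest distances by Floyd-Warshall dynamic programming,
# independent of the BFS path used by the package
floyd_warshall_oracle <- function(g) {
  ids <- igraph::V(g)$name
  n <- length(ids)
  d <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(d) <- 0
  el <- igraph::as_edgelist(g)
  for (i in seq_len(nrow(el))) {
    d[el[i, 1], el[i, 2]] <- 1
    d[el[i, 2], el[i, 1]] <- 1
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      dk <- d[i, k]
      if (is.finite(dk)) {
        d[i, ] <- pmin(d[i, ], dk + d[k, ])
      }
    }
  }
  d
}

# Mann-Whitney AUC by explicit pair counting
mann_whitney_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) {
    wins <- wins + sum(p > neg) + 0.5 * sum(p == neg)
  }
  wins / (length(pos) * length(neg))
}

# closed-form normal-equations solve for a 2-predictor fit with intercept
normal_equations_fit <- function(ts_vec, cs_vec, phi_vec) {
  X <- cbind(1, ts_vec, cs_vec)
  solve(t(X) %*% X, t(X) %*% phi_vec)[, 1]
}

# -- toy drug corpora -------------------------------------------------------

# the 4-assignment ATC corpus used in hand calculations:
# p(N05BA) = 3/4, p(N05BA01) = 1/2, p(N02AA01) = 1/4
toy_atc_corpus <- function() {
  data.frame(drug_id = c("a", "a2", "b", "c"),
             atc_code = c("N05BA01", "N05BA01", "N05BA12", "N02AA01"),
             stringsAsFactors = FALSE)
}

toy_probs <- function() estimate_code_probabilities(toy_atc_corpus())

# a small fully-specified drug set with fingerprints and targets
toy_drugs <- function() {
  list(
    d1 = drug_record("d1", atc_codes = c("N05BA01", "C01AA05"),
                     fingerprint = c(1, 1, 0, 0, 1, 0),
                     target_ids = c("p1", "p3")),
    d2 = drug_record("d2", atc_codes = "N05BA12",
                     fingerprint = c(1, 0, 1, 0, 1, 0),
                     target_ids = "p1"),
    d3 = drug_record("d3", atc_codes = "A07AA01",
                     fingerprint = c(0, 1, 0, 1, 0, 1),
                     target_ids = "p3")
  )
}

# small synthetic world for integration-style tests
small_world <- function(seed = 42) {
  generate_world(n_drugs = 12, n_proteins = 60, n_modules = 3,
                 seed = seed)
}

# write a matrix of strings as a TSV file, returning the path
write_tsv_tmp <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
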