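#' Subtract removed targets from a drug's closeness column
#'
#' In leave-one-out validation a drug's held-out targets must not leak into
#' its closeness column.  Because closeness is a sum of per-target transfer
#' terms, removing targets is exactly the subtraction of their terms:
#' phi(p, d) <- phi(p, d) - sum over removed t of transfer(L(p, t)),
#' which equals recomputing the closeness from the reduced target set.
#'
#' @param phi A `closeness_matrix` (carries the target-protein distance
#'   matrix and the transfer function used to build it).
#' @param drug_id Drug whose column is adjusted.
#' @param removed Character vector of target protein identifiers to remove;
#'   must be among the targets used to build `phi`.
#' @return The `closeness_matrix` with the one column adjusted.
#' @export
adjust_closeness_for_removed_targets <- function(phi, drug_id, removed) {
  stopifnot(inherits(phi, "closeness_matrix"))
  if (!drug_id %in% colnames(phi$values)) {
    stop("drug '", drug_id, "' has no closeness column")
  }
  removed <- unique(as.character(removed))
  if (length(removed) == 0) return(phi)
  unknown <- setdiff(removed, rownames(phi$target_distances))
  if (length(unknown) > 0) {
    stop("not known target protein(s): ", paste(unknown, collapse = ", "))
  }
  L <- phi$target_distances[removed, , drop = FALSE]
  w <- phi$transfer(L)
  w[is.infinite(L)] <- 0
  newcol <- phi$values[, drug_id] - colSums(w)[rownames(phi$values)]
  newcol[abs(newcol) < 1e-15] <- 0        # clamp float dust from subtraction
  if (all(newcol == 0)) {
    warning("all targets of drug '", drug_id,
            "' removed; its closeness column is now zero")
  }
  phi$values[, drug_id] <- newcol
  phi
}

#' Score a candidate protein set for one drug
#'
#' Internal scorer shared by the LOOCV machinery: candidates' closeness
#' rows are taken from `values` and the query drug's entries overridden by
#' `override_col` (the leave-one-out adjusted closeness).
#' @keywords internal
score_candidates <- function(candidates, drug_id, model, ts, cs, values,
                             override_col = NULL) {
  phiT <- t(values[candidates, , drop = FALSE])   # drugs x candidates
  if (!is.null(override_col)) {
    phiT[drug_id, ] <- override_col[candidates]
  }
  drugs <- rownames(phiT)
  if (model == "TS") return(cor_vec_cols(ts[drug_id, drugs], phiT))
  if (model == "CS") return(cor_vec_cols(cs[drug_id, drugs], phiT))
  if (model == "MS") {
    return(ms_scores(ts[drug_id, drugs], cs[drug_id, drugs], phiT))
  }
  if (model == "random") {
    out <- stats::runif(length(candidates))
    names(out) <- candidates
    return(out)
  }
  if (model == "oracle") {
    # reference scorer for calibration: the held-out target always wins
    out <- as.numeric(candidates == attr(override_col, "true_target"))
    names(out) <- candidates
    return(out)
  }
  stop("unknown model: ", model)
}

#' Leave-one-out cross-validated precision
#'
#' For every known drug-target pair: all other targets of the drug are
#' removed from its closeness column (see
#' [adjust_closeness_for_removed_targets()]), `n_negatives` negative-control
#' proteins are sampled uniformly from the network excluding the drug's
#' known targets, and the 1 + n_negatives candidates are scored.  A success
#' requires the held-out target to rank strictly first (ties count as
#' failure).  Precision is the success fraction over all pairs; the whole
#' procedure is repeated with fresh negative draws.
#'
#' @param model "TS", "CS" or "MS"; the calibration scorers "random"
#'   (uniform scores, analytic precision 1/(1+n_negatives)) and "oracle"
#'   (always ranks the true target first) are also accepted.
#' @param interactions Interaction data.frame of the gold-standard pairs.
#' @param phi A `closeness_matrix` built from the same interactions.
#' @param ts,cs Similarity matrices (may be NULL if the model ignores them).
#' @param n_negatives Number of negative controls per pair (default 19, so
#'   20 candidates in total).
#' @param n_repeats Number of repeats with fresh negative draws (default 100).
#' @param seed Integer seed; runs are exactly reproducible.
#' @return An object of class `validation_report`: list with `model`,
#'   `precision` (mean over repeats), `per_repeat`, `n_pairs`,
#'   `n_negatives`, `n_repeats`, `seed`.
#' @export
loocv_precision <- function(model, interactions, phi, ts = NULL, cs = NULL,
                            n_negatives = 19, n_repeats = 100, seed = 1) {
  stopifnot(inherits(phi, "closeness_matrix"), n_negatives >= 1,
            n_repeats >= 1)
  proteins <- rownames(phi$values)
  if (n_negatives >= length(proteins)) {
    stop("n_negatives (", n_negatives, ") must be smaller than the network (",
         length(proteins), " proteins)")
  }
  pairs <- interactions[interactions$drug_id %in% colnames(phi$values) &
                          interactions$protein_id %in% proteins, ]
  if (nrow(pairs) == 0) stop("no scorable drug-target pairs")
  drug_targets <- split(pairs$protein_id, pairs$drug_id)
  # leave-one-out closeness column for pair (d, t) is just transfer(L(t, .))
  loo_col <- function(t) {
    L <- phi$target_distances[t, proteins]
    w <- phi$transfer(L)
    w[is.infinite(L)] <- 0
    structure(w, true_target = t)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  per_repeat <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    wins <- 0L
    for (i in seq_len(nrow(pairs))) {
      d <- pairs$drug_id[i]; t <- pairs$protein_id[i]
      negatives <- sample(setdiff(proteins, drug_targets[[d]]), n_negatives)
      candidates <- c(t, negatives)
      s <- score_candidates(candidates, d, model, ts, cs, phi$values,
                            override_col = loo_col(t))
      if (s[[t]] > max(s[negatives])) wins <- wins + 1L
    }
    per_repeat[r] <- wins / nrow(pairs)
  }
  structure(list(model = model, precision = mean(per_repeat),
                 per_repeat = per_repeat, n_pairs = nrow(pairs),
                 n_negatives = n_negatives, n_repeats = n_repeats,
                 seed = seed),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> model ", x$model, ": precision ",
      format(x$precision, digits = 4), " over ", x$n_pairs, " pairs, ",
      x$n_repeats, " repeat(s), ", x$n_negatives, " negatives, seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

#' Pooled rank-threshold ROC curve and AUC
#'
#' Treats every (drug, protein) pair across all per-drug rankings as one
#' instance.  For each rank threshold r, proteins ranked at or above r are
#' predicted targets: pooled sensitivity is the fraction of gold pairs
#' ranked within r, pooled specificity is computed over all non-gold pairs.
#' The AUC is the trapezoidal area under sensitivity vs (1 - specificity).
#'
#' @param results List of `concordance_result` objects, one per drug, all
#'   ranking the same protein universe.
#' @param gold Interaction data.frame of gold-standard pairs; every gold
#'   pair's drug must have a result.
#' @return List with `auc` and `curve` (data.frame: rank threshold,
#'   sensitivity, specificity).
#' @export
pooled_rank_roc <- function(results, gold) {
  if (nrow(gold) == 0) stop("empty gold standard")
  drug_ids <- vapply(results, function(r) attr(r, "drug_id"), "")
  names(results) <- drug_ids
  missing <- setdiff(unique(gold$drug_id), drug_ids)
  if (length(missing) > 0) {
    stop("no ranking available for drug(s): ", paste(missing, collapse = ", "))
  }
  sizes <- vapply(results, nrow, 1L)
  if (length(unique(sizes)) != 1) {
    stop("all rankings must cover the same protein universe")
  }
  n_prot <- sizes[[1]]
  gold_ranks <- vapply(seq_len(nrow(gold)), function(i) {
    r <- results[[gold$drug_id[i]]]
    k <- r$rank[r$protein_id == gold$protein_id[i]]
    if (length(k) == 0) stop("gold protein '", gold$protein_id[i],
                             "' absent from the ranking of drug '",
                             gold$drug_id[i], "'")
    k
  }, 1L)
  n_drugs <- length(results)
  n_gold <- length(gold_ranks)
  n_total <- n_drugs * n_prot
  tp <- cumsum(tabulate(gold_ranks, nbins = n_prot))
  ranked <- seq_len(n_prot) * n_drugs        # pairs at or above each threshold
  sens <- tp / n_gold
  fpr <- (ranked - tp) / (n_total - n_gold)
  sens0 <- c(0, sens); fpr0 <- c(0, fpr)
  auc <- sum(diff(fpr0) * (utils::head(sens0, -1) + sens0[-1]) / 2)
  list(auc = auc,
       curve = data.frame(rank = seq_len(n_prot), sensitivity = sens,
                          specificity = 1 - fpr))
}

#' Fold enrichment of target ranks with a one-sided exact test
#'
#' Given the ranks of a drug's k known targets among N candidates, the
#' cutoff is the worst (largest) target rank r_max; all k targets fall
#' within the top r_max of N, so the fold enrichment over chance is
#' (k / r_max) / (k / N) = N / r_max.  The one-sided p-value is the
#' hypergeometric tail probability of drawing all k targets within the top
#' r_max positions by chance (Fisher exact test on the 2x2 table of
#' target status by cutoff side).
#'
#' @param target_ranks Distinct positive integer ranks, all <= n_candidates.
#' @param n_candidates Size of the ranked candidate universe.
#' @return List with `fold`, `p_one_sided`, `cutoff` (= max rank) and
#'   `n_targets`.
#' @examples
#' rank_enrichment(c(9, 12, 33, 267, 305), 9981)$fold  # ~33
#' @export
rank_enrichment <- function(target_ranks, n_candidates) {
  if (length(target_ranks) == 0) stop("empty target rank list")
  target_ranks <- as.integer(target_ranks)
  if (anyDuplicated(target_ranks)) stop("target ranks must be distinct")
  if (any(target_ranks < 1) || any(target_ranks > n_candidates)) {
    stop("ranks must lie in 1..n_candidates")
  }
  k <- length(target_ranks)
  r_max <- max(target_ranks)
  fold <- n_candidates / r_max
  # P(all k targets within top r_max | random placement) — hypergeometric tail
  p <- stats::phyper(k - 1, r_max, n_candidates - r_max, k,
                     lower.tail = FALSE)
  list(fold = fold, p_one_sided = p, cutoff = r_max, n_targets = k)
}

#' Enrichment of common-target drug pairs across similarity bins
#'
#' Bins all unordered drug pairs by their pharmacological similarity and
#' reports, per bin, the fold enrichment of pairs sharing at least one
#' known target relative to the overall share of such pairs.
#'
#' @param sim Symmetric similarity matrix (TS or CS) with drug dimnames.
#' @param interactions Interaction data.frame.
#' @param n_bins Number of equal-width bins over [0, 1] (default 10).
#' @return data.frame with columns `lower`, `upper`, `n_pairs`,
#'   `n_common`, `fold` (NaN for empty bins).
#' @export
similarity_bin_enrichment <- function(sim, interactions, n_bins = 10) {
  ids <- rownames(sim)
  with_targets <- ids[ids %in% interactions$drug_id]
  if (length(with_targets) < 2) stop("need at least 2 drugs with targets")
  tsets <- lapply(with_targets, targets_of, interactions = interactions)
  names(tsets) <- with_targets
  pairs <- utils::combn(with_targets, 2)
  simv <- sim[cbind(pairs[1, ], pairs[2, ])]
  common <- vapply(seq_len(ncol(pairs)), function(i) {
    length(intersect(tsets[[pairs[1, i]]], tsets[[pairs[2, i]]])) > 0
  }, TRUE)
  overall <- mean(common)
  if (overall == 0) warning("no common-target drug pairs; folds are NaN")
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- cut(simv, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  out <- data.frame(lower = breaks[-length(breaks)], upper = breaks[-1])
  out$n_pairs <- tabulate(bin, nbins = n_bins)
  out$n_common <- vapply(seq_len(n_bins),
                         function(b) sum(common[bin == b]), 1L)
  out$fold <- ifelse(out$n_pairs > 0,
                     (out$n_common / out$n_pairs) / overall, NaN)
  out
}

#' Spearman correlation between similarity matrices with a permutation test
#'
#' Correlates the upper-triangle entries of a pharmacological similarity
#' matrix with a genomic relatedness matrix, and assesses significance by
#' jointly shuffling the drug labels (rows and columns) of the second
#' matrix.  The one-sided empirical p-value uses the (count + 1) /
#' (n_perm + 1) estimator, so it is never exactly zero.
#'
#' @param sim,gr Symmetric matrices of identical shape.
#' @param n_perm Number of label shuffles (default 1000).
#' @param seed Integer seed.
#' @return List with `rho` (observed Spearman), `p_empirical`,
#'   `max_perm_rho`, `n_perm`, `seed`.
#' @export
correlation_with_permutation <- function(sim, gr, n_perm = 1000, seed = 1) {
  stopifnot(all(dim(sim) == dim(gr)))
  if (n_perm < 1) stop("n_perm must be at least 1")
  ut <- upper.tri(sim)
  x <- sim[ut]
  rho <- stats::cor(x, gr[ut], method = "spearman")
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  n <- nrow(gr)
  perm_rhos <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    stats::cor(x, gr[p, p][ut], method = "spearman")
  }, 0)
  list(rho = rho,
       p_empirical = (sum(perm_rhos >= rho) + 1) / (n_perm + 1),
       max_perm_rho = max(perm_rhos),
       n_perm = n_perm, seed = seed)
}

#' Compare scoring models by held-out interaction recovery
#'
#' The discriminating benchmark for the three models: for each random
#' split, one target of every multi-target drug is held out, the closeness
#' matrix is rebuilt from the remaining interactions only, every drug's
#' proteins are re-ranked under each model, and the pooled rank-threshold
#' ROC is computed over the held-out pairs.  Because a held-out target
#' contributes nothing to its drug's closeness column, recovery must come
#' from the pharmacological similarity structure, which is exactly where
#' the models differ.
#'
#' @param drugs Named list of `drug_record`s.
#' @param g An igraph PPI graph.
#' @param interactions Interaction data.frame.
#' @param models Character vector of models to compare.
#' @param n_splits Number of random hold-out splits to average (default 3).
#' @param seed Integer seed.
#' @param transfer Distance-to-closeness function.
#' @return Named numeric vector: mean held-out AUC per model.
#' @export
heldout_model_auc <- function(drugs, g, interactions,
                              models = c("TS", "CS", "MS"),
                              n_splits = 3, seed = 1,
                              transfer = transfer_function("exp_sq")) {
  stopifnot(n_splits >= 1)
  ts <- ts_matrix(drugs)
  cs <- cs_matrix(drugs)
  g <- ensure_proteins(g, interactions$protein_id)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  per_split <- vapply(seq_len(n_splits), function(s) {
    held <- do.call(rbind, lapply(split(interactions,
                                        interactions$drug_id),
                                  function(df) {
      if (nrow(df) < 2) return(NULL)
      df[sample(nrow(df), 1), ]
    }))
    if (is.null(held) || nrow(held) == 0) {
      stop("no drug has two or more targets; nothing can be held out")
    }
    key <- paste(interactions$drug_id, interactions$protein_id)
    train <- interactions[!key %in% paste(held$drug_id, held$protein_id), ]
    phi <- suppressMessages(
      closeness_matrix(g, train, drug_ids = names(drugs),
                       transfer = transfer))
    vapply(models, function(m) {
      ranks <- lapply(unique(held$drug_id), rank_proteins, model = m,
                      ts = ts, cs = cs, phi = phi)
      pooled_rank_roc(ranks, held)$auc
    }, 0)
  }, numeric(length(models)))
  out <- rowMeans(matrix(per_split, nrow = length(models)))
  names(out) <- models
  out
}
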