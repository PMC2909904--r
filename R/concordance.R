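#' Pearson correlation with a zero-variance guard
#'
#' Concordance scores are correlations; any correlation involving a
#' zero-variance vector is defined as 0 rather than NA, so that constant
#' closeness profiles (e.g. proteins disconnected from everything) rank
#' last rather than poisoning the ranking.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation in [-1, 1], or 0 when either vector is constant.
#' @keywords internal
safe_cor <- function(x, y) {
  if (length(x) != length(y)) {
    stop("vector length mismatch: ", length(x), " vs ", length(y))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

#' Columnwise correlation of a vector against a matrix, zero-variance guarded
#' @keywords internal
cor_vec_cols <- function(v, m) {
  out <- rep(0, ncol(m))
  sds <- apply(m, 2, stats::sd)
  if (stats::sd(v) > 0) {
    ok <- sds > 0
    if (any(ok)) {
      out[ok] <- as.numeric(stats::cor(v, m[, ok, drop = FALSE]))
    }
  }
  names(out) <- colnames(m)
  out
}

#' Therapeutic-similarity concordance score
#'
#' Scores how well protein p's closeness profile across drugs explains the
#' query drug's therapeutic similarity vector: the concordance is the
#' Pearson correlation between TS_d and Phi_p over all drugs.  A high score
#' means p sits close (in the PPI network) to the targets of exactly those
#' drugs that are therapeutically similar to d.
#'
#' @param ts_vec Therapeutic similarity vector of the query drug (length n
#'   drugs; row of the TS matrix).
#' @param phi_vec Closeness vector of the protein over the same n drugs.
#' @return Concordance score in [-1, 1]; 0 if either vector is constant.
#' @export
concordance_ts <- function(ts_vec, phi_vec) safe_cor(ts_vec, phi_vec)

#' Chemical-similarity concordance score
#'
#' As [concordance_ts()], with the drug's chemical similarity vector CS_d in
#' place of TS_d: the correlation between a drug's structural resemblance to
#' all drugs and the protein's closeness to those drugs' targets, in the
#' spirit of ligand-set similarity approaches.
#'
#' @param cs_vec Chemical similarity vector of the query drug.
#' @param phi_vec Closeness vector of the protein.
#' @return Concordance score in [-1, 1].
#' @export
concordance_cs <- function(cs_vec, phi_vec) safe_cor(cs_vec, phi_vec)

#' Least-squares fit of a closeness profile on TS and CS
#'
#' Fits Phi_p ~ a' TS_d + b' CS_d + intercept by least squares with the
#' similarity coefficients constrained non-negative: the model reads the
#' coefficients as contribution weights of non-negative similarity and
#' closeness quantities, so a negative weight has no interpretation.  For
#' two predictors the constrained solution is closed-form: the ordinary
#' least-squares fit when its coefficients are already non-negative,
#' otherwise the better of the two single-predictor fits (a predictor
#' whose marginal correlation is negative gets weight 0).  When the two
#' predictors are collinear after centering, the fit likewise reduces to
#' the single predictor more correlated with Phi_p.
#'
#' @param ts_vec,cs_vec Similarity vectors of the query drug (length n >= 3).
#' @param phi_vec Closeness vector of the protein.
#' @return An object of class `ms_fit`: list with `a_prime`, `b_prime`,
#'   `intercept`, `fitted`, `residual_norm`, `fallback` (NULL when the
#'   unconstrained fit was feasible; "ts", "cs" or "intercept" when the
#'   non-negativity constraint or a collinear design forced a reduced fit).
#' @export
fit_ms <- function(ts_vec, cs_vec, phi_vec) {
  n <- length(phi_vec)
  if (length(ts_vec) != n || length(cs_vec) != n) {
    stop("ts_vec, cs_vec and phi_vec must have equal length")
  }
  if (n < 3) stop("at least 3 drugs are required for the MS fit")
  X <- cbind(intercept = 1, ts = ts_vec, cs = cs_vec)
  qx <- qr(X)
  beta <- c(intercept = mean(phi_vec), ts = 0, cs = 0)
  fallback <- NULL
  full_ok <- FALSE
  if (qx$rank == 3) {
    b <- qr.coef(qx, phi_vec)
    if (b["ts"] >= 0 && b["cs"] >= 0) {
      beta <- b
      full_ok <- TRUE
    }
  }
  if (!full_ok) {
    # boundary of the non-negativity cone (or collinear design): the best
    # feasible fit uses the single predictor with the larger positive
    # marginal correlation, or the intercept alone if neither is positive
    r_ts <- safe_cor(ts_vec, phi_vec)
    r_cs <- safe_cor(cs_vec, phi_vec)
    if (max(r_ts, r_cs) <= 0) {
      fallback <- "intercept"
    } else {
      fallback <- if (r_ts >= r_cs) "ts" else "cs"
      keep <- if (fallback == "ts") c(1L, 2L) else c(1L, 3L)
      b2 <- qr.coef(qr(X[, keep, drop = FALSE]), phi_vec)
      b2[is.na(b2)] <- 0
      beta[colnames(X)[keep]] <- b2
    }
  }
  fitted <- as.numeric(X %*% beta)
  structure(list(a_prime = unname(beta["ts"]),
                 b_prime = unname(beta["cs"]),
                 intercept = unname(beta["intercept"]),
                 fitted = fitted,
                 residual_norm = sqrt(sum((phi_vec - fitted)^2)),
                 fallback = fallback),
            class = "ms_fit")
}

#' Multiple-similarity concordance score
#'
#' Scores the degree of fitness of the combined pharmacological profile for
#' the protein's closeness vector: the correlation between Phi_p and its
#' constrained least-squares reconstruction a' TS_d + b' CS_d (+
#' intercept), see [fit_ms()].  Because the two-predictor fit nests both
#' single-predictor fits, this score is never below either single-model
#' concordance whenever those are non-negative.
#'
#' @param fit An `ms_fit` produced from the same vectors.
#' @param ts_vec,cs_vec,phi_vec The vectors the fit was produced from.
#' @return Concordance score; 0 for a degenerate (constant) fitted vector.
#' @export
concordance_ms <- function(fit, ts_vec, cs_vec, phi_vec) {
  stopifnot(inherits(fit, "ms_fit"))
  safe_cor(phi_vec, fit$fitted)
}

#' Genome-wide concordance scores for one drug under one model
#'
#' Scores every protein column of the closeness matrix against the query
#' drug's similarity vector(s) and returns a deterministic descending
#' ranking.  Ties are broken by protein identifier (lexicographic), so
#' identical inputs always yield bit-identical rankings.
#'
#' @param drug_id Query drug identifier (must index the similarity matrices
#'   and the closeness columns).
#' @param model One of "TS", "CS", "MS".
#' @param ts,cs Similarity matrices (drugs x drugs); `ts` may be NULL for
#'   the CS model and vice versa.
#' @param phi A `closeness_matrix` (proteins x drugs) or a bare matrix.
#' @return An object of class `concordance_result`: data.frame with columns
#'   `protein_id`, `score`, `rank` (ordered by rank), plus attributes
#'   `drug_id` and `model`.
#' @export
rank_proteins <- function(drug_id, model = c("TS", "CS", "MS"),
                          ts = NULL, cs = NULL, phi) {
  model <- match.arg(model)
  values <- if (inherits(phi, "closeness_matrix")) phi$values else phi
  scores <- score_proteins(drug_id, model, ts, cs, values)
  ord <- order(-scores, names(scores), method = "radix")
  res <- data.frame(protein_id = names(scores)[ord],
                    score = unname(scores[ord]),
                    rank = seq_along(scores),
                    stringsAsFactors = FALSE)
  attr(res, "drug_id") <- drug_id
  attr(res, "model") <- model
  class(res) <- c("concordance_result", "data.frame")
  res
}

#' Vector of per-protein concordance scores for one drug
#'
#' The scoring core behind [rank_proteins()] and the fingerprint map: all
#' proteins are scored with one matrix operation (one QR factorization per
#' drug for the MS model).
#'
#' @inheritParams rank_proteins
#' @param values Proteins x drugs closeness matrix.
#' @return Named numeric vector of scores over proteins.
#' @export
score_proteins <- function(drug_id, model = c("TS", "CS", "MS"),
                           ts = NULL, cs = NULL, values) {
  model <- match.arg(model)
  drugs <- colnames(values)
  get_vec <- function(m, what) {
    if (is.null(m)) stop("model ", model, " needs the ", what, " matrix")
    if (!drug_id %in% rownames(m)) {
      stop("drug '", drug_id, "' not in the ", what, " matrix")
    }
    m[drug_id, drugs]
  }
  phiT <- t(values)                       # drugs x proteins
  if (model == "TS") {
    return(cor_vec_cols(get_vec(ts, "TS"), phiT))
  }
  if (model == "CS") {
    return(cor_vec_cols(get_vec(cs, "CS"), phiT))
  }
  ts_vec <- get_vec(ts, "TS")
  cs_vec <- get_vec(cs, "CS")
  ms_scores(ts_vec, cs_vec, phiT)
}

#' Vectorized MS concordance over many closeness profiles
#'
#' One QR factorization scores all proteins: profiles whose unconstrained
#' coefficients are non-negative get the fitted correlation, the rest fall
#' back to the larger non-negative marginal correlation (the closed-form
#' constrained optimum, see [fit_ms()]).
#' @keywords internal
ms_scores <- function(ts_vec, cs_vec, phiT) {
  r_ts <- cor_vec_cols(ts_vec, phiT)
  r_cs <- cor_vec_cols(cs_vec, phiT)
  boundary <- pmax(r_ts, r_cs, 0)
  X <- cbind(1, ts_vec, cs_vec)
  qx <- qr(X)
  if (qx$rank < 3) {
    scores <- boundary                    # collinear design for this drug
  } else {
    beta <- qr.coef(qx, phiT)             # 3 x proteins
    fitted <- X %*% beta                  # drugs x proteins
    full <- vapply(seq_len(ncol(phiT)), function(j) {
      safe_cor(phiT[, j], fitted[, j])
    }, 0)
    feasible <- beta[2, ] >= 0 & beta[3, ] >= 0
    scores <- ifelse(feasible, full, boundary)
  }
  names(scores) <- colnames(phiT)
  scores
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("<concordance_result> drug ", attr(x, "drug_id"), ", model ",
      attr(x, "model"), ", ", nrow(x), " proteins; top 5:\n", sep = "")
  print.data.frame(utils::head(x, 5))
  invisible(x)
}
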