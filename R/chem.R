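#' Tanimoto coefficient between two binary fingerprints
#'
#' The Tanimoto (Jaccard) coefficient |a AND b| / |a OR b| on 2D structural
#' fingerprints is the standard measure of drug chemical similarity.
#'
#' @param a,b Integer 0/1 vectors of equal length.
#' @return Score in [0, 1]; 1 for identical non-empty fingerprints.  Two
#'   all-zero fingerprints score 0 (with a warning) rather than NaN.
#' @examples
#' tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 1/3
#' @export
tanimoto <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) != length(b)) {
    stop("fingerprint length mismatch: ", length(a), " vs ", length(b))
  }
  union_n <- sum(a | b)
  if (union_n == 0) {
    warning("both fingerprints are all-zero; Tanimoto defined as 0")
    return(0)
  }
  sum(a & b) / union_n
}

#' Chemical similarity matrix over a drug set
#'
#' Pairwise Tanimoto coefficients between drug fingerprints, computed with
#' one cross-product for the whole set.
#'
#' @param drugs Named list of `drug_record`s; every drug must carry a
#'   fingerprint and all fingerprints must share a bit length.
#' @return Symmetric numeric matrix with unit diagonal; row d is the
#'   chemical similarity vector CS_d over all drugs.
#' @export
cs_matrix <- function(drugs) {
  ids <- unname(vapply(drugs, `[[`, "", "drug_id"))
  missing <- ids[vapply(drugs, function(d) is.null(d$fingerprint), TRUE)]
  if (length(missing) > 0) {
    stop("drug(s) without a fingerprint: ", paste(missing, collapse = ", "))
  }
  bits <- vapply(drugs, function(d) length(d$fingerprint), 1L)
  if (length(unique(bits)) > 1) {
    stop("fingerprints have differing bit lengths")
  }
  fp <- do.call(rbind, lapply(drugs, `[[`, "fingerprint"))
  inter <- fp %*% t(fp)                      # pairwise |a AND b|
  ones <- rowSums(fp)
  uni <- outer(ones, ones, `+`) - inter      # |a| + |b| - |a AND b|
  m <- ifelse(uni == 0, 0, inter / uni)
  diag(m) <- ifelse(ones == 0, 0, 1)
  if (any(ones == 0)) {
    warning("all-zero fingerprint(s): ", paste(ids[ones == 0], collapse = ", "))
  }
  dimnames(m) <- list(ids, ids)
  m
}
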