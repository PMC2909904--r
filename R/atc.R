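#' ATC code syntax check
#'
#' A full (leaf) ATC code is 7 characters: one uppercase letter (anatomical
#' main group), two digits (therapeutic subgroup), two letters
#' (pharmacological / chemical subgroups), two digits (chemical substance).
#' Input is case-insensitive.
#'
#' @param text Character scalar.
#' @return TRUE if `text` is a syntactically valid leaf ATC code.
#' @export
is_valid_atc_code <- function(text) {
  is.character(text) && length(text) == 1 && !is.na(text) &&
    grepl("^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$", toupper(text))
}

#' Parse an ATC code into its five hierarchy levels
#'
#' The WHO ATC classification is a five-level hierarchy encoded in one
#' 7-character string; the levels are the prefixes of lengths 1, 3, 4, 5
#' and 7.  Only leaf (7-character) codes are accepted in drug assignments.
#'
#' @param text Character scalar; lowercase input is normalized to uppercase.
#' @return A list of class `atc_code` with fields `code` (the leaf) and
#'   `levels` (the 5 nested prefixes).
#' @examples
#' parse_atc_code("N05BA01")$levels
#' @export
parse_atc_code <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text)) {
    stop("ATC code must be a single character string")
  }
  code <- toupper(trimws(text))
  if (!is_valid_atc_code(code)) {
    stop("malformed ATC code: '", text,
         "' (expected 7 characters, pattern letter-digit-digit-letter-",
         "letter-digit-digit)")
  }
  structure(list(code = code,
                 levels = substring(code, 1, c(1L, 3L, 4L, 5L, 7L))),
            class = "atc_code")
}

#' All level-boundary prefixes of a leaf ATC code
#' @param code 7-character ATC code string.
#' @return Character vector of the 5 prefixes (lengths 1, 3, 4, 5, 7).
#' @keywords internal
atc_prefixes <- function(code) {
  substring(code, 1, c(1L, 3L, 4L, 5L, 7L))
}

#' Estimate ATC code prior probabilities from a drug-code corpus
#'
#' Each drug-code assignment contributes one count to every level prefix of
#' its code.  The probability of a prefix is its count divided by the total
#' number of assignments, so the virtual root has probability 1 and
#' probabilities are monotone non-increasing along any root-to-leaf path.
#'
#' @param assignments A data.frame with columns `drug_id` and `atc_code`
#'   (leaf codes), one row per assignment, or a list of `drug_record`s
#'   (each drug contributes once per assigned code).
#' @return An object of class `atc_prob_table`: a list with `prob` (named
#'   numeric vector over prefixes, including the virtual root "<root>" = 1)
#'   and `n_assignments`.
#' @export
estimate_code_probabilities <- function(assignments) {
  if (is.list(assignments) && !is.data.frame(assignments)) {
    codes <- unlist(lapply(assignments, function(d) d$atc_codes),
                    use.names = FALSE)
  } else {
    stopifnot("atc_code" %in% names(assignments))
    codes <- toupper(assignments$atc_code)
  }
  if (length(codes) == 0) stop("empty ATC corpus: no assignments")
  bad <- !vapply(codes, is_valid_atc_code, TRUE)
  if (any(bad)) stop("malformed ATC code in corpus: ", codes[which(bad)[1]])
  prefixes <- unlist(lapply(codes, atc_prefixes), use.names = FALSE)
  counts <- table(prefixes)
  prob <- as.numeric(counts) / length(codes)
  names(prob) <- names(counts)
  prob <- c(prob, "<root>" = 1)
  structure(list(prob = prob, n_assignments = length(codes)),
            class = "atc_prob_table")
}

#' Look up a prefix probability, backing off to a pseudo-count for unseen codes
#' @keywords internal
prefix_prob <- function(prefix, probs) {
  p <- probs$prob[prefix]
  if (is.na(p)) {
    # unseen prefix: behave as if the corpus held one extra assignment of it
    message("ATC prefix '", prefix,
            "' not in the training corpus; using pseudo-count 1")
    p <- 1 / (probs$n_assignments + 1)
  }
  unname(p)
}

#' Information-content similarity between two ATC codes
#'
#' Codes are compared through their longest matched prefix at a level
#' boundary.  With p() the prefix frequency in the corpus, the similarity is
#' the Lin information-content ratio
#' \deqn{sim(i,j) = \frac{2 \log p(prefix(i,j))}{\log p(i) + \log p(j)}}
#' It is 1 for identical codes, 0 when the codes share only the root
#' (which carries no information), and grows with the depth (specificity)
#' of the shared prefix.
#'
#' @param i,j `atc_code` objects or code strings.
#' @param probs An `atc_prob_table` from [estimate_code_probabilities()].
#' @return Similarity score in [0, 1].
#' @export
code_similarity <- function(i, j, probs) {
  if (!inherits(i, "atc_code")) i <- parse_atc_code(i)
  if (!inherits(j, "atc_code")) j <- parse_atc_code(j)
  stopifnot(inherits(probs, "atc_prob_table"))
  if (i$code == j$code) return(1)
  shared <- i$levels[i$levels == j$levels]
  if (length(shared) == 0) return(0)
  lcp <- shared[length(shared)]
  p_common <- prefix_prob(lcp, probs)
  p_i <- prefix_prob(i$code, probs)
  p_j <- prefix_prob(j$code, probs)
  if (p_common >= 1) return(0)          # shared prefix carries no information
  2 * log(p_common) / (log(p_i) + log(p_j))
}

#' Therapeutic similarity between two drugs
#'
#' The therapeutic similarity TS of two drugs is the maximum
#' information-content similarity over all pairs of their ATC codes.
#'
#' @param d1,d2 `drug_record` objects with at least one ATC code each.
#' @param probs An `atc_prob_table`.
#' @return TS score in [0, 1]; symmetric in its arguments.
#' @export
therapeutic_similarity <- function(d1, d2, probs) {
  stopifnot(inherits(d1, "drug_record"), inherits(d2, "drug_record"))
  if (length(d1$atc_codes) == 0 || length(d2$atc_codes) == 0) {
    stop("therapeutic similarity undefined: drug '",
         if (length(d1$atc_codes) == 0) d1$drug_id else d2$drug_id,
         "' has no ATC codes")
  }
  best <- 0
  for (ci in d1$atc_codes) {
    for (cj in d2$atc_codes) {
      s <- code_similarity(ci, cj, probs)
      if (s > best) best <- s
      if (best >= 1) return(1)
    }
  }
  best
}

#' Therapeutic similarity matrix over a drug set
#'
#' @param drugs Named list of `drug_record`s, all with at least one ATC code.
#' @param probs An `atc_prob_table`; by default estimated from `drugs`
#'   themselves.
#' @return Symmetric numeric matrix with unit diagonal; rows and columns
#'   named by drug identifier.  Row d is the pharmacological similarity
#'   vector TS_d over all drugs.
#' @export
ts_matrix <- function(drugs, probs = estimate_code_probabilities(drugs)) {
  ids <- unname(vapply(drugs, `[[`, "", "drug_id"))
  n <- length(drugs)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  if (n > 1) {
    for (a in seq_len(n - 1)) {
      for (b in seq(a + 1, n)) {
        s <- therapeutic_similarity(drugs[[a]], drugs[[b]], probs)
        m[a, b] <- m[b, a] <- s
      }
    }
  }
  m
}
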