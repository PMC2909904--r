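#' Genome-wide biological fingerprint map
#'
#' A drug's biological fingerprint is its genome-wide vector of MS
#' concordance scores: how well each protein's network closeness profile is
#' explained by the drug's combined therapeutic and chemical similarity.
#' The map stacks these vectors into a drugs x proteins matrix.
#'
#' @param drug_ids Drugs to fingerprint (default: all drugs of the TS
#'   matrix).
#' @param ts,cs Similarity matrices.
#' @param phi A `closeness_matrix`.
#' @param model Scoring model (default "MS").
#' @return An object of class `fingerprint_map`: list with `scores`
#'   (drugs x proteins matrix) and `filter_meta` (NULL before filtering).
#' @export
build_fingerprint_map <- function(drug_ids = rownames(ts), ts, cs, phi,
                                  model = "MS") {
  if (length(drug_ids) == 0) stop("empty drug list")
  values <- if (inherits(phi, "closeness_matrix")) phi$values else phi
  rows <- lapply(drug_ids, function(d) {
    score_proteins(d, model, ts = ts, cs = cs, values = values)
  })
  scores <- do.call(rbind, rows)
  rownames(scores) <- drug_ids
  structure(list(scores = scores, model = model, filter_meta = NULL),
            class = "fingerprint_map")
}

#' @export
print.fingerprint_map <- function(x, ...) {
  cat("<fingerprint_map> ", nrow(x$scores), " drugs x ", ncol(x$scores),
      " proteins (", x$model, " scores)",
      if (!is.null(x$filter_meta)) paste0("; filtered: ",
                                          x$filter_meta$criterion) else "",
      "\n", sep = "")
  invisible(x)
}

#' Remove unspecific proteins from a fingerprint map
#'
#' Proteins that receive near-identical concordance scores for every drug
#' carry no discriminative information (typically proteins far from all
#' drug targets) and would inflate cosine resemblances.  The default
#' criterion drops proteins whose across-drug score standard deviation
#' falls below a configurable quantile of all protein SDs; zero-variance
#' proteins are always dropped.
#'
#' @param map A `fingerprint_map` built from at least 2 drugs.
#' @param sd_quantile Quantile of protein score SDs below which a protein
#'   is considered unspecific (default 0.034, which retains about 96.6
#'   percent of proteins on dispersion-homogeneous score matrices).
#' @return The filtered `fingerprint_map`, with `filter_meta` recording the
#'   criterion, threshold and counts.
#' @export
filter_unspecific_proteins <- function(map, sd_quantile = 0.034) {
  stopifnot(inherits(map, "fingerprint_map"))
  if (nrow(map$scores) < 2) stop("need at least 2 drugs to assess specificity")
  sds <- apply(map$scores, 2, stats::sd)
  cutoff <- stats::quantile(sds, sd_quantile, names = FALSE)
  keep <- sds > cutoff & sds > 0
  if (!any(keep)) stop("criterion removed every protein")
  map$filter_meta <- list(criterion = "sd_quantile",
                          sd_quantile = sd_quantile,
                          sd_cutoff = cutoff,
                          n_before = ncol(map$scores),
                          n_after = sum(keep))
  map$scores <- map$scores[, keep, drop = FALSE]
  map
}

#' Cosine activity resemblance between two biological fingerprints
#'
#' @param f1,f2 Numeric vectors of equal length (rows of a fingerprint map).
#' @return Cosine similarity in [-1, 1]; 0 (with a warning) if either
#'   vector is all-zero.
#' @examples
#' activity_resemblance(c(1, 2, 2), c(2, 1, 2))  # 8/9
#' @export
activity_resemblance <- function(f1, f2) {
  if (length(f1) != length(f2)) {
    stop("fingerprint length mismatch: ", length(f1), " vs ", length(f2))
  }
  n1 <- sqrt(sum(f1^2)); n2 <- sqrt(sum(f2^2))
  if (n1 == 0 || n2 == 0) {
    warning("zero fingerprint vector; resemblance defined as 0")
    return(0)
  }
  sum(f1 * f2) / (n1 * n2)
}

#' All pairwise activity resemblances of a fingerprint map
#'
#' @param map A `fingerprint_map`.
#' @return Symmetric drugs x drugs cosine matrix.
#' @export
resemblance_matrix <- function(map) {
  stopifnot(inherits(map, "fingerprint_map"))
  s <- map$scores
  norms <- sqrt(rowSums(s^2))
  norms[norms == 0] <- 1                  # zero rows resolve to resemblance 0
  m <- (s / norms) %*% t(s / norms)
  m[m > 1] <- 1; m[m < -1] <- -1
  m
}

#' Significance threshold for activity resemblance
#'
#' Returns the resemblance value exceeded by at most `alpha` of a null
#' distribution.  The default empirical null takes all observed unordered
#' drug-pair resemblances; the permutation null shuffles protein labels
#' independently within each fingerprint before computing pair
#' resemblances, breaking any drug-drug structure.
#'
#' @param map A `fingerprint_map`.
#' @param alpha Significance level in (0, 1) (default 0.05).
#' @param null_model "empirical" or "permutation".
#' @param n_perm Number of permutation draws (permutation null only).
#' @param seed Integer seed (permutation null only).
#' @return The threshold: the ceiling((1 - alpha) * n)-th order statistic
#'   of the null resemblances.
#' @export
resemblance_threshold <- function(map, alpha = 0.05,
                                  null_model = c("empirical", "permutation"),
                                  n_perm = 100, seed = 1) {
  stopifnot(inherits(map, "fingerprint_map"), alpha > 0, alpha < 1)
  null_model <- match.arg(null_model)
  if (null_model == "empirical") {
    m <- resemblance_matrix(map)
    null_values <- m[upper.tri(m)]
  } else {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           globalenv()))
    set.seed(seed)
    null_values <- unlist(lapply(seq_len(n_perm), function(i) {
      shuffled <- map
      shuffled$scores <- t(apply(map$scores, 1, sample))
      m <- resemblance_matrix(shuffled)
      m[upper.tri(m)]
    }))
  }
  if (length(null_values) < 3) {
    stop("too few null resemblances (", length(null_values),
         ") to estimate a quantile")
  }
  if (length(null_values) * alpha < 1) {
    warning("fewer than 1/alpha null resemblances; the threshold saturates ",
            "at the null maximum")
  }
  sorted <- sort(null_values)
  sorted[ceiling((1 - alpha) * length(sorted))]
}

#' Unexpected drug-drug relations
#'
#' Extracts drug pairs whose biological fingerprints resemble each other at
#' or above the significance threshold even though the drugs share no
#' first-level ATC class — i.e. pairs whose predicted activity overlap is
#' not anticipated by their therapeutic classification.  Pairs sharing a
#' known target are flagged.
#'
#' @param map A `fingerprint_map`.
#' @param drugs Named list of `drug_record`s (for ATC codes and targets);
#'   every fingerprinted drug must have at least one ATC code.
#' @param threshold Resemblance cutoff, e.g. from [resemblance_threshold()].
#' @param resemblances Optional precomputed cosine matrix.
#' @return An object of class `resemblance_result`: data.frame with one row
#'   per unordered pair (`drug1`, `drug2`, `resemblance`,
#'   `shares_target`), sorted by decreasing resemblance; the threshold is
#'   attached as an attribute.
#' @export
unexpected_relations <- function(map, drugs, threshold,
                                 resemblances = resemblance_matrix(map)) {
  ids <- rownames(map$scores)
  no_atc <- ids[vapply(ids, function(i) {
    length(drugs[[i]]$atc_codes) == 0
  }, TRUE)]
  if (length(no_atc) > 0) {
    stop("drug(s) without ATC codes: ", paste(no_atc, collapse = ", "))
  }
  level1 <- lapply(ids, function(i) {
    unique(substr(drugs[[i]]$atc_codes, 1, 1))
  })
  names(level1) <- ids
  rows <- list()
  n <- length(ids)
  if (n >= 2) {
    for (a in seq_len(n - 1)) {
      for (b in seq(a + 1, n)) {
        r <- resemblances[ids[a], ids[b]]
        if (r < threshold) next
        if (length(intersect(level1[[ids[a]]], level1[[ids[b]]])) > 0) next
        shares <- length(intersect(drugs[[ids[a]]]$target_ids,
                                   drugs[[ids[b]]]$target_ids)) > 0
        rows[[length(rows) + 1]] <- data.frame(
          drug1 = ids[a], drug2 = ids[b], resemblance = r,
          shares_target = shares, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows) > 0) {
    do.call(rbind, rows)
  } else {
    data.frame(drug1 = character(), drug2 = character(),
               resemblance = numeric(), shares_target = logical(),
               stringsAsFactors = FALSE)
  }
  out <- out[order(-out$resemblance, out$drug1, out$drug2), ]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("resemblance_result", "data.frame")
  out
}
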