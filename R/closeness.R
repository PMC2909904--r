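#' Distance-to-closeness transfer functions
#'
#' The closeness model converts a shortest-path distance L between two
#' proteins into a proximity weight.  The default Gaussian-decay kernel
#' exp(-L^2) gives weight 1 to a protein's own position, ~0.37 to direct
#' interaction partners, and effectively 0 beyond distance 2; disconnected
#' pairs (L = Inf) always map to 0.
#'
#' @param name One of "exp_sq" (exp(-L^2)) or "exp" (exp(-L)).
#' @return A vectorized pure function numeric -> numeric.
#' @export
transfer_function <- function(name = c("exp_sq", "exp")) {
  name <- match.arg(name)
  switch(name,
         exp_sq = function(L) exp(-L^2),
         exp = function(L) exp(-L))
}

#' Shortest-path distances from a set of source proteins
#'
#' Unweighted breadth-first distances from each source protein to every
#' node of the PPI graph.  Disconnected pairs get Inf; every protein is at
#' distance 0 from itself.
#'
#' @param g An igraph PPI graph (undirected, simple).
#' @param sources Character vector of protein identifiers, all present in `g`.
#' @return Numeric matrix, rows = sources, columns = all graph nodes.
#' @export
shortest_distances <- function(g, sources) {
  sources <- unique(as.character(sources))
  unknown <- setdiff(sources, igraph::V(g)$name)
  if (length(unknown) > 0) {
    stop("source protein(s) not in the PPI graph: ",
         paste(unknown, collapse = ", "))
  }
  d <- igraph::distances(g, v = sources, to = igraph::V(g),
                         algorithm = "unweighted")
  rownames(d) <- sources
  colnames(d) <- igraph::V(g)$name
  d
}

#' Drug-protein closeness matrix
#'
#' The closeness of protein p to drug d is the sum of distance-transformed
#' proximities between p and every known target of d:
#' phi(p, d) = sum over targets t of d of transfer(L(p, t)).
#' A target contributes transfer(0) to its own closeness; proteins
#' disconnected from every target of d score 0, as do all proteins for a
#' drug with no known targets.
#'
#' @param g An igraph PPI graph.  Target proteins absent from the graph are
#'   added as isolated nodes.
#' @param interactions Interaction data.frame (`drug_id`, `protein_id`).
#' @param drug_ids Drugs to build columns for; defaults to the drugs in
#'   `interactions`.  Drugs without targets yield zero columns.
#' @param transfer Distance-to-closeness function (default exp(-L^2)).
#' @return An object of class `closeness_matrix`: list with `values`
#'   (proteins x drugs matrix), `transfer`, and `target_distances`
#'   (targets x proteins shortest-distance matrix, reused by validation).
#' @export
closeness_matrix <- function(g, interactions,
                             drug_ids = sort(unique(interactions$drug_id)),
                             transfer = transfer_function("exp_sq")) {
  all_targets <- sort(unique(interactions$protein_id))
  g <- ensure_proteins(g, all_targets)
  proteins <- igraph::V(g)$name
  values <- matrix(0, nrow = length(proteins), ncol = length(drug_ids),
                   dimnames = list(proteins, drug_ids))
  if (length(all_targets) > 0) {
    dist <- shortest_distances(g, all_targets)
    w <- transfer(dist)
    w[is.infinite(dist)] <- 0
    for (d in drug_ids) {
      tg <- targets_of(interactions, d)
      if (length(tg) == 0) next
      values[, d] <- colSums(w[tg, , drop = FALSE])
    }
  } else {
    dist <- matrix(numeric(), nrow = 0, ncol = length(proteins),
                   dimnames = list(NULL, proteins))
  }
  no_target <- drug_ids[!drug_ids %in% interactions$drug_id]
  if (length(no_target) > 0) {
    message(length(no_target),
            " drug(s) without known targets have all-zero closeness columns")
  }
  structure(list(values = values, transfer = transfer,
                 target_distances = dist),
            class = "closeness_matrix")
}

#' @export
print.closeness_matrix <- function(x, ...) {
  cat("<closeness_matrix> ", nrow(x$values), " proteins x ",
      ncol(x$values), " drugs\n", sep = "")
  invisible(x)
}

#' Genomic relatedness of two drugs
#'
#' The genomic relatedness GR of two drugs is the average
#' distance-transformed closeness over all cross pairs of their known
#' target sets: drugs whose targets sit close together in the PPI network
#' are genomically related.
#'
#' @param d1,d2 `drug_record`s with at least one known target each.
#' @param distances Targets x proteins distance matrix covering both target
#'   sets (e.g. from [shortest_distances()] or a `closeness_matrix`).
#' @param transfer Distance-to-closeness function.
#' @return Mean transfer(L) over the |T1| x |T2| target cross pairs.
#' @export
genomic_relatedness <- function(d1, d2, distances,
                                transfer = transfer_function("exp_sq")) {
  t1 <- d1$target_ids; t2 <- d2$target_ids
  if (length(t1) == 0 || length(t2) == 0) {
    stop("genomic relatedness undefined: drug '",
         if (length(t1) == 0) d1$drug_id else d2$drug_id,
         "' has no known targets")
  }
  L <- distances[t1, t2, drop = FALSE]
  w <- transfer(L)
  w[is.infinite(L)] <- 0
  mean(w)
}

#' Genomic relatedness matrix over a drug set
#'
#' @param drugs Named list of `drug_record`s; drugs without targets are
#'   excluded (with a message).
#' @param g An igraph PPI graph (targets added as isolated nodes if absent).
#' @param transfer Distance-to-closeness function.
#' @return Symmetric matrix of pairwise genomic relatedness, including the
#'   self-relatedness diagonal (mean within-target-set closeness).
#' @export
gr_matrix <- function(drugs, g, transfer = transfer_function("exp_sq")) {
  has_targets <- vapply(drugs, function(d) length(d$target_ids) > 0, TRUE)
  if (any(!has_targets)) {
    message(sum(!has_targets), " drug(s) without targets excluded from GR")
  }
  drugs <- drugs[has_targets]
  if (length(drugs) == 0) stop("no drugs with known targets")
  ids <- vapply(drugs, `[[`, "", "drug_id")
  all_targets <- sort(unique(unlist(lapply(drugs, `[[`, "target_ids"))))
  g <- ensure_proteins(g, all_targets)
  dist <- shortest_distances(g, all_targets)[, all_targets, drop = FALSE]
  n <- length(drugs)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (a in seq_len(n)) {
    for (b in seq(a, n)) {
      v <- genomic_relatedness(drugs[[a]], drugs[[b]], dist, transfer)
      m[a, b] <- m[b, a] <- v
    }
  }
  m
}
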