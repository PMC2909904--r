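#' Generate a seeded synthetic drug-target world
#'
#' Builds a toy dataset with the statistical structure the concordance
#' models assume: (a) a modular PPI network (planted partition: dense
#' within-module, sparse between, plus a few isolated proteins), (b) drug
#' target sets concentrated in a per-drug home module, (c) ATC leaf codes
#' that share deep prefixes for same-module drugs, and (d) binary
#' fingerprints drawn around per-module prototypes so same-module drugs
#' have elevated Tanimoto similarity.
#'
#' The two pharmacological indexes are complementary by construction: the
#' drugs of one target module split into two therapeutic classes (ATC
#' branches) and, independently, into two chemotypes (fingerprint
#' prototypes).  A drug's therapeutic similarity therefore picks out its
#' class-mates and its chemical similarity its chemotype-mates — two
#' different halves of the same target-sharing drug population — so each
#' index alone explains only part of a target protein's closeness profile
#' and their combination explains most of it.  This mirrors the situation
#' where therapeutically aligned drug groups and structurally aligned drug
#' groups overlap but do not coincide on a shared target family.
#'
#' The coupling strengths set how reliable each index is:
#' `ts_strength` (`cs_strength`) is the probability that a drug's
#' therapeutic classification (chemical structure) is informative about
#' its target module at all.  An uninformative drug gets an ATC code in a
#' class of its own (near-zero therapeutic similarity to everyone) or a
#' background-noise fingerprint (flat chemical similarity).  At zero
#' coupling both similarities are independent of the network structure.
#'
#' All randomness flows from `seed` through R's RNG; two calls with the
#' same arguments return identical worlds, and the caller's RNG state is
#' restored on exit.
#'
#' @param n_drugs Number of drugs (default 60).
#' @param n_proteins Number of proteins (default 300).
#' @param n_modules Number of network modules (default 6; at most 10, since
#'   each module claims two ATC first-level letters).
#' @param coupling List with `ts_strength` and `cs_strength` in [0, 1]
#'   (default 0.8 each: strong pharmacological-genomic coupling, with the
#'   two indexes failing on independent ~20 percent subsets of drugs).
#' @param seed Integer seed.
#' @param p_within,p_between Within- and between-module edge probabilities
#'   (defaults 0.45 and 0.01: modules emulate dense complexes/families in
#'   an otherwise sparse interactome).
#' @param frac_isolated Fraction of proteins kept as isolated nodes
#'   (default 0.03).
#' @param frac_no_target Fraction of drugs with no known targets
#'   (default 0.05).
#' @param n_bits Fingerprint length (default 256).
#' @param targets_range Inclusive range of target-set sizes (default 3:6).
#' @return An object of class `synthetic_world`: list with `drugs` (named
#'   list of `drug_record`s), `graph` (igraph), `interactions`
#'   (data.frame), `truth` (module assignments and generator parameters)
#'   and `seed`.
#' @export
generate_world <- function(n_drugs = 60, n_proteins = 300, n_modules = 6,
                           coupling = list(ts_strength = 0.8,
                                           cs_strength = 0.8),
                           seed = 1,
                           p_within = 0.45, p_between = 0.01,
                           frac_isolated = 0.03, frac_no_target = 0.05,
                           n_bits = 256, targets_range = 3:6) {
  ts_strength <- coupling$ts_strength
  cs_strength <- coupling$cs_strength
  stopifnot(ts_strength >= 0, ts_strength <= 1,
            cs_strength >= 0, cs_strength <= 1)
  if (n_modules > n_proteins) stop("more modules than proteins")
  if (n_modules > 10) stop("at most 10 modules (two ATC letters each)")
  n_isolated <- round(frac_isolated * n_proteins)
  if (n_proteins - n_isolated < n_modules * max(targets_range)) {
    stop("too few connected proteins for ", n_modules, " modules with up to ",
         max(targets_range), " targets per drug")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)

  proteins <- sprintf("P%04d", seq_len(n_proteins))
  isolated <- if (n_isolated > 0) {
    sample(proteins, n_isolated)
  } else character()
  members <- setdiff(proteins, isolated)
  module_of <- sample(rep_len(seq_len(n_modules), length(members)))
  names(module_of) <- members

  # planted-partition edges over the non-isolated proteins
  pair_idx <- utils::combn(length(members), 2)
  same <- module_of[pair_idx[1, ]] == module_of[pair_idx[2, ]]
  p_edge <- ifelse(same, p_within, p_between)
  keep <- stats::runif(ncol(pair_idx)) < p_edge
  edges <- cbind(members[pair_idx[1, keep]], members[pair_idx[2, keep]])
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- ensure_proteins(g, proteins)

  # drugs: home module, targets mostly from home, ATC codes, fingerprints.
  # Each module owns two ATC branches (distinct first-level letters) and
  # two fingerprint chemotype prototypes; drugs pick one of each
  # independently, making TS and CS complementary views of the module.
  module_letters <- LETTERS[seq_len(2 * n_modules)]
  noise_letters <- setdiff(LETTERS, module_letters)
  branch_of <- paste0(module_letters,
                      sprintf("%02d", rep(seq_len(n_modules), each = 2)),
                      "AA")                     # branches 2m-1, 2m of module m
  prototypes <- matrix(stats::rbinom(2 * n_modules * n_bits, 1, 0.3),
                       nrow = 2 * n_modules)    # chemotypes 2m-1, 2m
  by_module <- split(members, factor(module_of, levels = seq_len(n_modules)))

  drug_ids <- sprintf("D%03d", seq_len(n_drugs))
  home <- sample(seq_len(n_modules), n_drugs, replace = TRUE)
  no_target <- stats::runif(n_drugs) < frac_no_target
  ts_inf <- cs_inf <- logical(n_drugs)
  drugs <- vector("list", n_drugs)
  pairs <- list()
  for (i in seq_len(n_drugs)) {
    m <- home[i]
    # targets: drawn mostly from the home module (itself a dense network
    # neighborhood), occasionally from anywhere in the connected part
    tg <- character()
    if (!no_target[i]) {
      k <- sample(targets_range, 1)
      from_home <- stats::runif(k) < 0.9
      tg <- unique(c(
        sample(by_module[[m]], sum(from_home)),
        if (any(!from_home)) sample(members, sum(!from_home)) else character()
      ))
      pairs[[i]] <- data.frame(drug_id = drug_ids[i], protein_id = tg,
                               stringsAsFactors = FALSE)
    }
    # ATC leaf: one of the home module's two branches if the therapeutic
    # index is informative, otherwise an out-of-pool class of its own
    ts_inf[i] <- stats::runif(1) < ts_strength
    branch <- if (ts_inf[i]) {
      branch_of[2 * (m - 1) + sample.int(2, 1)]
    } else {
      paste0(sample(noise_letters, 1), sprintf("%02d", sample.int(99, 1)),
             paste(sample(LETTERS, 2, replace = TRUE), collapse = ""))
    }
    code <- paste0(branch, sprintf("%02d", ((i - 1) %% 99) + 1))
    # fingerprint: one of the home module's two chemotype prototypes (with
    # light bit flips) if the chemical index is informative, else noise
    cs_inf[i] <- stats::runif(1) < cs_strength
    bits <- if (cs_inf[i]) {
      proto <- prototypes[2 * (m - 1) + sample.int(2, 1), ]
      ifelse(stats::runif(n_bits) < 0.05, 1L - proto, proto)
    } else {
      stats::rbinom(n_bits, 1, 0.3)
    }
    drugs[[i]] <- drug_record(drug_ids[i], atc_codes = code,
                              fingerprint = bits, target_ids = tg)
  }
  names(drugs) <- drug_ids
  interactions <- if (length(pairs) > 0) {
    do.call(rbind, pairs[!vapply(pairs, is.null, TRUE)])
  } else {
    data.frame(drug_id = character(), protein_id = character(),
               stringsAsFactors = FALSE)
  }
  rownames(interactions) <- NULL
  structure(list(drugs = drugs, graph = g, interactions = interactions,
                 truth = list(module_of_protein = module_of,
                              isolated = sort(isolated),
                              home_module = stats::setNames(home, drug_ids),
                              ts_informative = stats::setNames(ts_inf,
                                                               drug_ids),
                              cs_informative = stats::setNames(cs_inf,
                                                               drug_ids),
                              params = list(n_drugs = n_drugs,
                                            n_proteins = n_proteins,
                                            n_modules = n_modules,
                                            ts_strength = ts_strength,
                                            cs_strength = cs_strength,
                                            p_within = p_within,
                                            p_between = p_between)),
                 seed = seed),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  p <- x$truth$params
  cat("<synthetic_world> ", p$n_drugs, " drugs, ", p$n_proteins,
      " proteins, ", p$n_modules, " modules, coupling ts=", p$ts_strength,
      " cs=", p$cs_strength, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Export a synthetic world as the four canonical input tables
#'
#' Writes `atc.tsv`, `fingerprints.tsv`, `targets.tsv` and `ppi.tsv` into
#' `directory`.  Isolated proteins are serialized in `ppi.tsv` as
#' self-pairs, a convention [read_ppi_edgelist()] resolves back to
#' degree-0 nodes (the loop edge is dropped, the node is kept).
#'
#' @param world A `synthetic_world`.
#' @param directory Output directory (created if needed).
#' @return Invisibly, the character vector of file paths written.
#' @export
export_world <- function(world, directory) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  write_rows <- function(path, header, rows) {
    writeLines(c(paste(header, collapse = "\t"), rows), path)
  }
  paths <- file.path(directory,
                     c("atc.tsv", "fingerprints.tsv", "targets.tsv",
                       "ppi.tsv"))
  atc_rows <- unlist(lapply(world$drugs, function(d) {
    paste(d$drug_id, d$atc_codes, sep = "\t")
  }), use.names = FALSE)
  write_rows(paths[1], c("drug_id", "atc_code"), atc_rows)
  fp_rows <- vapply(world$drugs, function(d) {
    paste(d$drug_id, paste(d$fingerprint, collapse = ""), sep = "\t")
  }, "")
  write_rows(paths[2], c("drug_id", "fingerprint"), fp_rows)
  tg <- world$interactions
  write_rows(paths[3], c("drug_id", "protein_id"),
             if (nrow(tg) > 0) paste(tg$drug_id, tg$protein_id, sep = "\t")
             else character())
  el <- igraph::as_edgelist(world$graph)
  deg0 <- igraph::V(world$graph)$name[igraph::degree(world$graph) == 0]
  write_rows(paths[4], c("protein_a", "protein_b"),
             c(paste(el[, 1], el[, 2], sep = "\t"),
               paste(deg0, deg0, sep = "\t")))
  invisible(paths)
}

#' Re-read an exported synthetic world
#'
#' @param directory Directory written by [export_world()].
#' @return List with `drugs`, `graph`, `interactions`, comparable to the
#'   corresponding fields of the original world.
#' @export
import_world <- function(directory) {
  drugs <- read_drug_tables(file.path(directory, "atc.tsv"),
                            file.path(directory, "fingerprints.tsv"),
                            file.path(directory, "targets.tsv"))
  # isolated nodes travel as self-pairs; the loop-drop warning is expected
  g <- suppressWarnings(read_ppi_edgelist(file.path(directory, "ppi.tsv")))
  interactions <- read_interactions(file.path(directory, "targets.tsv"))
  list(drugs = drugs, graph = g, interactions = interactions)
}
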