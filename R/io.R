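#' Read a tab-separated table with '#' comment lines
#'
#' All tabular inputs use TSV with a header row; lines starting with '#'
#' are ignored.
#'
#' @param path Path to the file.
#' @param required_cols Character vector of column names that must be present.
#' @return A data.frame with character columns.
#' @keywords internal
read_tsv_table <- function(path, required_cols = NULL) {
  if (!file.exists(path)) {
    stop("file does not exist: ", path)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", colClasses = "character",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "")
  if (!is.null(required_cols)) {
    missing <- setdiff(required_cols, names(df))
    if (length(missing) > 0) {
      stop("file ", path, " is missing required column(s): ",
           paste(missing, collapse = ", "))
    }
  }
  df
}

#' Construct a drug record
#'
#' A `drug_record` bundles everything the scoring models need to know about
#' one drug: its ATC codes (therapeutic classification leaves), a binary
#' structural fingerprint, and its set of known protein targets.  Any field
#' except the identifier may be empty.
#'
#' @param drug_id Character scalar identifier, unique within a dataset.
#' @param atc_codes Character vector of 7-character ATC codes (may be empty).
#' @param fingerprint Integer 0/1 vector, or NULL when no structure is known.
#' @param target_ids Character vector of protein identifiers (may be empty).
#' @return An object of class `drug_record`.
#' @examples
#' d <- drug_record("d1", atc_codes = "N05BA01", target_ids = c("p1", "p2"))
#' n_targets(d)
#' @export
drug_record <- function(drug_id, atc_codes = character(),
                        fingerprint = NULL, target_ids = character()) {
  stopifnot(is.character(drug_id), length(drug_id) == 1, nzchar(drug_id))
  atc_codes <- vapply(atc_codes, function(code) parse_atc_code(code)$code, "")
  names(atc_codes) <- NULL
  if (!is.null(fingerprint)) {
    fingerprint <- as.integer(fingerprint)
    if (any(is.na(fingerprint)) || any(!fingerprint %in% c(0L, 1L))) {
      stop("fingerprint for drug ", drug_id, " must be a binary 0/1 vector")
    }
  }
  structure(list(drug_id = drug_id,
                 atc_codes = unique(atc_codes),
                 fingerprint = fingerprint,
                 target_ids = sort(unique(as.character(target_ids)))),
            class = "drug_record")
}

#' Number of known targets of a drug
#'
#' @param drug A `drug_record`.
#' @return Integer count of known targets.
#' @export
n_targets <- function(drug) {
  stopifnot(inherits(drug, "drug_record"))
  length(drug$target_ids)
}

#' @export
print.drug_record <- function(x, ...) {
  cat("<drug_record> ", x$drug_id, ": ",
      length(x$atc_codes), " ATC code(s), ",
      if (is.null(x$fingerprint)) "no fingerprint"
      else paste0(length(x$fingerprint), "-bit fingerprint"),
      ", ", length(x$target_ids), " target(s)\n", sep = "")
  invisible(x)
}

#' Read drug annotation tables into drug records
#'
#' Assembles one `drug_record` per distinct drug identifier appearing in any
#' of the three input tables.  Drugs absent from a table get the
#' corresponding empty field.
#'
#' @param atc_path TSV with columns `drug_id`, `atc_code` (one assignment per
#'   row), or NULL.
#' @param fingerprint_path TSV with columns `drug_id`, `fingerprint` (a
#'   literal bitstring such as "01101..."), or NULL.
#' @param target_path TSV with columns `drug_id`, `protein_id`, or NULL.
#' @return Named list of `drug_record` objects, sorted by drug identifier.
#' @details Duplicate (drug, code) or (drug, target) rows are collapsed with
#'   a warning.  A malformed ATC code raises an error naming the offending
#'   line.  All fingerprints in one dataset must share the same bit length.
#' @export
read_drug_tables <- function(atc_path = NULL, fingerprint_path = NULL,
                             target_path = NULL) {
  if (is.null(atc_path) && is.null(fingerprint_path) && is.null(target_path)) {
    stop("at least one input table must be given")
  }
  atc <- fp <- tg <- NULL
  if (!is.null(atc_path)) {
    atc <- read_tsv_table(atc_path, c("drug_id", "atc_code"))
    bad <- !vapply(atc$atc_code, is_valid_atc_code, TRUE)
    if (any(bad)) {
      i <- which(bad)[1]
      stop("malformed ATC code '", atc$atc_code[i], "' for drug '",
           atc$drug_id[i], "' (data row ", i, " of ", atc_path, ")")
    }
    atc$atc_code <- toupper(atc$atc_code)
    dup <- duplicated(atc[c("drug_id", "atc_code")])
    if (any(dup)) {
      warning(sum(dup), " duplicate (drug, ATC code) row(s) dropped")
      atc <- atc[!dup, ]
    }
  }
  if (!is.null(fingerprint_path)) {
    fp <- read_tsv_table(fingerprint_path, c("drug_id", "fingerprint"))
    if (anyDuplicated(fp$drug_id)) {
      stop("duplicate drug_id in fingerprint table: ",
           fp$drug_id[duplicated(fp$drug_id)][1])
    }
    if (any(grepl("[^01]", fp$fingerprint))) {
      stop("fingerprints must be bitstrings over {0,1}")
    }
    if (length(unique(nchar(fp$fingerprint))) > 1) {
      stop("all fingerprints must have the same bit length")
    }
  }
  if (!is.null(target_path)) {
    tg <- read_tsv_table(target_path, c("drug_id", "protein_id"))
    dup <- duplicated(tg[c("drug_id", "protein_id")])
    if (any(dup)) {
      warning(sum(dup), " duplicate (drug, target) row(s) dropped")
      tg <- tg[!dup, ]
    }
  }
  ids <- sort(unique(c(atc$drug_id, fp$drug_id, tg$drug_id)))
  if (length(ids) == 0) stop("no drugs found in the input tables")
  drugs <- lapply(ids, function(id) {
    bits <- NULL
    if (!is.null(fp) && id %in% fp$drug_id) {
      bits <- as.integer(strsplit(fp$fingerprint[fp$drug_id == id], "")[[1]])
    }
    drug_record(id,
                atc_codes = if (is.null(atc)) character()
                            else atc$atc_code[atc$drug_id == id],
                fingerprint = bits,
                target_ids = if (is.null(tg)) character()
                             else tg$protein_id[tg$drug_id == id])
  })
  names(drugs) <- ids
  drugs
}

#' Read a protein-protein interaction edge list
#'
#' Builds a simple undirected graph from a two-column TSV of protein
#' identifiers, or from a SIF file ("a interacts b").  Self-loops are
#' dropped with a warning; duplicate and reversed edges are collapsed.
#'
#' @param path Path to a TSV (first two columns used; extra columns ignored)
#'   or a `.sif` file (columns 1 and 3 used).
#' @return An [igraph::graph] object, undirected and simple.
#' @export
read_ppi_edgelist <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  is_sif <- grepl("\\.sif$", path, ignore.case = TRUE)
  if (!is_sif && length(lines) > 0) lines <- lines[-1]  # TSV header row
  if (length(lines) == 0) stop("empty PPI edge list: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  need <- if (is_sif) 3L else 2L
  if (any(ncol < need)) {
    stop("row ", which(ncol < need)[1], " of ", path, " has fewer than ",
         need, " columns")
  }
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", if (is_sif) 3L else 2L)
  loops <- a == b
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped from ", path)
  }
  g <- igraph::graph_from_edgelist(cbind(a, b), directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Ensure proteins are present in a PPI graph
#'
#' Target proteins missing from the interactome are added as isolated
#' nodes so that every known target can be scored.
#'
#' @param g An igraph graph.
#' @param protein_ids Character vector of protein identifiers.
#' @return The graph with any missing identifiers added as degree-0 nodes.
#' @export
ensure_proteins <- function(g, protein_ids) {
  missing <- setdiff(unique(protein_ids), igraph::V(g)$name)
  if (length(missing) > 0) {
    g <- igraph::add_vertices(g, length(missing), name = missing)
  }
  g
}

#' Read a drug-target interaction table
#'
#' @param path TSV with columns `drug_id`, `protein_id` and optionally `ki_nM`
#'   (binding affinity in nanomolar).
#' @return A data.frame of class `interaction_table` with the same columns;
#'   duplicate pairs collapsed with a warning.
#' @export
read_interactions <- function(path) {
  df <- read_tsv_table(path, c("drug_id", "protein_id"))
  if ("ki_nM" %in% names(df)) {
    df$ki_nM <- as.numeric(df$ki_nM)
    if (any(!is.na(df$ki_nM) & df$ki_nM <= 0)) {
      stop("Ki values must be strictly positive")
    }
  }
  dup <- duplicated(df[c("drug_id", "protein_id")])
  if (any(dup)) {
    warning(sum(dup), " duplicate interaction pair(s) dropped")
    df <- df[!dup, ]
  }
  class(df) <- c("interaction_table", "data.frame")
  df
}

#' Filter binding interactions by affinity
#'
#' Pairs with a Ki binding affinity strictly lower than the threshold are
#' treated as drug-target interactions; the conventional cutoff is 10 uM
#' (10,000 nM).
#'
#' @param interactions A data.frame with columns `drug_id`, `protein_id`,
#'   `ki_nM`; every row must carry a Ki value.
#' @param threshold_nM Affinity cutoff in nanomolar (default 10,000).
#' @return The rows with `ki_nM < threshold_nM`.
#' @export
apply_ki_filter <- function(interactions, threshold_nM = 10000) {
  stopifnot(is.data.frame(interactions))
  if (nrow(interactions) == 0) return(interactions)
  if (!"ki_nM" %in% names(interactions) || any(is.na(interactions$ki_nM))) {
    stop("every interaction must carry a ki_nM affinity value")
  }
  interactions[interactions$ki_nM < threshold_nM, , drop = FALSE]
}

#' Write a numeric matrix as TSV with row and column headers
#'
#' Values are serialized with 17 significant digits so that write-then-read
#' round-trips doubles exactly.
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  txt <- matrix(sprintf("%.17g", m), nrow = nrow(m))
  header <- paste(c("id", colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], txt[i, ]), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
}

#' Read a numeric matrix written by [write_matrix_tsv()]
#'
#' @param path Input path.
#' @return Numeric matrix with dimnames restored.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, comment.char = "#")
  as.matrix(df)
}

#' Extract the target set of one drug from an interaction table
#' @param interactions Interaction data.frame.
#' @param drug_id Drug identifier.
#' @return Character vector of protein identifiers.
#' @keywords internal
targets_of <- function(interactions, drug_id) {
  sort(unique(interactions$protein_id[interactions$drug_id == drug_id]))
}
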