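#' Default run configuration
#'
#' Validation defaults follow the standard protocol for this framework:
#' 19 negative controls per held-out pair (20 candidates), 100 repeats.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    atc = NULL, fingerprints = NULL, targets = NULL, ppi = NULL,
    out_dir = "drugcipher_out",
    model = "MS",
    transfer = "exp_sq",
    n_negatives = 19,
    n_repeats = 100,
    seed = 1,
    sd_quantile = 0.034,
    alpha = 0.05
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(overrides)] <- overrides
  cfg
}

#' Run the full scoring and analysis pipeline
#'
#' Chains the whole workflow on one configuration: read inputs, build the
#' TS and CS similarity matrices, compute the drug-protein closeness
#' matrix, rank all proteins for every drug under the configured model,
#' run leave-one-out validation and the pooled ROC, and build the filtered
#' biological fingerprint map with its unexpected drug-drug relations.
#' Deterministic given the seed.
#'
#' @param config List from [default_config()]; `atc`, `fingerprints`,
#'   `targets` and `ppi` must point to readable TSV files.
#' @return Invisibly, a list with the in-memory results (`ts`, `cs`,
#'   `phi`, `ranks`, `validation`, `roc`, `fingerprints`, `relations`) and
#'   `files`, the paths written into `config$out_dir`: ts.tsv, cs.tsv,
#'   phi.tsv, ranks.tsv, validation_report.tsv, fingerprint_map.tsv,
#'   resemblance_pairs.tsv, plus the resolved config and a log.
#' @export
run_all <- function(config = default_config()) {
  t0 <- Sys.time()
  for (key in c("atc", "fingerprints", "targets", "ppi")) {
    if (is.null(config[[key]]) || !file.exists(config[[key]])) {
      stop("stage input: configuration key '", key,
           "' must name an existing file")
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$out_dir, name)
  log_lines <- c(paste0("# drugcipher run, R ", getRversion()),
                 paste0("start\t", format(t0, "%Y-%m-%d %H:%M:%S")))
  stage <- function(name) {
    log_lines <<- c(log_lines, paste0("stage\t", name))
    message("[run_all] ", name)
  }

  stage("read inputs")
  drugs <- read_drug_tables(config$atc, config$fingerprints, config$targets)
  g <- suppressWarnings(read_ppi_edgelist(config$ppi))
  interactions <- read_interactions(config$targets)
  transfer <- transfer_function(config$transfer)

  stage("pharmacological similarity")
  probs <- estimate_code_probabilities(drugs)
  ts <- ts_matrix(drugs, probs)
  cs <- cs_matrix(drugs)
  write_matrix_tsv(ts, out("ts.tsv"))
  write_matrix_tsv(cs, out("cs.tsv"))

  stage("network closeness")
  drug_ids <- names(drugs)
  phi <- suppressMessages(
    closeness_matrix(g, interactions, drug_ids = drug_ids,
                     transfer = transfer))
  write_matrix_tsv(phi$values, out("phi.tsv"))

  stage("genome-wide ranking")
  with_targets <- sort(unique(interactions$drug_id))
  ranks <- lapply(drug_ids, rank_proteins, model = config$model,
                  ts = ts, cs = cs, phi = phi)
  names(ranks) <- drug_ids
  rank_df <- do.call(rbind, lapply(drug_ids, function(d) {
    cbind(drug_id = d, as.data.frame(ranks[[d]]))
  }))
  utils::write.table(rank_df, out("ranks.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  stage("validation")
  validation <- loocv_precision(config$model, interactions, phi,
                                ts = ts, cs = cs,
                                n_negatives = config$n_negatives,
                                n_repeats = config$n_repeats,
                                seed = config$seed)
  roc <- pooled_rank_roc(ranks[with_targets], interactions)
  report <- data.frame(repeat_index = seq_len(config$n_repeats),
                       precision = validation$per_repeat)
  header <- c(sprintf("# model\t%s", config$model),
              sprintf("# mean_precision\t%.6f", validation$precision),
              sprintf("# pooled_auc\t%.6f", roc$auc),
              sprintf("# n_negatives\t%d", config$n_negatives),
              sprintf("# seed\t%d", config$seed))
  writeLines(c(header, "repeat_index\tprecision",
               sprintf("%d\t%.6f", report$repeat_index, report$precision)),
             out("validation_report.tsv"))

  stage("biological fingerprints")
  fmap <- build_fingerprint_map(drug_ids, ts, cs, phi)
  fmap <- filter_unspecific_proteins(fmap, sd_quantile = config$sd_quantile)
  write_matrix_tsv(fmap$scores, out("fingerprint_map.tsv"))
  threshold <- resemblance_threshold(fmap, alpha = config$alpha)
  relations <- unexpected_relations(fmap, drugs, threshold)
  utils::write.table(cbind(as.data.frame(relations)),
                     out("resemblance_pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  stage("write config and log")
  cfg_lines <- vapply(names(config), function(k) {
    paste0(k, ": ", if (is.null(config[[k]])) "~" else config[[k]])
  }, "")
  writeLines(cfg_lines, out("config.yaml"))
  log_lines <- c(log_lines,
                 paste0("config_hash\t",
                        sum(utf8ToInt(paste(cfg_lines, collapse = "\n")))),
                 paste0("end\t", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  writeLines(log_lines, out("run.log"))

  invisible(list(ts = ts, cs = cs, phi = phi, ranks = ranks,
                 validation = validation, roc = roc,
                 fingerprints = fmap, relations = relations,
                 threshold = threshold,
                 files = vapply(c("ts.tsv", "cs.tsv", "phi.tsv", "ranks.tsv",
                                  "validation_report.tsv",
                                  "fingerprint_map.tsv",
                                  "resemblance_pairs.tsv"), out, "")))
}
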