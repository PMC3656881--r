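# End-to-end pipeline: compile -> rebalance -> select/train -> evaluate ->
# (optional) scan, with a manifest recording inputs, seeds and versions.

PIPELINE_KEYS <- c("interactions", "unlabeled", "min_positives",
                   "rebalance", "degrees", "costs", "outer", "outer_k",
                   "inner_k", "repeats", "scan", "seed", "out_dir")
SCAN_KEYS <- c("proteome", "phosphosites", "localization",
               "domain_proteins", "top_k", "promiscuity_threshold")

#' Validate a pipeline configuration
#'
#' Checks a configuration list (or YAML file) against the known keys;
#' unknown keys are rejected by name. Missing optional keys get defaults.
#'
#' @param config named list, or path to a YAML file.
#' @return validated configuration list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$interactions))
    stop("configuration requires 'interactions' (TSV path or data frame)")
  if (!is.null(config$scan)) {
    unknown <- setdiff(names(config$scan), SCAN_KEYS)
    if (length(unknown))
      stop("unknown scan key(s): ", paste(unknown, collapse = ", "))
  }
  defaults <- list(min_positives = 40L, degrees = c(1L, 2L),
                   costs = c(0.1, 1, 10), outer = "cv", outer_k = 5L,
                   inner_k = 10L, repeats = 5L, seed = 1L,
                   rebalance = list())
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  config
}

#' Run the full pipeline
#'
#' Compiles per-domain datasets from an interaction table, rebalances each by
#' self-training, selects (degree, cost) by the nested protocol, trains the
#' final model on the balanced data, and evaluates it; optionally runs the
#' proteome scan with the trained models. All artifacts (models, reports,
#' manifest) are written under `out_dir`. All randomness flows from
#' `config$seed`; identical configuration and seed reproduce identical
#' reports.
#'
#' @param config configuration list or YAML path (see [pipeline_config()]).
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return invisibly, a list with per-domain `models`, `reports`,
#'   `retention` and (if configured) the `scan` result.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- pipeline_config(config)
  out_dir <- out_dir %||% config$out_dir %||% stop("out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "models"), showWarnings = FALSE)

  records <- if (is.data.frame(config$interactions)) config$interactions
             else read_interactions(config$interactions)
  input_digest <- if (is.character(config$interactions))
    unname(tools::md5sum(config$interactions)) else NA_character_

  rc <- resolve_conflicts(records)
  unlabeled <- config$unlabeled
  if (is.character(unlabeled) && length(unlabeled) == 1L &&
      file.exists(unlabeled))
    unlabeled <- utils::read.delim(unlabeled, header = TRUE)$peptide
  datasets <- compile_datasets(rc$records, unlabeled = unlabeled)
  flt <- filter_domains(datasets, config$min_positives)

  models <- list(); reports <- list()
  seeds <- make_stage_seeds(config$seed, length(flt$datasets))
  for (i in seq_along(flt$datasets)) {
    d <- flt$datasets[[i]]
    if (NROW(d$negatives) < 1L) {
      warning("domain ", d$domain_id, " has no negatives; skipped")
      next
    }
    reb_cfg <- do.call(rebalance_config,
                       c(config$rebalance, list(seed = seeds[i])))
    reb <- rebalance(d, reb_cfg)
    x <- rbind(reb$balanced_positives, reb$balanced_negatives)
    y <- c(rep(1L, nrow(reb$balanced_positives)),
           rep(-1L, nrow(reb$balanced_negatives)))
    sel <- select_model(x, y, degrees = config$degrees, costs = config$costs,
                        outer = config$outer, outer_k = config$outer_k,
                        inner_k = config$inner_k, repeats = config$repeats,
                        seed = seeds[i])
    model <- svm_train(x, y, degree = sel$config$degree,
                       cost = sel$config$cost, scheme = d$scheme)
    models[[d$domain_id]] <- model
    save_model(model, file.path(out_dir, "models",
                                paste0(d$domain_id, ".json")))
    reports[[d$domain_id]] <- list(
      domain_id = d$domain_id,
      n_pos = NROW(d$positives), n_neg = NROW(d$negatives),
      n_mined = length(reb$mined_idx), rebalance_flags = as.list(reb$flags),
      config = sel$config, performance = as.list(as.data.frame(sel$report)))
  }

  scan_res <- NULL
  if (!is.null(config$scan) && length(models)) {
    sc <- config$scan
    proteome <- if (is.character(sc$proteome) && length(sc$proteome) == 1L &&
                    file.exists(sc$proteome)) read_fasta(sc$proteome)
                else sc$proteome
    sites <- if (is.character(sc$phosphosites))
      read_phosphosites(sc$phosphosites) else sc$phosphosites
    loc <- if (is.character(sc$localization))
      read_localization(sc$localization) else sc$localization
    scan_res <- scan_proteome(models, proteome, sites, loc,
                              domain_proteins = sc$domain_proteins,
                              top_k = sc$top_k %||% 50L,
                              promiscuity_threshold =
                                sc$promiscuity_threshold %||% 40L)
    utils::write.table(scan_res$predictions,
                       file.path(out_dir, "predictions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("sh2pep")),
    seed = config$seed, input_digest = input_digest,
    n_records = nrow(records), conflicts_discarded = rc$n_conflicts,
    duplicates_collapsed = rc$n_duplicates,
    domains_retained = names(flt$datasets))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(reports, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.table(flt$report, file.path(out_dir, "retention.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(models = models, reports = reports,
                 retention = flt$report, scan = scan_res))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# derive per-stage seeds from the single global seed (kept below 2^31)
make_stage_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}
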