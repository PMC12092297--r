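# End-to-end orchestration: simulate/ingest -> lexicon features -> factor
# scores -> preprocessing -> split-half mixed-model fits -> marker selection
# -> change evaluation, with every stage output written to disk before the
# next stage starts and a manifest sufficient to reproduce the run.

#' Pipeline configuration
#'
#' Collects paths, thresholds and seeds for [run_all()]. Inputs may either
#' be existing files (`paths`) or a [sim_config()] under `sim`, in which
#' case the simulate stage writes the input fixture first.
#'
#' @param outdir output directory; stage outputs and the manifest land here.
#' @param sim optional [sim_config()]; if present the pipeline simulates
#'   its own inputs.
#' @param paths named list of input files (`word_bags`, `survey_items`,
#'   `schedule`, `device_log`, `completion`, `domain_spec`); filled in
#'   automatically when `sim` is given.
#' @param category_lexicon_file,weighted_lexicon_files lexicon files;
#'   defaults are the package's bundled toy lexicons.
#' @param alpha significance level for both selection stages.
#' @param spearman_threshold redundancy-pruning threshold (strict).
#' @param zero_pct_threshold zero-percentage filter threshold (strict).
#' @param wordcount_cap daily word-count mask threshold (strict).
#' @param split_seed seed of the participant split.
#' @param endpoints endpoint timepoint days for change evaluation
#'   (default: first and last scheduled).
#' @param t_means,n_starts bivariate mixed model options.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir,
                            sim = NULL,
                            paths = list(),
                            category_lexicon_file =
                              system.file("extdata", "toy_categories.csv",
                                          package = "langmarker"),
                            weighted_lexicon_files =
                              system.file("extdata", "toy_distress.csv",
                                          package = "langmarker"),
                            alpha = 0.05,
                            spearman_threshold = 0.85,
                            zero_pct_threshold = 90,
                            wordcount_cap = 10000,
                            split_seed = 42,
                            endpoints = NULL,
                            t_means = FALSE,
                            n_starts = 5) {
  stopifnot(alpha > 0 || alpha == 0, alpha <= 1,
            spearman_threshold > 0, spearman_threshold <= 1,
            zero_pct_threshold >= 0, zero_pct_threshold <= 100,
            wordcount_cap > 0)
  structure(list(outdir = outdir, sim = sim, paths = paths,
                 category_lexicon_file = category_lexicon_file,
                 weighted_lexicon_files = weighted_lexicon_files,
                 alpha = alpha, spearman_threshold = spearman_threshold,
                 zero_pct_threshold = zero_pct_threshold,
                 wordcount_cap = wordcount_cap, split_seed = split_seed,
                 endpoints = endpoints, t_means = t_means,
                 n_starts = n_starts),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys mirror the [pipeline_config()] arguments
#'   (`sim` is a mapping passed to [sim_config()]).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  defaults <- formals(pipeline_config)
  args <- y[intersect(names(y), names(defaults))]
  do.call(pipeline_config, args)
}

out_path <- function(config, file) file.path(config$outdir, file)

in_path <- function(config, key) {
  p <- config$paths[[key]]
  if (is.null(p)) p <- out_path(config, file.path("input", paste0(key, ".csv")))
  if (key == "domain_spec" && !grepl("json$", p))
    p <- sub("csv$", "json", p)
  if (!file.exists(p)) stop_("input '%s' not found at %s", key, p)
  p
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (write the synthetic input fixture), `extract`
#' (word bags -> raw feature matrix), `score` (survey items -> factor
#' scores), `preprocess` (filters, split, normalization, pruning,
#' alignment), `fit` (per-pair bivariate mixed models on both halves),
#' `select` (two-stage marker selection), `evaluate` (missingness
#' diagnostic and change-prediction metrics). Each stage reads its inputs
#' from, and writes its outputs to, `config$outdir`, so [run_all()] is
#' exactly the composition of the seven stages.
#'
#' @param stage stage name.
#' @param config a [pipeline_config()].
#' @return invisibly, a list of the stage's in-memory outputs.
#' @export
run_stage <- function(stage, config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$outdir)) dir.create(config$outdir, recursive = TRUE)
  switch(stage,
         simulate = stage_simulate(config),
         extract = stage_extract(config),
         score = stage_score(config),
         preprocess = stage_preprocess(config),
         fit = stage_fit(config),
         select = stage_select(config),
         evaluate = stage_evaluate(config),
         stop_("unknown stage '%s'", stage))
}

stage_simulate <- function(config) {
  if (is.null(config$sim)) return(invisible(NULL))
  cohort <- simulate_cohort(config$sim)
  paths <- write_fixture(cohort, out_path(config, "input"))
  invisible(list(cohort = cohort, paths = paths))
}

stage_extract <- function(config) {
  bags <- read_word_bags(in_path(config, "word_bags"))
  cats <- read_category_lexicons(config$category_lexicon_file)
  wts <- lapply(config$weighted_lexicon_files, read_weighted_lexicon)
  fm <- build_feature_matrix(bags, cats, wts)
  utils::write.csv(fm, out_path(config, "features_raw.csv"), row.names = FALSE)
  invisible(list(features = fm))
}

stage_score <- function(config) {
  items <- read_survey_items(in_path(config, "survey_items"))
  ds <- jsonlite::read_json(in_path(config, "domain_spec"),
                            simplifyVector = TRUE)
  ds <- lapply(ds, function(d) list(domain = d$domain,
                                    items = unlist(d$items),
                                    timepoints = unlist(d$timepoints)))
  sc <- score_domains(items, ds, n_starts = config$n_starts)
  utils::write.csv(sc$scores, out_path(config, "scores.csv"),
                   row.names = FALSE)
  conv <- data.frame(domain = names(sc$models),
                     converged = vapply(sc$models, `[[`, TRUE, "converged"),
                     loglik = vapply(sc$models, `[[`, 0, "loglik"))
  jsonlite::write_json(conv, out_path(config, "measurement_summary.json"),
                       digits = NA)
  invisible(sc)
}

stage_preprocess <- function(config) {
  fm <- utils::read.csv(out_path(config, "features_raw.csv"),
                        check.names = FALSE,
                        colClasses = c(participant_id = "character",
                                       date = "Date"))
  scores <- utils::read.csv(out_path(config, "scores.csv"),
                            colClasses = c(participant_id = "character"))
  schedule <- utils::read.csv(in_path(config, "schedule"),
                              colClasses = c(participant_id = "character",
                                             date = "Date"))
  device_log <- utils::read.csv(in_path(config, "device_log"),
                                colClasses = c(participant_id = "character"))
  report <- list()

  cap <- cap_word_count(fm, config$wordcount_cap)
  report$n_wordcount_masked <- cap$n_cells_masked
  zf <- filter_zero_features(cap$matrix, config$zero_pct_threshold)
  report$zero_filtered <- zf$dropped
  osf <- drop_os_switchers(zf$matrix, device_log)
  report$os_switchers_removed <- osf$removed
  fm <- osf$matrix
  scores <- scores[!scores$participant_id %in% osf$removed, , drop = FALSE]
  schedule <- schedule[!schedule$participant_id %in% osf$removed, ,
                       drop = FALSE]

  split <- split_participants(sort(unique(c(fm$participant_id,
                                            scores$participant_id))),
                              config$split_seed)
  id_half <- names(split)[split == "identification"]
  fm <- normalize_features(fm, fit_rows = fm$participant_id %in% id_half)

  pr <- prune_redundant(fm, scores, schedule,
                        threshold = config$spearman_threshold)
  report$pruned <- pr$report
  fm <- pr$matrix

  panel <- align_observations(fm, scores, schedule)
  utils::write.csv(panel, out_path(config, "panel.csv"), row.names = FALSE)
  utils::write.csv(data.frame(participant_id = names(split),
                              half = as.vector(unclass(split))),
                   out_path(config, "split.csv"), row.names = FALSE)
  jsonlite::write_json(report, out_path(config, "filter_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(panel = panel, split = split, report = report))
}

read_panel <- function(config) {
  utils::read.csv(out_path(config, "panel.csv"),
                  colClasses = c(participant_id = "character"))
}

stage_fit <- function(config) {
  panel <- read_panel(config)
  split <- utils::read.csv(out_path(config, "split.csv"),
                           colClasses = c(participant_id = "character"))
  id_half <- split$participant_id[split$half == "identification"]
  f1 <- fit_pairs(panel[panel$participant_id %in% id_half, , drop = FALSE],
                  t_means = config$t_means, n_starts = config$n_starts)
  f2 <- fit_pairs(panel[!panel$participant_id %in% id_half, , drop = FALSE],
                  t_means = config$t_means, n_starts = config$n_starts)
  utils::write.csv(f1, out_path(config, "fits_identification.csv"),
                   row.names = FALSE)
  utils::write.csv(f2, out_path(config, "fits_validation.csv"),
                   row.names = FALSE)
  invisible(list(identification = f1, validation = f2))
}

stage_select <- function(config) {
  f1 <- utils::read.csv(out_path(config, "fits_identification.csv"))
  f2 <- utils::read.csv(out_path(config, "fits_validation.csv"))
  mt <- run_selection(f1, f2, alpha = config$alpha)
  utils::write.csv(mt, out_path(config, "marker_table.csv"),
                   row.names = FALSE)
  invisible(list(markers = mt))
}

stage_evaluate <- function(config) {
  mt <- utils::read.csv(out_path(config, "marker_table.csv"))
  class(mt) <- c("marker_table", "data.frame")
  panel <- read_panel(config)
  scores <- utils::read.csv(out_path(config, "scores.csv"),
                            colClasses = c(participant_id = "character"))
  scores <- scores[scores$participant_id %in% panel$participant_id, ,
                   drop = FALSE]
  records <- compute_changes(scores, panel, endpoints = config$endpoints)
  metrics <- evaluate_markers(mt, records)
  utils::write.csv(metrics, out_path(config, "change_metrics.csv"),
                   row.names = FALSE)

  diag <- tryCatch({
    completion <- utils::read.csv(in_path(config, "completion"),
                                  colClasses = c(participant_id = "character"))
    missingness_diagnostic(scores, completion)
  }, error = function(e) NULL)
  if (!is.null(diag))
    jsonlite::write_json(list(mar_plausible = diag$mar_plausible,
                              correlations = diag$correlations),
                         out_path(config, "missingness_diagnostic.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(list(metrics = metrics, records = records, diagnostic = diag))
}

#' Run the complete marker pipeline
#'
#' Executes simulate (if configured), extract, score, preprocess, fit,
#' select and evaluate in order; every stage's outputs are written to
#' `config$outdir` before the next stage starts. With identical
#' configuration and inputs, every output file is byte-identical across
#' reruns (all randomness flows from the configured seeds).
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the run manifest (also written to `manifest.json`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$outdir)) dir.create(config$outdir, recursive = TRUE)
  counts <- list()
  run_stage("simulate", config)
  ex <- run_stage("extract", config)
  counts$feature_rows <- nrow(ex$features)
  sc <- run_stage("score", config)
  counts$score_rows <- nrow(sc$scores)
  pp <- run_stage("preprocess", config)
  counts$panel_rows <- nrow(pp$panel)
  ft <- run_stage("fit", config)
  counts$pairs <- nrow(ft$identification)
  counts$nonconverged <- sum(!ft$identification$converged) +
    sum(!ft$validation$converged)
  sel <- run_stage("select", config)
  counts$validated <- sum(sel$markers$status == "validated")
  ev <- run_stage("evaluate", config)
  counts$change_records <- nrow(ev$records)

  manifest <- list(
    package_version = as.character(utils::packageVersion("langmarker")),
    config = config_snapshot(config),
    seeds = list(split_seed = config$split_seed,
                 sim_seed = if (is.null(config$sim)) NULL else config$sim$seed),
    row_counts = counts,
    filter_report = pp$report,
    mar_plausible = if (is.null(ev$diagnostic)) NA else
      ev$diagnostic$mar_plausible)
  jsonlite::write_json(manifest, out_path(config, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

config_snapshot <- function(config) {
  cf <- unclass(config)
  if (!is.null(cf$sim)) cf$sim <- unclass(cf$sim)
  cf
}
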