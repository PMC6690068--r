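# Single entry point over the pipeline stages (simulate, curate,
# benchmark, temporal, report) driven by a config list or YAML file, with
# per-stage artifacts and a run manifest.

.default_config <- function() {
  list(
    stages = c("simulate", "curate", "benchmark", "report"),
    seed = 1L,
    synthetic = list(),         # overrides for synthetic_config()
    rf = list(),                # overrides for rf_config()
    plan = list(),              # overrides for split_plan()
    epsilons = c(0.30, 0.20, 0.10),
    p_value_mode = "literal",
    metric_modes = c("incl", "excl"),
    temporal_new_separability = NULL,
    min_per_target = 10L,
    input = NULL,               # existing activity CSV (skips simulate)
    output_dir = "cpqsar_run"
  )
}

#' Validate and complete a pipeline configuration
#'
#' Unknown keys are an error (naming them), epsilons must lie in (0, 1),
#' and sub-configurations are completed with their defaults.
#'
#' @param config list of settings, or a path to a YAML file with the same
#'   keys.
#' @return completed configuration list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  defaults <- .default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  merged <- utils::modifyList(defaults, config, keep.null = TRUE)
  if (any(merged$epsilons <= 0 | merged$epsilons >= 1)) {
    stop("configuration field 'epsilons' must lie strictly in (0, 1); got ",
         paste(merged$epsilons, collapse = ", "), call. = FALSE)
  }
  if (!merged$p_value_mode %in% c("literal", "adjusted")) {
    stop("configuration field 'p_value_mode' must be 'literal' or 'adjusted'",
         call. = FALSE)
  }
  for (nm in c("synthetic", "rf", "plan")) {
    if (!is.list(merged[[nm]])) {
      stop("configuration field '", nm, "' must be a list of overrides",
           call. = FALSE)
    }
  }
  merged
}

write_manifest <- function(dir, config, extra = list()) {
  manifest <- c(list(
    package = "cpqsar",
    package_version = as.character(utils::packageVersion("cpqsar")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    ranger_version = as.character(utils::packageVersion("ranger")),
    seed = config$seed,
    config = config[setdiff(names(config), "output_dir")]
  ), extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
}

#' Run the pipeline
#'
#' Executes the configured stages in order: `simulate` writes the
#' synthetic activity table, truth table and feature store; `curate`
#' produces per-target curated CSVs and the run summary; `benchmark` runs
#' both modelling arms under shared seeds and writes per-target
#' predictions and the metrics table; `temporal` generates a release pair
#' and writes pooled temporal metrics; `report` writes family aggregates
#' and confusion-count tables.  Every run writes `manifest.json` (config,
#' seeds, versions).  A failing target is logged and skipped; a failing
#' stage aborts with a nonzero-exit-worthy error.
#'
#' @param config configuration list or YAML path (see
#'   [validate_config()]).
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = list()) {
  config <- validate_config(config)
  dir <- config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  results <- list()
  syn_cfg <- do.call(synthetic_config,
                     utils::modifyList(config$synthetic,
                                       list(seed = config$seed)))
  rf_cfg <- do.call(rf_config, config$rf)
  plan <- do.call(split_plan,
                  utils::modifyList(config$plan, list(seed = config$seed)))
  study <- NULL
  if ("simulate" %in% stages) {
    study <- generate_activity_table(syn_cfg)
    utils::write.csv(study$records, file.path(dir, "activity_records.csv"),
                     row.names = FALSE)
    utils::write.csv(study$truth, file.path(dir, "truth.csv"),
                     row.names = FALSE)
    results$study <- study
  } else if (!is.null(config$input)) {
    study <- list(records = utils::read.csv(config$input), features = NULL)
  }
  curated <- NULL
  if ("curate" %in% stages) {
    if (is.null(study)) {
      stop("curate stage needs a simulate stage or an 'input' table",
           call. = FALSE)
    }
    curated <- curate_activity_table(study$records)
    write_curated(curated, file.path(dir, "curated"))
    results$curated <- curated
  }
  bench <- NULL
  if ("benchmark" %in% stages) {
    if (is.null(curated) || is.null(study$features)) {
      stop("benchmark stage needs curated targets and a feature store",
           call. = FALSE)
    }
    bench <- run_benchmark(curated$datasets, study$features, plan, rf_cfg,
                           config$epsilons, config$p_value_mode)
    utils::write.csv(bench$metrics, file.path(dir, "metrics.csv"),
                     row.names = FALSE)
    pred_dir <- file.path(dir, "predictions")
    dir.create(pred_dir, showWarnings = FALSE)
    for (tid in names(bench$predictions)) {
      p <- bench$predictions[[tid]]
      if (!is.null(p$qsar)) {
        utils::write.csv(p$qsar, file.path(pred_dir, paste0(tid, "_qsar.csv")),
                         row.names = FALSE)
      }
      if (!is.null(p$mcp)) {
        utils::write.csv(p$mcp, file.path(pred_dir, paste0(tid, "_mcp.csv")),
                         row.names = FALSE)
      }
    }
    if (length(bench$errors)) {
      utils::write.csv(
        data.frame(target_id = names(bench$errors),
                   error = unname(bench$errors)),
        file.path(dir, "target_errors.csv"), row.names = FALSE)
    }
    results$benchmark <- bench
  }
  if ("temporal" %in% stages) {
    pair <- generate_temporal_pair(syn_cfg,
                                   new_separability = config$temporal_new_separability)
    cur_a <- curate_activity_table(pair$release_a$records)
    cur_b <- curate_activity_table(pair$release_b$records)
    temp <- temporal_validate(cur_a, cur_b, pair$release_b$features, plan,
                              rf_cfg, config$epsilons, config$p_value_mode,
                              config$min_per_target)
    utils::write.csv(temp$pooled, file.path(dir, "temporal_pooled.csv"),
                     row.names = FALSE)
    results$temporal <- temp
  }
  if ("report" %in% stages && !is.null(bench) && nrow(bench$metrics)) {
    utils::write.csv(aggregate_by_family(bench$metrics),
                     file.path(dir, "family_metrics.csv"),
                     row.names = FALSE)
  }
  write_manifest(dir, config,
                 extra = list(split_seeds = plan$split_seeds))
  invisible(results)
}

#' Command-line interface
#'
#' Thin shell over [run_pipeline()]:
#' `cpqsar_cli(c("run", "--config", "cfg.yaml", "--out", "dir",
#' "--seed", "7"))`.  The first argument selects the stage set: `run`
#' (configured stages), or one of `simulate`, `curate`, `benchmark`,
#' `temporal`, `report` to run the stages up to and including that one.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
cpqsar_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: cpqsar <run|simulate|curate|benchmark|temporal|report>",
    "[--config FILE] [--out DIR] [--seed N]")
  if (!length(args) || args[[1L]] %in% c("-h", "--help")) {
    message(usage)
    return(invisible(0L))
  }
  cmd <- args[[1L]]
  stage_sets <- list(
    simulate = "simulate",
    curate = c("simulate", "curate"),
    benchmark = c("simulate", "curate", "benchmark"),
    temporal = c("simulate", "curate", "benchmark", "temporal"),
    report = c("simulate", "curate", "benchmark", "report"))
  if (!cmd %in% c("run", names(stage_sets))) {
    message("unknown command: ", cmd, "\n", usage)
    return(invisible(2L))
  }
  opt <- function(flag) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[[i + 1L]] else NULL
  }
  config <- opt("--config") %||% list()
  status <- tryCatch({
    config <- validate_config(config)
    out <- opt("--out")
    if (!is.null(out)) config$output_dir <- out
    seed <- opt("--seed")
    if (!is.null(seed)) config$seed <- as.integer(seed)
    if (cmd != "run") config$stages <- stage_sets[[cmd]]
    run_pipeline(config)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
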