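#' Pipeline configuration
#'
#' One structured object drives the whole analysis: either file inputs
#' (survey + climate tables) or a synthetic-data block, the retention rules,
#' metric options, the model battery selection and MCMC control, ordination
#' metrics, and the null-model block. All randomness flows from `seed`,
#' split deterministically per stage.
#'
#' @param survey_path,climate_path delimited input files (ignored when a
#'   synthetic block is given).
#' @param synthetic `NULL`, or a list with `scenario` (name) and optional
#'   [synth_config()] overrides — the pipeline then generates its input.
#' @param rules retention rules, see [retention_rules()].
#' @param turnover_component headline turnover component
#'   (`"replacement"` or `"total"`).
#' @param models battery subset to fit (`NULL` = all), see [model_battery()].
#' @param mcmc list with `chains`, `iter`, `warmup`.
#' @param ordination_metrics dissimilarity metrics for the homogenization
#'   analysis.
#' @param null list passed to [null_config()].
#' @param level credible level for model summaries.
#' @param seed root seed.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(survey_path = NULL, climate_path = NULL,
                            synthetic = list(scenario = "paper_like"),
                            rules = retention_rules(),
                            turnover_component = "replacement",
                            models = NULL,
                            mcmc = list(chains = 4, iter = 2000,
                                        warmup = 1000),
                            ordination_metrics = c("jaccard", "braycurtis"),
                            null = list(n_replicates = 100),
                            level = 0.95, seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   arguments (rule fields given under `rules` are passed to
#'   [retention_rules()]).
#' @return a `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$rules)) y$rules <- do.call(retention_rules, y$rules)
  # `null` is a YAML keyword; accept `null_model` as the block name
  if (!is.null(y$null_model)) {
    y$null <- y$null_model
    y$null_model <- NULL
  }
  do.call(pipeline_config, y)
}

#' Run the analysis pipeline (or one of its stages)
#'
#' Stages: `validate` (read/generate and validate inputs), `simulate`
#' (synthetic generation only), `metrics` (retention, harmonization,
#' diversity states, turnover, trajectories), `trends` (per-plot and
#' climate slopes), `models` (hierarchical model battery), `ordination`
#' (subsite homogenization analysis), `nullmodel`, `all`. Artifacts are
#' written as delimited text under `outdir` together with a run manifest
#' (config hash, seed, package version, failures).
#'
#' @param config a [pipeline_config()].
#' @param stage one stage name or `"all"`.
#' @param outdir output directory (created if needed); `NULL` = no files.
#' @param seed optional override of `config$seed`.
#' @return (invisibly) a list of in-memory artifacts: `tables`
#'   ([pipeline_tables()] output), and per-stage results `suite`, `homog`,
#'   `null_result`, `null_comparison`, `truth`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), stage = "all",
                         outdir = NULL, seed = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- match.arg(stage, c("all", "validate", "simulate", "metrics",
                              "trends", "models", "ordination", "nullmodel"))
  if (!is.null(seed)) config$seed <- seed
  failures <- character(0)
  art <- list()

  # --- inputs -------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$synthetic)) {
    overrides <- config$synthetic[setdiff(names(config$synthetic), "scenario")]
    gen <- do.call(scenario, c(list(name = config$synthetic$scenario %||%
                                      "paper_like"),
                               overrides,
                               if (!"seed" %in% names(overrides))
                                 list(seed = config$seed)))
    sim <- generate_synthetic(gen)
    survey <- sim$survey; climate <- sim$climate; truth <- sim$truth
  } else {
    if (is.null(config$survey_path)) stop("no survey input: give survey_path or a synthetic block")
    survey <- read_survey_table(config$survey_path)
    climate <- if (!is.null(config$climate_path))
      read_climate_series(config$climate_path) else NULL
  }
  art$truth <- truth
  if (stage %in% c("validate", "simulate")) {
    art$survey <- survey; art$climate <- climate
    return(invisible(.finish_run(art, config, outdir, failures, stage)))
  }

  # --- tables (metrics + trends) -----------------------------------------
  tables <- tryCatch(pipeline_tables(survey, climate, config$rules),
                     error = function(e) {
                       failures["tables"] <<- conditionMessage(e); NULL
                     })
  art$tables <- tables
  if (is.null(tables) || stage %in% c("metrics", "trends"))
    return(invisible(.finish_run(art, config, outdir, failures, stage)))

  # --- models -------------------------------------------------------------
  if (stage %in% c("all", "models")) {
    art$suite <- tryCatch(
      run_model_suite(tables, models = config$models,
                      battery = model_battery(config$turnover_component),
                      chains = config$mcmc$chains, iter = config$mcmc$iter,
                      warmup = config$mcmc$warmup, level = config$level,
                      seed = config$seed + 101L),
      error = function(e) { failures["models"] <<- conditionMessage(e); NULL })
  }
  # --- ordination ---------------------------------------------------------
  if (stage %in% c("all", "ordination")) {
    art$homog <- tryCatch(
      homogenization_report(tables$community_temporal,
                            metrics = config$ordination_metrics),
      error = function(e) { failures["ordination"] <<- conditionMessage(e); NULL })
  }
  # --- null model ---------------------------------------------------------
  if (stage %in% c("all", "nullmodel")) {
    art$null_result <- tryCatch({
      nc <- do.call(null_config,
                    utils::modifyList(list(seed = config$seed + 202L),
                                      config$null %||% list()))
      simulate_null(tables$community_temporal, nc)
    }, error = function(e) { failures["nullmodel"] <<- conditionMessage(e); NULL })
    if (!is.null(art$null_result) && !is.null(tables$design_plot))
      art$null_comparison <- compare_null(tables$design_plot, art$null_result)
  }
  invisible(.finish_run(art, config, outdir, failures, stage))
}

.finish_run <- function(art, config, outdir, failures, stage) {
  art$manifest <- list(
    stage = stage, seed = config$seed,
    config_hash = .config_hash(config),
    package_version = as.character(utils::packageVersion("tundiv")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    failures = as.list(failures))
  if (length(failures) > 0)
    warning("pipeline stage failure(s): ",
            paste(names(failures), collapse = ", "))
  if (!is.null(outdir)) .write_artifacts(art, outdir)
  art
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config[order(names(unclass(config)))]), f)
  unname(tools::md5sum(f))
}

.write_artifacts <- function(art, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) {
    if (!is.null(x))
      utils::write.csv(x, file.path(outdir, name), row.names = FALSE)
  }
  t <- art$tables
  if (!is.null(t)) {
    wr(t$states, "diversity_states.csv")
    wr(t$trends, "metric_trends.csv")
    wr(t$turnover, "turnover.csv")
    wr(t$trajectories, "trajectories.csv")
    wr(t$fg_change, "functional_group_change.csv")
    wr(t$design_plot, "design_plot.csv")
    wr(t$rarity, "species_loss_rarity.csv")
    if (!is.null(t$retention)) {
      con <- file(file.path(outdir, "retention_report.txt"), "w")
      sink(con); print(t$retention); sink(); close(con)
    }
    if (!is.null(t$community_temporal))
      utils::write.csv(as.data.frame(unclass(t$community_temporal)),
                       file.path(outdir, "community_temporal.csv"))
  }
  if (!is.null(art$suite)) wr(art$suite$coefficients, "model_coefficients.csv")
  if (!is.null(art$homog)) {
    wr(art$homog$summary, "homogenization_summary.csv")
    for (m in names(art$homog$detail))
      wr(art$homog$detail[[m]]$shifts, paste0("shifts_", m, ".csv"))
  }
  if (!is.null(art$null_result)) wr(art$null_result$summary, "null_summary.csv")
  if (!is.null(art$null_comparison)) wr(art$null_comparison, "null_comparison.csv")
  jsonlite::write_json(art$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}
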