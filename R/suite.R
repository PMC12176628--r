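#' Compute every upstream table of the analysis pipeline
#'
#' Runs retention filtering, cover harmonization, diversity states, per-plot
#' trends, turnover partitions, trajectories, functional-group composition
#' and change, climate summaries and trailing temperatures, and assembles the
#' plot-level and plot-year-level design tables that the model battery
#' consumes.
#'
#' @param survey a `survey_table`.
#' @param climate optional climate series ([as_climate_series()]).
#' @param rules retention rules ([retention_rules()]).
#' @param midpoints cover-class midpoint map.
#' @param climate_window year range for climatologies and change slopes.
#' @return a named list of tables (see [assemble_design()]) plus
#'   `design_plot`, `design_plot_year`, `shrub_year`, `shrub_change_long`,
#'   `rarity`, the community matrices and the retention report.
#' @export
pipeline_tables <- function(survey, climate = NULL,
                            rules = retention_rules(),
                            midpoints = cover_class_midpoints(),
                            climate_window = c(1979, 2013)) {
  ret <- apply_retention_filters(survey, rules)
  traits <- trait_map(ret$spatial)
  tr <- species_traits(ret$spatial)
  shrub_cats <- setNames(tr$shrub_category, tr$species)

  mat_sp <- community_matrix(ret$spatial, midpoints)
  mat_tm <- community_matrix(ret$temporal, midpoints)
  states_sp <- diversity_state(mat_sp)
  states_tm <- diversity_state(mat_tm)
  trends <- metric_trends(states_tm)
  fg_change <- functional_group_change(mat_tm, traits, shrub_cats)
  turn <- plot_turnover(mat_tm)
  fcomp <- functional_composition(mat_sp, traits)

  cc <- clim <- trail <- NULL
  if (!is.null(climate)) {
    cc <- climate_change(climate, climate_window)
    clim <- climatology(climate, climate_window)
  }

  tables <- list(samples = sample_info(mat_sp), states = states_sp,
                 trends = trends, fg_change = fg_change,
                 turnover = turn$turnover, trajectories = turn$trajectories,
                 fcomp = fcomp$by_plot, climate_change = cc,
                 climatology = clim)
  design_plot <- assemble_design(tables, unit = "plot")
  design_py <- assemble_design(tables, unit = "plot_year")

  # shrub cover by category per plot-year (post hoc sensitivity analysis)
  s_tm <- sample_info(mat_tm)
  shrub_year <- NULL
  for (cat in c("dwarf", "erect")) {
    sel <- shrub_cats[colnames(mat_tm)] == cat
    if (!any(sel)) next
    d <- data.frame(plot = s_tm$plot, subsite = s_tm$subsite,
                    year = s_tm$year, shrub_category = cat,
                    cover_prop = rowSums(mat_tm[, sel, drop = FALSE]) / 100,
                    stringsAsFactors = FALSE)
    shrub_year <- rbind(shrub_year, d)
  }
  if (!is.null(shrub_year) && !is.null(climate)) {
    trail <- trailing_mean_temp(climate,
                                unique(shrub_year[, c("plot", "subsite", "year")]))
    shrub_year <- merge(shrub_year, trail[, c("plot", "year", "mean5",
                                              "centered5")],
                        by = c("plot", "year"))
  }

  # per-category shrub change, long format (dwarf vs erect interaction models)
  shrub_change_long <- NULL
  for (cat in c("dwarf", "erect")) {
    m <- paste0("shrub_", cat)
    d <- fg_change[fg_change$metric == m, c("unit", "slope")]
    if (nrow(d) == 0) next
    names(d) <- c("plot", "shrub_cat_change")
    d$shrub_category <- cat
    shrub_change_long <- rbind(shrub_change_long, d)
  }
  if (!is.null(shrub_change_long)) {
    meta <- unique(design_plot[, c("plot", "subsite", "latitude")])
    shrub_change_long <- merge(shrub_change_long, meta, by = "plot")
    if (!is.null(cc))
      shrub_change_long <- merge(shrub_change_long, cc, by = "subsite",
                                 all.x = TRUE)
  }

  rarity <- species_loss_rarity(turn$species, ret$spatial)
  rarity$prop_lost <- rarity$pct_lost / 100

  c(tables, list(design_plot = design_plot, design_plot_year = design_py,
                 shrub_year = shrub_year, shrub_change_long = shrub_change_long,
                 rarity = rarity, species = turn$species,
                 trailing_temp = trail,
                 community_spatial = mat_sp, community_temporal = mat_tm,
                 retention = ret$report, spatial = ret$spatial,
                 temporal = ret$temporal, traits = tr))
}

.headline <- function(component = c("replacement", "total")) {
  component <- match.arg(component)
  if (component == "replacement") c(jac = "jac_replacement", bc = "bc_balanced")
  else c(jac = "jac_total", bc = "bc_total")
}

#' The default hierarchical model battery
#'
#' One descriptor per model: high-level richness/evenness change over time
#' (nested random slopes), spatial gradients, two-time-point turnover and
#' trajectory models (climate and one-functional-group-at-a-time variants,
#' which are fitted separately because group covers are compositionally
#' anti-correlated), temporal change-over-time models on per-plot slopes,
#' post hoc shrub sensitivity models, and the rarity-versus-loss regression.
#'
#' @param turnover_component headline turnover component, `"replacement"`
#'   (default: replacement/balanced) or `"total"`.
#' @return named list of model descriptors (data, response, family, fixed,
#'   random) understood by [run_model_suite()].
#' @export
model_battery <- function(turnover_component = "replacement") {
  hl <- .headline(turnover_component)
  ttp <- function(resp, extra = character(0))
    list(data = "design_plot", response = resp, family = "zoi_beta_logit",
         fixed = c("mtwq_clim_c", "precip_clim_mm", "temp_change_c_yr",
                   "precip_change_mm_yr", "ln_plot_size", "duration",
                   "mean_richness", extra),
         random = "subsite")
  fgv <- function(resp, grp)
    list(data = "design_plot", response = resp, family = "zoi_beta_logit",
         fixed = c(paste0(grp, "_change"), "ln_plot_size", "duration",
                   "mean_richness"),
         random = "subsite")
  list(
    high_richness_time = list(
      data = "design_plot_year", response = "richness",
      family = "negbinomial_log", fixed = c("year_c", "ln_plot_size"),
      random = "nested"),
    high_evenness_time = list(
      data = "design_plot_year", response = "pielou",
      family = "zoi_beta_logit", fixed = "year_c", random = "nested"),
    spatial_richness_geo = list(
      data = "design_plot", response = "richness_last",
      family = "negbinomial_log", fixed = c("latitude", "ln_plot_size"),
      random = "subsite"),
    spatial_richness_clim = list(
      data = "design_plot", response = "richness_last",
      family = "negbinomial_log",
      fixed = c("mtwq_clim_c", "precip_clim_mm", "ln_plot_size"),
      random = "subsite"),
    spatial_richness_fg_shrub = list(
      data = "design_plot", response = "richness_last",
      family = "negbinomial_log", fixed = c("shrub_pct", "ln_plot_size"),
      random = "subsite"),
    spatial_richness_fg_forb = list(
      data = "design_plot", response = "richness_last",
      family = "negbinomial_log", fixed = c("forb_pct", "ln_plot_size"),
      random = "subsite"),
    spatial_evenness_geo = list(
      data = "design_plot", response = "pielou_last",
      family = "zoi_beta_logit", fixed = "latitude", random = "subsite"),
    turnover_jac_clim = ttp(hl[["jac"]]),
    turnover_bc_clim = ttp(hl[["bc"]]),
    turnover_jac_fg_shrub = fgv(hl[["jac"]], "shrub"),
    turnover_jac_fg_graminoid = fgv(hl[["jac"]], "graminoid"),
    turnover_jac_fg_forb = fgv(hl[["jac"]], "forb"),
    turnover_bc_fg_shrub = fgv(hl[["bc"]], "shrub"),
    prop_lost_clim = ttp("prop_lost"),
    prop_gained_clim = ttp("prop_gained"),
    prop_persisting_clim = ttp("prop_persisting"),
    prop_lost_fg_shrub = fgv("prop_lost", "shrub"),
    prop_gained_fg_shrub = fgv("prop_gained", "shrub"),
    richness_change_latitude = list(
      data = "design_plot", response = "richness_change", family = "gaussian",
      fixed = c("latitude", "ln_plot_size"), random = "subsite"),
    richness_change_tempchange = list(
      data = "design_plot", response = "richness_change", family = "gaussian",
      fixed = c("temp_change_c_yr", "ln_plot_size"), random = "subsite"),
    richness_change_fg_shrub = list(
      data = "design_plot", response = "richness_change", family = "gaussian",
      fixed = c("shrub_change", "ln_plot_size"), random = "subsite"),
    richness_change_fg_shrub_cats = list(
      data = "design_plot", response = "richness_change", family = "gaussian",
      fixed = c("shrub_dwarf_change", "shrub_erect_change", "ln_plot_size"),
      random = "subsite"),
    richness_change_fg_forb = list(
      data = "design_plot", response = "richness_change", family = "gaussian",
      fixed = c("forb_change", "ln_plot_size"), random = "subsite"),
    evenness_change_tempchange = list(
      data = "design_plot", response = "pielou_change", family = "gaussian",
      fixed = "temp_change_c_yr", random = "subsite"),
    shrub_sensitivity_temp = list(
      data = "shrub_year", response = "cover_prop",
      family = "zoi_beta_logit", fixed = "centered5 * shrub_category",
      random = "nested_shrub"),
    shrub_change_warming = list(
      data = "shrub_change_long", response = "shrub_cat_change",
      family = "gaussian", fixed = "temp_change_c_yr * shrub_category",
      random = "subsite"),
    shrub_change_latitude = list(
      data = "shrub_change_long", response = "shrub_cat_change",
      family = "gaussian", fixed = "latitude", random = "subsite"),
    rarity_loss = list(
      data = "rarity", response = "prop_lost", family = "zoi_beta_logit",
      fixed = "n_study_areas", random = NULL),
    turnover_jac_richness = list(
      data = "design_plot", response = hl[["jac"]],
      family = "zoi_beta_logit", fixed = "mean_richness", random = "subsite"),
    turnover_bc_richness = list(
      data = "design_plot", response = hl[["bc"]],
      family = "zoi_beta_logit", fixed = "mean_richness", random = "subsite")
  )
}

#' Run the hierarchical model battery
#'
#' Fits every (selected) model of [model_battery()] on the tables produced
#' by [pipeline_tables()]. A failing model is recorded and the suite
#' continues.
#'
#' @param tables output of [pipeline_tables()].
#' @param models optional character vector naming battery entries to run
#'   (default: all whose data are available).
#' @param battery battery definition, see [model_battery()].
#' @param chains,iter,warmup MCMC control, see [fit_hmodel()].
#' @param level credible level.
#' @param seed integer seed; model k runs at `seed + k`.
#' @return list with `fits` (named `hier_fit`s), `coefficients` (one tidy
#'   data.frame: model, term, estimate, sd, lower, upper, rhat, converged)
#'   and `errors` (named character vector of failures).
#' @export
run_model_suite <- function(tables, models = NULL,
                            battery = model_battery(),
                            chains = 4, iter = 2000, warmup = floor(iter / 2),
                            level = 0.95, seed = 1) {
  if (is.null(models)) models <- names(battery)
  unknown <- setdiff(models, names(battery))
  fits <- list()
  errors <- character(0)
  for (nm in unknown) errors[nm] <- "unknown model name"
  k <- 0
  for (nm in intersect(models, names(battery))) {
    k <- k + 1
    b <- battery[[nm]]
    dat <- tables[[b$data]]
    res <- tryCatch({
      if (is.null(dat)) stop("data table '", b$data, "' not available")
      random <- switch(b$random %||% "none",
        none = NULL,
        subsite = ranef_intercept("subsite"),
        nested = ranef_nested_slopes("subsite", "plot", "year_c"),
        nested_shrub = ranef_nested_intercepts("subsite", "plot"))
      spec <- hier_spec(b$response, b$family, fixed = b$fixed,
                        random = random, level = level)
      fit_hmodel(spec, dat, chains = chains, iter = iter, warmup = warmup,
                 seed = seed + k)
    }, error = function(e) conditionMessage(e))
    if (inherits(res, "hier_fit")) fits[[nm]] <- res
    else errors[nm] <- res
  }
  coefs <- .rbind_reset(lapply(names(fits), function(nm) {
    d <- fits[[nm]]$coefficients
    cbind(model = nm, d, converged = fits[[nm]]$converged,
          stringsAsFactors = FALSE)
  }))
  list(fits = fits, coefficients = coefs, errors = errors)
}
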