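#' Configuration for the synthetic vegetation-survey generator
#'
#' Defines an Arctic-like hierarchical monitoring design (plots in subsites
#' in study areas along a latitudinal gradient), a nested species pool with
#' functional groups, initial communities with a latitudinal/thermal
#' richness gradient, yearly gain/loss dynamics with optional
#' shrubification coupling, a warming climate, and the observation layer
#' (percent cover, point framing, cover classes).
#'
#' @param n_study_areas,subsites_per_area,plots_per_subsite design counts.
#' @param latitude_range degrees N spanned by the study areas.
#' @param species_pool_size size of the overall species pool.
#' @param regional_pool_size species available per study area.
#' @param subsite_pool_size species available per subsite.
#' @param baseline_log_richness intercept of log expected plot richness.
#' @param richness_latitude_slope log-species per degree latitude.
#' @param richness_temperature_slope log-species per degree C (MTWQ).
#' @param richness_dispersion negative-binomial size of initial richness.
#' @param survey_years calendar years at which every plot is surveyed.
#' @param loss_prob per-species, per-year local extinction probability.
#' @param gain_rate per-year colonist intensity as a fraction of initial
#'   richness (colonist count is Poisson with mean `gain_rate * S0`).
#' @param fg_mix named proportions for shrub/graminoid/forb in the pool.
#' @param dwarf_split fraction of shrub species that are dwarf shrubs.
#' @param shrub_trend list: `mean` and `sd` of the per-plot shrub cover
#'   trend (percent points per year), `erect_only` (apply to erect shrubs
#'   only) and `loss_boost` (multiplier on the loss probability of
#'   non-shrub species per percent-per-year of positive shrub trend).
#' @param cover_noise_sd sd of the lognormal year-to-year cover wobble on
#'   persisting species (0 = static relative abundances).
#' @param method_mix named proportions of subsites surveyed by
#'   `percent_cover`, `point_frame_top`, `point_frame_topbottom`,
#'   `point_frame_allhits` and `cover_class`.
#' @param point_frame_points grid points per point-frame survey.
#' @param warming_rate mean MTWQ trend in degrees C per year.
#' @param warming_sd between-subsite sd of the warming trend.
#' @param mtwq_noise_sd interannual MTWQ noise (degrees C).
#' @param mtwq_at_60 mean MTWQ at 60 degrees N (degrees C).
#' @param lat_temp_gradient MTWQ decline per degree latitude.
#' @param clim_sd between-subsite climatology noise (degrees C).
#' @param end_blend blend weight applied to final-survey covers toward
#'   (positive) or away from (negative) the across-plot mean profile;
#'   used by the homogenizing/differentiating scenarios.
#' @param plot_sizes m2 sizes sampled per plot (constant over years).
#' @param seed integer seed; generation is fully reproducible.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_study_areas = 12, subsites_per_area = 3,
                         plots_per_subsite = 8,
                         latitude_range = c(61, 81),
                         species_pool_size = 400,
                         regional_pool_size = 80,
                         subsite_pool_size = 50,
                         baseline_log_richness = 3.75,
                         richness_latitude_slope = -0.03,
                         richness_temperature_slope = 0.06,
                         richness_dispersion = 8,
                         survey_years = c(2000, 2005, 2010),
                         loss_prob = 0.026,
                         gain_rate = 0.028,
                         fg_mix = c(shrub = 0.3, graminoid = 0.3, forb = 0.4),
                         dwarf_split = 0.5,
                         shrub_trend = list(mean = 0, sd = 0,
                                            erect_only = TRUE, loss_boost = 0),
                         cover_noise_sd = 0.35,
                         method_mix = c(percent_cover = 1),
                         point_frame_points = 100,
                         warming_rate = 0.05,
                         warming_sd = 0.02,
                         mtwq_noise_sd = 0.6,
                         mtwq_at_60 = 12,
                         lat_temp_gradient = 0.4,
                         clim_sd = 1,
                         end_blend = 0,
                         plot_sizes = c(0.25, 0.5, 1),
                         seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$loss_prob >= 0, cfg$loss_prob <= 1, cfg$gain_rate >= 0,
            cfg$subsite_pool_size <= cfg$regional_pool_size,
            cfg$regional_pool_size <= cfg$species_pool_size,
            length(cfg$survey_years) >= 1,
            abs(sum(cfg$fg_mix) - 1) < 1e-8)
  structure(cfg, class = "synth_config")
}

#' Canned generator scenarios
#'
#' `null_change`: no dynamics, no warming, static covers — every diversity
#' change metric is exactly zero. `paper_like`: gradients and per-year
#' gain/loss rates set to reproduce typical circumarctic resurvey
#' conditions (about 64% of species persisting, 19% gained, 17% lost per
#' plot over a decade). `homogenizing`/`differentiating`: final-survey
#' composition pulled toward / pushed away from the across-plot mean.
#' `shrubification`: erect-shrub cover increasing with a loss boost on
#' co-occurring species.
#'
#' @param name scenario name.
#' @param ... overrides passed to [synth_config()].
#' @return a `synth_config`.
#' @export
scenario <- function(name = c("null_change", "paper_like", "homogenizing",
                              "differentiating", "shrubification"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    null_change = list(n_study_areas = 8, subsites_per_area = 2,
                       plots_per_subsite = 6, loss_prob = 0, gain_rate = 0,
                       cover_noise_sd = 0, warming_rate = 0, warming_sd = 0),
    paper_like = list(),
    homogenizing = list(n_study_areas = 8, subsites_per_area = 2,
                        plots_per_subsite = 6, end_blend = 0.6,
                        loss_prob = 0, gain_rate = 0, cover_noise_sd = 0),
    differentiating = list(n_study_areas = 8, subsites_per_area = 2,
                           plots_per_subsite = 6, end_blend = -0.6,
                           loss_prob = 0, gain_rate = 0, cover_noise_sd = 0),
    shrubification = list(shrub_trend = list(mean = 1.5, sd = 1,
                                             erect_only = TRUE,
                                             loss_boost = 0.6)))
  do.call(synth_config, utils::modifyList(base, list(...)))
}

#' Generate a synthetic survey table, climate series and truth record
#'
#' @param config a [synth_config()].
#' @return list with `survey` (a validated `survey_table`), `climate`
#'   (subsite climate series 1979 to the last survey year) and `truth`
#'   (list: per-plot realized initial richness, gains/losses/persistence
#'   between first and last survey, shrub trend, plus the per-subsite
#'   climatologies and warming slopes and the config).
#' @export
generate_synthetic <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  yrs <- sort(unique(config$survey_years))
  y0 <- min(yrs); y1 <- max(yrs)

  # species pool with traits and commonness weights
  n_sp <- config$species_pool_size
  sp_names <- sprintf("sp%03d", seq_len(n_sp))
  fg <- sample(names(config$fg_mix), n_sp, replace = TRUE,
               prob = config$fg_mix)
  shrub_cat <- ifelse(fg != "shrub", "none",
                      ifelse(runif(n_sp) < config$dwarf_split, "dwarf",
                             "erect"))
  commonness <- rlnorm(n_sp, 0, 1)
  names(fg) <- names(shrub_cat) <- names(commonness) <- sp_names

  lats <- seq(config$latitude_range[1], config$latitude_range[2],
              length.out = config$n_study_areas)
  survey <- list(); climate <- list(); truth_plots <- list()
  truth_subsites <- list()
  cover_store <- list()  # plot -> year -> named cover vector (relative)

  for (a in seq_len(config$n_study_areas)) {
    area_id <- sprintf("A%02d", a)
    lat <- lats[a]
    regional <- sample(sp_names, config$regional_pool_size)
    for (ssi in seq_len(config$subsites_per_area)) {
      subsite_id <- sprintf("%s.S%d", area_id, ssi)
      sub_pool <- sample(regional, config$subsite_pool_size)
      mtwq_clim <- config$mtwq_at_60 -
        config$lat_temp_gradient * (lat - 60) + rnorm(1, 0, config$clim_sd)
      precip_clim <- max(150, 500 - 10 * (lat - 60) + rnorm(1, 0, 60))
      warm <- rnorm(1, config$warming_rate, config$warming_sd)
      clim_years <- seq(1979, max(2013, y1))
      ref <- mean(range(clim_years))
      climate[[subsite_id]] <- data.frame(
        subsite = subsite_id, year = clim_years,
        mtwq_c = mtwq_clim + warm * (clim_years - ref) +
          rnorm(length(clim_years), 0, config$mtwq_noise_sd),
        precip_mm = pmax(50, precip_clim +
                           rnorm(length(clim_years), 0, 40)),
        stringsAsFactors = FALSE)
      truth_subsites[[subsite_id]] <- data.frame(
        subsite = subsite_id, study_area = area_id, latitude = lat,
        mtwq_clim = mtwq_clim, precip_clim = precip_clim,
        warming = warm, stringsAsFactors = FALSE)
      method <- sample(names(config$method_mix), 1,
                       prob = config$method_mix)

      for (pi in seq_len(config$plots_per_subsite)) {
        plot_id <- sprintf("%s.P%02d", subsite_id, pi)
        plot_size <- sample(config$plot_sizes, 1)
        mu <- exp(config$baseline_log_richness +
                    config$richness_latitude_slope * lat +
                    config$richness_temperature_slope * mtwq_clim)
        S0 <- max(1L, rnbinom(1, mu = mu, size = config$richness_dispersion))
        if (S0 > config$subsite_pool_size)
          stop("infeasible config: demanded richness ", S0,
               " exceeds the subsite pool (", config$subsite_pool_size, ")")
        present <- sample(sub_pool, S0, prob = commonness[sub_pool])
        w <- setNames(rlnorm(S0, 0, 1) * commonness[present], present)

        shrub_slope <- rnorm(1, config$shrub_trend$mean,
                             config$shrub_trend$sd)
        shrub_set <- if (isTRUE(config$shrub_trend$erect_only))
          names(shrub_cat)[shrub_cat == "erect"] else
          names(fg)[fg == "shrub"]
        p_loss_other <- min(1, config$loss_prob *
                              (1 + config$shrub_trend$loss_boost *
                                 max(0, shrub_slope)))

        # walk years; record covers at survey years
        covers_by_year <- list()
        record <- function(year, wts) {
          if (config$cover_noise_sd > 0)
            wts <- wts * rlnorm(length(wts), 0, config$cover_noise_sd)
          # shrubification: exponential tilt of the shrub weights so the
          # relative shrub cover drifts ~shrub_slope percent points/year
          if (shrub_slope != 0 && length(intersect(names(wts), shrub_set))) {
            sh <- names(wts) %in% shrub_set
            p0 <- sum(wts[sh]) / sum(wts)
            if (p0 > 0 && p0 < 1) {
              gam <- shrub_slope / (100 * p0 * (1 - p0))
              wts[sh] <- wts[sh] * exp(gam * (year - y0))
            }
          }
          covers_by_year[[as.character(year)]] <<- wts / sum(wts) * 100
        }
        record(y0, w)
        if (length(yrs) > 1) {
          for (step_year in (y0 + 1):y1) {
            if (length(w) > 0 && config$loss_prob > 0) {
              pl <- ifelse(fg[names(w)] == "shrub", config$loss_prob,
                           p_loss_other)
              keep <- runif(length(w)) > pl
              if (!any(keep)) keep[sample(length(w), 1)] <- TRUE
              w <- w[keep]
            }
            if (config$gain_rate > 0) {
              n_new <- rpois(1, config$gain_rate * S0)
              cand <- setdiff(sub_pool, names(w))
              n_new <- min(n_new, length(cand))
              if (n_new > 0) {
                newsp <- sample(cand, n_new, prob = commonness[cand])
                w <- c(w, setNames(
                  rlnorm(n_new, -0.5, 1) * commonness[newsp], newsp))
              }
            }
            if (step_year %in% yrs) record(step_year, w)
          }
        }
        cover_store[[plot_id]] <- covers_by_year
        truth_plots[[plot_id]] <- data.frame(
          plot = plot_id, subsite = subsite_id, study_area = area_id,
          latitude = lat, S0 = S0, shrub_slope = shrub_slope,
          plot_size_m2 = plot_size, method = method,
          stringsAsFactors = FALSE)
      }
    }
  }

  # optional contraction/expansion of final-survey composition about the
  # across-plot mean (homogenizing / differentiating constructions)
  if (config$end_blend > 0) {
    # pull every plot's final covers toward the global mean profile
    key1 <- as.character(y1)
    all_sp <- sort(unique(unlist(lapply(cover_store, function(cs)
      names(cs[[key1]])))))
    M <- matrix(0, length(cover_store), length(all_sp),
                dimnames = list(names(cover_store), all_sp))
    for (p in names(cover_store)) M[p, names(cover_store[[p]][[key1]])] <-
      cover_store[[p]][[key1]]
    gmean <- colMeans(M)
    for (p in names(cover_store)) {
      v <- M[p, ] + config$end_blend * (gmean - M[p, ])
      v <- pmax(v, 0)
      v <- v[v > 0]
      cover_store[[p]][[key1]] <- v / sum(v) * 100
    }
  } else if (config$end_blend < 0) {
    # give every subsite exclusive marker species at the final survey, so
    # end profiles move apart under presence- and abundance-based metrics
    # (a pure rescaling away from the mean would cancel on relativization)
    key1 <- as.character(y1)
    n_mk <- ceiling(10 * abs(config$end_blend))
    marker_cover <- 100 * abs(config$end_blend) / n_mk
    # species occupancy across plots at the final survey: widespread
    # (shared) species are dropped so communities lose common ground
    occ_tab <- table(unlist(lapply(cover_store, function(cs)
      names(cs[[key1]]))))
    widespread <- names(occ_tab)[occ_tab > abs(config$end_blend) *
                                   length(cover_store)]
    for (p in names(cover_store)) {
      v0 <- cover_store[[p]][[key1]]
      keep <- setdiff(names(v0), widespread)
      if (length(keep) > 0) cover_store[[p]][[key1]] <- v0[keep]
      ss <- truth_plots[[p]]$subsite
      mk <- sprintf("mk_%s_%d", ss, seq_len(n_mk))
      new_fg <- setNames(rep("forb", n_mk), mk)
      new_sc <- setNames(rep("none", n_mk), mk)
      fg <- c(fg, new_fg[setdiff(mk, names(fg))])
      shrub_cat <- c(shrub_cat, new_sc[setdiff(mk, names(shrub_cat))])
      v <- c(cover_store[[p]][[key1]], setNames(rep(marker_cover, n_mk), mk))
      cover_store[[p]][[key1]] <- v / sum(v) * 100
    }
  }

  # emit long records through the observation layer
  rows <- list()
  for (p in names(truth_plots)) {
    tp <- truth_plots[[p]]
    for (yc in names(cover_store[[p]])) {
      cv <- cover_store[[p]][[yc]]
      if (length(cv) == 0) next
      base <- data.frame(
        study_area = tp$study_area, subsite = tp$subsite, plot = p,
        year = as.integer(yc), species = names(cv),
        functional_group = unname(fg[names(cv)]),
        shrub_category = unname(shrub_cat[names(cv)]),
        method = tp$method, plot_size_m2 = tp$plot_size_m2,
        latitude = tp$latitude, longitude = -100 + tp$latitude,
        treatment = "CTL", stringsAsFactors = FALSE)
      base <- .observe(base, cv, tp$method, config)
      rows[[paste(p, yc)]] <- base
    }
  }
  survey_df <- do.call(rbind, rows)
  rownames(survey_df) <- NULL
  survey <- as_survey_table(survey_df)

  # realized trajectories from the emitted covers (presence is preserved
  # by every observation method)
  truth_tab <- do.call(rbind, truth_plots)
  truth_tab$n_lost <- truth_tab$n_gained <- truth_tab$n_persisting <- NA_integer_
  for (p in names(cover_store)) {
    cs <- cover_store[[p]]
    s0 <- names(cs[[as.character(y0)]])
    s1 <- names(cs[[as.character(y1)]]) %||% character(0)
    truth_tab[truth_tab$plot == p, c("n_lost", "n_gained", "n_persisting")] <-
      c(length(setdiff(s0, s1)), length(setdiff(s1, s0)),
        length(intersect(s0, s1)))
  }
  rownames(truth_tab) <- NULL

  list(survey = survey,
       climate = as_climate_series(do.call(rbind, climate)),
       truth = list(plots = truth_tab,
                    subsites = .rbind_reset(truth_subsites),
                    config = config))
}

# express true relative covers in the subsite's survey method; optional
# columns are always present so records from mixed methods bind cleanly
.observe <- function(base, cv, method, config) {
  base$cover_raw <- NA_real_
  base$cover_class <- NA_character_
  base$total_points <- NA_real_
  if (method == "percent_cover") {
    base$cover_raw <- unname(cv)
  } else if (method == "cover_class") {
    base$cover_class <- vapply(cv, .to_class, character(1))
  } else {
    # deterministic point framing; present species always score >= 1 hit
    hits <- pmax(1, round(cv / 100 * config$point_frame_points))
    base$cover_raw <- unname(hits)
    base$total_points <- config$point_frame_points
  }
  base
}

.to_class <- function(pct) {
  if (pct <= 0.1) "r" else if (pct <= 1) "+" else if (pct <= 5) "1"
  else if (pct <= 25) "2" else if (pct <= 50) "3" else if (pct <= 75) "4"
  else "5"
}
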