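#' Null-model configuration for turnover
#'
#' @param removal_fraction proportion of resident species randomly removed
#'   per plot (simulated losses).
#' @param addition_fraction proportion (of start richness) of donor-pool
#'   species randomly added per plot (simulated gains).
#' @param pool donor-pool rule: species recorded anywhere in the same
#'   `"subsite"` (default) or `"study_area"`, excluding the plot's residents.
#' @param n_replicates number of seeded replicates.
#' @param seed integer root seed.
#' @return a `null_config` list.
#' @export
null_config <- function(removal_fraction = 0.2, addition_fraction = 0.2,
                        pool = c("subsite", "study_area"), n_replicates = 100,
                        seed = 1) {
  stopifnot(removal_fraction >= 0, removal_fraction < 1,
            addition_fraction >= 0, addition_fraction < 1, n_replicates >= 1)
  structure(list(removal_fraction = removal_fraction,
                 addition_fraction = addition_fraction,
                 pool = match.arg(pool), n_replicates = n_replicates,
                 seed = seed), class = "null_config")
}

# nearest integer, halves away from zero
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Simulate the species removal/addition null model
#'
#' For every plot's baseline community: remove `round(f_r * S)` uniformly
#' chosen resident species and add `round(f_a * S)` species drawn uniformly
#' from the donor pool (pool species absent from the plot; truncated to the
#' pool size when too few, and flagged). Added species receive the pool-mean
#' relative cover of that species; the simulated end row is then
#' relativized and compared to the baseline with the usual turnover
#' partition. Because removal and addition counts are deterministic given S,
#' every replicate's total Jaccard dissimilarity per plot equals
#' `(r + g) / (S + g)` regardless of the seed.
#'
#' @param mat community matrix of the temporal plot set (baseline rows are
#'   each plot's first survey year).
#' @param config a [null_config()].
#' @return a `null_result`: list with `per_plot` (replicate, plot, turnover
#'   partition columns, richness), `summary` (per-replicate means of each
#'   turnover component), `truncated` (plots whose additions were cut short)
#'   and the config.
#' @export
simulate_null <- function(mat, config = null_config()) {
  s <- sample_info(mat)
  plots <- split(seq_len(nrow(mat)), s$plot)
  start_idx <- vapply(plots, function(i) i[which.min(s$year[i])], 1L)
  start_rows <- mat[start_idx, , drop = FALSE]
  plot_names <- names(plots)
  group_of <- if (config$pool == "subsite") s$subsite[start_idx] else
    s$study_area[start_idx]

  # donor pools: species recorded anywhere in the plot's group (any year)
  pool_group <- if (config$pool == "subsite") s$subsite else s$study_area
  pool_species <- lapply(unique(pool_group), function(g) {
    colnames(mat)[colSums(mat[pool_group == g, , drop = FALSE]) > 0]
  })
  names(pool_species) <- unique(pool_group)
  # pool mean cover per species within group (over rows where present)
  pool_mean_cover <- lapply(unique(pool_group), function(g) {
    sub <- mat[pool_group == g, , drop = FALSE]
    cs <- colSums(sub); np <- colSums(sub > 0)
    ifelse(np > 0, cs / pmax(np, 1), 0)
  })
  names(pool_mean_cover) <- unique(pool_group)

  res <- list(); truncated <- character(0)
  set.seed(config$seed)
  for (rep_i in seq_len(config$n_replicates)) {
    rows <- list()
    for (k in seq_along(plot_names)) {
      p <- plot_names[k]
      x <- start_rows[k, ]
      resident <- names(x)[x > 0]
      S <- length(resident)
      if (S == 0) next
      r <- min(.round_half_away(config$removal_fraction * S), S)
      g <- .round_half_away(config$addition_fraction * S)
      donors <- setdiff(pool_species[[group_of[k]]], resident)
      if (g > length(donors)) {
        truncated <- unique(c(truncated, p))
        g <- length(donors)
      }
      removed <- if (r > 0) sample(resident, r) else character(0)
      added <- if (g > 0) sample(donors, g) else character(0)
      y <- x
      y[removed] <- 0
      y[added] <- pool_mean_cover[[group_of[k]]][added]
      if (sum(y) > 0) y <- y / sum(y) * 100
      tt <- temporal_turnover(x, y, plot = p)
      tt$replicate <- rep_i
      tt$richness_start <- S
      rows[[p]] <- tt
    }
    res[[rep_i]] <- .rbind_reset(rows)
  }
  per_plot <- .rbind_reset(res)
  comp <- c("jac_total", "jac_replacement", "jac_nestedness",
            "bc_total", "bc_balanced", "bc_gradient")
  summary <- do.call(rbind, lapply(split(per_plot, per_plot$replicate),
    function(d) {
      out <- as.data.frame(as.list(colMeans(d[, comp])))
      out$replicate <- d$replicate[1]
      # a priori turnover-richness relationship within the replicate
      # (undefined when all plots share one richness value)
      if (length(unique(d$richness_start)) >= 2) {
        out$jac_richness_slope <-
          ols_slope(d$richness_start, d$jac_total)$slope
        out$bc_richness_slope <-
          ols_slope(d$richness_start, d$bc_total)$slope
      } else {
        out$jac_richness_slope <- out$bc_richness_slope <- NA_real_
      }
      out
    }))
  rownames(summary) <- NULL
  structure(list(per_plot = per_plot, summary = summary,
                 truncated = truncated, config = config),
            class = "null_result")
}

#' Compare observed turnover with the null-model distribution
#'
#' @param observed per-plot turnover table ([plot_turnover()]`$turnover`)
#'   with a `mean_richness` or start-richness column joined, or the
#'   `design_plot` table from [pipeline_tables()].
#' @param null a [simulate_null()] result on the same plots.
#' @return data.frame, one row per turnover component: observed mean, null
#'   mean, null replicate sd (NA for a single replicate), and the observed
#'   vs null mean slope of turnover against richness.
#' @export
compare_null <- function(observed, null) {
  comp <- c("jac_total", "jac_replacement", "jac_nestedness",
            "bc_total", "bc_balanced", "bc_gradient")
  rich_col <- intersect(c("mean_richness", "richness_start"), names(observed))[1]
  n_rep <- length(unique(null$summary$replicate))
  rows <- lapply(comp, function(m) {
    obs_slope <- if (!is.na(rich_col) && m %in% c("jac_total", "bc_total"))
      ols_slope(observed[[rich_col]], observed[[m]])$slope else NA_real_
    null_slope <- switch(m, jac_total = mean(null$summary$jac_richness_slope),
                         bc_total = mean(null$summary$bc_richness_slope),
                         NA_real_)
    data.frame(
      component = m,
      observed_mean = mean(observed[[m]], na.rm = TRUE),
      null_mean = mean(null$summary[[m]]),
      null_sd = if (n_rep > 1) stats::sd(null$summary[[m]]) else NA_real_,
      observed_richness_slope = obs_slope,
      null_richness_slope = null_slope,
      stringsAsFactors = FALSE)
  })
  .rbind_reset(rows)
}
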