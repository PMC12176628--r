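#' Declare a hierarchical regression model
#'
#' A declarative model description: response, likelihood family, fixed
#' covariates (referring to columns of the assembled design table), random
#' structure, and prior scales. Inflation components (`zi`, `zoi`, `coi`) are
#' intercept-only, matching the usual treatment of boundary mass in
#' proportion-valued diversity metrics.
#'
#' @param response column name of the response.
#' @param family likelihood family, see [loglik()].
#' @param fixed character vector of fixed-term column names (an intercept is
#'   always included).
#' @param random `NULL`, [ranef_intercept()], or [ranef_nested_slopes()].
#' @param level credible level for reported intervals (0.95 default, 0.975
#'   also used in practice).
#' @param priors list with `beta_sd` (normal sd on coefficients), `sd_scale`
#'   (half-normal scale on random-effect sds) and `aux_scale` (half-normal
#'   scale on the family dispersion/precision parameter).
#' @return a `hier_spec` object.
#' @export
hier_spec <- function(response, family, fixed = character(0), random = NULL,
                      level = 0.95, priors = default_priors()) {
  family <- match.arg(family, .families)
  structure(list(response = response, family = family, fixed = fixed,
                 random = random, level = level, priors = priors),
            class = "hier_spec")
}

#' Weakly informative default priors
#'
#' Normal(0, 2.5) on coefficients, half-Normal(0, 2.5) on random-effect and
#' residual standard deviations, half-Normal(0, 20) on the negative-binomial
#' dispersion and beta precision (a precision parameter lives on a larger
#' scale than an sd), Beta(1,1) on inflation probabilities.
#'
#' @return list of prior scales.
#' @export
default_priors <- function() {
  list(beta_sd = 2.5, sd_scale = 2.5, aux_scale = 20)
}

#' Random-effect structure descriptors
#'
#' `ranef_intercept()` declares a random intercept per grouping unit
#' (typically subsite). `ranef_nested_slopes()` declares random intercepts
#' and year-slopes at a grouping level and at a second level nested within it
#' (typically plot within subsite), with independent variance components.
#'
#' @param group column name of the grouping factor.
#' @param nested column name of the nested unit.
#' @param slope_var column whose coefficient varies by group (centred year).
#' @return a `ranef` descriptor.
#' @export
ranef_intercept <- function(group) {
  structure(list(type = "intercept", group = group), class = "ranef")
}

#' @rdname ranef_intercept
#' @export
ranef_nested_slopes <- function(group, nested, slope_var) {
  structure(list(type = "nested_slopes", group = group, nested = nested,
                 slope_var = slope_var), class = "ranef")
}

#' @rdname ranef_intercept
#' @export
ranef_nested_intercepts <- function(group, nested) {
  structure(list(type = "nested_intercepts", group = group, nested = nested),
            class = "ranef")
}

#' Assemble a model-ready design table from pipeline products
#'
#' Joins the pipeline's tidy tables into one row per analysis unit and adds
#' the derived sampling-design covariates: `ln_plot_size` (natural log of
#' plot size in m2), `year_c` (year centred at the table mean), `duration`
#' (last minus first survey year per plot) and `mean_richness` (per-plot mean
#' richness over surveyed years).
#'
#' @param tables named list of pipeline tables; recognized names:
#'   `samples` (plot, year, subsite, study_area, plot_size_m2, latitude),
#'   `states` ([diversity_state()]), `turnover` and `trajectories`
#'   ([plot_turnover()]), `trends` ([metric_trends()]), `fg_change`
#'   ([functional_group_change()]), `climate_change`, `climatology`,
#'   `fcomp` ([functional_composition()]`$by_plot`).
#' @param unit `"plot_year"` (one row per survey), `"plot"` (one row per
#'   plot) — the grain of the model.
#' @param require character vector of column names the caller's model needs;
#'   an informative error names any that cannot be derived.
#' @return a data.frame, one row per analysis unit.
#' @export
assemble_design <- function(tables, unit = c("plot", "plot_year"),
                            require = character(0)) {
  unit <- match.arg(unit)
  samples <- tables$samples
  if (is.null(samples)) stop("assemble_design needs a 'samples' table")

  plot_meta <- unique(samples[, intersect(
    c("plot", "subsite", "study_area", "plot_size_m2", "latitude"),
    names(samples)), drop = FALSE])
  if (anyDuplicated(plot_meta$plot))
    stop("plots with inconsistent metadata across years")

  per_plot <- plot_meta
  if (!is.null(tables$states)) {
    agg <- do.call(rbind, lapply(split(tables$states, tables$states$plot),
      function(d) {
        dl <- d[which.max(d$year), ]
        data.frame(plot = d$plot[1], mean_richness = mean(d$richness),
                   richness_last = dl$richness, pielou_last = dl$pielou,
                   duration = diff(range(d$year)), stringsAsFactors = FALSE)
      }))
    per_plot <- merge(per_plot, agg, by = "plot", all.x = TRUE)
  }
  merge_in <- function(base, tab, by) {
    if (is.null(tab)) return(base)
    merge(base, tab, by = by, all.x = TRUE)
  }
  if (!is.null(tables$trends)) {
    w <- .widen_slopes(tables$trends, suffix = "_change")
    per_plot <- merge_in(per_plot, w, "plot")
  }
  if (!is.null(tables$fg_change)) {
    w <- .widen_slopes(tables$fg_change, suffix = "_change")
    per_plot <- merge_in(per_plot, w, "plot")
  }
  if (!is.null(tables$fcomp)) per_plot <- merge_in(per_plot, tables$fcomp, "plot")
  if (!is.null(tables$turnover))
    per_plot <- merge_in(per_plot,
                         tables$turnover[, setdiff(names(tables$turnover),
                                                   c("year_start", "year_end"))],
                         "plot")
  if (!is.null(tables$trajectories))
    per_plot <- merge_in(per_plot,
                         tables$trajectories[, setdiff(names(tables$trajectories),
                           c("year_start", "year_end", "n_union"))], "plot")
  if (!is.null(tables$climate_change))
    per_plot <- merge_in(per_plot, tables$climate_change, "subsite")
  if (!is.null(tables$climatology))
    per_plot <- merge_in(per_plot, tables$climatology, "subsite")

  out <- if (unit == "plot") {
    per_plot
  } else {
    py <- samples[, intersect(c("plot", "year"), names(samples)), drop = FALSE]
    if (!is.null(tables$states))
      py <- merge(py, tables$states, by = c("plot", "year"), all.x = TRUE)
    merge(py, per_plot[, setdiff(names(per_plot),
                                 intersect(names(per_plot),
                                           setdiff(names(py), "plot"))),
                       drop = FALSE], by = "plot", all.x = TRUE)
  }
  if ("plot_size_m2" %in% names(out)) {
    if (any(out$plot_size_m2 <= 0))
      stop("log of non-positive plot size at plot(s): ",
           paste(utils::head(out$plot[out$plot_size_m2 <= 0]), collapse = ", "))
    out$ln_plot_size <- log(out$plot_size_m2)
  }
  if ("year" %in% names(out)) out$year_c <- out$year - mean(out$year)
  miss <- setdiff(require, names(out))
  if (length(miss) > 0)
    stop("covariate(s) not derivable from the supplied tables: ",
         paste(miss, collapse = ", "))
  rownames(out) <- NULL
  out
}

.widen_slopes <- function(slopes, suffix = "_change") {
  metrics <- unique(slopes$metric)
  out <- data.frame(plot = unique(slopes$unit), stringsAsFactors = FALSE)
  for (m in metrics) {
    d <- slopes[slopes$metric == m, c("unit", "slope")]
    names(d) <- c("plot", paste0(m, suffix))
    out <- merge(out, d, by = "plot", all.x = TRUE)
  }
  out
}

#' Fit a hierarchical model by adaptive MCMC
#'
#' Samples the joint posterior of fixed effects, random effects, variance
#' components and family parameters with an adaptive Metropolis-within-Gibbs
#' sampler (proposal scales tuned to 44% acceptance during warmup, frozen
#' afterwards). Convergence is summarized by split-Rhat over chains.
#'
#' @param spec a [hier_spec()].
#' @param data assembled design table containing the response, the fixed
#'   terms and the grouping columns.
#' @param chains number of chains.
#' @param iter iterations per chain (including warmup).
#' @param warmup warmup iterations per chain.
#' @param thin keep every `thin`-th post-warmup draw.
#' @param seed integer seed; the fit is reproducible given the seed.
#' @param rhat_threshold split-Rhat threshold for the `converged` flag.
#' @return a `hier_fit`: list with `coefficients` (term, estimate, sd, lower,
#'   upper, rhat), `converged`, `draws` (chains x kept x params array),
#'   `unit_effects` (posterior-mean random effects per group level), `spec`,
#'   and `diagnostics`.
#' @export
fit_hmodel <- function(spec, data, chains = 4, iter = 2000,
                       warmup = floor(iter / 2), thin = 1, seed = 1,
                       rhat_threshold = 1.01) {
  stopifnot(inherits(spec, "hier_spec"))
  fixed_vars <- if (length(spec$fixed) > 0)
    all.vars(stats::reformulate(spec$fixed)) else character(0)
  cols <- c(spec$response, fixed_vars)
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0)
    stop("model term(s) missing from data: ", paste(miss, collapse = ", "))
  keep <- stats::complete.cases(data[, cols, drop = FALSE])
  data <- data[keep, , drop = FALSE]
  y <- data[[spec$response]]
  .check_support(spec$family, y)

  X <- if (length(spec$fixed) > 0) {
    stats::model.matrix(stats::reformulate(spec$fixed), data)
  } else {
    matrix(1, nrow = nrow(data), dimnames = list(NULL, "(Intercept)"))
  }

  # random structure -> group index vectors and flags
  g1 <- integer(0); g2 <- integer(0); tvec <- numeric(nrow(data))
  flags <- c(FALSE, FALSE, FALSE, FALSE)
  re <- spec$random
  dropped_random <- FALSE
  if (!is.null(re)) {
    grp <- data[[re$group]]
    if (is.null(grp)) stop("grouping column not in data: ", re$group)
    if (length(unique(grp)) < 2) {
      warning("only one level in grouping '", re$group,
              "'; random term dropped")
      re <- NULL
      dropped_random <- TRUE
    }
  }
  if (!is.null(re)) {
    g1 <- as.integer(factor(data[[re$group]])) - 1L
    if (re$type == "intercept") {
      flags[1] <- TRUE
    } else {
      g2 <- as.integer(factor(paste(data[[re$group]], data[[re$nested]],
                                    sep = "\r"))) - 1L
      if (re$type == "nested_intercepts") {
        flags[c(1, 3)] <- TRUE
      } else {
        flags[1:4] <- TRUE
        tvec <- data[[re$slope_var]]
        if (is.null(tvec)) stop("slope column not in data: ", re$slope_var)
      }
    }
  }

  # initialize the intercept near the link-scale response mean
  init_int <- switch(spec$family,
    gaussian = mean(y),
    negbinomial_log = log(mean(y) + 0.1),
    log(pmin(pmax(mean(y[y > 0 & y < 1], na.rm = TRUE), 0.05), 0.95) /
          (1 - pmin(pmax(mean(y[y > 0 & y < 1], na.rm = TRUE), 0.05), 0.95))))
  beta_init <- c(init_int, rep(0, ncol(X) - 1))
  aux_init <- switch(spec$family,
    gaussian = log(stats::sd(y) + 1e-3),
    negbinomial_log = log(5),
    beta_logit = log(5),
    zi_beta_logit = c(log(5), stats::qlogis(pmin(pmax(mean(y == 0), 0.02), 0.98))),
    zoi_beta_logit = c(log(5),
                       stats::qlogis(pmin(pmax(mean(y == 0 | y == 1), 0.02), 0.98)),
                       stats::qlogis(pmin(pmax(mean(y[y == 0 | y == 1] == 1),
                                               0.02), 0.98))))
  aux_init[!is.finite(aux_init)] <- 0

  sd_names <- c("sd_group_intercept", "sd_group_slope", "sd_nested_intercept",
                "sd_nested_slope")[flags]
  aux_names <- switch(spec$family,
    gaussian = "sigma", negbinomial_log = "shape", beta_logit = "phi",
    zi_beta_logit = c("phi", "zi"), zoi_beta_logit = c("phi", "zoi", "coi"))
  par_names <- c(colnames(X), aux_names, sd_names)

  # QR preconditioning of the fixed-effects block: sampling happens in an
  # orthogonalized basis (decorrelated posterior), coefficients are mapped
  # back through Rinv afterwards
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient fixed-effect design (collinear terms): ",
         paste(colnames(X), collapse = ", "))
  Qm <- qr.Q(qrX); Rm <- qr.R(qrX)
  sgn <- sign(diag(Rm)); sgn[sgn == 0] <- 1
  Qm <- sweep(Qm, 2, sgn, `*`); Rm <- sweep(Rm, 1, sgn, `*`)
  sc <- sqrt(max(nrow(X) - 1, 1))
  Xs <- Qm * sc
  Rs <- Rm / sc
  Rinv <- backsolve(Rs, diag(ncol(X)))
  theta_init <- as.numeric(Rs %*% beta_init)

  runs <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(seed + 1000L * (ch - 1L))
    runs[[ch]] <- .mwg_sample(
      as.numeric(y), Xs, .family_code(spec$family), as.numeric(tvec),
      g1, g2, flags, as.integer(iter), as.integer(warmup), as.integer(thin),
      spec$priors$beta_sd, spec$priors$sd_scale, spec$priors$aux_scale,
      theta_init, aux_init, Rinv)
  }
  draws <- lapply(runs, function(r) {
    d <- r$draws
    # back-transform the fixed-effect block to the coefficient scale
    d[, seq_len(ncol(X))] <- d[, seq_len(ncol(X)), drop = FALSE] %*% t(Rinv)
    colnames(d) <- par_names
    d
  })
  # natural scale for aux parameters
  for (ch in seq_along(draws)) {
    for (nm in aux_names) {
      v <- draws[[ch]][, nm]
      draws[[ch]][, nm] <- if (nm %in% c("zi", "zoi", "coi"))
        stats::plogis(v) else exp(v)
    }
  }
  all_draws <- do.call(rbind, draws)
  alpha <- (1 - spec$level) / 2
  coefs <- data.frame(
    term = par_names,
    estimate = colMeans(all_draws),
    sd = apply(all_draws, 2, stats::sd),
    lower = apply(all_draws, 2, stats::quantile, probs = alpha),
    upper = apply(all_draws, 2, stats::quantile, probs = 1 - alpha),
    rhat = vapply(par_names, function(nm)
      split_rhat(lapply(draws, function(d) d[, nm])), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)

  unit_effects <- NULL
  if (!is.null(re)) {
    lev1 <- levels(factor(data[[re$group]]))
    unit_effects <- list(group = data.frame(
      unit = lev1,
      intercept = Reduce(`+`, lapply(runs, `[[`, "u1_mean")) / chains,
      stringsAsFactors = FALSE))
    if (re$type %in% c("nested_slopes", "nested_intercepts")) {
      lev2 <- levels(factor(paste(data[[re$group]], data[[re$nested]],
                                  sep = "\r")))
      unit_effects$nested <- data.frame(
        unit = sub("^.*\r", "", lev2),
        group = sub("\r.*$", "", lev2),
        intercept = Reduce(`+`, lapply(runs, `[[`, "u2_mean")) / chains,
        stringsAsFactors = FALSE)
      if (re$type == "nested_slopes") {
        unit_effects$group$slope <-
          Reduce(`+`, lapply(runs, `[[`, "u1s_mean")) / chains
        unit_effects$nested$slope <-
          Reduce(`+`, lapply(runs, `[[`, "u2s_mean")) / chains
      }
    }
  }
  rh <- coefs$rhat[is.finite(coefs$rhat)]
  structure(list(
    coefficients = coefs,
    converged = length(rh) == 0 || max(rh) <= rhat_threshold,
    draws = draws,
    unit_effects = unit_effects,
    diagnostics = list(rhat_max = if (length(rh)) max(rh) else NA_real_,
                       accept_beta = mean(vapply(runs, `[[`, numeric(1),
                                                 "accept_beta")),
                       n_obs = nrow(data),
                       dropped_random = dropped_random),
    spec = spec), class = "hier_fit")
}

#' @export
print.hier_fit <- function(x, ...) {
  cat(sprintf("Hierarchical %s model for '%s' (%d obs), %s\n",
              x$spec$family, x$spec$response, x$diagnostics$n_obs,
              if (x$converged) "converged" else "NOT converged"))
  print(format(x$coefficients, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Split-Rhat convergence statistic
#'
#' Potential scale reduction computed after splitting each chain in half,
#' the standard convergence check for MCMC output.
#'
#' @param chains list of numeric vectors, one per chain.
#' @return the split-Rhat value (NA for constant draws).
#' @export
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(v) {
    h <- floor(length(v) / 2)
    list(v[seq_len(h)], v[(h + 1):(2 * h)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W <= 1e-300) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}
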