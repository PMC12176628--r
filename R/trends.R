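#' Ordinary least-squares slope of a metric over calendar year
#'
#' The first step of the two-step change-over-time modelling: one linear
#' model per analysis unit with survey year as the only predictor.
#'
#' @param xs numeric years (>= 2 distinct values).
#' @param ys metric values, same length.
#' @param unit,metric identifiers carried through.
#' @return one-row data.frame `unit, metric, slope, intercept, n_points,
#'   span_years`.
#' @export
ols_slope <- function(xs, ys, unit = NA_character_, metric = NA_character_) {
  keep <- is.finite(xs) & is.finite(ys)
  xs <- xs[keep]; ys <- ys[keep]
  if (length(xs) < 2 || length(unique(xs)) < 2)
    stop("ols_slope needs >= 2 distinct x values (unit ", unit, ", metric ",
         metric, ")")
  xc <- xs - mean(xs)
  slope <- sum(xc * (ys - mean(ys))) / sum(xc^2)
  data.frame(unit = unit, metric = metric,
             slope = slope,
             intercept = mean(ys) - slope * mean(xs),
             n_points = length(xs), span_years = diff(range(xs)),
             stringsAsFactors = FALSE)
}

# grouped closed-form OLS: one slope per level of `g`, computed with
# aggregated sums (no per-group R calls)
.grouped_slopes <- function(g, x, y, metric) {
  keep <- is.finite(x) & is.finite(y)
  g <- g[keep]; x <- x[keep]; y <- y[keep]
  g <- factor(g)
  n <- as.numeric(table(g))
  sx <- tapply(x, g, sum); sy <- tapply(y, g, sum)
  sxx <- tapply(x * x, g, sum); sxy <- tapply(x * y, g, sum)
  span <- tapply(x, g, function(v) diff(range(v)))
  den <- sxx - sx^2 / n
  ok <- n >= 2 & den > 0
  slope <- ifelse(ok, (sxy - sx * sy / n) / den, NA_real_)
  out <- data.frame(unit = levels(g), metric = metric,
                    slope = as.numeric(slope),
                    intercept = as.numeric(sy / n - slope * sx / n),
                    n_points = as.integer(n),
                    span_years = as.numeric(span),
                    stringsAsFactors = FALSE)
  out[ok, , drop = FALSE]
}

#' Per-plot diversity trends
#'
#' Fits one OLS line per plot for richness and (where defined for at least
#' two years) Pielou evenness against survey year.
#'
#' @param states output of [diversity_state()] on a community matrix.
#' @return data.frame of [ols_slope()] rows, metrics `richness` and `pielou`.
#' @export
metric_trends <- function(states) {
  out <- rbind(
    .grouped_slopes(states$plot, states$year, states$richness, "richness"),
    .grouped_slopes(states$plot, states$year, states$pielou, "pielou"))
  rownames(out) <- NULL
  out
}

#' Functional-group cover change per plot
#'
#' Sums relative cover per functional group and year and fits one OLS line
#' per plot and group (percent cover per year). When shrub categories are
#' present, dwarf and erect shrub cover slopes are returned as well.
#'
#' @param mat community matrix (temporal plot set).
#' @param traits named species -> functional group map ([trait_map()]).
#' @param shrub_categories optional named species -> {dwarf, erect, none} map;
#'   taken from [species_traits()] when a survey table is attached.
#' @return data.frame of [ols_slope()] rows; metric is the group name
#'   (`shrub`, `graminoid`, `forb`, and `shrub_dwarf`/`shrub_erect` when
#'   available). Groups absent from a plot in all years get slope 0 and
#'   `absent = TRUE`.
#' @export
functional_group_change <- function(mat, traits, shrub_categories = NULL) {
  s <- sample_info(mat)
  g <- traits[colnames(mat)]
  groups <- list(shrub = g == "shrub", graminoid = g == "graminoid",
                 forb = g == "forb")
  if (!is.null(shrub_categories)) {
    sc <- shrub_categories[colnames(mat)]
    groups$shrub_dwarf <- sc == "dwarf"
    groups$shrub_erect <- sc == "erect"
  }
  multi <- names(which(table(s$plot) >= 2))
  keep <- s$plot %in% multi
  out <- list()
  for (gn in names(groups)) {
    cov <- rowSums(mat[keep, groups[[gn]], drop = FALSE])
    sl <- .grouped_slopes(s$plot[keep], s$year[keep], cov, gn)
    absent <- tapply(cov, factor(s$plot[keep]), function(v) all(v == 0))
    sl$absent <- as.logical(absent[sl$unit])
    sl$slope[sl$absent] <- 0
    sl$intercept[sl$absent] <- 0
    out[[gn]] <- sl
  }
  .rbind_reset(out)
}

#' Read a subsite climate series table
#'
#' @param path delimited text with columns `subsite, year, mtwq_c, precip_mm`.
#' @param sep field separator.
#' @return a validated climate series data.frame.
#' @export
read_climate_series <- function(path, sep = ",") {
  d <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  as_climate_series(d)
}

#' @rdname read_climate_series
#' @param df in-memory data.frame with the same columns.
#' @export
as_climate_series <- function(df) {
  need <- c("subsite", "year", "mtwq_c", "precip_mm")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("climate series missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(paste(df$subsite, df$year)))
    stop("duplicate subsite-year rows in climate series")
  df[order(df$subsite, df$year), , drop = FALSE]
}

#' Climate change slopes per subsite
#'
#' OLS slopes of yearly mean temperature of the warmest quarter (MTWQ) and
#' annual precipitation over the climate window, one line per subsite.
#' Because coordinates exist only at the subsite level, every plot of a
#' subsite inherits the same change values; the downstream hierarchical
#' models account for this with a subsite random effect.
#'
#' @param series climate series ([as_climate_series()]).
#' @param window two-element year range to fit over (default 1979-2013).
#' @return data.frame (subsite, temp_change_c_yr, precip_change_mm_yr,
#'   n_years).
#' @export
climate_change <- function(series, window = c(1979, 2013)) {
  series <- series[series$year >= window[1] & series$year <= window[2], ]
  out <- lapply(split(series, series$subsite), function(d) {
    data.frame(subsite = d$subsite[1],
               temp_change_c_yr = ols_slope(d$year, d$mtwq_c)$slope,
               precip_change_mm_yr = ols_slope(d$year, d$precip_mm)$slope,
               n_years = nrow(d), stringsAsFactors = FALSE)
  })
  .rbind_reset(out)
}

#' Subsite climatologies (means over the climate window)
#'
#' @inheritParams climate_change
#' @return data.frame (subsite, mtwq_clim_c, precip_clim_mm).
#' @export
climatology <- function(series, window = c(1979, 2013)) {
  series <- series[series$year >= window[1] & series$year <= window[2], ]
  out <- lapply(split(series, series$subsite), function(d)
    data.frame(subsite = d$subsite[1], mtwq_clim_c = mean(d$mtwq_c),
               precip_clim_mm = mean(d$precip_mm), stringsAsFactors = FALSE))
  .rbind_reset(out)
}

#' Trailing 5-year temperature per survey time point
#'
#' For each plot-year, the mean MTWQ over the survey year and the four
#' preceding years, then centred within subsite across all of that subsite's
#' plot-year rows (so magnitudes are comparable across regions).
#'
#' @param series climate series.
#' @param surveys data.frame (plot, subsite, year) of survey time points.
#' @param window_years length of the trailing window (default 5, including
#'   the survey year itself).
#' @return data.frame (plot, subsite, year, mean5, centered5).
#' @export
trailing_mean_temp <- function(series, surveys, window_years = 5) {
  key <- split(series$mtwq_c, series$subsite)
  yrs <- split(series$year, series$subsite)
  mean5 <- vapply(seq_len(nrow(surveys)), function(i) {
    ss <- surveys$subsite[i]
    want <- (surveys$year[i] - window_years + 1):surveys$year[i]
    if (is.null(key[[ss]])) stop("no climate series for subsite ", ss)
    hit <- match(want, yrs[[ss]])
    if (anyNA(hit))
      stop("climate series for subsite ", ss, " misses year(s) ",
           paste(want[is.na(hit)], collapse = ", "))
    mean(key[[ss]][hit])
  }, numeric(1))
  out <- data.frame(plot = surveys$plot, subsite = surveys$subsite,
                    year = surveys$year, mean5 = mean5,
                    stringsAsFactors = FALSE)
  ctr <- stats::ave(out$mean5, out$subsite, FUN = function(v) v - mean(v))
  out$centered5 <- ctr
  out
}
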