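#' Read a long-format vegetation survey table
#'
#' Parses a delimited text file of plot-level species cover records collected
#' in the usual monitoring hierarchy (plots nested in subsites nested in study
#' areas) and validates it into a `survey_table`. One row is one
#' species x plot x year observation in the survey method's native unit:
#' percent cover, point-frame hit counts (with a `total_points` column), or a
#' cover-class label (in a `cover_class` column).
#'
#' @param path path to a delimited text file with a header row.
#' @param schema optional named character vector mapping canonical column
#'   names (names of the vector) to the file's column names (values), e.g.
#'   `c(cover_raw = "abundance")`. Canonical columns not mentioned are assumed
#'   to carry their canonical name in the file.
#' @param sep field separator, comma by default.
#' @return A `survey_table`: a `data.frame` with canonical columns
#'   `study_area, subsite, plot, year, species, functional_group,
#'   shrub_category, cover_raw, method, plot_size_m2, latitude, longitude,
#'   treatment` and optionally `total_points` and `cover_class`, plus a
#'   `validation_log` attribute recording coercions.
#' @seealso [as_survey_table()] for in-memory data frames,
#'   [apply_retention_filters()], [harmonize_cover()].
#' @export
read_survey_table <- function(path, schema = NULL, sep = ",") {
  if (!file.exists(path)) stop("survey file not found: ", path)
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (!is.null(schema)) {
    miss <- setdiff(unname(schema), names(raw))
    if (length(miss) > 0)
      stop("schema maps to columns absent from the file: ",
           paste(miss, collapse = ", "))
    for (canon in names(schema)) {
      names(raw)[names(raw) == schema[[canon]]] <- canon
    }
  }
  as_survey_table(raw)
}

.required_cols <- c("study_area", "subsite", "plot", "year", "species",
                    "functional_group", "shrub_category", "cover_raw",
                    "method", "plot_size_m2", "latitude", "longitude",
                    "treatment")

#' Validate a data frame of cover records into a survey table
#'
#' @param df a data.frame carrying the canonical columns of
#'   [read_survey_table()].
#' @return a validated `survey_table` with a `validation_log` attribute.
#' @export
as_survey_table <- function(df) {
  miss <- setdiff(.required_cols, names(df))
  if (length(miss) > 0)
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  log <- character(0)

  df$year <- .coerce_numeric(df, "year", integer = TRUE)
  for (col in c("plot_size_m2", "latitude", "longitude")) {
    df[[col]] <- .coerce_numeric(df, col)
  }
  # cover_raw may legitimately be NA for cover-class rows carrying a label
  cc_rows <- df$method == "cover_class" & "cover_class" %in% names(df) &
    !is.na(df[["cover_class"]] %||% NA)
  cov <- suppressWarnings(as.numeric(df$cover_raw))
  bad <- which(is.na(cov) & !is.na(df$cover_raw) & !cc_rows)
  if (length(bad) > 0)
    stop("non-numeric cover at row(s): ", paste(utils::head(bad, 10), collapse = ", "),
         " (value(s): ", paste(utils::head(df$cover_raw[bad], 3), collapse = ", "), ")")
  if (!identical(df$cover_raw, cov)) log <- c(log, "cover_raw coerced to numeric")
  df$cover_raw <- cov

  bad_m <- setdiff(unique(df$method), .methods_known)
  if (length(bad_m) > 0)
    stop("unknown survey method(s): ", paste(bad_m, collapse = ", "),
         "; accepted: ", paste(.methods_known, collapse = ", "))
  if (any(df$cover_raw < 0, na.rm = TRUE)) stop("negative cover_raw values")
  if (any(!is.finite(df$plot_size_m2) | df$plot_size_m2 <= 0))
    stop("plot_size_m2 must be positive")

  pf <- df$method %in% .point_frame_methods
  if (any(pf) && !"total_points" %in% names(df))
    stop("point-frame records present but no total_points column")
  if (any(pf)) {
    df$total_points <- .coerce_numeric(df, "total_points")
    if (any(!is.finite(df$total_points[pf]) | df$total_points[pf] <= 0))
      stop("point-frame rows need total_points > 0")
  }

  key <- paste(df$study_area, df$subsite, df$plot, df$year, df$species, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf(
      "duplicate record for (study_area=%s, subsite=%s, plot=%s, year=%s, species=%s)",
      d$study_area, d$subsite, d$plot, d$year, d$species))
  }
  sc_bad <- (df$functional_group == "shrub" & df$shrub_category == "none") |
    (df$functional_group != "shrub" & df$shrub_category != "none")
  if (any(sc_bad))
    stop("shrub_category must be dwarf/erect for shrubs and 'none' otherwise (",
         sum(sc_bad), " offending rows)")
  bad_fg <- setdiff(unique(df$functional_group), .functional_groups)
  if (length(bad_fg) > 0)
    stop("unknown functional group(s): ", paste(bad_fg, collapse = ", "))

  structure(df, class = c("survey_table", "data.frame"), validation_log = log)
}

.coerce_numeric <- function(df, col, integer = FALSE) {
  v <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(v) & !is.na(df[[col]]))
  if (length(bad) > 0)
    stop("non-numeric ", col, " at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  if (integer) as.integer(round(v)) else v
}

#' Default retention-filter rules
#'
#' The standard inclusion rules for circumarctic resurvey syntheses: ambient
#' (control) plots only, north of 60 degrees latitude (strictly), surveyed
#' area at most 1 m2, and — for the temporal subset — at least two survey
#' years spanning at least 5 years with a consistent method and plot size
#' throughout.
#'
#' @param control_treatments treatment labels considered ambient/control.
#' @param min_latitude latitude threshold in degrees N (exclusive).
#' @param max_plot_size_m2 maximum surveyed area in m2 (inclusive).
#' @param min_surveys minimum number of survey years for the temporal set.
#' @param min_span_years minimum last-minus-first year span (inclusive).
#' @param require_consistent_method drop plots whose survey method or plot
#'   size changes across years from the temporal set.
#' @param plot_size_exactly_1 sensitivity switch restricting to 1 m2 plots.
#' @return a named list of rules for [apply_retention_filters()].
#' @export
retention_rules <- function(control_treatments = c("CTL", "control", "ambient"),
                            min_latitude = 60,
                            max_plot_size_m2 = 1,
                            min_surveys = 2,
                            min_span_years = 5,
                            require_consistent_method = TRUE,
                            plot_size_exactly_1 = FALSE) {
  list(control_treatments = control_treatments,
       min_latitude = min_latitude,
       max_plot_size_m2 = max_plot_size_m2,
       min_surveys = min_surveys,
       min_span_years = min_span_years,
       require_consistent_method = require_consistent_method,
       plot_size_exactly_1 = plot_size_exactly_1)
}

#' Apply spatial and temporal retention filters
#'
#' Splits a survey table into the spatial analysis set (all plots passing the
#' static rules) and the temporal analysis set (additionally resurveyed at
#' least twice over the minimum span, with consistent method and plot size).
#' Plots are the unit of retention: a plot is kept or dropped whole.
#'
#' @param table a `survey_table`.
#' @param rules a rule list from [retention_rules()].
#' @return a list with elements `spatial` (survey_table), `temporal`
#'   (survey_table) and `report` (a `retention_report`: per-rule plot
#'   exclusion counts, attributed to the first failing rule in the order
#'   control, latitude, plot size, [exact size], survey count, span,
#'   consistency).
#' @export
apply_retention_filters <- function(table, rules = retention_rules()) {
  stopifnot(inherits(table, "survey_table"))
  per_plot <- .plot_summary(table)
  n_input <- nrow(per_plot)

  fail <- list(
    not_control = !(per_plot$treatment %in% rules$control_treatments),
    latitude    = !(per_plot$latitude > rules$min_latitude),
    plot_size   = !(per_plot$max_size <= rules$max_plot_size_m2)
  )
  if (isTRUE(rules$plot_size_exactly_1))
    fail$plot_size_not_1 <- !(per_plot$max_size == 1 & per_plot$min_size == 1)

  spatial_fail <- Reduce(`|`, fail)
  fail_t <- c(fail, list(
    too_few_surveys = per_plot$n_years < rules$min_surveys,
    short_span      = per_plot$span < rules$min_span_years
  ))
  if (isTRUE(rules$require_consistent_method))
    fail_t$inconsistent_sampling <- !per_plot$consistent
  temporal_fail <- Reduce(`|`, fail_t)

  spatial_plots  <- per_plot$plot[!spatial_fail]
  temporal_plots <- per_plot$plot[!temporal_fail]
  # attribute each excluded plot to its first failing rule
  count_first <- function(fl) {
    remaining <- rep(TRUE, n_input)
    out <- integer(length(fl)); names(out) <- names(fl)
    for (r in names(fl)) {
      hit <- remaining & fl[[r]]
      out[r] <- sum(hit)
      remaining <- remaining & !hit
    }
    out
  }
  report <- structure(list(
    n_input = n_input,
    n_retained_spatial = length(spatial_plots),
    n_retained_temporal = length(temporal_plots),
    spatial_exclusions = count_first(fail),
    temporal_exclusions = count_first(fail_t)
  ), class = "retention_report")

  spat <- table[table$plot %in% spatial_plots, , drop = FALSE]
  temp <- table[table$plot %in% temporal_plots, , drop = FALSE]
  if (nrow(spat) == 0) warning("no plots retained in the spatial set")
  if (nrow(temp) == 0) warning("no plots retained in the temporal set")
  list(spatial = .restamp(spat), temporal = .restamp(temp), report = report)
}

.restamp <- function(df) {
  rownames(df) <- NULL
  structure(as.data.frame(df), class = c("survey_table", "data.frame"))
}

.plot_summary <- function(table) {
  g <- factor(table$plot)
  first <- !duplicated(g)
  nuniq <- function(v) tapply(v, g, function(x) length(unique(x)))
  n_years <- nuniq(table$year)
  data.frame(
    plot = levels(g),
    study_area = table$study_area[first][order(g[first])],
    subsite = table$subsite[first][order(g[first])],
    treatment = table$treatment[first][order(g[first])],
    latitude = table$latitude[first][order(g[first])],
    min_size = as.numeric(tapply(table$plot_size_m2, g, min)),
    max_size = as.numeric(tapply(table$plot_size_m2, g, max)),
    n_years = as.integer(n_years),
    span = as.numeric(tapply(table$year, g, function(v) diff(range(v)))),
    consistent = as.logical(nuniq(table$method) == 1 &
                              nuniq(table$plot_size_m2) == 1),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.retention_report <- function(x, ...) {
  cat("Retention report\n")
  cat(sprintf("  plots in: %d | spatial set: %d (%.1f%%) | temporal set: %d (%.1f%%)\n",
              x$n_input, x$n_retained_spatial,
              100 * x$n_retained_spatial / max(1, x$n_input),
              x$n_retained_temporal,
              100 * x$n_retained_temporal / max(1, x$n_input)))
  cat("  spatial exclusions: ",
      paste(sprintf("%s=%d", names(x$spatial_exclusions), x$spatial_exclusions),
            collapse = ", "), "\n")
  cat("  temporal exclusions:",
      paste(sprintf("%s=%d", names(x$temporal_exclusions), x$temporal_exclusions),
            collapse = ", "), "\n")
  invisible(x)
}

#' Conventional cover-class midpoints
#'
#' Midpoints (percent cover) for the Braun-Blanquet-style class labels, used
#' to convert cover-class records to an absolute cover scale before
#' relativization. The subsequent relativization removes most of the scale
#' arbitrariness of any particular midpoint convention.
#'
#' @return named numeric vector of percent-cover midpoints.
#' @export
cover_class_midpoints <- function() {
  c("r" = 0.1, "+" = 0.5, "1" = 2.5, "2" = 15, "3" = 37.5, "4" = 62.5,
    "5" = 87.5)
}

#' Harmonize survey records of one plot-year to relative cover
#'
#' Converts each method's native unit to an absolute percent-cover scale
#' (percent cover used directly; point-frame hits divided by total points;
#' cover classes mapped through their midpoints) and then relativizes so the
#' vascular-plant covers of the plot-year sum to 100.
#'
#' @param records a `survey_table` subset holding exactly one plot-year (all
#'   rows share one method).
#' @param midpoints named midpoint map for cover-class labels.
#' @return named numeric vector of relative covers (percent) by species; an
#'   all-zero plot-year returns an empty vector with attribute `empty = TRUE`.
#' @export
harmonize_cover <- function(records, midpoints = cover_class_midpoints()) {
  if (nrow(records) == 0) return(structure(numeric(0), empty = TRUE))
  meth <- unique(records$method)
  if (length(meth) > 1)
    stop("records of one plot-year mix survey methods: ",
         paste(meth, collapse = ", "))
  abs_cover <- switch(
    meth,
    percent_cover = records$cover_raw,
    cover_class = {
      lab <- as.character(records$cover_class %||% records$cover_raw)
      unknown <- setdiff(lab, names(midpoints))
      if (length(unknown) > 0)
        stop("unknown cover-class label(s): ", paste(unknown, collapse = ", "),
             "; accepted: ", paste(names(midpoints), collapse = ", "))
      unname(midpoints[lab])
    },
    # any point-frame variant: hits / total points
    records$cover_raw / records$total_points * 100
  )
  tot <- sum(abs_cover)
  if (tot <= 0) {
    return(structure(setNames(numeric(nrow(records)), records$species),
                     empty = TRUE))
  }
  setNames(abs_cover / tot * 100, records$species)
}

#' Build a plot-year x species community matrix of relative cover
#'
#' Applies [harmonize_cover()] to every plot-year of a survey table and
#' assembles the rows into a wide community matrix (samples x species, values
#' are relative cover in percent, each non-empty row summing to 100).
#'
#' @param table a `survey_table`.
#' @param midpoints cover-class midpoint map.
#' @return a numeric matrix with one row per plot-year (rownames
#'   `"plot@year"`) and a `samples` attribute: a data.frame with columns
#'   `plot, year, subsite, study_area, plot_size_m2, latitude, method`.
#' @export
community_matrix <- function(table, midpoints = cover_class_midpoints()) {
  stopifnot(inherits(table, "survey_table"))
  species <- sort(unique(table$species))
  key <- paste(table$plot, table$year, sep = "@")

  # vectorized harmonization (same conversion rules as harmonize_cover)
  mixed <- tapply(table$method, key, function(m) length(unique(m)))
  if (any(mixed > 1))
    stop("records of one plot-year mix survey methods: ",
         names(mixed)[mixed > 1][1])
  abs_cover <- table$cover_raw
  pf <- table$method %in% .point_frame_methods
  abs_cover[pf] <- table$cover_raw[pf] / table$total_points[pf] * 100
  cc <- table$method == "cover_class"
  if (any(cc)) {
    lab <- as.character((table$cover_class %||% table$cover_raw)[cc])
    unknown <- setdiff(lab, names(midpoints))
    if (length(unknown) > 0)
      stop("unknown cover-class label(s): ", paste(unknown, collapse = ", "),
           "; accepted: ", paste(names(midpoints), collapse = ", "))
    abs_cover[cc] <- unname(midpoints[lab])
  }

  rows <- sort(unique(key))
  mat <- matrix(0, nrow = length(rows), ncol = length(species),
                dimnames = list(rows, species))
  mat[cbind(match(key, rows), match(table$species, species))] <- abs_cover
  tot <- rowSums(mat)
  nz <- tot > 0
  mat[nz, ] <- mat[nz, , drop = FALSE] / tot[nz] * 100

  first <- !duplicated(key)
  samples <- data.frame(
    plot = table$plot[first], year = table$year[first],
    subsite = table$subsite[first], study_area = table$study_area[first],
    plot_size_m2 = table$plot_size_m2[first],
    latitude = table$latitude[first], method = table$method[first],
    stringsAsFactors = FALSE)
  samples <- samples[match(rows, key[first]), , drop = FALSE]
  ord <- order(samples$plot, samples$year)
  mat <- mat[ord, , drop = FALSE]
  samples <- samples[ord, , drop = FALSE]
  rownames(samples) <- rownames(mat)
  attr(mat, "samples") <- samples
  mat
}

#' Sample metadata of a community matrix
#' @param mat a matrix from [community_matrix()].
#' @return the `samples` data.frame (plot, year, subsite, ...).
#' @export
sample_info <- function(mat) {
  s <- attr(mat, "samples")
  if (is.null(s)) stop("matrix lacks a 'samples' attribute; build it with community_matrix()")
  s
}

#' Functional-group composition per plot-year and per plot
#'
#' Sums relative cover within the three vascular functional groups (shrub,
#' graminoid, forb) for every plot-year, and averages those percentages over
#' each plot's surveyed years (unweighted).
#'
#' @param mat community matrix from [community_matrix()].
#' @param traits named character vector mapping species to functional group.
#' @return list with `by_year` (plot, year, shrub_pct, graminoid_pct,
#'   forb_pct) and `by_plot` (plot, shrub_pct, graminoid_pct, forb_pct —
#'   means over years).
#' @export
functional_composition <- function(mat, traits) {
  unmapped <- setdiff(colnames(mat), names(traits))
  if (length(unmapped) > 0)
    stop("species without a functional group: ",
         paste(utils::head(unmapped, 10), collapse = ", "))
  g <- traits[colnames(mat)]
  bad <- setdiff(unique(g), .functional_groups)
  if (length(bad) > 0)
    stop("unknown functional group(s) in traits: ", paste(bad, collapse = ", "))
  sums <- sapply(.functional_groups, function(grp)
    rowSums(mat[, g == grp, drop = FALSE]))
  if (nrow(mat) == 1) sums <- matrix(sums, nrow = 1,
                                     dimnames = list(rownames(mat), .functional_groups))
  s <- sample_info(mat)
  by_year <- data.frame(plot = s$plot, year = s$year,
                        shrub_pct = sums[, "shrub"],
                        graminoid_pct = sums[, "graminoid"],
                        forb_pct = sums[, "forb"],
                        row.names = NULL, stringsAsFactors = FALSE)
  by_plot <- do.call(rbind, lapply(split(by_year, by_year$plot), function(d)
    data.frame(plot = d$plot[1], shrub_pct = mean(d$shrub_pct),
               graminoid_pct = mean(d$graminoid_pct),
               forb_pct = mean(d$forb_pct), stringsAsFactors = FALSE)))
  rownames(by_plot) <- NULL
  list(by_year = by_year, by_plot = by_plot)
}

#' Extract the species trait map carried by a survey table
#'
#' @param table a `survey_table`.
#' @return a data.frame (species, functional_group, shrub_category), one row
#'   per species; inconsistent group assignments across records are an error.
#' @export
species_traits <- function(table) {
  d <- unique(data.frame(species = table$species,
                         functional_group = table$functional_group,
                         shrub_category = table$shrub_category,
                         stringsAsFactors = FALSE))
  if (anyDuplicated(d$species)) {
    dup <- d$species[duplicated(d$species)]
    stop("species with inconsistent trait assignments: ",
         paste(unique(dup), collapse = ", "))
  }
  rownames(d) <- NULL
  d
}

#' @rdname species_traits
#' @return `trait_map()`: a named character vector species -> functional group.
#' @export
trait_map <- function(table) {
  d <- species_traits(table)
  setNames(d$functional_group, d$species)
}
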