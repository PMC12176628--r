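# In-code fixtures: small survey tables and random community rows used
# across the test files.

toy_record <- function(plot = "p1", year = 2000, species = "sp1",
                       fg = "forb", cover = 50, method = "percent_cover",
                       subsite = "s1", study_area = "a1", size = 1,
                       lat = 70, treatment = "CTL", shrub_category = NULL) {
  data.frame(study_area = study_area, subsite = subsite, plot = plot,
             year = year, species = species, functional_group = fg,
             shrub_category = shrub_category %||%
               ifelse(fg == "shrub", "dwarf", "none"),
             cover_raw = cover, method = method, plot_size_m2 = size,
             latitude = lat, longitude = -105, treatment = treatment,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_survey <- function(rows) as_survey_table(do.call(rbind, rows))

# a small two-year, two-plot survey with known composition
two_year_survey <- function() {
  toy_survey(list(
    toy_record("p1", 2000, "sp1", "shrub", 40),
    toy_record("p1", 2000, "sp2", "graminoid", 40),
    toy_record("p1", 2000, "sp3", "forb", 20),
    toy_record("p1", 2006, "sp1", "shrub", 30),
    toy_record("p1", 2006, "sp2", "graminoid", 50),
    toy_record("p1", 2006, "sp4", "forb", 20),
    toy_record("p2", 2000, "sp1", "shrub", 100, subsite = "s1"),
    toy_record("p2", 2006, "sp1", "shrub", 60),
    toy_record("p2", 2006, "sp2", "graminoid", 40)))
}

# random relative-cover row over a fixed species universe
random_row <- function(n_species = 12, p_present = 0.6,
                       universe = sprintf("sp%02d", seq_len(n_species))) {
  x <- setNames(numeric(length(universe)), universe)
  pres <- runif(length(universe)) < p_present
  x[pres] <- rlnorm(sum(pres))
  if (sum(x) > 0) x <- x / sum(x) * 100
  x
}

small_sim <- function(seed = 1, ...) {
  generate_synthetic(scenario("paper_like", n_study_areas = 4,
                              subsites_per_area = 2, plots_per_subsite = 4,
                              seed = seed, ...))
}
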