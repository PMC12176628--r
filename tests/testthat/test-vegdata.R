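test_that("survey CSV round-trips through read_survey_table, with schema mapping", {
  df <- do.call(rbind, list(
    toy_record("p1", 2000, "sp1", "forb", 60),
    toy_record("p1", 2000, "sp2", "graminoid", 40),
    toy_record("p2", 2000, "sp1", "forb", 100)))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  tab <- read_survey_table(f)
  expect_s3_class(tab, "survey_table")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$cover_raw, c(60, 40, 100))

  # renamed abundance column via schema
  df2 <- df
  names(df2)[names(df2) == "cover_raw"] <- "abundance"
  write.csv(df2, f, row.names = FALSE)
  expect_error(read_survey_table(f), "cover_raw")
  tab2 <- read_survey_table(f, schema = c(cover_raw = "abundance"))
  expect_equal(tab2$cover_raw, tab$cover_raw)
})

test_that("duplicate keys and non-numeric covers are rejected with context", {
  dup <- rbind(toy_record("p1", 2000, "sp1"), toy_record("p1", 2000, "sp1"))
  expect_error(as_survey_table(dup), "duplicate record.*p1.*sp1")
  bad <- toy_record("p1", 2000, "sp1")
  bad$cover_raw <- "abc"
  expect_error(as_survey_table(bad), "non-numeric cover.*1")
  expect_error(as_survey_table(toy_record()[, -3]), "missing required")
  wrongcat <- toy_record(fg = "forb", shrub_category = "dwarf")
  expect_error(as_survey_table(wrongcat), "shrub_category")
})

test_that("retention filters split plots into spatial and temporal sets", {
  rows <- list(
    # passes everything (span 6 years)
    toy_record("pA", 2000, "sp1"), toy_record("pA", 2006, "sp1"),
    # south of the Arctic boundary
    toy_record("pB", 2000, "sp1", lat = 55), toy_record("pB", 2006, "sp1", lat = 55),
    # exactly on the 60 degree boundary: excluded (strict >)
    toy_record("pC", 2000, "sp1", lat = 60), toy_record("pC", 2006, "sp1", lat = 60),
    # 4-year span only -> spatial only
    toy_record("pD", 1999, "sp1"), toy_record("pD", 2003, "sp1"),
    # single survey -> spatial only
    toy_record("pE", 2000, "sp1"),
    # experimental treatment
    toy_record("pF", 2000, "sp1", treatment = "OTC"),
    toy_record("pF", 2006, "sp1", treatment = "OTC"),
    # too large a plot
    toy_record("pG", 2000, "sp1", size = 4), toy_record("pG", 2006, "sp1", size = 4))
  ret <- apply_retention_filters(toy_survey(rows))
  expect_setequal(unique(ret$spatial$plot), c("pA", "pD", "pE"))
  expect_equal(unique(ret$temporal$plot), "pA")
  rep <- ret$report
  expect_equal(rep$n_input, 7)
  expect_equal(rep$n_retained_spatial, 3)
  expect_equal(rep$n_retained_temporal, 1)
  # exclusions account exactly for the dropped plots
  expect_equal(sum(rep$spatial_exclusions), rep$n_input - rep$n_retained_spatial)
  expect_equal(sum(rep$temporal_exclusions), rep$n_input - rep$n_retained_temporal)
  expect_lte(rep$n_retained_temporal, rep$n_retained_spatial)
})

test_that("six-plot toy table with two failures per rule reports (2,2,2)", {
  rows <- list(
    toy_record("q1", 2000, "sp1", treatment = "OTC"),
    toy_record("q2", 2000, "sp1", treatment = "warmed"),
    toy_record("q3", 2000, "sp1", lat = 58),
    toy_record("q4", 2000, "sp1", lat = 59.9),
    toy_record("q5", 2000, "sp1", size = 2),
    toy_record("q6", 2000, "sp1", size = 1.5))
  ret <- suppressWarnings(apply_retention_filters(toy_survey(rows)))
  ex <- ret$report$spatial_exclusions
  expect_equal(unname(ex[c("not_control", "latitude", "plot_size")]),
               c(2L, 2L, 2L))
  expect_equal(ret$report$n_retained_spatial, 0)
})

test_that("a plot whose method or size changes over time leaves the temporal set", {
  rows <- list(
    toy_record("p1", 2000, "sp1", size = 1),
    toy_record("p1", 2006, "sp1", size = 0.5),
    toy_record("p2", 2000, "sp1"), toy_record("p2", 2006, "sp1"))
  ret <- apply_retention_filters(toy_survey(rows))
  expect_setequal(unique(ret$spatial$plot), c("p1", "p2"))
  expect_equal(unique(ret$temporal$plot), "p2")
  expect_equal(unname(ret$report$temporal_exclusions["inconsistent_sampling"]), 1L)
})

test_that("harmonization converts each method to relative cover summing to 100", {
  pc <- toy_survey(list(toy_record("p1", 2000, "A", cover = 50),
                        toy_record("p1", 2000, "B", cover = 30),
                        toy_record("p1", 2000, "C", cover = 20)))
  expect_equal(unname(harmonize_cover(pc)[c("A", "B", "C")]), c(50, 30, 20))

  pf <- do.call(rbind, list(
    toy_record("p1", 2000, "A", cover = 25, method = "point_frame_top"),
    toy_record("p1", 2000, "B", cover = 25, method = "point_frame_top")))
  pf$total_points <- 100
  row <- harmonize_cover(as_survey_table(pf))
  expect_equal(unname(row[c("A", "B")]), c(50, 50))

  cc <- do.call(rbind, list(toy_record("p1", 2000, "A", method = "cover_class"),
                            toy_record("p1", 2000, "B", method = "cover_class")))
  cc$cover_raw <- NA_real_
  cc$cover_class <- c("2", "4")
  row <- harmonize_cover(as_survey_table(cc))
  expect_equal(unname(row[c("A", "B")]),
               c(15 / 77.5 * 100, 62.5 / 77.5 * 100), tolerance = 1e-10)

  cc$cover_class <- c("2", "9")
  expect_error(harmonize_cover(as_survey_table(cc)), "unknown cover-class.*9")

  pf$cover_raw <- c(0, 0)
  empty <- harmonize_cover(as_survey_table(pf))
  expect_true(isTRUE(attr(empty, "empty")))
  expect_equal(sum(empty), 0)
})

test_that("relativization is idempotent and rows always sum to 100", {
  set.seed(42)
  for (i in 1:20) {
    x <- random_row()
    x <- x[x > 0]
    if (length(x) == 0) next
    recs <- toy_survey(lapply(names(x), function(sp)
      toy_record("p1", 2000, sp, cover = unname(x[sp]))))
    h1 <- harmonize_cover(recs)
    expect_equal(sum(h1), 100, tolerance = 1e-6)
    recs2 <- toy_survey(lapply(names(h1), function(sp)
      toy_record("p1", 2000, sp, cover = unname(h1[sp]))))
    expect_equal(harmonize_cover(recs2), h1, tolerance = 1e-12)
  }
})

test_that("retention outcome is order-independent and idempotent", {
  sim <- small_sim(seed = 3)
  tab <- sim$survey
  ret <- apply_retention_filters(tab)
  # re-filtering the retained set changes nothing
  ret2 <- apply_retention_filters(ret$spatial)
  expect_setequal(unique(ret2$spatial$plot), unique(ret$spatial$plot))
  # intersecting independent single-rule applications reproduces the set
  one_rule <- function(rules) unique(
    apply_retention_filters(tab, rules)$spatial$plot)
  r_all <- retention_rules()
  loose <- retention_rules(control_treatments = unique(tab$treatment),
                           min_latitude = -90, max_plot_size_m2 = Inf)
  by_rule <- Reduce(intersect, list(
    one_rule(modifyList(loose, list(control_treatments = r_all$control_treatments))),
    one_rule(modifyList(loose, list(min_latitude = 60))),
    one_rule(modifyList(loose, list(max_plot_size_m2 = 1)))))
  expect_setequal(by_rule, unique(ret$spatial$plot))
})

test_that("functional composition sums to 100 and averages across years", {
  one <- toy_survey(list(toy_record("p1", 2000, "sp1", "shrub", 100)))
  m <- community_matrix(one)
  fc <- functional_composition(m, trait_map(one))
  expect_equal(unlist(fc$by_year[, c("shrub_pct", "graminoid_pct", "forb_pct")],
                      use.names = FALSE), c(100, 0, 0))

  sv <- two_year_survey()
  m <- community_matrix(sv)
  fc <- functional_composition(m, trait_map(sv))
  y1 <- fc$by_year[fc$by_year$plot == "p1" & fc$by_year$year == 2000, ]
  expect_equal(unlist(y1[, c("shrub_pct", "graminoid_pct", "forb_pct")],
                      use.names = FALSE), c(40, 40, 20))
  # plot means are unweighted over years: (40,40,20) and (30,50,20)
  p1 <- fc$by_plot[fc$by_plot$plot == "p1", ]
  expect_equal(unlist(p1[, c("shrub_pct", "graminoid_pct", "forb_pct")],
                      use.names = FALSE), c(35, 45, 20))
  # triple sums to 100 wherever the row does
  sums <- rowSums(fc$by_year[, c("shrub_pct", "graminoid_pct", "forb_pct")])
  expect_equal(sums, rep(100, length(sums)), tolerance = 1e-6)

  expect_error(functional_composition(m, c(sp1 = "shrub")), "without a functional group")
})
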