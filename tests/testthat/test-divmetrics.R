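test_that("richness, Shannon and Pielou follow their definitions", {
  even <- c(A = 50, B = 50)
  d <- diversity_state(even)
  expect_equal(d$richness, 2L)
  expect_equal(d$pielou, 1.0)

  mono <- c(A = 100)
  d <- diversity_state(mono)
  expect_equal(d$richness, 1L)
  expect_equal(d$shannon, 0)
  expect_true(is.na(d$pielou))

  skew <- c(A = 70, B = 20, C = 10)
  d <- diversity_state(skew)
  expect_equal(d$shannon, 0.8018, tolerance = 1e-4)
  expect_equal(d$pielou, 0.7298, tolerance = 1e-4)

  empty <- c(A = 0, B = 0)
  d <- diversity_state(empty)
  expect_equal(d$richness, 0L)
  expect_equal(d$shannon, 0)
  expect_true(is.na(d$pielou))
})

test_that("turnover partition reproduces hand-computed cases", {
  x <- c(A = 30, B = 30, C = 40)
  tt <- temporal_turnover(x, x)
  expect_equal(tt$jac_total, 0)
  expect_equal(tt$bc_total, 0)

  # one-for-one substitution: pure replacement
  y <- c(A = 30, B = 30, D = 40)
  tt <- temporal_turnover(x, y)
  expect_equal(c(tt$a, tt$b, tt$c), c(2, 1, 1))
  expect_equal(tt$jac_total, 0.5)
  expect_equal(tt$jac_replacement, 0.5)
  expect_equal(tt$jac_nestedness, 0)

  # halving both covers: pure abundance gradient
  tt <- temporal_turnover(c(A = 10, B = 10), c(A = 5, B = 5))
  expect_equal(tt$bc_total, 1 / 3)
  expect_equal(tt$bc_balanced, 0)
  expect_equal(tt$bc_gradient, 1 / 3)

  # swapping abundances: pure balanced variation
  tt <- temporal_turnover(c(A = 6, B = 2), c(A = 2, B = 6))
  expect_equal(tt$bc_total, 0.5)
  expect_equal(tt$bc_balanced, 0.5)
  expect_equal(tt$bc_gradient, 0)
})

test_that("species trajectories split the union into lost/gained/persisting", {
  x <- c(A = 30, B = 30, C = 40)
  y <- c(A = 30, B = 30, D = 40)
  tr <- trajectories(x, y)
  expect_equal(c(tr$n_lost, tr$n_gained, tr$n_persisting), c(1, 1, 2))
  expect_equal(c(tr$prop_lost, tr$prop_gained, tr$prop_persisting),
               c(0.25, 0.25, 0.5))

  expect_equal(trajectories(x, x)$prop_persisting, 1)
  disj <- trajectories(c(A = 50, B = 50), c(C = 60, D = 40))
  expect_equal(disj$prop_persisting, 0)
  expect_equal(disj$prop_lost + disj$prop_gained, 1)

  none <- trajectories(c(A = 0), c(A = 0))
  expect_true(none$degenerate)
  expect_true(is.na(none$prop_lost))
})

test_that("partition identities and brute-force oracles hold on random pairs", {
  set.seed(101)
  for (i in 1:1000) {
    x <- random_row(10)
    y <- random_row(10)
    tt <- temporal_turnover(x, y)
    tr <- trajectories(x, y)
    expect_equal(tt$jac_total, tt$jac_replacement + tt$jac_nestedness,
                 tolerance = 1e-12)
    expect_equal(tt$bc_total, tt$bc_balanced + tt$bc_gradient,
                 tolerance = 1e-12)
    expect_true(tt$jac_replacement <= tt$jac_total + 1e-15)
    expect_true(tt$bc_balanced <= tt$bc_total + 1e-15)
    # brute-force set arithmetic for Jaccard
    sx <- names(x)[x > 0]; sy <- names(y)[y > 0]
    if (length(union(sx, sy)) > 0) {
      expect_equal(tt$jac_total,
                   1 - length(intersect(sx, sy)) / length(union(sx, sy)),
                   tolerance = 1e-12)
      # trajectory proportions partition the Jaccard index
      expect_equal(tr$prop_lost + tr$prop_gained, tt$jac_total,
                   tolerance = 1e-12)
      expect_equal(tr$prop_persisting, 1 - tt$jac_total, tolerance = 1e-12)
    }
    # direct-summation Bray-Curtis
    if (sum(x) + sum(y) > 0)
      expect_equal(tt$bc_total, sum(abs(x - y)) / sum(x + y),
                   tolerance = 1e-12)
    # permutation invariance of the species universe
    perm <- sample(names(x))
    tt2 <- temporal_turnover(x[perm], y[perm])
    expect_equal(tt2[, -(1:3)], tt[, -(1:3)], tolerance = 1e-12)
  }
})

test_that("plot_turnover compares first and last survey only", {
  sv <- toy_survey(list(
    toy_record("p1", 2000, "A", cover = 50), toy_record("p1", 2000, "B", cover = 50),
    toy_record("p1", 2003, "C", cover = 100),  # intermediate year ignored
    toy_record("p1", 2006, "A", cover = 50), toy_record("p1", 2006, "B", cover = 50)))
  pt <- plot_turnover(community_matrix(sv))
  expect_equal(pt$turnover$jac_total, 0)
  expect_equal(pt$turnover$year_start, 2000)
  expect_equal(pt$turnover$year_end, 2006)
  expect_equal(pt$trajectories$n_persisting, 2)
})

test_that("pooled two-proportion z test matches the closed form", {
  r <- two_proportion_z(20, 100, 20, 100)
  expect_equal(r$z, 0)
  expect_equal(r$p, 1)
  r <- two_proportion_z(30, 100, 10, 100)
  expect_equal(r$z, 3.5355, tolerance = 1e-4)
  expect_lt(r$p, 0.001)
  r <- two_proportion_z(0, 10, 0, 10)
  expect_true(r$degenerate)
  expect_equal(r$p, 1)
  # agrees with the uncorrected base-R test on a non-trivial case
  pt <- prop.test(c(17, 9), c(60, 45), correct = FALSE)
  expect_equal(two_proportion_z(17, 60, 9, 45)$z^2,
               unname(pt$statistic), tolerance = 1e-10)
})

test_that("species loss table tabulates per-species loss percentages", {
  traj <- data.frame(
    plot = c("p1", "p1", "p2", "p2", "p3", "p3"),
    species = c("A", "B", "A", "B", "A", "C"),
    trajectory = c("lost", "persisting", "lost", "lost", "persisting",
                   "persisting"),
    stringsAsFactors = FALSE)
  spatial <- toy_survey(list(
    toy_record("p1", 2000, "A"), toy_record("p2", 2000, "A"),
    toy_record("p3", 2000, "A", study_area = "a2", subsite = "s9"),
    toy_record("p1", 2000, "B"), toy_record("p2", 2000, "B"),
    toy_record("p3", 2000, "C", study_area = "a2", subsite = "s9")))
  tab <- species_loss_rarity(traj, spatial)
  a <- tab[tab$species == "A", ]
  expect_equal(a$pct_lost, 100 * 2 / 3)
  expect_equal(a$n_study_areas, 2L)
  expect_equal(tab$pct_lost[tab$species == "C"], 0)
  expect_equal(tab$pct_lost[tab$species == "B"], 50)
})

test_that("vectorized per-plot turnover equals the pairwise computation", {
  sim <- small_sim(seed = 29)
  tb <- pipeline_tables(sim$survey, sim$climate)
  mat <- tb$community_temporal
  s <- sample_info(mat)
  pt <- plot_turnover(mat)
  for (p in sample(pt$turnover$plot, 10)) {
    i <- which(s$plot == p)
    i0 <- i[which.min(s$year[i])]; i1 <- i[which.max(s$year[i])]
    ref <- temporal_turnover(mat[i0, ], mat[i1, ])
    row <- pt$turnover[pt$turnover$plot == p, ]
    for (col in c("a", "b", "c", "jac_total", "jac_replacement",
                  "bc_total", "bc_balanced"))
      expect_equal(row[[col]], ref[[col]], tolerance = 1e-12)
  }
})
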