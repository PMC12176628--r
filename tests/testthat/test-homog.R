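make_ord <- function(coords, labels = NULL) {
  coords <- as.matrix(coords)
  rownames(coords) <- labels %||% sprintf("r%d", seq_len(nrow(coords)))
  structure(list(coordinates = coords,
                 neg_coordinates = matrix(0, nrow(coords), 0),
                 eigenvalues = rep(1, ncol(coords)), negative_inertia = 0,
                 labels = rownames(coords)),
            class = "ordination")
}

test_that("subsite aggregation takes unweighted means with implicit zeros", {
  sv <- toy_survey(list(
    toy_record("p1", 2000, "A", cover = 40), toy_record("p1", 2000, "B", cover = 60),
    toy_record("p1", 2006, "A", cover = 100),
    toy_record("p2", 2000, "A", cover = 100),
    toy_record("p2", 2006, "B", cover = 100)))
  prof <- aggregate_subsites(community_matrix(sv))
  # start: plot1 {A40,B60}, plot2 {A100,B0} -> mean {A70, B30}
  expect_equal(unname(prof["s1#start", c("A", "B")]), c(70, 30))
  expect_equal(unname(prof["s1#end", c("A", "B")]), c(50, 50))

  single <- toy_survey(list(toy_record("p1", 2000, "A", cover = 30),
                            toy_record("p1", 2000, "B", cover = 70),
                            toy_record("p1", 2006, "A", cover = 30),
                            toy_record("p1", 2006, "B", cover = 70)))
  m <- community_matrix(single)
  prof <- aggregate_subsites(m)
  expect_equal(unname(prof["s1#start", ]), unname(m[1, ]))
  expect_equal(unname(prof["s1#start", ]), unname(prof["s1#end", ]))
})

test_that("dissimilarity metrics match hand-computed values", {
  prof <- rbind(p = c(A = 10, B = 0), q = c(A = 0, B = 10))
  expect_equal(dissimilarity(prof, "manhattan")["p", "q"], 20)
  expect_equal(dissimilarity(prof, "euclidean")["p", "q"], sqrt(200),
               tolerance = 1e-6)

  pres <- rbind(x = c(A = 1, B = 1, C = 1, D = 0),
                y = c(A = 1, B = 1, C = 0, D = 1))
  expect_equal(dissimilarity(pres, "jaccard")["x", "y"], 0.5)
  expect_equal(dissimilarity(pres, "sorensen")["x", "y"], 1 / 3,
               tolerance = 1e-12)

  # modified Gower: t(v) = log2(v)+1 for v>0 else 0; double zeros excluded
  mg <- rbind(x = c(A = 4, B = 0, C = 0), y = c(A = 1, B = 2, C = 0))
  # |t(4)-t(1)| = |3-1| = 2 ; |t(0)-t(2)| = |0-2| = 2 ; C excluded -> mean 2
  expect_equal(dissimilarity(mg, "modified_gower")["x", "y"], 2,
               tolerance = 1e-12)

  for (m in c("jaccard", "sorensen", "braycurtis", "modified_gower",
              "manhattan", "euclidean")) {
    same <- rbind(a = c(A = 5, B = 5), b = c(A = 5, B = 5))
    expect_equal(unname(dissimilarity(same, m)["a", "b"]), 0,
                 tolerance = 1e-12)
  }
})

test_that("Sorensen never exceeds Jaccard on presence-absence profiles", {
  set.seed(8)
  prof <- matrix(rbinom(10 * 15, 1, 0.5), nrow = 10,
                 dimnames = list(NULL, sprintf("sp%d", 1:15)))
  prof <- prof[rowSums(prof) > 0, ]
  dj <- dissimilarity(prof, "jaccard")
  ds <- dissimilarity(prof, "sorensen")
  expect_true(all(ds <= dj + 1e-12))
})

test_that("PCoA reproduces the two-point case and Euclidean embeddings", {
  D <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("u", "v"), c("u", "v")))
  ord <- pcoa_ordination(D)
  expect_equal(unname(sort(ord$coordinates[, 1])), c(-1, 1))
  expect_equal(ord$eigenvalues[1], 2)

  Z <- matrix(0, 3, 3)
  expect_equal(pcoa_ordination(Z)$eigenvalues, rep(0, 3))
  expect_equal(ncol(pcoa_ordination(Z)$coordinates), 0)

  # planted 2-D configuration: coordinate distances reproduce the input
  set.seed(4)
  pts <- matrix(rnorm(14), ncol = 2)
  D <- as.matrix(dist(pts))
  ord <- pcoa_ordination(D)
  expect_lt(max(abs(as.matrix(dist(ord$coordinates)) - D)), 1e-8)
  expect_equal(ord$negative_inertia, 0)
  # agrees with the classical-scaling reference implementation
  ref <- cmdscale(D, k = 2, eig = TRUE)
  expect_equal(sort(ord$eigenvalues, decreasing = TRUE)[1:2], ref$eig[1:2],
               tolerance = 1e-8)

  expect_error(pcoa_ordination(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("dispersion distances and the one-way ANOVA follow the construction", {
  # axis-1 scores +1/-1 in each group: centroids at 0, all distances 1
  ord <- make_ord(cbind(c(1, -1, 1, -1)))
  disp <- dispersion(ord, c("a", "a", "b", "b"))
  expect_equal(disp$distances$distance, rep(1, 4))
  expect_true(disp$degenerate)

  # constructed 2-D groups with distances (1,2,3) and (2,3,4) -> F = 1.5
  g1 <- rbind(c(1, 0), c(2, 0), c(-3, 0))
  th <- acos(0.25)
  g2 <- rbind(c(2, 0), 3 * c(cos(th), sin(th)),
              -(c(2, 0) + 3 * c(cos(th), sin(th))))
  ord <- make_ord(rbind(g1, g2))
  disp <- dispersion(ord, rep(c("s", "e"), each = 3))
  expect_equal(sort(disp$distances$distance[1:3]), c(1, 2, 3), tolerance = 1e-8)
  expect_equal(sort(disp$distances$distance[4:6]), c(2, 3, 4), tolerance = 1e-8)
  expect_equal(disp$anova$F, 1.5, tolerance = 1e-8)

  expect_error(dispersion(ord, c("a", rep("b", 5))), "at least two")
})

test_that("dispersion agrees with the independent reference implementation", {
  set.seed(12)
  comm <- matrix(rpois(12 * 20, 3), nrow = 12)
  groups <- rep(c("start", "end"), each = 6)
  D <- dissimilarity(comm, "braycurtis")  # non-Euclidean: negative axes occur
  ord <- pcoa_ordination(D)
  disp <- dispersion(ord, groups)
  ref <- vegan::betadisper(as.dist(D), groups, type = "centroid")
  expect_equal(disp$distances$distance, unname(ref$distances),
               tolerance = 1e-6)
  ref_aov <- anova(ref)
  expect_equal(disp$anova$F, ref_aov$`F value`[1], tolerance = 1e-6)
  expect_equal(disp$anova$p, ref_aov$`Pr(>F)`[1], tolerance = 1e-6)
})

test_that("Cartesian shifts use the first two axes", {
  ord <- make_ord(rbind(c(0, 0), c(3, 4), c(1, 2), c(4, 6)),
                  labels = c("s1#start", "s1#end", "s2#start", "s2#end"))
  meta <- data.frame(subsite = c("s1", "s1", "s2", "s2"),
                     time_point = c("start", "end", "start", "end"))
  sh <- eq_shift(ord, meta)
  expect_equal(sh$shift[sh$subsite == "s1"], 5)
  expect_equal(sh$shift[sh$subsite == "s2"], 5)

  same <- make_ord(rbind(c(1, 1), c(1, 1)), labels = c("s1#start", "s1#end"))
  meta1 <- data.frame(subsite = "s1", time_point = c("start", "end"))
  expect_equal(eq_shift(same, meta1)$shift, 0)
})

test_that("dispersion statistics are invariant to axis sign flips and label order", {
  set.seed(3)
  comm <- matrix(rpois(10 * 14, 4), nrow = 10)
  rownames(comm) <- sprintf("s%d#%s", rep(1:5, each = 2),
                            rep(c("start", "end"), 5))
  groups <- rep(c("start", "end"), 5)
  D <- dissimilarity(comm, "braycurtis")
  ord <- pcoa_ordination(D)
  d1 <- dispersion(ord, groups)
  # sign-flip every axis: distances unchanged
  ord2 <- ord
  ord2$coordinates <- -ord2$coordinates
  ord2$neg_coordinates <- -ord2$neg_coordinates
  d2 <- dispersion(ord2, groups)
  expect_equal(d1$distances$distance, d2$distances$distance, tolerance = 1e-10)
  # permuting profiles: same multiset of distances and same F
  perm <- sample(nrow(comm))
  ordp <- pcoa_ordination(dissimilarity(comm[perm, ], "braycurtis"))
  dp <- dispersion(ordp, groups[perm])
  expect_equal(sort(dp$distances$distance), sort(d1$distances$distance),
               tolerance = 1e-8)
  expect_equal(dp$anova$F, d1$anova$F, tolerance = 1e-8)
})

test_that("the homogenization report summarizes constructed scenarios correctly", {
  sim <- generate_synthetic(scenario("null_change", seed = 2))
  tb <- suppressWarnings(pipeline_tables(sim$survey, sim$climate))
  hr <- homogenization_report(tb$community_temporal)
  expect_equal(hr$summary$delta_mean, c(0, 0), tolerance = 1e-10)
  expect_equal(hr$summary$shift_mean, c(0, 0), tolerance = 1e-10)

  sim <- generate_synthetic(scenario("homogenizing", seed = 2))
  tb <- suppressWarnings(pipeline_tables(sim$survey, sim$climate))
  hr <- homogenization_report(tb$community_temporal)
  expect_true(all(hr$summary$delta_mean < 0))

  sim <- generate_synthetic(scenario("differentiating", seed = 2))
  tb <- suppressWarnings(pipeline_tables(sim$survey, sim$climate))
  hr <- homogenization_report(tb$community_temporal)
  expect_true(all(hr$summary$delta_mean > 0))
})
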