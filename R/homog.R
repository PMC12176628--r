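#' Aggregate temporal plots to subsite start/end composition profiles
#'
#' For every subsite with at least one temporally retained plot, the mean
#' relative cover per species across the subsite's plots at their baseline
#' surveys ("start") and at their final surveys ("end"). Species absent from
#' a plot contribute zero to the mean; start and end years are per-plot
#' baselines/finals, so a profile can mix calendar years.
#'
#' @param mat community matrix of the temporal plot set.
#' @return a numeric matrix of profiles x species, rownames
#'   `"subsite#start"` / `"subsite#end"`, with a `profiles` attribute
#'   (data.frame subsite, time_point).
#' @export
aggregate_subsites <- function(mat) {
  s <- sample_info(mat)
  plots <- split(seq_len(nrow(mat)), s$plot)
  multi <- names(plots)[vapply(plots, length, 1L) >= 2]
  if (length(multi) == 0) stop("no plot has two survey years")
  rows <- list()
  for (p in multi) {
    i <- plots[[p]]
    yrs <- s$year[i]
    rows[[p]] <- list(subsite = s$subsite[i[1]],
                      start = mat[i[which.min(yrs)], ],
                      end = mat[i[which.max(yrs)], ])
  }
  subs <- vapply(rows, `[[`, character(1), "subsite")
  out <- list(); info <- list()
  for (ss in unique(subs)) {
    members <- rows[subs == ss]
    for (tp in c("start", "end")) {
      prof <- colMeans(do.call(rbind, lapply(members, `[[`, tp)))
      key <- paste0(ss, "#", tp)
      out[[key]] <- prof
      info[[key]] <- data.frame(subsite = ss, time_point = tp,
                                n_plots = length(members),
                                stringsAsFactors = FALSE)
    }
  }
  profiles <- do.call(rbind, out)
  meta <- do.call(rbind, info)
  rownames(meta) <- rownames(profiles)
  attr(profiles, "profiles") <- meta
  profiles
}

.dissim_metrics <- c("jaccard", "sorensen", "braycurtis", "modified_gower",
                     "manhattan", "euclidean")

#' Pairwise dissimilarity between composition profiles
#'
#' Six beta-diversity metrics with varying emphasis on presence-absence
#' versus abundance: Jaccard and Sørensen on presence-absence, Bray-Curtis
#' on covers, Manhattan and Euclidean on raw cover differences, and the
#' modified Gower measure — mean absolute difference of `log2(cover)+1`
#' (zeros kept at zero) over species present in at least one of the pair.
#' Computed with `vegan::vegdist` (with `vegan::decostand`'s log
#' transformation for the modified Gower).
#'
#' @param profiles matrix of profiles x species ([aggregate_subsites()] or
#'   any non-negative matrix).
#' @param metric one of `jaccard, sorensen, braycurtis, modified_gower,
#'   manhattan, euclidean`.
#' @return a symmetric `dissim_matrix` (base matrix with `metric` attribute,
#'   zero diagonal).
#' @export
dissimilarity <- function(profiles, metric = .dissim_metrics) {
  metric <- match.arg(metric)
  if (nrow(profiles) < 2) stop("need at least two profiles")
  if (any(profiles < 0)) stop("profiles must be non-negative")
  d <- switch(metric,
    jaccard = vegan::vegdist(profiles, "jaccard", binary = TRUE),
    sorensen = vegan::vegdist(profiles, "bray", binary = TRUE),
    braycurtis = vegan::vegdist(profiles, "bray"),
    manhattan = vegan::vegdist(profiles, "manhattan"),
    euclidean = vegan::vegdist(profiles, "euclidean"),
    modified_gower = vegan::vegdist(
      vegan::decostand(profiles, "log", logbase = 2), "altGower"))
  m <- as.matrix(d)
  m[!is.finite(m)] <- 0  # all-zero profile pairs: undefined ratio -> 0
  dimnames(m) <- list(rownames(profiles), rownames(profiles))
  structure(m, metric = metric, class = c("dissim_matrix", class(m)))
}

#' Principal coordinates analysis (metric multidimensional scaling)
#'
#' Gower double-centering of the squared dissimilarities,
#' `B = -1/2 J (D*D) J` with `J = I - 11'/n`, followed by
#' eigendecomposition. Scores on axis k are `v_k * sqrt(lambda_k)` for
#' positive eigenvalues; negative eigenvalues (possible for non-Euclidean
#' dissimilarities) are retained unconverted, with their axes kept separately
#' for the dispersion computation.
#'
#' @param D a symmetric dissimilarity matrix (e.g. from [dissimilarity()]).
#' @return an `ordination`: list with `coordinates` (n x k scores on
#'   positive axes, ordered by descending eigenvalue), `neg_coordinates`
#'   (scores `v * sqrt(-lambda)` on negative axes), `eigenvalues` (all,
#'   descending), `negative_inertia` (sum of negative eigenvalues) and
#'   `labels`.
#' @export
pcoa_ordination <- function(D) {
  D <- unclass(as.matrix(D))
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("dissimilarity matrix is not symmetric")
  n <- nrow(D)
  if (is.null(rownames(D)))
    dimnames(D) <- list(sprintf("p%d", 1:n), sprintf("p%d", 1:n))
  A <- -0.5 * D^2
  B <- A - rowMeans(A) - rep(colMeans(A), each = n) + mean(A)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  lam <- e$values
  tol <- max(abs(lam)) * 1e-9
  pos <- which(lam > tol)
  neg <- which(lam < -tol)
  coords <- if (length(pos) > 0)
    sweep(e$vectors[, pos, drop = FALSE], 2, sqrt(lam[pos]), `*`)
  else matrix(0, n, 0)
  negc <- if (length(neg) > 0)
    sweep(e$vectors[, neg, drop = FALSE], 2, sqrt(-lam[neg]), `*`)
  else matrix(0, n, 0)
  rownames(coords) <- rownames(negc) <- rownames(D)
  structure(list(coordinates = coords, neg_coordinates = negc,
                 eigenvalues = lam, negative_inertia = sum(lam[neg]),
                 labels = rownames(D), metric = attr(D, "metric")),
            class = "ordination")
}

#' Multivariate dispersion: distances to group centroids plus ANOVA
#'
#' Distance of each profile to its group's centroid in the full principal
#' coordinate space: squared coordinate differences accumulate positively on
#' positive axes and negatively on negative axes, floored at zero before the
#' square root (the standard homogeneity-of-dispersions treatment of
#' non-Euclidean ordinations). Group means are compared with a one-way
#' ANOVA.
#'
#' @param ord an [pcoa_ordination()] result.
#' @param groups factor/character of group membership (e.g. start/end), one
#'   per profile; each group needs n >= 2.
#' @return list with `distances` (data.frame label, group, distance),
#'   `group_means`, `anova` (F, p, df) and `degenerate` (TRUE when all
#'   distances coincide so F is undefined).
#' @export
dispersion <- function(ord, groups) {
  stopifnot(inherits(ord, "ordination"))
  groups <- as.character(groups)
  if (length(groups) != nrow(ord$coordinates))
    stop("one group label per profile required")
  if (any(table(groups) < 2)) stop("each group needs at least two profiles")
  dist_sq <- numeric(length(groups))
  for (g in unique(groups)) {
    i <- which(groups == g)
    cpos <- colMeans(ord$coordinates[i, , drop = FALSE])
    cneg <- colMeans(ord$neg_coordinates[i, , drop = FALSE])
    dpos <- sweep(ord$coordinates[i, , drop = FALSE], 2, cpos)
    dneg <- sweep(ord$neg_coordinates[i, , drop = FALSE], 2, cneg)
    dist_sq[i] <- rowSums(dpos^2) - rowSums(dneg^2)
  }
  d <- sqrt(pmax(dist_sq, 0))
  out <- data.frame(label = ord$labels, group = groups, distance = d,
                    stringsAsFactors = FALSE)
  degenerate <- stats::var(d) < 1e-24
  if (degenerate) {
    an <- list(F = NA_real_, p = NA_real_)
  } else {
    fit <- stats::aov(distance ~ group, data = out)
    s <- summary(fit)[[1]]
    an <- list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1],
               df = s[["Df"]])
  }
  gm <- tapply(out$distance, out$group, mean)
  gs <- tapply(out$distance, out$group, stats::sd)
  list(distances = out,
       group_means = data.frame(group = names(gm), mean = as.numeric(gm),
                                sd = as.numeric(gs), stringsAsFactors = FALSE),
       anova = an, degenerate = degenerate)
}

#' Cartesian shift of each subsite between time points in ordination space
#'
#' Euclidean distance between a subsite's start and end positions on the
#' first two positive principal axes:
#' `shift = sqrt((x2-x1)^2 + (y2-y1)^2)`, with x/y the first/second axis
#' scores, subscript 2 the final time point.
#'
#' @param ord ordination of the joint start+end profiles
#'   ([aggregate_subsites()] then [pcoa_ordination()]).
#' @param profiles_meta data.frame (subsite, time_point) matching the
#'   ordination rows; taken from the `profiles` attribute when `ord` was
#'   built from [aggregate_subsites()] output.
#' @return data.frame (subsite, x1, y1, x2, y2, shift, shift_full) where
#'   `shift_full` uses all positive axes.
#' @export
eq_shift <- function(ord, profiles_meta) {
  stopifnot(inherits(ord, "ordination"))
  k <- ncol(ord$coordinates)
  if (k < 2)
    warning("fewer than two positive axes; shift computed on available axes")
  use <- seq_len(min(2, k))
  out <- list()
  for (ss in unique(profiles_meta$subsite)) {
    i1 <- which(profiles_meta$subsite == ss & profiles_meta$time_point == "start")
    i2 <- which(profiles_meta$subsite == ss & profiles_meta$time_point == "end")
    if (length(i1) != 1 || length(i2) != 1)
      stop("subsite ", ss, " lacks a start or end profile in the ordination")
    p1 <- ord$coordinates[i1, use]; p2 <- ord$coordinates[i2, use]
    p1 <- c(p1, 0)[1:2]; p2 <- c(p2, 0)[1:2]
    full <- sqrt(sum((ord$coordinates[i2, ] - ord$coordinates[i1, ])^2))
    out[[ss]] <- data.frame(subsite = ss, x1 = p1[1], y1 = p1[2],
                            x2 = p2[1], y2 = p2[2],
                            shift = sqrt(sum((p2 - p1)^2)),
                            shift_full = full, stringsAsFactors = FALSE)
  }
  .rbind_reset(out)
}

#' Subsite-level homogenization analysis across dissimilarity metrics
#'
#' For each metric: joint PCoA of all start and end subsite profiles,
#' distance-to-centroid dispersion with a start-versus-end ANOVA, and the
#' per-subsite Cartesian shift on the first two axes. A decrease in mean
#' distance to centroid from start to end indicates compositional
#' homogenization; an increase, differentiation.
#'
#' @param mat community matrix of the temporal plot set.
#' @param metrics dissimilarity metrics to analyse.
#' @return a `homog_report`: list with `summary` (one row per metric: mean
#'   and sd of start/end centroid distances, their difference, ANOVA F and
#'   p, mean and sd shift) and `detail` (per-metric list with the
#'   dissimilarity matrix, ordination, dispersion and shift tables, and the
#'   per-subsite change in distance to centroid `delta_dist` for second-stage
#'   models).
#' @export
homogenization_report <- function(mat, metrics = c("jaccard", "braycurtis")) {
  profiles <- aggregate_subsites(mat)
  meta <- attr(profiles, "profiles")
  detail <- list(); rows <- list()
  for (m in metrics) {
    D <- dissimilarity(profiles, m)
    ord <- pcoa_ordination(D)
    disp <- dispersion(ord, meta$time_point)
    shifts <- eq_shift(ord, meta)
    dd <- merge(
      stats::setNames(disp$distances[disp$distances$group == "start",
                                     c("label", "distance")],
                      c("label", "dist_start")),
      data.frame(label = sub("#end$", "#start",
                             disp$distances$label[disp$distances$group == "end"]),
                 dist_end = disp$distances$distance[disp$distances$group == "end"]),
      by = "label")
    dd$subsite <- sub("#start$", "", dd$label)
    dd$delta_dist <- dd$dist_end - dd$dist_start
    gm <- disp$group_means
    st <- gm[gm$group == "start", ]; en <- gm[gm$group == "end", ]
    rows[[m]] <- data.frame(
      metric = m, start_mean = st$mean, start_sd = st$sd,
      end_mean = en$mean, end_sd = en$sd,
      delta_mean = en$mean - st$mean,
      anova_F = disp$anova$F, anova_p = disp$anova$p,
      shift_mean = mean(shifts$shift), shift_sd = stats::sd(shifts$shift),
      stringsAsFactors = FALSE)
    detail[[m]] <- list(dissimilarity = D, ordination = ord,
                        dispersion = disp, shifts = shifts,
                        delta_dist = dd[, c("subsite", "dist_start",
                                            "dist_end", "delta_dist")])
  }
  structure(list(summary = .rbind_reset(rows), detail = detail),
            class = "homog_report")
}

#' @export
print.homog_report <- function(x, ...) {
  cat("Homogenization report (distance to centroid, start vs end)\n")
  print(format(x$summary, digits = 3), row.names = FALSE)
  invisible(x)
}
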