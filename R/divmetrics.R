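#' Plot-level diversity state: richness, Shannon index, Pielou evenness
#'
#' Richness is the number of species with cover > 0 in the plot-year, the
#' Shannon index is computed in nats on relative-cover proportions, and
#' Pielou evenness is J = H / log(S). J is undefined (NA) for S <= 1.
#'
#' @param mat community matrix ([community_matrix()]), or a single named
#'   relative-cover row.
#' @return data.frame with columns `plot, year, richness, shannon, pielou`
#'   (plot/year absent when a bare vector is given).
#' @export
diversity_state <- function(mat) {
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1, dimnames = list("row", names(mat)))
  S <- rowSums(mat > 0)
  H <- apply(mat, 1, function(x) {
    p <- x[x > 0] / 100
    if (length(p) == 0) 0 else -sum(p * log(p))
  })
  J <- ifelse(S > 1, H / log(S), NA_real_)
  out <- data.frame(richness = as.integer(S), shannon = H, pielou = J,
                    row.names = NULL)
  s <- attr(mat, "samples")
  if (!is.null(s)) out <- cbind(s[, c("plot", "year")], out)
  rownames(out) <- NULL
  out
}

#' Partition temporal turnover between two surveys of one plot
#'
#' Compares a plot's baseline and final relative-cover rows and partitions
#' compositional dissimilarity in two families. On presence-absence, the
#' Jaccard index is split into a replacement (species-substitution) component
#' and a nestedness-resultant (richness-difference) component; on relative
#' covers, the Bray-Curtis index is split into balanced variation in
#' abundance and an abundance-gradient component. With a = shared species,
#' b = species lost, c = species gained:
#' \deqn{jac_{tot} = (b+c)/(a+b+c), \quad
#'       jac_{repl} = 2\min(b,c)/(a+2\min(b,c))}
#' and with A = sum of pairwise minima, B/C = start/end surpluses:
#' \deqn{bc_{tot} = (B+C)/(2A+B+C), \quad
#'       bc_{bal} = \min(B,C)/(A+\min(B,C)).}
#' The nestedness/gradient components are the differences to the totals.
#'
#' @param row_start,row_end named numeric vectors of relative cover sharing a
#'   species universe (species absent from a row are 0).
#' @param plot optional plot identifier carried through.
#' @param year_start,year_end optional calendar years carried through.
#' @return one-row data.frame with `a, b, c, n_union`, Jaccard components
#'   (`jac_total, jac_replacement, jac_nestedness`) and Bray-Curtis
#'   components (`bc_total, bc_balanced, bc_gradient`). Degenerate all-empty
#'   comparisons give all components 0.
#' @references Baselga-type partition of beta diversity into replacement and
#'   nestedness (presence-absence) and balanced-variation and gradient
#'   (abundance) components.
#' @export
temporal_turnover <- function(row_start, row_end, plot = NA_character_,
                              year_start = NA_integer_, year_end = NA_integer_) {
  u <- union(names(row_start), names(row_end))
  x <- setNames(numeric(length(u)), u); x[names(row_start)] <- row_start
  y <- setNames(numeric(length(u)), u); y[names(row_end)] <- row_end
  px <- x > 0; py <- y > 0
  a <- sum(px & py); b <- sum(px & !py); c <- sum(!px & py)

  jt <- if (a + b + c > 0) (b + c) / (a + b + c) else 0
  m <- min(b, c)
  jr <- if (a + 2 * m > 0) 2 * m / (a + 2 * m) else 0
  jn <- jt - jr

  A <- sum(pmin(x, y)); B <- sum(x - pmin(x, y)); C <- sum(y - pmin(x, y))
  bt <- if (2 * A + B + C > 0) (B + C) / (2 * A + B + C) else 0
  mb <- min(B, C)
  bb <- if (A + mb > 0) mb / (A + mb) else 0
  bg <- bt - bb

  data.frame(plot = plot, year_start = year_start, year_end = year_end,
             a = a, b = b, c = c, n_union = a + b + c,
             jac_total = jt, jac_replacement = jr, jac_nestedness = jn,
             bc_total = bt, bc_balanced = bb, bc_gradient = bg,
             stringsAsFactors = FALSE)
}

#' Classify species trajectories between two surveys of one plot
#'
#' Species present at baseline but absent at the final survey are "lost",
#' present only at the final survey "gained", present at both "persisting".
#' Proportions divide each count by the plot's union richness across the two
#' time points, so that prop_lost + prop_gained equals the total Jaccard
#' dissimilarity and prop_persisting its complement.
#'
#' @inheritParams temporal_turnover
#' @return one-row data.frame with counts `n_lost, n_gained, n_persisting`
#'   and proportions `prop_lost, prop_gained, prop_persisting` (NA, flagged
#'   `degenerate`, when both rows are empty).
#' @export
trajectories <- function(row_start, row_end, plot = NA_character_,
                         year_start = NA_integer_, year_end = NA_integer_) {
  s0 <- names(row_start)[row_start > 0]
  s1 <- names(row_end)[row_end > 0]
  lost <- setdiff(s0, s1); gained <- setdiff(s1, s0); pers <- intersect(s0, s1)
  n_union <- length(lost) + length(gained) + length(pers)
  degenerate <- n_union == 0
  den <- if (degenerate) NA_real_ else n_union
  data.frame(plot = plot, year_start = year_start, year_end = year_end,
             n_lost = length(lost), n_gained = length(gained),
             n_persisting = length(pers), n_union = n_union,
             prop_lost = length(lost) / den,
             prop_gained = length(gained) / den,
             prop_persisting = length(pers) / den,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Per-plot turnover partitions and trajectories, first vs last survey
#'
#' For every plot with at least two survey years in the community matrix,
#' compares the baseline (first) and final (last) rows; intermediate surveys
#' are ignored at this stage.
#'
#' @param mat community matrix from [community_matrix()].
#' @return list with `turnover` (one row per plot, [temporal_turnover()]
#'   columns plus identifiers) and `trajectories` ([trajectories()] columns),
#'   plus `species` — a long table (plot, species, trajectory) feeding
#'   [species_loss_rarity()].
#' @export
plot_turnover <- function(mat) {
  s <- sample_info(mat)
  plots <- split(seq_len(nrow(mat)), s$plot)
  plots <- plots[vapply(plots, length, 1L) >= 2]
  if (length(plots) == 0)
    return(list(turnover = NULL, trajectories = NULL, species = NULL))
  i0 <- vapply(plots, function(i) i[which.min(s$year[i])], 1L)
  i1 <- vapply(plots, function(i) i[which.max(s$year[i])], 1L)
  S <- mat[i0, , drop = FALSE]; E <- mat[i1, , drop = FALSE]

  # vectorized partition over all plots at once (same arithmetic as
  # temporal_turnover on each pair)
  px <- S > 0; py <- E > 0
  a <- rowSums(px & py); b <- rowSums(px & !py); c_ <- rowSums(!px & py)
  n_union <- a + b + c_
  jt <- ifelse(n_union > 0, (b + c_) / n_union, 0)
  m <- pmin(b, c_)
  jr <- ifelse(a + 2 * m > 0, 2 * m / (a + 2 * m), 0)
  Amin <- rowSums(pmin(S, E))
  B <- rowSums(S) - Amin; C <- rowSums(E) - Amin
  bt <- ifelse(2 * Amin + B + C > 0, (B + C) / (2 * Amin + B + C), 0)
  mb <- pmin(B, C)
  bb <- ifelse(Amin + mb > 0, mb / (Amin + mb), 0)

  turn <- data.frame(
    plot = names(plots), year_start = s$year[i0], year_end = s$year[i1],
    a = as.integer(a), b = as.integer(b), c = as.integer(c_),
    n_union = as.integer(n_union),
    jac_total = jt, jac_replacement = jr, jac_nestedness = jt - jr,
    bc_total = bt, bc_balanced = bb, bc_gradient = bt - bb,
    row.names = NULL, stringsAsFactors = FALSE)
  degenerate <- n_union == 0
  den <- ifelse(degenerate, NA_real_, n_union)
  traj <- data.frame(
    plot = names(plots), year_start = s$year[i0], year_end = s$year[i1],
    n_lost = as.integer(b), n_gained = as.integer(c_),
    n_persisting = as.integer(a), n_union = as.integer(n_union),
    prop_lost = b / den, prop_gained = c_ / den, prop_persisting = a / den,
    degenerate = degenerate, row.names = NULL, stringsAsFactors = FALSE)

  idx <- which(px | py, arr.ind = TRUE)
  cls <- ifelse(px[idx] & py[idx], "persisting",
                ifelse(px[idx], "lost", "gained"))
  species <- data.frame(plot = names(plots)[idx[, 1]],
                        species = colnames(mat)[idx[, 2]],
                        trajectory = cls, row.names = NULL,
                        stringsAsFactors = FALSE)
  species <- species[order(species$plot, species$species), ]
  rownames(species) <- NULL
  list(turnover = turn, trajectories = traj, species = species)
}

.rbind_reset <- function(lst) {
  if (length(lst) == 0) return(NULL)
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}

#' Two-proportion z test with pooled variance
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @return list with `z`, two-sided `p`, and `degenerate` (TRUE when the
#'   pooled proportion is 0 or 1, in which case z = 0 and p = 1).
#' @export
two_proportion_z <- function(k1, n1, k2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  pool <- (k1 + k2) / (n1 + n2)
  if (pool <= 0 || pool >= 1)
    return(list(z = 0, p = 1, degenerate = TRUE))
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- (k1 / n1 - k2 / n2) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
}

#' Proportional species losses versus range size
#'
#' For each species, the percentage of its plot-level trajectory records that
#' are losses, together with the number of study areas where the species
#' occurs (from the spatial table) — the input to the rarity-versus-loss
#' regression.
#'
#' @param species_trajectories long table from [plot_turnover()]`$species`.
#' @param spatial_table the spatial `survey_table` (for study-area counts).
#' @return data.frame (species, n_records, n_lost, pct_lost, n_study_areas).
#' @export
species_loss_rarity <- function(species_trajectories, spatial_table) {
  sp <- split(species_trajectories, species_trajectories$species)
  areas <- tapply(spatial_table$study_area, spatial_table$species,
                  function(a) length(unique(a)))
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(species = d$species[1], n_records = nrow(d),
               n_lost = sum(d$trajectory == "lost"),
               pct_lost = 100 * mean(d$trajectory == "lost"),
               n_study_areas = as.integer(areas[d$species[1]] %||% NA),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
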