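#' Shannon diversity index
#'
#' H = -sum(p_i log p_i) over nonzero proportions, natural log.
#'
#' @param counts non-negative numeric vector with a positive sum.
#' @return numeric scalar.
#' @export
shannon <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- sum(counts)
  if (tot <= 0) stop("Shannon index undefined for an all-zero vector")
  p <- counts[counts > 0] / tot
  -sum(p * log(p))
}

#' Bray-Curtis dissimilarity between two composition vectors
#'
#' BC = 1 - 2 * sum(min(x_i, y_i)) / (sum(x) + sum(y)); 0 for identical
#' compositions, 1 for disjoint support.
#'
#' @param x,y equal-length non-negative vectors, not both all-zero.
#' @return numeric in [0, 1].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  tot <- sum(x) + sum(y)
  if (tot <= 0) stop("Bray-Curtis undefined when both vectors are all-zero")
  1 - 2 * sum(pmin(x, y)) / tot
}

#' Bray-Curtis dissimilarity matrix over samples
#'
#' Columns are converted to relative abundances before comparison, so
#' between-sample differences in sequencing depth do not masquerade as
#' compositional change.
#'
#' @param table numeric matrix, viral groups x samples.
#' @param relative convert columns to proportions first (default TRUE).
#' @return symmetric matrix of pairwise dissimilarities with zero diagonal.
#' @export
bray_curtis_matrix <- function(table, relative = TRUE) {
  if (relative) {
    cs <- colSums(table)
    if (any(cs <= 0)) stop("every sample must have a positive total")
    table <- sweep(table, 2, cs, "/")
  }
  n <- ncol(table)
  d <- matrix(0, n, n, dimnames = list(colnames(table), colnames(table)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- bray_curtis(table[, i], table[, j])
  }
  d
}

#' Principal coordinate analysis of a dissimilarity matrix
#'
#' Classical scaling: the squared dissimilarities are double-centred and
#' eigendecomposed; axes are ordered by eigenvalue. Negative eigenvalues
#' (possible for non-Euclidean dissimilarities such as Bray-Curtis) are
#' dropped from both the coordinates and the variance denominator.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal.
#' @return list with `points` (samples x axes), `eig` (positive
#'   eigenvalues), `variance_explained` (percent per axis, non-increasing)
#'   and `negative_eig_dropped` (count).
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("dissimilarity matrix must be symmetric")
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- e$values > tol
  lam <- e$values[pos]
  pts <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(lam), sum(pos))
  rownames(pts) <- rownames(d)
  colnames(pts) <- sprintf("PCo%d", seq_len(ncol(pts)))
  list(points = pts, eig = lam,
       variance_explained = 100 * lam / sum(lam),
       negative_eig_dropped = sum(e$values < -tol))
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Partitions the total sum of squared dissimilarities into between- and
#' within-group components (Gower-centred formulation): with n samples and
#' g groups, SS_total = sum(d_ij^2)/n over all pairs, SS_within is the
#' analogous within-group sum, R^2 = SS_between / SS_total and
#' pseudo-F = (SS_between/(g-1)) / (SS_within/(n-g)). The p value is the
#' fraction of label permutations (observed ordering included) whose
#' pseudo-F is at least the observed one.
#'
#' @param d symmetric dissimilarity matrix.
#' @param grouping factor-like vector, one label per sample; >= 2 groups
#'   each with >= 2 samples.
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutation stream.
#' @return list with `R2`, `F`, `p`, `n_perm` and the SS decomposition.
#' @export
permanova <- function(d, grouping, n_perm = 999, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  grouping <- as.factor(grouping)
  if (length(grouping) != n) stop("one group label per sample required")
  g <- nlevels(droplevels(grouping))
  if (g < 2) stop("PERMANOVA needs at least two groups")
  if (any(table(grouping) < 2)) stop("every group needs >= 2 samples")
  d2 <- d^2
  ss_total <- sum(d2[upper.tri(d2)]) / n

  ss_within <- function(lab) {
    s <- 0
    for (lev in levels(lab)) {
      idx <- which(lab == lev)
      if (length(idx) > 1)
        s <- s + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
    s
  }
  f_stat <- function(lab) {
    ssw <- ss_within(lab)
    ssb <- ss_total - ssw
    (ssb / (g - 1)) / (ssw / (n - g))
  }
  f_obs <- f_stat(grouping)
  ssw_obs <- ss_within(grouping)
  r2 <- (ss_total - ssw_obs) / ss_total
  exceed <- 1L  # observed ordering counts
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      if (f_stat(grouping[sample.int(n)]) >= f_obs) exceed <- exceed + 1L
    }
  })
  list(R2 = r2, F = f_obs, p = exceed / (n_perm + 1L), n_perm = n_perm,
       SS_between = ss_total - ssw_obs, SS_within = ssw_obs,
       SS_total = ss_total, df_between = g - 1, df_within = n - g)
}

#' Per-animal longitudinal Bray-Curtis dissimilarity
#'
#' For each animal computes the Bray-Curtis dissimilarity between its
#' baseline and each later timepoint and between the two later timepoints,
#' classifies whether the community drifted further from baseline by the
#' late timepoint, and averages within treatment and within cage.
#'
#' @param table count matrix, viral groups x samples.
#' @param metadata data.frame(sample_id, animal_id, cage_id, treatment,
#'   timepoint) covering the table's columns.
#' @param timepoints character of length 3: baseline, early, late.
#' @return list with `animals` (data.frame animal_id, cage_id, treatment,
#'   bc_base_t1, bc_base_t5, bc_t1_t5, direction), `by_treatment` and
#'   `by_cage` (mean dissimilarities).
#' @export
longitudinal_dissimilarity <- function(table, metadata,
                                       timepoints = c("Base", "T1", "T5")) {
  stopifnot(length(timepoints) == 3)
  rel <- sweep(table, 2, colSums(table), "/")
  recs <- list()
  for (an in unique(metadata$animal_id)) {
    md <- metadata[metadata$animal_id == an, , drop = FALSE]
    sid <- function(tp) {
      s <- md$sample_id[md$timepoint == tp]
      if (length(s) == 1 && s %in% colnames(rel)) s else NA_character_
    }
    s0 <- sid(timepoints[1]); s1 <- sid(timepoints[2]); s5 <- sid(timepoints[3])
    if (is.na(s0)) {
      warning(sprintf("animal %s lacks a %s sample; skipped", an,
                      timepoints[1]))
      next
    }
    if (is.na(s1) && is.na(s5)) {
      warning(sprintf("animal %s has no post-baseline sample; skipped", an))
      next
    }
    bc01 <- if (is.na(s1)) NA_real_ else bray_curtis(rel[, s0], rel[, s1])
    bc05 <- if (is.na(s5)) NA_real_ else bray_curtis(rel[, s0], rel[, s5])
    bc15 <- if (is.na(s1) || is.na(s5)) NA_real_ else
      bray_curtis(rel[, s1], rel[, s5])
    dir <- if (is.na(bc01) || is.na(bc05)) NA_character_
    else if (bc05 > bc01) "T5_more_dissimilar"
    else if (bc01 > bc05) "T1_more_dissimilar"
    else "tie"
    recs[[an]] <- data.frame(
      animal_id = an, cage_id = md$cage_id[1], treatment = md$treatment[1],
      bc_base_t1 = bc01, bc_base_t5 = bc05, bc_t1_t5 = bc15,
      direction = dir, stringsAsFactors = FALSE)
  }
  animals <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
  avg_by <- function(key) {
    sp <- split(animals, animals[[key]])
    do.call(rbind, c(lapply(names(sp), function(k) data.frame(
      group = k,
      bc_base_t1 = mean(sp[[k]]$bc_base_t1, na.rm = TRUE),
      bc_base_t5 = mean(sp[[k]]$bc_base_t5, na.rm = TRUE),
      bc_t1_t5 = mean(sp[[k]]$bc_t1_t5, na.rm = TRUE),
      n = nrow(sp[[k]]), stringsAsFactors = FALSE)),
      list(make.row.names = FALSE)))
  }
  list(animals = animals, by_treatment = avg_by("treatment"),
       by_cage = avg_by("cage_id"))
}

#' Rank-based group comparison with Bonferroni correction
#'
#' Two groups are compared with the Wilcoxon rank-sum test, three or more
#' with the Kruskal-Wallis test. The Bonferroni-adjusted p value is
#' min(1, m * p), where m defaults to the number of tests performed in the
#' call but can be set to the size of a wider comparison family.
#'
#' @param values numeric vector of observations.
#' @param grouping group label per observation.
#' @param test "auto" picks by group count; or force "wilcoxon"/"kruskal".
#' @param m_comparisons Bonferroni family size (default: tests in this
#'   call, i.e. 1).
#' @return data.frame(test, statistic, p, p_adj).
#' @export
group_compare <- function(values, grouping,
                          test = c("auto", "wilcoxon", "kruskal"),
                          m_comparisons = 1) {
  test <- match.arg(test)
  grouping <- as.factor(grouping)
  g <- nlevels(droplevels(grouping))
  if (g < 2) stop("need at least two groups")
  if (any(table(droplevels(grouping)) < 2))
    stop("every group needs at least two observations")
  if (test == "auto") test <- if (g == 2) "wilcoxon" else "kruskal"
  if (test == "wilcoxon") {
    if (g != 2) stop("wilcoxon applies to exactly two groups")
    lv <- levels(droplevels(grouping))
    ht <- suppressWarnings(wilcox.test(values[grouping == lv[1]],
                                       values[grouping == lv[2]]))
  } else {
    ht <- kruskal.test(values, grouping)
  }
  data.frame(test = test, statistic = unname(ht$statistic), p = ht$p.value,
             p_adj = min(1, ht$p.value * m_comparisons),
             stringsAsFactors = FALSE)
}
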