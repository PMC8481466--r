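#' Median-of-ratios size factors
#'
#' Per-sample scaling factors for library-depth normalization: each sample's
#' factor is the median across viral groups of the ratio of its count to the
#' group's geometric mean, computed over groups with no zero count. When no
#' group is zero-free the median is taken per sample over that sample's
#' positive-count groups, with a warning. Factors are rescaled so their
#' geometric mean is 1.
#'
#' @param table count matrix, viral groups x samples.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative")
  log_geo <- rowMeans(log(table))         # -Inf for rows with any zero
  usable <- is.finite(log_geo)
  if (any(usable)) {
    lf <- log(table[usable, , drop = FALSE]) - log_geo[usable]
    sf <- exp(apply(lf, 2, median))
  } else {
    warning("no group is zero-free in all samples; using positive counts only")
    log_geo <- apply(table, 1, function(r) mean(log(r[r > 0])))
    sf <- vapply(seq_len(ncol(table)), function(j) {
      r <- log(table[, j]) - log_geo
      exp(median(r[is.finite(r)]))
    }, numeric(1))
  }
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(table)
  sf
}

# method-of-moments NB dispersion per group, pooled across the two
# conditions; negative estimates floor at `floor`
mom_dispersion <- function(q1, q2, floor = 1e-8) {
  num <- 0; den <- 0
  for (q in list(q1, q2)) {
    n <- ncol(q)
    if (n < 2) next
    m <- rowMeans(q)
    v <- apply(q, 1, var)
    ok <- m > 0
    contrib <- rep(0, nrow(q))
    contrib[ok] <- (v[ok] - m[ok]) / m[ok]^2
    num <- num + (n - 1) * contrib
    den <- den + (n - 1)
  }
  pmax(num / den, floor)
}

#' Negative-binomial Wald test for a two-condition contrast
#'
#' Per-group differential abundance between a reference and a test
#' condition. Counts are normalized with [size_factors()]; the log2 fold
#' change is the log-ratio of normalized group means (pseudocount 0.5).
#' Per-group dispersions are method-of-moments estimates pooled across the
#' two conditions, stabilized by taking the maximum of the per-group
#' estimate and the median estimate over all groups (a conservative
#' trend-style moderation, so noisy per-group underestimates cannot inflate
#' the Wald statistic). The Wald z is the natural-log fold change over its
#' delta-method standard error under NB variance mu + a*mu^2; p values are
#' two-sided normal.
#'
#' @param table count matrix, viral groups x samples (both conditions).
#' @param condition vector over columns with exactly two levels; the first
#'   level (or `ref`) is the reference.
#' @param ref optional reference level name.
#' @param sf optional precomputed size factors for the columns.
#' @param pseudocount added to normalized group means.
#' @param dispersion_floor lower bound for dispersion estimates.
#' @return data.frame(group_id, base_mean, log2fc, se_log2fc, stat, p);
#'   groups with zero counts throughout are excluded (attribute
#'   "excluded" lists them).
#' @export
nb_wald_test <- function(table, condition, ref = NULL, sf = NULL,
                         pseudocount = 0.5, dispersion_floor = 1e-8) {
  table <- as.matrix(table)
  condition <- as.factor(condition)
  if (nlevels(droplevels(condition)) != 2)
    stop("condition must have exactly two levels")
  condition <- droplevels(condition)
  if (!is.null(ref)) condition <- stats::relevel(condition, ref = ref)
  if (any(table(condition) < 2)) stop("need >= 2 samples per condition")
  if (is.null(sf)) sf <- size_factors(table)
  q <- sweep(table, 2, sf, "/")
  excluded <- rownames(table)[rowSums(table) == 0]
  keep <- rowSums(table) > 0
  q <- q[keep, , drop = FALSE]

  i1 <- condition == levels(condition)[1]
  i2 <- !i1
  q1 <- q[, i1, drop = FALSE]; q2 <- q[, i2, drop = FALSE]
  m1 <- rowMeans(q1) + pseudocount
  m2 <- rowMeans(q2) + pseudocount
  disp <- mom_dispersion(q1, q2, floor = dispersion_floor)
  disp_trend <- if (length(disp) >= 5) median(disp) else
    max(disp, dispersion_floor)
  disp_use <- pmax(disp, disp_trend)

  log2fc <- log2(m2 / m1)
  n1 <- sum(i1); n2 <- sum(i2)
  se_ln <- sqrt((1 / m1 + disp_use) / n1 + (1 / m2 + disp_use) / n2)
  stat <- log(m2 / m1) / se_ln
  p <- 2 * pnorm(-abs(stat))
  out <- data.frame(group_id = rownames(q),
                    base_mean = rowMeans(q),
                    log2fc = log2fc, se_log2fc = se_ln / log(2),
                    stat = stat, p = p,
                    dispersion = disp_use,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Differential abundance of viral groups across timepoints, per treatment
#'
#' Runs [nb_wald_test()] for the baseline-versus-T1 and baseline-versus-T5
#' contrasts within each treatment arm and applies Bonferroni correction
#' over all groups x contrasts tested within that treatment. A group is
#' significant when its adjusted p value falls below `alpha`.
#'
#' @param table count matrix, viral groups x samples.
#' @param metadata data.frame(sample_id, treatment, timepoint) covering the
#'   columns.
#' @param treatments treatments to test (default: all in metadata).
#' @param timepoints character of length 3: baseline, early, late.
#' @param alpha adjusted-p significance threshold (default 1e-5).
#' @return data.frame(group_id, treatment, contrast, base_mean, log2fc,
#'   stat, p, p_adj, significant) with contrast in
#'   "Base_vs_T1"/"Base_vs_T5"; attribute "m_bonferroni" records the family
#'   size per treatment.
#' @export
differential_abundance <- function(table, metadata, treatments = NULL,
                                   timepoints = c("Base", "T1", "T5"),
                                   alpha = 1e-5) {
  if (is.null(treatments)) treatments <- unique(metadata$treatment)
  res <- list(); m_log <- list()
  for (tr in treatments) {
    md <- metadata[metadata$treatment == tr, , drop = FALSE]
    runs <- list()
    for (tp in timepoints[2:3]) {
      cols <- md$sample_id[md$timepoint %in% c(timepoints[1], tp)]
      cols <- intersect(colnames(table), cols)
      cond <- metadata$timepoint[match(cols, metadata$sample_id)]
      if (length(unique(cond)) < 2 || any(table(cond) < 2)) next
      r <- nb_wald_test(table[, cols, drop = FALSE],
                        factor(cond, levels = c(timepoints[1], tp)))
      r$treatment <- tr
      r$contrast <- paste0(timepoints[1], "_vs_", tp)
      runs[[tp]] <- r
    }
    if (length(runs) == 0) next
    rr <- do.call(rbind, c(runs, list(make.row.names = FALSE)))
    m <- nrow(rr)
    rr$p_adj <- pmin(1, rr$p * m)
    rr$significant <- rr$p_adj < alpha
    m_log[[tr]] <- m
    res[[tr]] <- rr
  }
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  out <- out[, c("group_id", "treatment", "contrast", "base_mean", "log2fc",
                 "se_log2fc", "stat", "p", "p_adj", "significant",
                 "dispersion")]
  attr(out, "m_bonferroni") <- unlist(m_log)
  attr(out, "alpha") <- alpha
  out
}

#' Cross-treatment concordance of differentially abundant groups
#'
#' For every viral group significant in at least one (treatment, contrast)
#' cell, collects the treatments and timepoints where it is altered, the
#' direction of change in each cell, and classifies it as altered in a
#' single treatment or in multiple treatments; groups significant at both
#' post-baseline timepoints within one treatment are flagged persistent.
#'
#' @param results data.frame from [differential_abundance()].
#' @return list with `records` (one row per altered group: group_id,
#'   n_treatments, treatments_altered, timepoints_altered, category,
#'   persistent_both_timepoints), `summary` (category counts, total and
#'   single-treatment percentage) and `pair_overlap` (matrix of shared
#'   altered groups per treatment pair).
#' @export
concordance <- function(results) {
  sig <- results[results$significant, , drop = FALSE]
  if (nrow(sig) == 0) {
    return(list(records = data.frame(), summary = data.frame(
      n_total = 0, n_single_treatment = 0, n_multi_treatment = 0,
      n_persistent = 0, pct_single_treatment = NA_real_),
      pair_overlap = NULL))
  }
  sig$timepoint <- sub("^.*_vs_", "", sig$contrast)
  recs <- lapply(split(sig, sig$group_id), function(s) {
    trs <- sort(unique(s$treatment))
    tps <- sort(unique(s$timepoint))
    persistent <- any(vapply(split(s$timepoint, s$treatment),
                             function(x) length(unique(x)) >= 2, logical(1)))
    data.frame(
      group_id = s$group_id[1],
      n_treatments = length(trs),
      treatments_altered = paste(trs, collapse = ","),
      timepoints_altered = paste(tps, collapse = ","),
      direction = paste(sprintf("%s:%s:%s", s$treatment, s$timepoint,
                                ifelse(s$log2fc > 0, "up", "down")),
                        collapse = ";"),
      category = if (length(trs) == 1) "single_treatment" else
        "multi_treatment",
      persistent_both_timepoints = persistent,
      stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
  treatments <- sort(unique(sig$treatment))
  pair <- matrix(0L, length(treatments), length(treatments),
                 dimnames = list(treatments, treatments))
  by_tr <- lapply(treatments, function(tr)
    unique(sig$group_id[sig$treatment == tr]))
  names(by_tr) <- treatments
  for (a in treatments) for (b in treatments)
    pair[a, b] <- length(intersect(by_tr[[a]], by_tr[[b]]))
  smry <- concordance_summary_counts(
    n_single = sum(records$category == "single_treatment"),
    n_total = nrow(records),
    n_persistent = sum(records$persistent_both_timepoints))
  list(records = records, summary = smry, pair_overlap = pair)
}

#' Concordance summary arithmetic
#'
#' Formats the headline concordance numbers from their component counts:
#' the total number of differentially abundant groups (optionally as the
#' sum of contig-level and cluster-level components) and the percentage
#' altered in only one treatment, rounded to one decimal.
#'
#' @param n_single groups altered in a single treatment.
#' @param n_total total altered groups; alternatively supply `n_contigs`
#'   and `n_vcs` whose sum is used.
#' @param n_contigs,n_vcs optional component counts (contig-level and
#'   viral-cluster-level groups).
#' @param n_persistent groups altered at both post-baseline timepoints.
#' @return data.frame(n_total, n_single_treatment, n_multi_treatment,
#'   n_persistent, pct_single_treatment).
#' @export
concordance_summary_counts <- function(n_single, n_total = NULL,
                                       n_contigs = NULL, n_vcs = NULL,
                                       n_persistent = NA_integer_) {
  if (is.null(n_total)) {
    if (is.null(n_contigs) || is.null(n_vcs))
      stop("supply n_total or both n_contigs and n_vcs")
    n_total <- n_contigs + n_vcs
  }
  if (n_single > n_total) stop("n_single cannot exceed n_total")
  data.frame(n_total = n_total,
             n_single_treatment = n_single,
             n_multi_treatment = n_total - n_single,
             n_persistent = n_persistent,
             pct_single_treatment =
               if (n_total > 0) round(100 * n_single / n_total, 1)
               else NA_real_)
}
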