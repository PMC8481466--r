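nb_table <- function(G, n1, n2, mu, lfc = rep(0, G), size = 10) {
  tab <- cbind(matrix(rnbinom(G * n1, mu = mu, size = size), G),
               matrix(rnbinom(G * n2, mu = mu * 2^lfc, size = size), G))
  dimnames(tab) <- list(sprintf("g%03d", 1:G),
                        sprintf("s%02d", 1:(n1 + n2)))
  tab
}

test_that("size factors reproduce scaling and the brute-force oracle", {
  tab <- matrix(rep(c(4L, 10L, 25L), 3), nrow = 3,
                dimnames = list(letters[1:3], c("s1", "s2", "s3")))
  expect_equal(unname(size_factors(tab)), c(1, 1, 1))

  tab2 <- tab
  tab2[, 2] <- tab2[, 2] * 2L
  sf <- size_factors(tab2)
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(unname(sf[2] / sf[3]), 2)
  expect_equal(exp(mean(log(sf))), 1)

  set.seed(22)
  tab3 <- nb_table(100, 4, 4, mu = exp(runif(100, 2, 6)))
  expect_equal(size_factors(tab3), size_factors_oracle(tab3),
               tolerance = 1e-12)

  # no zero-free group triggers the positive-count fallback
  tab4 <- nb_table(20, 3, 3, mu = 2)
  tab4[cbind(1:20, sample(1:6, 20, TRUE))] <- 0L
  expect_warning(sf4 <- size_factors(tab4), "zero-free")
  expect_true(all(sf4 > 0))
})

test_that("size factors agree with the DESeq2 median-of-ratios", {
  skip_if_not_installed("DESeq2")
  set.seed(23)
  tab <- nb_table(150, 5, 5, mu = exp(runif(150, 2, 7)))
  ours <- size_factors(tab)
  ref <- DESeq2::estimateSizeFactorsForMatrix(tab)
  ref <- ref / exp(mean(log(ref)))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("equal means give near-zero fold change, never significance", {
  set.seed(24)
  tab <- nb_table(200, 6, 6, mu = 500)
  r <- nb_wald_test(tab, rep(c("A", "B"), each = 6))
  expect_lt(median(abs(r$log2fc)), 0.2)
  expect_true(all(pmin(1, r$p * nrow(r)) > 1e-5))
})

test_that("fold-change sign agrees with the normalized mean ratio", {
  set.seed(25)
  tab <- nb_table(100, 5, 5, mu = exp(runif(100, 2, 6)),
                  lfc = sample(c(-2, 0, 2), 100, TRUE))
  cond <- rep(c("A", "B"), each = 5)
  r <- nb_wald_test(tab, cond)
  q <- sweep(tab, 2, size_factors(tab), "/")
  m1 <- rowMeans(q[r$group_id, cond == "A"]) + 0.5
  m2 <- rowMeans(q[r$group_id, cond == "B"]) + 0.5
  expect_true(all(sign(r$log2fc) == sign(log2(m2 / m1))))
  expect_true(all(sign(r$stat) == sign(r$log2fc) | r$log2fc == 0))
})

test_that("an 8-fold spike is recovered within half a log2 unit", {
  set.seed(26)
  hits <- replicate(40, {
    mu <- exp(runif(60, log(200), log(1000)))
    tab <- nb_table(60, 6, 6, mu = mu, lfc = c(3, rep(0, 59)))
    r <- nb_wald_test(tab, rep(c("A", "B"), each = 6))
    abs(r$log2fc[r$group_id == "g001"] - 3) <= 0.5
  })
  expect_gte(mean(hits), 0.9)
})

test_that("all-zero groups are excluded and reported", {
  set.seed(27)
  tab <- nb_table(10, 3, 3, mu = 100)
  tab["g003", ] <- 0L
  r <- nb_wald_test(tab, rep(c("A", "B"), each = 3))
  expect_false("g003" %in% r$group_id)
  expect_identical(attr(r, "excluded"), "g003")
})

test_that("the per-treatment wrapper tests both contrasts with Bonferroni", {
  com <- generate_genomes(n_viral = 20, n_contaminant = 0, seed = 33)
  ids <- com$truth$genome_id
  eff <- rbind(
    data.frame(genome_id = ids[1], treatment = "PFF", timepoint = "T5",
               log2fc = 5),
    data.frame(genome_id = ids[2], treatment = "PFF", timepoint = c("T1", "T5"),
               log2fc = 4))
  des <- community_design(ids, n_animals_per_treatment = 6,
                          effect_table = eff, reads_per_sample = 30000,
                          dispersion = 0.05, seed = 33)
  md <- des$metadata[des$metadata$treatment %in% c("PFF", "Sham"), ]
  sim <- simulate_reads(com, des, samples = md$sample_id)
  res <- differential_abundance(sim$counts[, md$sample_id], md,
                                treatments = c("PFF", "Sham"))
  expect_setequal(unique(res$contrast), c("Base_vs_T1", "Base_vs_T5"))
  expect_true(all(res$p_adj >= res$p))
  expect_true(all(res$p_adj <= 1))
  m <- attr(res, "m_bonferroni")[["PFF"]]
  got <- res[res$treatment == "PFF", ]
  expect_equal(got$p_adj, pmin(1, got$p * m))

  hit <- res[res$group_id == ids[1] & res$treatment == "PFF" &
               res$contrast == "Base_vs_T5", ]
  expect_true(hit$significant)
  expect_gt(hit$log2fc, 2)
  sham_sig <- res$significant[res$treatment == "Sham"]
  expect_lte(sum(sham_sig), 1)
})

test_that("concordance classifies planted shared and private effects", {
  mk <- function(group_id, treatment, timepoint) {
    data.frame(group_id = group_id, treatment = treatment,
               contrast = paste0("Base_vs_", timepoint), log2fc = 3,
               p = 1e-10, p_adj = 1e-9, significant = TRUE,
               stringsAsFactors = FALSE)
  }
  treatments <- c("Sham", "LPS", "monomer", "monomer_LPS", "PFF", "PFF_LPS")
  rows <- list()
  for (i in 1:40)  # private: one treatment, one timepoint
    rows[[length(rows) + 1L]] <- mk(sprintf("priv%02d", i),
                                    treatments[(i %% 6) + 1], "T1")
  for (i in 1:10)  # shared across two treatments
    rows[[length(rows) + 1L]] <- rbind(
      mk(sprintf("shared%02d", i), "PFF", "T5"),
      mk(sprintf("shared%02d", i), "PFF_LPS", "T5"))
  res <- do.call(rbind, rows)
  res$significant <- res$p_adj < 1e-5
  cc <- concordance(res)
  expect_equal(cc$summary$n_total, 50)
  expect_equal(cc$summary$n_single_treatment, 40)
  expect_equal(cc$summary$n_multi_treatment, 10)
  expect_equal(cc$summary$pct_single_treatment, 80)
  expect_equal(cc$pair_overlap["PFF", "PFF_LPS"], 10L)

  pers <- rbind(mk("p1", "monomer", "T1"), mk("p1", "monomer", "T5"),
                mk("p2", "monomer", "T1"))
  pp <- concordance(pers)
  expect_true(pp$records$persistent_both_timepoints[
    pp$records$group_id == "p1"])
  expect_false(pp$records$persistent_both_timepoints[
    pp$records$group_id == "p2"])
  expect_equal(pp$records$category[pp$records$group_id == "p1"],
               "single_treatment")

  none <- mk("x", "Sham", "T1"); none$significant <- FALSE
  expect_equal(concordance(none)$summary$n_total, 0)
})

test_that("the concordance formatter reproduces component arithmetic", {
  s <- concordance_summary_counts(n_single = 48, n_contigs = 36, n_vcs = 42)
  expect_equal(s$n_total, 78)
  expect_equal(s$pct_single_treatment, 61.5)
  expect_equal(s$n_multi_treatment, 30)
  expect_error(concordance_summary_counts(n_single = 10, n_total = 5),
               "exceed")
  expect_error(concordance_summary_counts(n_single = 1), "supply")
})
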