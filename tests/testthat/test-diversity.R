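test_that("Shannon index matches closed forms and vegan", {
  expect_equal(shannon(c(5, 5, 5, 5)), log(4))
  expect_equal(shannon(c(0, 7, 0)), 0)
  expect_equal(shannon(c(2, 1, 1)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  expect_equal(round(shannon(c(2, 1, 1)), 4), 1.0397)
  expect_error(shannon(c(0, 0)), "all-zero")
  expect_error(shannon(c(-1, 2)), "non-negative")
  skip_if_not_installed("vegan")
  set.seed(15)
  x <- rpois(20, 30)
  expect_equal(shannon(x), unname(vegan::diversity(x, index = "shannon")))
})

test_that("Bray-Curtis matches closed forms, symmetry and vegan", {
  expect_equal(bray_curtis(c(3, 1, 4), c(3, 1, 4)), 0)
  expect_equal(bray_curtis(c(5, 0, 2), c(0, 3, 0)), 1)
  expect_equal(bray_curtis(c(2, 0, 1), c(1, 1, 0)), 0.6)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(bray_curtis(1:3, 1:4), "equal length")
  set.seed(16)
  for (i in 1:20) {
    x <- rpois(10, 20); y <- rpois(10, 20)
    b <- bray_curtis(x, y)
    expect_gte(b, 0); expect_lte(b, 1)
    expect_equal(b, bray_curtis(y, x))
  }
  skip_if_not_installed("vegan")
  x <- rpois(15, 25); y <- rpois(15, 25)
  expect_equal(bray_curtis(x, y),
               as.numeric(vegan::vegdist(rbind(x, y), method = "bray")))
})

test_that("PCoA recovers planar configurations and orders axes", {
  # three equidistant points: two equal positive eigenvalues, 50/50
  d3 <- matrix(1, 3, 3) - diag(3)
  p3 <- pcoa(d3)
  expect_equal(p3$variance_explained[1:2], c(50, 50), tolerance = 1e-10)

  set.seed(17)
  pts <- cbind(runif(8, 0, 10), runif(8, 0, 10))
  d <- as.matrix(dist(pts))
  p <- pcoa(d)
  expect_lt(procrustes_error(pts, p$points[, 1:2]), 1e-8)
  expect_true(all(diff(p$variance_explained) <= 1e-8))
  expect_lte(sum(p$variance_explained), 100 + 1e-8)
  # agreement with classical scaling
  cs <- stats::cmdscale(d, k = 2)
  expect_lt(procrustes_error(cs, p$points[, 1:2]), 1e-8)

  # duplicated sample maps to identical coordinates
  d2 <- as.matrix(dist(pts[c(1, 1:8), ]))
  pdup <- pcoa(d2)
  expect_equal(pdup$points[1, ], pdup$points[2, ], tolerance = 1e-8)

  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("PERMANOVA matches the Gower-trace oracle and vegan", {
  set.seed(18)
  x <- matrix(rnorm(6 * 3), 6)
  d <- as.matrix(dist(x))
  g <- rep(c("a", "b"), each = 3)
  pm <- permanova(d, g, n_perm = 99, seed = 1)
  expect_equal(pm$R2, permanova_r2_oracle(d, g), tolerance = 1e-10)
  expect_gte(pm$R2, 0); expect_lte(pm$R2, 1)
  skip_if_not_installed("vegan")
  ad <- vegan::adonis2(stats::as.dist(d) ~ g, permutations = 49)
  expect_equal(pm$R2, ad$R2[1], tolerance = 1e-10)
  expect_equal(pm$F, ad$F[1], tolerance = 1e-10)
})

test_that("PERMANOVA separates constructed clusters and validates input", {
  set.seed(19)
  x <- rbind(matrix(rnorm(24, 0), 8), matrix(rnorm(24, 4), 8))
  d <- as.matrix(dist(x))
  g <- rep(c("a", "b"), each = 8)
  pm <- permanova(d, g, n_perm = 999, seed = 5)
  expect_gte(pm$R2, 0.5)
  expect_lte(pm$p, 0.005)
  expect_error(permanova(d, rep("a", 16)), "two groups")
  expect_error(permanova(d, c(rep("a", 15), "b")), ">= 2 samples")
})

test_that("random-label PERMANOVA R2 has mean about (g-1)/(n-1)", {
  set.seed(20)
  n <- 20; g <- 4
  r2s <- replicate(60, {
    x <- matrix(rnorm(n * 4), n)
    d <- as.matrix(dist(x))
    lab <- sample(rep(letters[1:g], each = n / g))
    permanova(d, lab, n_perm = 0, seed = 1)$R2
  })
  expect_lt(abs(mean(r2s) - (g - 1) / (n - 1)), 0.02)
})

test_that("longitudinal dissimilarity classifies drift from baseline", {
  tab <- cbind(a_Base = c(10, 10, 10), a_T1 = c(10, 10, 10),
               a_T5 = c(30, 5, 0),
               b_Base = c(10, 0, 5), b_T1 = c(0, 10, 5))
  rownames(tab) <- c("g1", "g2", "g3")
  md <- data.frame(
    sample_id = colnames(tab),
    animal_id = rep(c("a", "b"), c(3, 2)),
    cage_id = rep(c("C1", "C2"), c(3, 2)),
    treatment = rep(c("Sham", "LPS"), c(3, 2)),
    timepoint = c("Base", "T1", "T5", "Base", "T1"),
    stringsAsFactors = FALSE)
  out <- longitudinal_dissimilarity(tab, md)
  a <- out$animals[out$animals$animal_id == "a", ]
  expect_equal(a$bc_base_t1, 0)
  expect_gt(a$bc_base_t5, 0)
  expect_equal(a$direction, "T5_more_dissimilar")
  b <- out$animals[out$animals$animal_id == "b", ]
  expect_true(is.na(b$bc_base_t5))
  expect_equal(out$by_treatment$bc_base_t1[out$by_treatment$group == "Sham"],
               0)

  md_nobase <- md
  md_nobase$timepoint[4] <- "T5"
  expect_warning(longitudinal_dissimilarity(tab, md_nobase), "lacks")
})

test_that("direction rule follows the base-anchored comparison", {
  tab <- cbind(x_Base = c(1, 9), x_T1 = c(4, 6), x_T5 = c(6, 4))
  rownames(tab) <- c("g1", "g2")
  md <- data.frame(sample_id = colnames(tab), animal_id = "x",
                   cage_id = "C1", treatment = "Sham",
                   timepoint = c("Base", "T1", "T5"),
                   stringsAsFactors = FALSE)
  rec <- longitudinal_dissimilarity(tab, md)$animals
  expect_equal(rec$bc_base_t1, 0.3)
  expect_equal(rec$bc_base_t5, 0.5)
  expect_equal(rec$direction, "T5_more_dissimilar")
})

test_that("a persistent post-baseline shift shows the expected pattern", {
  com <- generate_genomes(n_viral = 15, n_contaminant = 0, seed = 29)
  ids <- com$truth$genome_id
  # the same perturbation at T1 and T5: baseline vs either timepoint is
  # a large change, T1 vs T5 a small one
  eff <- rbind(
    data.frame(genome_id = ids[1:3], treatment = "PFF", timepoint = "T1",
               log2fc = c(4, -4, 3)),
    data.frame(genome_id = ids[1:3], treatment = "PFF", timepoint = "T5",
               log2fc = c(4, -4, 3)))
  des <- community_design(ids, n_animals_per_treatment = 3,
                          effect_table = eff, reads_per_sample = 5000,
                          dispersion = 0.02, seed = 31)
  keep <- des$metadata$sample_id[des$metadata$treatment == "PFF"]
  sim <- simulate_reads(com, des, samples = keep)
  out <- longitudinal_dissimilarity(sim$counts[, keep],
                                    des$metadata[des$metadata$treatment ==
                                                   "PFF", ])
  avg <- out$by_treatment
  expect_gt(avg$bc_base_t1, avg$bc_t1_t5)
  expect_gt(avg$bc_base_t5, avg$bc_t1_t5)
  expect_equal(avg$bc_base_t1, avg$bc_base_t5, tolerance = 0.25)
})

test_that("rank-based comparisons and Bonferroni behave as printed", {
  x <- c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5)
  g <- rep(c("a", "b"), each = 5)
  out <- group_compare(x, g)
  expect_equal(out$p_adj, 1)

  expect_equal(min(1, 0.04 * 3), 0.12)  # Bonferroni arithmetic
  out3 <- group_compare(c(x, 101:105), rep(c("a", "b", "c"), each = 5))
  expect_equal(out3$test, "kruskal")

  set.seed(21)
  hits <- replicate(100, {
    a <- rnorm(10); b <- rnorm(10, mean = 3)
    group_compare(c(a, b), rep(c("a", "b"), each = 10))$p < 0.01
  })
  expect_gte(mean(hits), 0.95)

  expect_error(group_compare(1:4, rep("a", 4)), "two groups")
  expect_error(group_compare(1:3, c("a", "a", "b")), "two observations")
  out_m <- group_compare(c(rnorm(5), rnorm(5, 4)), g[1:10],
                         m_comparisons = 3)
  expect_equal(out_m$p_adj, min(1, out_m$p * 3))
})
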