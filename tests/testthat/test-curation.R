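make_set <- function(seqs) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- names(seqs)
  x
}

test_that("length filter drops strictly-shorter contigs and keeps order", {
  set.seed(1)
  seqs <- make_set(list(a = random_dna_str(999), b = random_dna_str(1000),
                        c = random_dna_str(1500)))
  out <- length_filter(seqs)
  expect_identical(names(out), c("b", "c"))

  all_long <- make_set(list(x = random_dna_str(1200), y = random_dna_str(2000)))
  expect_identical(names(length_filter(all_long)), c("x", "y"))

  lens <- sample(500:2000, 50, replace = TRUE)
  rnd <- Biostrings::DNAStringSet(vapply(lens, random_dna_str, character(1)))
  names(rnd) <- sprintf("c%02d", 1:50)
  expect_identical(names(length_filter(rnd)), names(rnd)[lens >= 1000])

  expect_warning(length_filter(Biostrings::DNAStringSet()), "empty")
})

test_that("circularity requires an exact terminal repeat of >= 20 bp", {
  set.seed(2)
  com <- generate_genomes(n_viral = 6, n_contaminant = 0,
                          circular_fraction = 1, seed = 4)
  expect_true(all(detect_circularity(com$sequences) == "circular"))

  lin <- random_dna_str(5000)
  expect_equal(unname(detect_circularity(lin)), "linear")

  # a 30-bp repeat near both ends but not terminal must not qualify
  rep30 <- random_dna_str(30)
  body <- random_dna_str(2000)
  near <- paste0("ACGT", rep30, body, rep30, "TGCA")
  expect_equal(unname(detect_circularity(near)), "linear")

  circ <- paste0(body, substr(body, 1, 25))
  expect_equal(unname(detect_circularity(circ)), "circular")

  expect_warning(out <- detect_circularity(random_dna_str(30), k_min = 20),
                 "linear")
  expect_equal(unname(out), "linear")
})

test_that("pVOG tiers return the printed thresholds", {
  expect_identical(pvog_tier_threshold(12000), 5L)
  expect_identical(pvog_tier_threshold(4999), 3L)
  expect_identical(pvog_tier_threshold(5000), 4L)
  expect_identical(pvog_tier_threshold(60000), 8L)
  expect_identical(pvog_tier_threshold(c(1000, 9999, 10000, 19999, 20000,
                                         39999, 40000, 59999)),
                   c(3L, 4L, 5L, 5L, 6L, 6L, 7L, 7L))
  expect_error(pvog_tier_threshold(999), ">= 1000")
})

ev_row <- function(contig_id = "c1", length_bp = 3000, topology = "linear",
                   source = "viral_enriched", refseq = FALSE, ext = FALSE,
                   dark = FALSE, pvog = 0L, rib = FALSE, plasmid = NA_real_,
                   lys = FALSE) {
  data.frame(contig_id = contig_id, length_bp = length_bp,
             topology = topology, source = source, refseq_viral_hit = refseq,
             external_classifier_viral = ext, dark_matter = dark,
             pvog_hit_count = pvog, ribosomal_hit = rib,
             plasmid_rep_hit_score = plasmid, integrase_or_recombinase = lys,
             stringsAsFactors = FALSE)
}

test_that("viral classification pools evidence as a set union", {
  expect_true(classify_viral(ev_row(topology = "circular"))[["c1"]])
  # circularity and dark matter only rescue the viral-enriched fraction
  expect_false(classify_viral(ev_row(topology = "circular",
                                     source = "wgs"))[["c1"]])
  expect_false(classify_viral(ev_row(dark = TRUE, source = "wgs"))[["c1"]])
  expect_true(classify_viral(ev_row(dark = TRUE))[["c1"]])
  expect_true(classify_viral(ev_row(length_bp = 12000, pvog = 5L))[["c1"]])
  expect_false(classify_viral(ev_row(length_bp = 12000, pvog = 4L))[["c1"]])
  expect_true(classify_viral(ev_row(refseq = TRUE))[["c1"]])
  expect_true(classify_viral(ev_row(ext = TRUE, source = "wgs"))[["c1"]])
})

test_that("adding a true evidence flag never revokes a viral call", {
  set.seed(3)
  for (i in 1:50) {
    base <- ev_row(length_bp = sample(1000:70000, 1),
                   topology = sample(c("circular", "linear"), 1),
                   source = sample(c("viral_enriched", "wgs"), 1),
                   refseq = runif(1) < 0.3, ext = runif(1) < 0.3,
                   dark = runif(1) < 0.3, pvog = sample(0:9, 1))
    v0 <- classify_viral(base)[[1]]
    for (fld in c("refseq_viral_hit", "external_classifier_viral",
                  "dark_matter")) {
      up <- base; up[[fld]] <- TRUE
      expect_true(classify_viral(up)[[1]] >= v0)
    }
    up <- base; up$pvog_hit_count <- up$pvog_hit_count + 5L
    expect_true(classify_viral(up)[[1]] >= v0)
  }
})

test_that("contaminant removal applies the ribosomal and plasmid rules", {
  ev <- rbind(ev_row("rib", refseq = TRUE, rib = TRUE),
              ev_row("pl15", refseq = TRUE, plasmid = 15.0),
              ev_row("pl149", refseq = TRUE, plasmid = 14.9),
              ev_row("clean", refseq = TRUE))
  out <- remove_contaminants(ev$contig_id, ev)
  expect_setequal(out$kept, c("pl149", "clean"))
  expect_setequal(out$removed$contig_id, c("rib", "pl15"))
  expect_equal(out$removed$reason[out$removed$contig_id == "rib"],
               "ribosomal_protein")
  expect_equal(out$removed$reason[out$removed$contig_id == "pl15"],
               "plasmid_replication")
  # no contaminant evidence: identity
  clean <- rbind(ev_row("a", refseq = TRUE), ev_row("b", refseq = TRUE))
  expect_identical(remove_contaminants(c("a", "b"), clean)$kept, c("a", "b"))
})

test_that("redundancy merging keeps the larger of homologous sequences", {
  set.seed(4)
  dup <- random_dna_str(1500)
  two <- make_set(list(b = dup, a = dup))
  m <- merge_redundant(two)
  expect_identical(names(m$sequences), "a")  # equal length: smaller id wins
  expect_identical(m$absorbed$absorbed_by, "a")

  big <- random_dna_str(5000)
  small <- substr(big, 1001, 3000)
  m2 <- merge_redundant(make_set(list(small = small, big = big)))
  expect_identical(names(m2$sequences), "big")

  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(big, 2001, 4000))))
  m3 <- merge_redundant(make_set(list(big = big, rcsub = rc)))
  expect_identical(names(m3$sequences), "big")

  # unrelated sequences are untouched
  un <- make_set(list(u1 = random_dna_str(2000), u2 = random_dna_str(2500)))
  expect_equal(length(merge_redundant(un)$sequences), 2)
})

test_that("merging matches the all-pairs greedy oracle and is idempotent", {
  set.seed(5)
  # planted homology chains: contained fragments and rc-contained fragments
  seqs <- list()
  for (fam in 1:4) {
    root <- random_dna_str(sample(3000:6000, 1))
    seqs[[sprintf("f%d_root", fam)]] <- root
    n_child <- sample(1:3, 1)
    for (ch in seq_len(n_child)) {
      L <- nchar(root)
      a <- sample(seq_len(L - 1500), 1)
      frag <- substr(root, a, a + sample(1200:1450, 1))
      if (runif(1) < 0.5)
        frag <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(frag)))
      seqs[[sprintf("f%d_c%d", fam, ch)]] <- frag
    }
  }
  for (k in 1:5) seqs[[sprintf("lone%d", k)]] <- random_dna_str(2000)
  seqs <- unlist(seqs)
  stopifnot(length(seqs) <= 20)

  expected <- greedy_merge_oracle(seqs)
  got <- merge_redundant(make_set(as.list(seqs)))
  expect_setequal(names(got$sequences), expected)

  # idempotent
  again <- merge_redundant(got$sequences)
  expect_identical(names(again$sequences), names(got$sequences))
  expect_equal(nrow(again$absorbed), 0)

  # order invariant
  perm <- sample(length(seqs))
  got2 <- merge_redundant(make_set(as.list(seqs[perm])))
  expect_setequal(names(got2$sequences), expected)

  expect_lte(length(got$sequences), length(seqs))
})

test_that("full curation recovers the planted truth labels", {
  com <- generate_genomes(n_viral = 20, n_contaminant = 8, seed = 13)
  cur <- curate_contigs(com$sequences, com$annotations, com$flags)
  truth_viral <- com$truth$genome_id[com$truth$role == "virus"]
  expect_setequal(names(cur$sequences), truth_viral)
  gone <- cur$report$contig_id[cur$report$decision %in%
                                 c("not_viral", "contaminant")]
  expect_true(all(com$truth$role[match(gone, com$truth$genome_id)] != "virus"))
})
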