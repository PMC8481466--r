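#' Discard contigs below a minimum length
#'
#' @param contigs [Biostrings::DNAStringSet].
#' @param min_len minimum retained length in bp; the boundary is inclusive
#'   (contigs strictly shorter are discarded).
#' @return the surviving subset, input order preserved.
#' @export
length_filter <- function(contigs, min_len = 1000) {
  if (length(contigs) == 0) {
    warning("empty contig set")
    return(contigs)
  }
  keep <- Biostrings::width(contigs) >= min_len
  if (!any(keep)) warning("no contigs survive the length filter")
  contigs[keep]
}

# longest proper border (prefix that equals a suffix) via the
# Knuth-Morris-Pratt prefix function
longest_border <- function(x) {
  s <- utf8ToInt(x)
  n <- length(s)
  pi <- integer(n)
  k <- 0L
  for (i in 2:n) {
    while (k > 0L && s[k + 1L] != s[i]) k <- pi[k]
    if (s[k + 1L] == s[i]) k <- k + 1L
    pi[i] <- k
  }
  pi[n]
}

#' Detect circular contigs from their sequence termini
#'
#' A contig is called circular when a prefix of length at least `k_min`
#' exactly matches a suffix (a terminal direct repeat, the signature left by
#' linearizing a circular assembly). Internal repeats do not qualify.
#'
#' @param contigs [Biostrings::DNAStringSet] (or a single character string).
#' @param k_min minimum terminal-repeat length in bp.
#' @return character vector of "circular"/"linear", one per contig.
#' @export
detect_circularity <- function(contigs, k_min = 20) {
  if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(contigs)
  out <- character(length(contigs))
  sq <- as.character(contigs)
  for (i in seq_along(sq)) {
    if (nchar(sq[i]) < 2 * k_min) {
      warning(sprintf("contig %d shorter than 2*k_min; calling linear", i))
      out[i] <- "linear"
      next
    }
    out[i] <- if (longest_border(sq[i]) >= k_min) "circular" else "linear"
  }
  names(out) <- names(contigs)
  out
}

#' Required pVOG hit count for a contig length
#'
#' Tiered enrichment thresholds used to call contigs rich in viral
#' orthologous-group proteins: <5 kb needs >= 3 hits; 5-10 kb, 4; 10-20 kb,
#' 5; 20-40 kb, 6; 40-60 kb, 7; >= 60 kb, 8. Tiers are half-open on the
#' lower bound (5,000 bp falls in the 5-10 kb tier).
#'
#' @param length_bp contig length(s) in bp, each >= 1000.
#' @return integer vector of required hit counts.
#' @export
pvog_tier_threshold <- function(length_bp) {
  if (any(length_bp < 1000))
    stop("pVOG tiers are defined for contigs >= 1000 bp")
  breaks <- c(0, 5e3, 1e4, 2e4, 4e4, 6e4, Inf)
  vals <- c(3L, 4L, 5L, 6L, 7L, 8L)
  vals[findInterval(length_bp, breaks, rightmost.closed = FALSE)]
}

#' Assemble per-contig evidence records
#'
#' Combines contig properties (length, topology, sequencing source) with the
#' annotation table and externally supplied evidence flags into one row per
#' contig, the input to [classify_viral()] and [remove_contaminants()].
#'
#' @param contigs [Biostrings::DNAStringSet] of candidate contigs.
#' @param annotations data.frame(contig_id, protein_index, category, value,
#'   score) with category in pVOG/ribosomal/plasmid_rep/integrase/
#'   recombinase/family.
#' @param flags data.frame(contig_id, source, refseq_viral_hit,
#'   external_classifier_viral, dark_matter). Missing contigs default to
#'   source "viral_enriched" and all flags FALSE.
#' @param topology optional named character vector; computed with
#'   [detect_circularity()] when NULL.
#' @return data.frame, one row per contig, with the evidence fields.
#' @export
build_evidence <- function(contigs, annotations, flags = NULL,
                           topology = NULL) {
  ids <- names(contigs)
  if (is.null(ids)) stop("contigs must be named")
  if (is.null(topology)) topology <- detect_circularity(contigs)
  a <- annotations[annotations$contig_id %in% ids, , drop = FALSE]
  pvog <- table(factor(a$contig_id[a$category == "pVOG"], levels = ids))
  rib <- ids %in% a$contig_id[a$category == "ribosomal"]
  lys <- ids %in% a$contig_id[a$category %in% c("integrase", "recombinase")]
  plas <- rep(NA_real_, length(ids))
  pa <- a[a$category == "plasmid_rep", , drop = FALSE]
  if (nrow(pa)) {
    mx <- tapply(pa$score, pa$contig_id, max)
    plas[match(names(mx), ids)] <- as.numeric(mx)
  }
  ev <- data.frame(
    contig_id = ids,
    length_bp = Biostrings::width(contigs),
    topology = unname(topology[ids]),
    source = "viral_enriched",
    refseq_viral_hit = FALSE,
    external_classifier_viral = FALSE,
    dark_matter = FALSE,
    pvog_hit_count = as.integer(pvog[ids]),
    ribosomal_hit = rib,
    plasmid_rep_hit_score = plas,
    integrase_or_recombinase = lys,
    stringsAsFactors = FALSE)
  if (!is.null(flags)) {
    m <- match(ids, flags$contig_id)
    ok <- !is.na(m)
    ev$source[ok] <- flags$source[m[ok]]
    ev$refseq_viral_hit[ok] <- flags$refseq_viral_hit[m[ok]]
    ev$external_classifier_viral[ok] <- flags$external_classifier_viral[m[ok]]
    ev$dark_matter[ok] <- flags$dark_matter[m[ok]]
  }
  ev
}

#' Pool viral evidence into a per-contig viral call
#'
#' A contig is called viral if any of the pooled lines of evidence holds:
#' a viral RefSeq hit; circular topology in the viral-enriched fraction
#' (circular contigs from virome sequencing are taken as viral); an external
#' viral classifier call; dark matter (no reference-database hit) from the
#' viral-enriched fraction; or a pVOG hit count meeting the length-tiered
#' threshold of [pvog_tier_threshold()]. Pooling is a set union, so adding
#' evidence can only add calls.
#'
#' @param evidence data.frame from [build_evidence()].
#' @return logical vector named by contig_id.
#' @export
classify_viral <- function(evidence) {
  v <- evidence$refseq_viral_hit |
    (evidence$topology == "circular" & evidence$source == "viral_enriched") |
    evidence$external_classifier_viral |
    (evidence$dark_matter & evidence$source == "viral_enriched") |
    (evidence$pvog_hit_count >= pvog_tier_threshold(evidence$length_bp))
  names(v) <- evidence$contig_id
  v
}

#' Remove contaminant contigs from a viral set
#'
#' Contigs encoding ribosomal proteins are removed outright; contigs with a
#' plasmid replication-protein HMM hit scoring at least `plasmid_score_min`
#' are likewise discarded.
#'
#' @param viral_ids character vector of contig ids called viral.
#' @param evidence data.frame from [build_evidence()].
#' @param plasmid_score_min HMM score at or above which a plasmid
#'   replication hit disqualifies a contig.
#' @return list with `kept` (character vector) and `removed`
#'   (data.frame contig_id, reason).
#' @export
remove_contaminants <- function(viral_ids, evidence, plasmid_score_min = 15) {
  m <- match(viral_ids, evidence$contig_id)
  rib <- evidence$ribosomal_hit[m]
  plas <- !is.na(evidence$plasmid_rep_hit_score[m]) &
    evidence$plasmid_rep_hit_score[m] >= plasmid_score_min
  reason <- ifelse(rib, "ribosomal_protein",
                   ifelse(plas, "plasmid_replication", NA_character_))
  removed <- data.frame(contig_id = viral_ids[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  list(kept = viral_ids[is.na(reason)], removed = removed)
}

# k-mer sets for the seed prefilter (forward strand)
kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

# local alignment between candidate pair; returns TRUE when identity and
# containment coverage of the shorter sequence meet the thresholds
is_homologous_pair <- function(long_seq, short_seq, identity_min,
                               coverage_min) {
  test_one <- function(p) {
    al <- Biostrings::pairwiseAlignment(
      pattern = p, subject = long_seq, type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -2, baseOnly = TRUE),
      gapOpening = 5, gapExtension = 2)
    alen <- nchar(as.character(Biostrings::alignedPattern(al)))
    if (alen == 0) return(FALSE)
    ident <- Biostrings::nmatch(al) / alen
    cover <- (Biostrings::nmatch(al) + Biostrings::nmismatch(al)) /
      nchar(short_seq)
    ident >= identity_min && cover >= coverage_min
  }
  test_one(short_seq) || test_one(reverse_complement_chr(short_seq))
}

#' Collapse redundant sequences, retaining the larger of homologous pairs
#'
#' Greedy nonredundancy merge: sequences are visited longest-first (ties
#' broken by lexicographic id) and each is kept only if it is not homologous
#' to an already-kept sequence. Homology means pairwise identity of at least
#' `identity_min` over at least `coverage_min` of the shorter sequence
#' (containment), assessed by k-mer-seeded local alignment on both strands.
#' Exact duplicates collapse to one; the result is invariant to input order.
#'
#' @param contigs named [Biostrings::DNAStringSet].
#' @param identity_min minimum pairwise identity (default 0.90).
#' @param coverage_min minimum fraction of the shorter sequence aligned
#'   (default 0.90).
#' @param seed_k k-mer size of the candidate-pair prefilter.
#' @param min_seed_hits pairs sharing fewer than this many `seed_k`-mers
#'   (either strand) are never aligned; homologous pairs at the 90%/90%
#'   thresholds share hundreds, while chance sharing between unrelated
#'   sequences rarely exceeds one or two.
#' @return list with `sequences` (survivors, original relative order) and
#'   `absorbed` (data.frame contig_id, absorbed_by).
#' @export
merge_redundant <- function(contigs, identity_min = 0.90,
                            coverage_min = 0.90, seed_k = 15,
                            min_seed_hits = 8) {
  ids <- names(contigs)
  if (is.null(ids) || anyDuplicated(ids))
    stop("contigs must have unique names")
  sq <- as.character(contigs)
  n <- length(sq)
  if (n <= 1) return(list(sequences = contigs,
                          absorbed = data.frame(contig_id = character(0),
                                                absorbed_by = character(0))))
  ord <- order(-nchar(sq), ids)
  kmers <- lapply(sq, function(s)
    unique(c(kmer_set(s, seed_k), kmer_set(reverse_complement_chr(s), seed_k))))
  kept <- integer(0)
  absorbed_by <- rep(NA_character_, n)
  for (i in ord) {
    owner <- NA_character_
    for (j in kept) {
      if (sum(kmers[[i]] %in% kmers[[j]]) < min_seed_hits) next
      if (sq[i] == sq[j] ||
          is_homologous_pair(sq[j], sq[i], identity_min, coverage_min)) {
        owner <- ids[j]
        break
      }
    }
    if (is.na(owner)) kept <- c(kept, i) else absorbed_by[i] <- owner
  }
  keep_mask <- seq_len(n) %in% kept
  list(sequences = contigs[keep_mask],
       absorbed = data.frame(contig_id = ids[!keep_mask],
                             absorbed_by = absorbed_by[!keep_mask],
                             stringsAsFactors = FALSE))
}

#' Curate an assembled contig set into a nonredundant viral database
#'
#' Runs the full curation chain: length filter, circularity detection,
#' evidence assembly, pooled viral classification, contaminant removal and
#' redundancy merging. Returns the surviving sequences together with a
#' per-contig report recording each decision and its reason.
#'
#' @param contigs named [Biostrings::DNAStringSet] of assembled contigs.
#' @param annotations annotation table (see [build_evidence()]).
#' @param flags evidence-flag table (see [build_evidence()]), or NULL.
#' @param min_len minimum contig length in bp.
#' @param k_min minimum terminal-repeat length for circularity.
#' @param identity_min,coverage_min redundancy-merge thresholds.
#' @param plasmid_score_min plasmid-hit score cutoff for removal.
#' @return list with `sequences` (curated viral [Biostrings::DNAStringSet]),
#'   `evidence` (the evidence table), and `report` (data.frame contig_id,
#'   decision in retained/short/not_viral/contaminant/redundant, detail).
#' @export
curate_contigs <- function(contigs, annotations, flags = NULL,
                           min_len = 1000, k_min = 20,
                           identity_min = 0.90, coverage_min = 0.90,
                           plasmid_score_min = 15) {
  ids <- names(contigs)
  report <- data.frame(contig_id = ids, decision = NA_character_,
                       detail = "", stringsAsFactors = FALSE)
  mark <- function(rep, id, decision, detail = "") {
    i <- match(id, rep$contig_id)
    rep$decision[i] <- decision; rep$detail[i] <- detail
    rep
  }

  long <- suppressWarnings(length_filter(contigs, min_len))
  for (id in setdiff(ids, names(long)))
    report <- mark(report, id, "short", sprintf("< %d bp", min_len))

  topo <- detect_circularity(long, k_min)
  ev <- build_evidence(long, annotations, flags, topology = topo)
  viral <- classify_viral(ev)
  for (id in names(viral)[!viral])
    report <- mark(report, id, "not_viral", "no pooled viral evidence")

  cont <- remove_contaminants(names(viral)[viral], ev, plasmid_score_min)
  for (i in seq_len(nrow(cont$removed)))
    report <- mark(report, cont$removed$contig_id[i], "contaminant",
                   cont$removed$reason[i])

  merged <- merge_redundant(long[cont$kept], identity_min, coverage_min)
  for (i in seq_len(nrow(merged$absorbed)))
    report <- mark(report, merged$absorbed$contig_id[i], "redundant",
                   paste0("absorbed_by=", merged$absorbed$absorbed_by[i]))
  for (id in names(merged$sequences))
    report <- mark(report, id, "retained", topo[id])

  list(sequences = merged$sequences, evidence = ev, report = report)
}
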