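#' Generate a synthetic faecal virome community with known ground truth
#'
#' Builds a set of phage-like genomes plus bacterial and plasmid contaminants,
#' together with the per-contig protein annotation table and the evidence
#' flags that the curation stage consumes. Every downstream rule of the
#' pipeline (tiered viral-protein enrichment, circularity detection,
#' contaminant removal, lysogeny labelling, family voting, gene-sharing
#' clustering) can recover the planted truth labels, which makes the
#' generator the reference fixture for round-trip testing.
#'
#' Circular genomes are emitted in linearized form with their first
#' `dup_len` bases duplicated at the 3' terminus, the signature the
#' circularity detector looks for. Bacterial contaminants carry ribosomal
#' protein annotations and an embedded copy of a `cpn60`-like marker gene;
#' plasmid contaminants carry a plasmid replication-protein hit with an HMM
#' score of at least 15. Viral genomes in the same planted cluster share a
#' core set of viral orthologous-group (pVOG) identifiers.
#'
#' @param n_viral number of viral genomes.
#' @param n_contaminant number of contaminant genomes.
#' @param length_range two-element numeric, min/max genome length in bp
#'   (uniform draw); must be >= 1000.
#' @param circular_fraction probability that a viral genome is circular.
#' @param lysogenic_fraction probability that a viral genome carries an
#'   integrase or recombinase gene.
#' @param plasmid_fraction probability that a contaminant is a plasmid
#'   rather than a bacterial chromosome fragment.
#' @param n_clusters number of planted viral clusters (pseudogenera).
#' @param clustered_fraction fraction of viral genomes assigned to clusters.
#' @param dup_len length of the terminal duplication marking circular
#'   genomes; shared constant with [detect_circularity()].
#' @param marker_len length of the synthetic `cpn60`-like marker gene.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return object of class `virome_community`: list with elements
#'   `sequences` ([Biostrings::DNAStringSet] of emitted contigs), `truth`
#'   (data.frame: genome_id, length_bp, topology, lifestyle, role,
#'   family_label, cluster_label), `annotations` (data.frame: contig_id,
#'   protein_index, category, value, score), `flags` (data.frame of
#'   per-contig evidence booleans and source), and `marker_db`
#'   ([Biostrings::DNAStringSet] with the marker gene).
#' @export
generate_genomes <- function(n_viral = 50, n_contaminant = 10,
                             length_range = c(1500, 12000),
                             circular_fraction = 0.1,
                             lysogenic_fraction = 0.2,
                             plasmid_fraction = 0.4,
                             n_clusters = 8, clustered_fraction = 0.6,
                             dup_len = 20, marker_len = 1600,
                             seed = NULL) {
  stopifnot_scalar_count(n_viral, "n_viral")
  stopifnot_scalar_count(n_contaminant, "n_contaminant")
  if (n_viral + n_contaminant <= 0)
    stop("at least one genome must be requested")
  if (any(c(circular_fraction, lysogenic_fraction, plasmid_fraction,
            clustered_fraction) < 0) ||
      any(c(circular_fraction, lysogenic_fraction, plasmid_fraction,
            clustered_fraction) > 1))
    stop("fractions must lie in [0, 1]")
  if (length(length_range) != 2L || min(length_range) < 1000)
    stop("length_range must be a [min, max] interval with min >= 1000")

  with_seed(seed, {
    families <- c("Siphoviridae", "Myoviridae", "Podoviridae", "Microviridae")
    marker <- random_dna(marker_len)

    ids <- character(0); seqs <- character(0)
    truth <- list(); ann <- list(); flags <- list()
    fresh_vog <- function(n) sprintf("VOG%07d", sample.int(9999999L, n))
    # pVOG core vocabulary per planted cluster; members draw 4 of 6 core
    # identifiers so any two members share >= 2 protein families
    cluster_core <- replicate(max(n_clusters, 1L), fresh_vog(6L),
                              simplify = FALSE)

    n_clustered <- round(n_viral * clustered_fraction)
    cluster_of <- rep(NA_integer_, n_viral)
    if (n_viral > 0 && n_clustered > 0 && n_clusters > 0) {
      idx <- seq_len(n_clustered)
      cluster_of[idx] <- rep_len(seq_len(n_clusters), n_clustered)
    }

    for (i in seq_len(n_viral)) {
      id <- sprintf("vir_%03d", i)
      L <- round(runif(1, length_range[1], length_range[2]))
      circ <- runif(1) < circular_fraction
      lys <- runif(1) < lysogenic_fraction
      genome <- random_dna(L)
      emitted <- if (circ) paste0(genome, substr(genome, 1, dup_len)) else genome
      fam <- sample(families, 1)
      cl <- cluster_of[i]

      tier <- pvog_tier_threshold(nchar(emitted))
      n_pvog <- max(tier + rpois(1, 2), 4L)
      if (!is.na(cl)) {
        vogs <- c(sample(cluster_core[[cl]], 4L), fresh_vog(n_pvog - 4L))
      } else {
        vogs <- fresh_vog(n_pvog)
      }
      rows <- data.frame(
        contig_id = id,
        protein_index = seq_along(vogs),
        category = "pVOG", value = vogs,
        score = round(runif(length(vogs), 20, 200), 1),
        stringsAsFactors = FALSE)
      nfam <- 3L
      fam_rows <- data.frame(
        contig_id = id, protein_index = max(rows$protein_index) + seq_len(nfam),
        category = "family", value = fam,
        score = round(runif(nfam, 30, 150), 1), stringsAsFactors = FALSE)
      if (runif(1) < 0.2) {
        fam_rows <- rbind(fam_rows, data.frame(
          contig_id = id, protein_index = max(fam_rows$protein_index) + 1L,
          category = "family", value = sample(setdiff(families, fam), 1),
          score = round(runif(1, 30, 150), 1), stringsAsFactors = FALSE))
      }
      rows <- rbind(rows, fam_rows)
      if (lys) {
        rows <- rbind(rows, data.frame(
          contig_id = id, protein_index = max(rows$protein_index) + 1L,
          category = sample(c("integrase", "recombinase"), 1), value = "",
          score = round(runif(1, 25, 120), 1), stringsAsFactors = FALSE))
      }

      src <- if (runif(1) < 0.85) "viral_enriched" else "wgs"
      refseq <- runif(1) < 0.5
      classifier <- runif(1) < 0.4
      dark <- !refseq && !classifier && runif(1) < 0.5

      ids <- c(ids, id); seqs <- c(seqs, emitted)
      truth[[id]] <- data.frame(
        genome_id = id, length_bp = nchar(emitted),
        topology = if (circ) "circular" else "linear",
        lifestyle = if (lys) "lysogenic" else "unknown",
        role = "virus", family_label = fam,
        cluster_label = if (is.na(cl)) id else sprintf("cluster_%02d", cl),
        stringsAsFactors = FALSE)
      ann[[id]] <- rows
      flags[[id]] <- data.frame(
        contig_id = id, source = src, refseq_viral_hit = refseq,
        external_classifier_viral = classifier, dark_matter = dark,
        stringsAsFactors = FALSE)
    }

    for (i in seq_len(n_contaminant)) {
      id <- sprintf("cont_%03d", i)
      is_plasmid <- runif(1) < plasmid_fraction
      L <- round(runif(1, length_range[1], length_range[2]))
      L <- max(L, marker_len + 200)
      genome <- random_dna(L)
      circ <- is_plasmid && runif(1) < 0.5
      if (!is_plasmid) {
        # embed the marker gene so virome reads from this genome register
        # in the marker-based contamination estimate
        at <- sample.int(L - marker_len + 1L, 1)
        substr(genome, at, at + marker_len - 1L) <- marker
      }
      emitted <- if (circ) paste0(genome, substr(genome, 1, dup_len)) else genome

      n_pvog <- sample(0:2, 1)
      rows <- NULL
      if (n_pvog > 0) {
        rows <- data.frame(
          contig_id = id, protein_index = seq_len(n_pvog),
          category = "pVOG", value = fresh_vog(n_pvog),
          score = round(runif(n_pvog, 20, 80), 1), stringsAsFactors = FALSE)
      }
      nxt <- if (is.null(rows)) 0L else max(rows$protein_index)
      if (is_plasmid) {
        extra <- data.frame(
          contig_id = id, protein_index = nxt + 1L,
          category = "plasmid_rep", value = "",
          score = round(runif(1, 15, 40), 1), stringsAsFactors = FALSE)
      } else {
        nrib <- sample(2:4, 1)
        extra <- data.frame(
          contig_id = id, protein_index = nxt + seq_len(nrib),
          category = "ribosomal", value = "",
          score = round(runif(nrib, 25, 200), 1), stringsAsFactors = FALSE)
      }
      rows <- rbind(rows, extra)

      ids <- c(ids, id); seqs <- c(seqs, emitted)
      truth[[id]] <- data.frame(
        genome_id = id, length_bp = nchar(emitted),
        topology = if (circ) "circular" else "linear",
        lifestyle = "unknown",
        role = if (is_plasmid) "plasmid_contaminant" else "bacterial_contaminant",
        family_label = "none", cluster_label = id, stringsAsFactors = FALSE)
      ann[[id]] <- rows
      flags[[id]] <- data.frame(
        contig_id = id,
        source = if (runif(1) < 0.5) "viral_enriched" else "wgs",
        refseq_viral_hit = FALSE, external_classifier_viral = FALSE,
        dark_matter = FALSE, stringsAsFactors = FALSE)
    }

    sequences <- Biostrings::DNAStringSet(seqs)
    names(sequences) <- ids
    out <- list(
      sequences = sequences,
      truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
      annotations = do.call(rbind, c(ann, list(make.row.names = FALSE))),
      flags = do.call(rbind, c(flags, list(make.row.names = FALSE))),
      marker_db = {
        m <- Biostrings::DNAStringSet(marker); names(m) <- "cpn60_marker"; m
      },
      dup_len = dup_len)
    class(out) <- "virome_community"
    out
  })
}

#' @export
print.virome_community <- function(x, ...) {
  cat(sprintf("virome_community: %d genomes (%d viral, %d contaminant)\n",
              nrow(x$truth), sum(x$truth$role == "virus"),
              sum(x$truth$role != "virus")))
  cat(sprintf("  length range %d-%d bp; %d circular; %d lysogenic\n",
              min(x$truth$length_bp), max(x$truth$length_bp),
              sum(x$truth$topology == "circular"),
              sum(x$truth$lifestyle == "lysogenic")))
  invisible(x)
}

#' Describe a longitudinal study design for read simulation
#'
#' Encodes the repeated-sampling layout used throughout the package: six
#' treatment arms, three timepoints (pre-treatment baseline and one and five
#' months post-treatment) and animals housed in two cages per arm. Baseline
#' genome abundances default to a log-normal profile, the heavy-tailed shape
#' typical of faecal viromes. Treatment effects are expressed as log2 fold
#' changes applied to specific (genome, treatment, timepoint) cells.
#'
#' @param genome_ids character vector of genome identifiers to simulate.
#' @param treatments character vector of treatment-arm names.
#' @param n_animals_per_treatment animals per arm (split over two cages).
#' @param timepoints ordered character vector; first element is the baseline.
#' @param baseline_abundances positive numeric named by genome_id, or NULL
#'   for a log-normal draw (meanlog 0, sdlog 1.5).
#' @param effect_table data.frame(genome_id, treatment, timepoint, log2fc)
#'   or NULL for no treatment effects.
#' @param dispersion negative-binomial overdispersion of per-genome counts.
#' @param reads_per_sample reads emitted per sample (exactly).
#' @param read_length read length in nt.
#' @param seed integer seed governing all randomness downstream of the design.
#' @return object of class `community_design` with a `metadata` data.frame
#'   (sample_id, animal_id, cage_id, treatment, timepoint).
#' @export
community_design <- function(genome_ids,
                             treatments = c("Sham", "LPS", "monomer",
                                            "monomer_LPS", "PFF", "PFF_LPS"),
                             n_animals_per_treatment = 6,
                             timepoints = c("Base", "T1", "T5"),
                             baseline_abundances = NULL,
                             effect_table = NULL,
                             dispersion = 0.1,
                             reads_per_sample = 20000,
                             read_length = 150,
                             seed = NULL) {
  stopifnot(length(genome_ids) > 0, !anyDuplicated(genome_ids))
  if (is.null(baseline_abundances)) {
    baseline_abundances <- with_seed(
      if (is.null(seed)) NULL else seed + 1L,
      stats::rlnorm(length(genome_ids), meanlog = 0, sdlog = 1.5))
    names(baseline_abundances) <- genome_ids
  }
  if (is.null(names(baseline_abundances)))
    names(baseline_abundances) <- genome_ids
  if (!all(genome_ids %in% names(baseline_abundances)))
    stop("baseline_abundances must cover every genome_id")
  if (any(baseline_abundances <= 0))
    stop("baseline abundances must be strictly positive")
  if (!is.null(effect_table)) {
    need <- c("genome_id", "treatment", "timepoint", "log2fc")
    if (!all(need %in% names(effect_table)))
      stop("effect_table needs columns genome_id, treatment, timepoint, log2fc")
    if (!all(effect_table$genome_id %in% genome_ids))
      stop("effect_table references unknown genome_ids")
    if (!all(effect_table$treatment %in% treatments))
      stop("effect_table references unknown treatments")
    if (!all(effect_table$timepoint %in% timepoints))
      stop("effect_table references unknown timepoints")
  }
  if (dispersion < 0) stop("dispersion must be non-negative")

  # two cages per treatment, animals split between them; animal ids use
  # the cage-rat convention C<cage>-R<rat>
  meta <- list()
  cage_no <- 0L
  for (tr in seq_along(treatments)) {
    n <- n_animals_per_treatment
    per_cage <- c(ceiling(n / 2), floor(n / 2))
    for (cg in 1:2) {
      cage_no <- cage_no + 1L
      for (r in seq_len(per_cage[cg])) {
        animal <- sprintf("C%02d-R%d", cage_no, r)
        for (tp in timepoints) {
          meta[[length(meta) + 1L]] <- data.frame(
            sample_id = paste(animal, tp, sep = "_"),
            animal_id = animal, cage_id = sprintf("C%02d", cage_no),
            treatment = treatments[tr], timepoint = tp,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- list(genome_ids = genome_ids,
              treatments = treatments,
              timepoints = timepoints,
              baseline_abundances = baseline_abundances[genome_ids],
              effect_table = effect_table,
              dispersion = dispersion,
              reads_per_sample = reads_per_sample,
              read_length = read_length,
              seed = seed,
              metadata = do.call(rbind, c(meta, list(make.row.names = FALSE))))
  class(out) <- "community_design"
  out
}

#' @export
print.community_design <- function(x, ...) {
  cat(sprintf(
    "community_design: %d genomes, %d treatments x %d timepoints, %d samples\n",
    length(x$genome_ids), length(x$treatments), length(x$timepoints),
    nrow(x$metadata)))
  cat(sprintf("  %d reads/sample (len %d), NB dispersion %.3g, %d effects\n",
              x$reads_per_sample, x$read_length, x$dispersion,
              if (is.null(x$effect_table)) 0L else nrow(x$effect_table)))
  invisible(x)
}

# expected (relative) abundance of each genome in one sample
expected_abundance <- function(design, treatment, timepoint) {
  lam <- design$baseline_abundances
  et <- design$effect_table
  if (!is.null(et)) {
    hit <- et$treatment == treatment & et$timepoint == timepoint
    if (any(hit)) {
      idx <- match(et$genome_id[hit], names(lam))
      lam[idx] <- lam[idx] * 2^et$log2fc[hit]
    }
  }
  lam
}

#' Simulate error-free shotgun reads from a synthetic community
#'
#' Per-sample genome counts follow a Gamma-Poisson (negative-binomial)
#' abundance model: expected abundances are the design baselines scaled by
#' `2^log2fc` for perturbed (treatment, timepoint) cells, multiplied by
#' Gamma-distributed noise with the design's dispersion, and the fixed read
#' budget is then allocated multinomially so each sample emits exactly
#' `reads_per_sample` reads. Reads are error-free substrings drawn with
#' uniform start positions; on circular genomes starts may wrap across the
#' junction.
#'
#' @param community a `virome_community` from [generate_genomes()].
#' @param design a `community_design`.
#' @param samples optional character vector restricting which sample_ids to
#'   simulate (all by default).
#' @return list with `reads` (named list of [Biostrings::DNAStringSet], one
#'   per sample), `counts` (integer matrix genomes x samples, the truth
#'   table) and `metadata`.
#' @export
simulate_reads <- function(community, design, samples = NULL) {
  stopifnot(inherits(community, "virome_community"),
            inherits(design, "community_design"))
  if (!all(design$genome_ids %in% names(community$sequences)))
    stop("design references genomes absent from the community")
  meta <- design$metadata
  if (!is.null(samples)) meta <- meta[meta$sample_id %in% samples, , drop = FALSE]
  r <- design$read_length
  if (design$reads_per_sample == 0)
    warning("reads_per_sample is 0; emitting empty samples")

  seqs <- as.character(community$sequences[design$genome_ids])
  circular <- community$truth$topology[match(design$genome_ids,
                                             community$truth$genome_id)] ==
    "circular"
  dup <- community$dup_len
  # pre-extend sequences so uniform circular starts can wrap the junction
  tmpl <- character(length(seqs)); npos <- integer(length(seqs))
  for (g in seq_along(seqs)) {
    if (circular[g]) {
      underlying <- substr(seqs[g], 1, nchar(seqs[g]) - dup)
      tmpl[g] <- paste0(underlying, substr(underlying, 1, r - 1))
      npos[g] <- nchar(underlying)
    } else {
      tmpl[g] <- seqs[g]
      npos[g] <- nchar(seqs[g]) - r + 1L
    }
  }

  counts <- matrix(0L, nrow = length(design$genome_ids), ncol = nrow(meta),
                   dimnames = list(design$genome_ids, meta$sample_id))
  reads <- vector("list", nrow(meta)); names(reads) <- meta$sample_id

  with_seed(design$seed, {
    for (s in seq_len(nrow(meta))) {
      lam <- expected_abundance(design, meta$treatment[s], meta$timepoint[s])
      if (design$dispersion > 0) {
        w <- rgamma(length(lam), shape = 1 / design$dispersion,
                    scale = lam * design$dispersion)
        w[w <= 0 | !is.finite(w)] <- .Machine$double.xmin
      } else w <- lam
      n <- design$reads_per_sample
      cnt <- if (n > 0) as.integer(rmultinom(1, n, prob = w)) else
        integer(length(lam))
      counts[, s] <- cnt
      if (n == 0) {
        rs <- Biostrings::DNAStringSet(character(0))
      } else {
        pieces <- character(n); k <- 0L
        for (g in which(cnt > 0L)) {
          starts <- sample.int(npos[g], cnt[g], replace = TRUE)
          pieces[k + seq_len(cnt[g])] <-
            substring(tmpl[g], starts, starts + r - 1L)
          k <- k + cnt[g]
        }
        rs <- Biostrings::DNAStringSet(pieces)
        names(rs) <- sprintf("%s_r%06d", meta$sample_id[s], seq_len(n))
      }
      reads[[s]] <- rs
    }
  })
  list(reads = reads, counts = counts, metadata = meta)
}

#' Write a simulated community to disk as plain-text files
#'
#' Emits genome FASTA, per-sample read FASTA, annotation/flags/truth/metadata
#' TSVs and the marker-gene FASTA under `dir`.
#'
#' @param community `virome_community`.
#' @param sim result of [simulate_reads()], or NULL to skip reads.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_community <- function(community, sim = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(community$sequences,
                              file.path(dir, "genomes.fasta"))
  Biostrings::writeXStringSet(community$marker_db,
                              file.path(dir, "marker.fasta"))
  write_tsv(community$truth, file.path(dir, "truth.tsv"))
  write_tsv(community$annotations, file.path(dir, "annotations.tsv"))
  write_tsv(community$flags, file.path(dir, "flags.tsv"))
  if (!is.null(sim)) {
    rd <- file.path(dir, "reads"); dir.create(rd, showWarnings = FALSE)
    for (s in names(sim$reads))
      Biostrings::writeXStringSet(sim$reads[[s]],
                                  file.path(rd, paste0(s, ".fasta")))
    write_tsv(sim$metadata, file.path(dir, "metadata.tsv"))
    cnt <- data.frame(genome_id = rownames(sim$counts), sim$counts,
                      check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(cnt, file.path(dir, "truth_counts.tsv"))
  }
  invisible(dir)
}
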