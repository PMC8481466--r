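#' Pipeline configuration with the study's printed thresholds as defaults
#'
#' Central configuration for [run_pipeline()]. Threshold defaults are the
#' analysis constants of the underlying protocol: 1000 bp minimum contig
#' length, 90% identity / 90% coverage redundancy merging, 20 bp terminal
#' repeat for circularity, minimum three reads with tiered breadth for
#' presence, plasmid-hit score 15 for removal, and an adjusted-p
#' significance threshold of 1e-5 for differential abundance.
#'
#' @param contigs,annotations,flags,reads_dir,metadata,marker input paths
#'   (FASTA / TSV; `reads_dir` holds one `<sample_id>.fasta` per sample).
#' @param out_dir output directory for stage artifacts.
#' @param min_len,k_min,identity_min,coverage_min,plasmid_score_min,min_reads,min_shared,alpha
#'   analysis thresholds (see Details).
#' @param call_orfs whether the annotation stage also calls ORFs.
#' @param seed integer seed governing the permutation stream.
#' @param stages character vector of stages to run, in order.
#' @return named list of class `virome_config`.
#' @export
virome_config <- function(contigs = NULL, annotations = NULL, flags = NULL,
                          reads_dir = NULL, metadata = NULL, marker = NULL,
                          out_dir = "virome_out",
                          min_len = 1000, k_min = 20,
                          identity_min = 0.90, coverage_min = 0.90,
                          plasmid_score_min = 15, min_reads = 3,
                          min_shared = 2, alpha = 1e-5,
                          call_orfs = TRUE, seed = 1,
                          stages = c("curation", "annotation", "clustering",
                                     "abundance", "diversity",
                                     "differential_abundance",
                                     "concordance")) {
  cfg <- list(contigs = contigs, annotations = annotations, flags = flags,
              reads_dir = reads_dir, metadata = metadata, marker = marker,
              out_dir = out_dir, min_len = min_len, k_min = k_min,
              identity_min = identity_min, coverage_min = coverage_min,
              plasmid_score_min = plasmid_score_min, min_reads = min_reads,
              min_shared = min_shared, alpha = alpha, call_orfs = call_orfs,
              seed = seed, stages = stages)
  class(cfg) <- "virome_config"
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' Fields present in the file override [virome_config()] defaults; every
#' override is echoed in the run log.
#'
#' @param path YAML file.
#' @return `virome_config` list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- virome_config()
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(user)] <- user
  attr(cfg, "overrides") <- names(user)
  cfg
}

# hash of the scientific configuration (thresholds, seed, stages); input
# and output locations are deployment detail and do not change the hash
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg[c("contigs", "annotations", "flags", "reads_dir", "metadata",
        "marker", "out_dir")] <- NULL
  tmp <- tempfile()
  writeLines(yaml::as.yaml(cfg), tmp)
  h <- unname(tools::md5sum(tmp))
  unlink(tmp)
  h
}

#' Run the virome analysis pipeline end to end
#'
#' Executes the enabled stages in order: curation -> annotation ->
#' clustering -> abundance -> diversity -> differential abundance ->
#' concordance, writing each stage's artifacts as TSV/FASTA under
#' `config$out_dir` together with a manifest carrying the configuration
#' hash. A rerun with the same inputs, configuration and seed is
#' byte-identical. A stage failure aborts with the failing stage named;
#' artifacts of completed stages are retained.
#'
#' @param config a `virome_config` (see [virome_config()], [load_config()]).
#' @return invisible list of in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "virome_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  log_lines <- c("viromeflow run", paste0("config_hash: ", hash), "",
                 "configuration:",
                 strsplit(yaml::as.yaml(unclass(config)), "\n")[[1]])
  ov <- attr(config, "overrides")
  if (length(ov)) log_lines <- c(log_lines, "",
                                 paste0("overridden fields: ",
                                        paste(ov, collapse = ", ")))
  artifacts <- character(0)
  emit <- function(x, name) {
    p <- file.path(out, name)
    if (inherits(x, "DNAStringSet")) Biostrings::writeXStringSet(x, p)
    else write_tsv(x, p)
    artifacts <<- c(artifacts, name)
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  need <- function(paths, stage_name) {
    miss <- paths[!vapply(paths, function(p) !is.null(p) && file.exists(p),
                          logical(1))]
    if (length(miss))
      stop(sprintf("pipeline stage '%s' aborted: missing input(s): %s",
                   stage_name, paste(unlist(miss), collapse = ", ")),
           call. = FALSE)
  }
  res <- list()
  st <- config$stages

  # ---- curation ----------------------------------------------------------
  need(list(config$contigs, config$annotations), "curation")
  contigs <- Biostrings::readDNAStringSet(config$contigs)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  annotations <- read_tsv(config$annotations)
  flags <- if (!is.null(config$flags) && file.exists(config$flags))
    read_tsv(config$flags) else NULL
  if ("curation" %in% st) {
    res$curation <- stage("curation", curate_contigs(
      contigs, annotations, flags,
      min_len = config$min_len, k_min = config$k_min,
      identity_min = config$identity_min, coverage_min = config$coverage_min,
      plasmid_score_min = config$plasmid_score_min))
    emit(res$curation$sequences, "viral_db.fasta")
    emit(res$curation$report, "curation_report.tsv")
    emit(res$curation$evidence, "evidence.tsv")
  }
  viral <- res$curation$sequences
  viral_ids <- names(viral)
  topo <- res$curation$evidence$topology
  names(topo) <- res$curation$evidence$contig_id

  # ---- annotation --------------------------------------------------------
  if ("annotation" %in% st) {
    res$annotation <- stage("annotation", {
      lf <- assign_lifestyle(viral_ids, annotations)
      fam <- assign_family(viral_ids, annotations)
      orfs <- NULL
      if (isTRUE(config$call_orfs)) {
        orfs <- do.call(rbind, lapply(viral_ids, function(id)
          find_orfs(viral[[id]], contig_id = id)))
      }
      list(lifestyle = lf, family = fam, orfs = orfs)
    })
    emit(merge(res$annotation$lifestyle, res$annotation$family,
               by = "contig_id"), "lifestyle_family.tsv")
    if (!is.null(res$annotation$orfs))
      write_orfs_gff3(res$annotation$orfs, file.path(out, "orfs.gff3"))
  }

  # ---- clustering --------------------------------------------------------
  if ("clustering" %in% st) {
    res$clustering <- stage("clustering", {
      g <- shared_gene_graph(viral_ids, annotations, config$min_shared)
      list(graph = g, map = cluster_graph(g))
    })
    emit(res$clustering$map, "cluster_map.tsv")
    emit(res$clustering$graph$edges, "gene_sharing_edges.tsv")
  }

  # ---- abundance ---------------------------------------------------------
  if ("abundance" %in% st) {
    need(list(config$reads_dir, config$metadata), "abundance")
    metadata <- read_tsv(config$metadata)
    res$metadata <- metadata
    res$abundance <- stage("abundance", {
      files <- file.path(config$reads_dir,
                         paste0(metadata$sample_id, ".fasta"))
      if (!all(file.exists(files)))
        stop("read FASTA missing for some samples")
      reads <- lapply(files, Biostrings::readDNAStringSet)
      names(reads) <- metadata$sample_id
      ab <- abundance_table(reads, viral, topology = topo,
                            min_reads = config$min_reads)
      ab$clustered <- aggregate_clusters(ab$table, res$clustering$map)
      if (!is.null(config$marker) && file.exists(config$marker)) {
        mdb <- Biostrings::readDNAStringSet(config$marker)
        ab$marker_fraction <- data.frame(
          sample_id = metadata$sample_id,
          fraction = vapply(reads, function(r)
            suppressWarnings(marker_contamination_fraction(r, mdb)),
            numeric(1)), stringsAsFactors = FALSE)
      }
      ab
    })
    as_df <- function(m, key) data.frame(group_id = rownames(m), m,
                                         check.names = FALSE,
                                         stringsAsFactors = FALSE)
    emit(as_df(res$abundance$table), "counts_contigs.tsv")
    emit(as_df(res$abundance$clustered), "counts_groups.tsv")
    emit(res$abundance$coverage, "coverage.tsv")
    if (!is.null(res$abundance$marker_fraction))
      emit(res$abundance$marker_fraction, "marker_contamination.tsv")
  }

  # ---- diversity ---------------------------------------------------------
  if ("diversity" %in% st) {
    res$diversity <- stage("diversity", {
      tab <- res$abundance$clustered
      keep <- colSums(tab) > 0
      tab <- tab[, keep, drop = FALSE]
      md <- res$metadata[match(colnames(tab), res$metadata$sample_id), ]
      alpha_div <- data.frame(sample_id = colnames(tab),
                              shannon = apply(tab, 2, shannon),
                              stringsAsFactors = FALSE)
      bc <- bray_curtis_matrix(tab)
      ord <- pcoa(bc)
      pmv_time <- permanova(bc, md$timepoint, n_perm = 999,
                            seed = config$seed)
      by_treat <- lapply(split(seq_len(nrow(md)), md$treatment), function(i) {
        if (length(unique(md$timepoint[i])) < 2) return(NULL)
        permanova(bc[i, i], md$timepoint[i], n_perm = 999,
                  seed = config$seed)
      })
      long <- longitudinal_dissimilarity(tab, md)
      list(alpha = alpha_div, bc = bc, pcoa = ord, permanova_time = pmv_time,
           permanova_by_treatment = by_treat, longitudinal = long)
    })
    emit(res$diversity$alpha, "alpha_diversity.tsv")
    emit(data.frame(sample_id = rownames(res$diversity$bc),
                    res$diversity$bc, check.names = FALSE), "bray_curtis.tsv")
    emit(data.frame(sample_id = rownames(res$diversity$pcoa$points),
                    res$diversity$pcoa$points, check.names = FALSE),
         "pcoa_coordinates.tsv")
    emit(res$diversity$longitudinal$animals, "longitudinal_dissimilarity.tsv")
    pm <- res$diversity$permanova_time
    emit(data.frame(factor = "timepoint", R2 = pm$R2, F = pm$F, p = pm$p,
                    n_perm = pm$n_perm), "permanova.tsv")
  }

  # ---- differential abundance -------------------------------------------
  if ("differential_abundance" %in% st) {
    res$da <- stage("differential_abundance", differential_abundance(
      res$abundance$clustered, res$metadata, alpha = config$alpha))
    emit(res$da, "differential_abundance.tsv")
    volcano <- data.frame(group_id = res$da$group_id,
                          treatment = res$da$treatment,
                          contrast = res$da$contrast,
                          log2fc = res$da$log2fc,
                          neg_log10_p_adj = -log10(pmax(res$da$p_adj,
                                                        1e-300)))
    emit(volcano, "volcano.tsv")
  }

  # ---- concordance -------------------------------------------------------
  if ("concordance" %in% st) {
    res$concordance <- stage("concordance", concordance(res$da))
    if (nrow(res$concordance$records))
      emit(res$concordance$records, "concordance.tsv")
    emit(res$concordance$summary, "concordance_summary.tsv")
  }

  manifest <- data.frame(artifact = artifacts, config_hash = hash,
                         stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(out, "MANIFEST.tsv"))
  writeLines(c(log_lines, "", "artifacts:", paste0("  ", artifacts)),
             file.path(out, "run_log.txt"))
  invisible(res)
}

#' One-command synthetic demonstration run
#'
#' Generates a seeded synthetic community with planted treatment effects,
#' writes its inputs under `out_dir/inputs`, and runs the full pipeline on
#' them. The planted effect table spikes a handful of genomes at large fold
#' changes, some private to one treatment arm, some shared across arms and
#' some persistent across both post-baseline timepoints, so the
#' differential-abundance and concordance stages have structure to find.
#'
#' @param out_dir output directory.
#' @param seed integer seed; the whole run is deterministic given it.
#' @param n_viral,n_contaminant community size.
#' @param n_animals_per_treatment animals per arm.
#' @param reads_per_sample reads per sample.
#' @return invisible list with the pipeline results plus `community`,
#'   `design` and `sim` ground truth.
#' @export
run_demo <- function(out_dir = "virome_demo", seed = 7,
                     n_viral = 25, n_contaminant = 6,
                     n_animals_per_treatment = 2,
                     reads_per_sample = 5000) {
  community <- generate_genomes(n_viral = n_viral,
                                n_contaminant = n_contaminant,
                                seed = seed)
  vir <- community$truth$genome_id[community$truth$role == "virus"]
  spike <- vir[seq_len(min(6, length(vir)))]
  effects <- rbind(
    data.frame(genome_id = spike[1], treatment = "PFF_LPS",
               timepoint = c("T1", "T5"), log2fc = 4),
    data.frame(genome_id = spike[2], treatment = c("monomer", "monomer_LPS"),
               timepoint = "T5", log2fc = 3.5),
    data.frame(genome_id = spike[3], treatment = "PFF",
               timepoint = "T5", log2fc = -4),
    data.frame(genome_id = spike[4], treatment = "Sham",
               timepoint = "T1", log2fc = 3),
    data.frame(genome_id = spike[5], treatment = "PFF_LPS",
               timepoint = "T5", log2fc = 5),
    data.frame(genome_id = spike[6], treatment = c("PFF", "PFF_LPS"),
               timepoint = "T1", log2fc = 3.5))
  design <- community_design(
    genome_ids = community$truth$genome_id,
    n_animals_per_treatment = n_animals_per_treatment,
    effect_table = effects, reads_per_sample = reads_per_sample,
    seed = seed)
  sim <- simulate_reads(community, design)
  inputs <- file.path(out_dir, "inputs")
  write_community(community, sim, inputs)
  cfg <- virome_config(
    contigs = file.path(inputs, "genomes.fasta"),
    annotations = file.path(inputs, "annotations.tsv"),
    flags = file.path(inputs, "flags.tsv"),
    reads_dir = file.path(inputs, "reads"),
    metadata = file.path(inputs, "metadata.tsv"),
    marker = file.path(inputs, "marker.fasta"),
    out_dir = file.path(out_dir, "results"),
    seed = seed)
  res <- run_pipeline(cfg)
  invisible(c(res, list(community = community, design = design, sim = sim,
                        config = cfg)))
}
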