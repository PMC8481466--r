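#' Required breadth of coverage for a contig length
#'
#' Tiered breadth-of-coverage thresholds guarding against reads stacking on
#' a single conserved element: contigs <5 kb must have 50% of their
#' positions covered, 5-20 kb 30%, and >= 20 kb 10%.
#'
#' @param length_bp contig length(s), each >= 1000.
#' @return numeric vector of required breadths.
#' @export
breadth_threshold <- function(length_bp) {
  if (any(length_bp < 1000))
    stop("breadth tiers are defined for contigs >= 1000 bp")
  c(0.50, 0.30, 0.10)[findInterval(length_bp, c(0, 5e3, 2e4, Inf))]
}

#' Apply the presence filter to coverage profiles
#'
#' A contig counts as present in a sample only when it attracted at least
#' `min_reads` reads AND the breadth of coverage meets the length-tiered
#' threshold of [breadth_threshold()]; otherwise zero reads are recorded.
#'
#' @param read_count reads assigned to the contig in the sample.
#' @param breadth fraction of contig positions covered by >= 1 read.
#' @param length_bp contig length.
#' @param min_reads minimum read count.
#' @return data.frame(present, count): `count` is `read_count` when present
#'   and exactly 0 otherwise. All arguments recycle.
#' @export
presence_filter <- function(read_count, breadth, length_bp, min_reads = 3) {
  present <- read_count >= min_reads & breadth >= breadth_threshold(length_bp)
  data.frame(present = present, count = ifelse(present, read_count, 0L))
}

# per-contig coverage (read_count, covered_bases, breadth) from read start
# positions; circular contigs wrap positions past `fold_len` (the length of
# the deduplicated circle) back to the start
coverage_from_starts <- function(starts_by_contig, widths, read_length,
                                 circular, fold_len = widths) {
  ids <- names(widths)
  out <- data.frame(contig_id = ids, read_count = 0L, covered_bases = 0L,
                    breadth = 0, stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    st <- starts_by_contig[[ids[i]]]
    if (is.null(st) || length(st) == 0) next
    L <- as.integer(fold_len[i])
    ir <- IRanges::IRanges(start = st, width = read_length)
    over <- IRanges::end(ir) > L
    if (circular[i] && any(over)) {
      wrap <- IRanges::IRanges(start = 1,
                               width = pmin(IRanges::end(ir)[over] - L, L))
      ir <- c(IRanges::restrict(ir, start = 1L, end = L), wrap)
    } else {
      ir <- IRanges::restrict(ir, start = 1L, end = L)
    }
    cov <- sum(IRanges::width(IRanges::reduce(ir)))
    out$read_count[i] <- length(st)
    out$covered_bases[i] <- cov
    out$breadth[i] <- cov / widths[i]
  }
  out
}

#' Map reads onto a viral contig database by exact matching
#'
#' Desk-scale stand-in for an end-to-end short-read aligner, for error-free
#' simulated reads: each read is assigned to at most one contig by exact
#' substring match (reverse complement tried for otherwise-unmapped reads),
#' with ties broken deterministically towards the lexicographically smallest
#' contig id. Circular contigs are matched against a junction-extended copy
#' so reads wrapping the terminus still map, and their coverage positions
#' wrap accordingly. For real alignments ingest a SAM file with
#' [sam_coverage()] instead.
#'
#' @param reads [Biostrings::DNAStringSet] of equal-length reads.
#' @param database named [Biostrings::DNAStringSet], nonredundant.
#' @param topology optional named character vector ("circular"/"linear") for
#'   junction-aware matching; all linear when NULL.
#' @return list with `profiles` (data.frame contig_id, read_count,
#'   covered_bases, breadth), `counts` (named integer vector) and `unmapped`
#'   (number of unassigned reads).
#' @export
map_reads <- function(reads, database, topology = NULL) {
  ids <- sort(names(database))
  database <- database[ids]
  widths <- Biostrings::width(database); names(widths) <- ids
  circular <- if (is.null(topology)) rep(FALSE, length(ids)) else
    unname(topology[ids] == "circular")
  circular[is.na(circular)] <- FALSE
  n <- length(reads)
  if (n == 0) {
    prof <- coverage_from_starts(list(), widths, 0L, circular)
    return(list(profiles = prof,
                counts = stats::setNames(prof$read_count, ids), unmapped = 0L))
  }
  rl <- unique(Biostrings::width(reads))
  if (length(rl) != 1) stop("map_reads expects equal-length reads")

  # junction-aware subjects: circular contigs are deduplicated (terminal
  # repeat trimmed) and extended by the first read-length-1 bases so reads
  # wrapping the junction still match; subjects are concatenated with N
  # spacers so one scan covers the whole database, and because subjects are
  # in ascending id order the first match of a multi-mapping read is the
  # lexicographically smallest contig
  seqs <- as.character(database)
  subj <- character(length(ids))
  fold_len <- widths
  for (i in seq_along(ids)) {
    if (circular[i]) {
      b <- longest_border(seqs[i])
      b <- min(b, widths[i] - 1L)
      u <- substr(seqs[i], 1, widths[i] - b)
      fold_len[i] <- nchar(u)
      subj[i] <- paste0(u, substr(u, 1, rl - 1))
    } else subj[i] <- seqs[i]
  }
  sep <- strrep("N", rl)
  big <- Biostrings::DNAString(paste(subj, collapse = sep))
  offsets <- cumsum(c(0L, utils::head(nchar(subj) + rl, -1)))

  assign_to <- rep(NA_integer_, n)
  assign_pos <- rep(NA_integer_, n)
  match_pass <- function(readset, map_back) {
    names(readset) <- NULL  # PDict rejects duplicated names
    m <- Biostrings::matchPDict(Biostrings::PDict(readset), big)
    nh <- S4Vectors::elementNROWS(m)
    hit <- which(nh > 0L)
    if (length(hit) == 0) return(invisible())
    st <- IRanges::start(unlist(m))
    first <- vapply(split(st, rep.int(hit, nh[hit])), min, integer(1))
    ci <- findInterval(first, offsets + 1L)
    assign_to[map_back[hit]] <<- ci
    assign_pos[map_back[hit]] <<- as.integer(first - offsets[ci])
    invisible()
  }
  match_pass(reads, seq_len(n))
  left <- which(is.na(assign_to))
  if (length(left))
    match_pass(Biostrings::reverseComplement(reads[left]), left)

  starts_by_contig <- split(assign_pos[!is.na(assign_to)],
                            ids[assign_to[!is.na(assign_to)]])
  prof <- coverage_from_starts(starts_by_contig, widths, rl, circular,
                               fold_len)
  list(profiles = prof,
       counts = stats::setNames(prof$read_count, prof$contig_id),
       unmapped = sum(is.na(assign_to)))
}

#' Per-contig coverage profiles from a SAM file
#'
#' Ingests primary alignments from a SAM file and computes the per-contig
#' read count and breadth of coverage (reference span taken from the CIGAR;
#' coverage is the interval union of aligned spans).
#'
#' @param sam_path path to a SAM file.
#' @param database named [Biostrings::DNAStringSet] the reads were aligned
#'   to (supplies contig lengths).
#' @return data.frame(contig_id, read_count, covered_bases, breadth).
#' @export
sam_coverage <- function(sam_path, database) {
  bam <- Rsamtools::asBam(sam_path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  al <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("rname", "pos", "cigar"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE)))[[1]]
  widths <- Biostrings::width(database)
  names(widths) <- names(database)
  ids <- names(widths)
  out <- data.frame(contig_id = ids, read_count = 0L, covered_bases = 0L,
                    breadth = 0, stringsAsFactors = FALSE)
  if (length(al$pos)) {
    span <- GenomicAlignments::cigarWidthAlongReferenceSpace(al$cigar)
    ir_all <- split(IRanges::IRanges(start = al$pos, width = span),
                    as.character(al$rname))
    for (id in names(ir_all)) {
      i <- match(id, ids)
      if (is.na(i)) next
      ir <- IRanges::restrict(ir_all[[id]], start = 1L,
                              end = as.integer(widths[i]))
      out$read_count[i] <- length(ir_all[[id]])
      out$covered_bases[i] <- sum(IRanges::width(IRanges::reduce(ir)))
      out$breadth[i] <- out$covered_bases[i] / widths[i]
    }
  }
  out
}

#' Build the presence-filtered contig-by-sample count table
#'
#' Maps every sample's reads against the curated database, applies the
#' presence filter and assembles the count matrix; cells failing the filter
#' are exactly zero.
#'
#' @param reads_by_sample named list of [Biostrings::DNAStringSet].
#' @param database curated viral [Biostrings::DNAStringSet].
#' @param topology optional topology vector passed to [map_reads()].
#' @param min_reads minimum read count for presence.
#' @return list with `table` (integer matrix contigs x samples, filtered),
#'   `raw` (unfiltered counts) and `coverage` (long data.frame of profiles).
#' @export
abundance_table <- function(reads_by_sample, database, topology = NULL,
                            min_reads = 3) {
  ids <- sort(names(database))
  samples <- names(reads_by_sample)
  raw <- filt <- matrix(0L, length(ids), length(samples),
                        dimnames = list(ids, samples))
  covs <- list()
  widths <- Biostrings::width(database)[match(ids, names(database))]
  for (s in samples) {
    mp <- map_reads(reads_by_sample[[s]], database, topology)
    prof <- mp$profiles
    raw[prof$contig_id, s] <- prof$read_count
    pf <- presence_filter(prof$read_count, prof$breadth,
                          widths[match(prof$contig_id, ids)], min_reads)
    filt[prof$contig_id, s] <- pf$count
    prof$sample_id <- s
    prof$present <- pf$present
    covs[[s]] <- prof
  }
  list(table = filt, raw = raw,
       coverage = do.call(rbind, c(covs, list(make.row.names = FALSE))))
}

#' Aggregate contig counts into viral-cluster counts
#'
#' Counts of contigs in the same cluster are summed; contigs flagged
#' ambiguous and unclustered contigs are retained as singleton rows.
#' Per-sample totals are conserved.
#'
#' @param table integer matrix, contigs x samples.
#' @param cluster_map data.frame(contig_id, status) from [cluster_graph()];
#'   contigs missing from the map are treated as unclustered with a warning.
#' @return integer matrix, viral groups x samples; cluster rows keep the
#'   `cluster:<k>` name, singleton rows keep the contig id.
#' @export
aggregate_clusters <- function(table, cluster_map) {
  ids <- rownames(table)
  m <- match(ids, cluster_map$contig_id)
  if (anyNA(m)) {
    warning(sprintf("%d contig(s) missing from cluster map; unclustered",
                    sum(is.na(m))))
  }
  status <- ifelse(is.na(m), "unclustered", cluster_map$status[m])
  group <- ifelse(startsWith(status, "cluster:"), status, ids)
  agg <- rowsum(table, group = group)
  storage.mode(agg) <- "integer"
  agg[order(rownames(agg)), , drop = FALSE]
}

#' Marker-gene contamination fraction of a read set
#'
#' Fraction of reads mapping to a marker-gene database (e.g. the bacterial
#' housekeeping gene cpn60), an estimate of bacterial contamination in
#' virome sequencing data.
#'
#' @param reads [Biostrings::DNAStringSet].
#' @param marker_db non-empty [Biostrings::DNAStringSet] of marker genes.
#' @return proportion in [0, 1].
#' @export
marker_contamination_fraction <- function(reads, marker_db) {
  if (length(marker_db) == 0) stop("marker database is empty")
  if (length(reads) == 0) {
    warning("empty read set; returning 0")
    return(0)
  }
  if (is.null(names(marker_db)))
    names(marker_db) <- sprintf("marker_%d", seq_along(marker_db))
  mp <- map_reads(reads, marker_db)
  sum(mp$counts) / length(reads)
}
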