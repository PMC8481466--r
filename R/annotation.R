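STOP_CODONS <- c("TAA", "TAG", "TGA")

# ORFs on the forward strand of `seq`; returns start/end in `seq`
# coordinates (1-based inclusive, stop codon included)
orfs_forward <- function(seq, min_aa) {
  n <- nchar(seq)
  out <- list()
  for (frame in 0:2) {
    starts <- seq.int(1 + frame, n - 2, by = 3)
    if (length(starts) == 0) next
    codons <- substring(seq, starts, starts + 2)
    is_stop <- codons %in% STOP_CODONS
    is_atg <- codons == "ATG"
    # segment index between stops; ORF = first ATG of segment .. next stop
    seg <- cumsum(c(TRUE, utils::head(is_stop, -1)))
    for (s in split(seq_along(codons), seg)) {
      stop_i <- s[is_stop[s]]
      if (length(stop_i) == 0) next       # ORF must terminate in a stop
      atg_i <- s[is_atg[s]]
      atg_i <- atg_i[atg_i < stop_i[1]]
      if (length(atg_i) == 0) next
      first <- atg_i[1]
      aa_len <- stop_i[1] - first         # codons before the stop
      if (aa_len < min_aa) next
      out[[length(out) + 1L]] <- c(starts[first], starts[stop_i[1]] + 2L)
    }
  }
  out
}

has_long_n_run <- function(seq, max_run = 10) {
  grepl(paste0("N{", max_run + 1, ",}"), seq)
}

#' Find open reading frames on both strands
#'
#' Simplified gene caller: maximal ATG-to-stop frames of at least `min_aa`
#' codons on both strands, using the standard genetic code and ATG starts
#' only. Calls spanning a run of more than 10 ambiguous bases are
#' suppressed. Coordinates are 1-based inclusive on the forward
#' representation of the contig; minus-strand calls report the forward
#' interval they occupy.
#'
#' @param contig a character string or [Biostrings::DNAString]; alphabet
#'   A/C/G/T/N.
#' @param min_aa minimum protein length in amino acids (stop excluded).
#' @param contig_id identifier recorded in the output.
#' @return data.frame(contig_id, start, end, strand, protein), ordered by
#'   ascending start.
#' @export
find_orfs <- function(contig, min_aa = 30, contig_id = "contig") {
  seq <- toupper(as.character(contig))
  if (grepl("[^ACGTN]", seq)) stop("sequence alphabet must be A/C/G/T/N")
  n <- nchar(seq)
  res <- list()
  fwd <- orfs_forward(seq, min_aa)
  for (iv in fwd)
    res[[length(res) + 1L]] <- data.frame(
      contig_id = contig_id, start = iv[1], end = iv[2], strand = "+",
      stringsAsFactors = FALSE)
  rc <- reverse_complement_chr(seq)
  for (iv in orfs_forward(rc, min_aa)) {
    # map reverse-strand coordinates back to the forward representation
    res[[length(res) + 1L]] <- data.frame(
      contig_id = contig_id, start = n - iv[2] + 1L, end = n - iv[1] + 1L,
      strand = "-", stringsAsFactors = FALSE)
  }
  if (length(res) == 0)
    return(data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      protein = character(0), stringsAsFactors = FALSE))
  df <- do.call(rbind, res)
  nt <- substring(seq, df$start, df$end)
  flip <- df$strand == "-"
  nt[flip] <- vapply(nt[flip], reverse_complement_chr, character(1))
  keep <- !vapply(nt, has_long_n_run, logical(1))
  df <- df[keep, , drop = FALSE]; nt <- nt[keep]
  prot <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(nt), if.fuzzy.codon = "X"))
  df$protein <- sub("\\*$", "", prot)
  df <- df[order(df$start, df$end, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Assign phage replication lifestyle from protein annotations
#'
#' A contig encoding a phage integrase and/or recombinase is annotated as a
#' lysogenic phage; all others replicate through an unknown strategy. The
#' call is a pure function of the annotation table.
#'
#' @param contig_ids contigs to label.
#' @param annotations annotation table (category column holds
#'   integrase/recombinase rows).
#' @return data.frame(contig_id, lifestyle) with lifestyle in
#'   lysogenic/unknown.
#' @export
assign_lifestyle <- function(contig_ids, annotations) {
  missing <- setdiff(contig_ids, annotations$contig_id)
  if (length(missing))
    warning(sprintf("%d contig(s) absent from annotation table; 'unknown'",
                    length(missing)))
  lys_ids <- unique(annotations$contig_id[
    annotations$category %in% c("integrase", "recombinase")])
  data.frame(contig_id = contig_ids,
             lifestyle = ifelse(contig_ids %in% lys_ids, "lysogenic",
                                "unknown"),
             stringsAsFactors = FALSE)
}

#' Assign a putative family label by majority vote
#'
#' Each protein-level family annotation contributes one vote; the contig
#' takes the majority family, with ties and contigs lacking family rows
#' labelled "unclassified".
#'
#' @param contig_ids contigs to label.
#' @param annotations annotation table (rows with category "family" carry
#'   the family name in `value`).
#' @return data.frame(contig_id, family).
#' @export
assign_family <- function(contig_ids, annotations) {
  fa <- annotations[annotations$category == "family", , drop = FALSE]
  lab <- vapply(contig_ids, function(id) {
    v <- fa$value[fa$contig_id == id]
    if (length(v) == 0) return("unclassified")
    tab <- sort(table(v), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) return("unclassified")
    names(tab)[1]
  }, character(1))
  data.frame(contig_id = contig_ids, family = unname(lab),
             stringsAsFactors = FALSE)
}

#' Export ORF calls as GFF3
#'
#' @param orfs data.frame from [find_orfs()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_orfs_gff3 <- function(orfs, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(orfs)) {
    lines <- sprintf("%s\tviromeflow\tCDS\t%d\t%d\t.\t%s\t0\tID=%s_orf%d",
                     orfs$contig_id, orfs$start, orfs$end, orfs$strand,
                     orfs$contig_id, seq_len(nrow(orfs)))
    writeLines(lines, con)
  }
  invisible(path)
}
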