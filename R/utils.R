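#' @importFrom stats rbinom rgamma rmultinom rnbinom rpois runif median var
#'   pnorm p.adjust wilcox.test kruskal.test complete.cases
#' @importFrom utils write.table read.table head
NULL

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. seed = NULL runs expr as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write a data frame as tab-separated text
#'
#' Plain TSV with a header row, no quoting and no row names; the on-disk
#' interchange format used by every pipeline stage.
#'
#' @param x data.frame to write.
#' @param path output file path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated file written by [write_tsv()]
#'
#' @param path file path.
#' @return data.frame with character columns left as-is.
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             comment.char = "", quote = "")
}

# random DNA of length n
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

reverse_complement_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

stopifnot_scalar_count <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 0 || x != as.integer(x))
    stop(sprintf("'%s' must be a single non-negative integer", name))
}
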