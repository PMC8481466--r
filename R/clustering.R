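#' Build the shared-protein-family graph over contigs
#'
#' Two contigs are connected when they share at least `min_shared` protein
#' families (pVOG identifiers in the annotation table); the edge weight is
#' the number of shared families. This gene-sharing graph is the substrate
#' for pseudogenus-level viral clustering.
#'
#' @param contig_ids nodes of the graph (contigs with no annotated proteins
#'   become isolated nodes).
#' @param annotations annotation table; rows with category "pVOG" carry the
#'   protein-family identifier in `value`.
#' @param min_shared minimum shared-family count for an edge.
#' @return list with `nodes` (character) and `edges`
#'   (data.frame from, to, weight; from < to).
#' @export
shared_gene_graph <- function(contig_ids, annotations, min_shared = 2) {
  pv <- annotations[annotations$category == "pVOG" &
                      annotations$contig_id %in% contig_ids, , drop = FALSE]
  fams <- lapply(split(pv$value, pv$contig_id), unique)
  edges <- list()
  n <- length(contig_ids)
  for (i in seq_len(max(n - 1, 0))) {
    fi <- fams[[contig_ids[i]]]
    if (is.null(fi)) next
    for (j in (i + 1):n) {
      fj <- fams[[contig_ids[j]]]
      if (is.null(fj)) next
      w <- sum(fi %in% fj)
      if (w >= min_shared) {
        a <- sort(c(contig_ids[i], contig_ids[j]))
        edges[[length(edges) + 1L]] <- data.frame(
          from = a[1], to = a[2], weight = w, stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0), weight = numeric(0),
               stringsAsFactors = FALSE)
  list(nodes = sort(contig_ids), edges = edges)
}

#' Cluster the gene-sharing graph into viral clusters
#'
#' Connected components of size >= 2 become viral clusters (VCs); isolated
#' nodes are "unclustered"; articulation points — nodes whose removal splits
#' their component, i.e. contigs bridging otherwise-separate groups — are
#' flagged "ambiguous" and are treated as singletons downstream.
#'
#' @param graph result of [shared_gene_graph()].
#' @return data.frame(contig_id, status) where status is `cluster:<k>`,
#'   `ambiguous` or `unclustered`; every node receives exactly one status.
#' @export
cluster_graph <- function(graph) {
  nodes <- graph$nodes
  g <- igraph::graph_from_data_frame(graph$edges[, c("from", "to")],
                                     directed = FALSE, vertices = nodes)
  comp <- igraph::components(g)
  arts <- names(igraph::articulation_points(g))
  status <- character(length(nodes))
  # stable cluster numbering: by smallest member id
  memb <- comp$membership[nodes]
  big <- which(comp$csize >= 2)
  relabel <- rep(NA_integer_, comp$no)
  if (length(big)) {
    firsts <- vapply(big, function(k) min(nodes[memb == k]), character(1))
    relabel[big[order(firsts)]] <- seq_along(big)
  }
  for (i in seq_along(nodes)) {
    if (nodes[i] %in% arts) status[i] <- "ambiguous"
    else if (comp$csize[memb[i]] >= 2)
      status[i] <- sprintf("cluster:%d", relabel[memb[i]])
    else status[i] <- "unclustered"
  }
  data.frame(contig_id = nodes, status = status, stringsAsFactors = FALSE)
}

#' Cluster viral contigs by shared protein content
#'
#' Convenience wrapper: builds the gene-sharing graph and clusters it.
#'
#' @inheritParams shared_gene_graph
#' @return data.frame(contig_id, status) as in [cluster_graph()].
#' @export
cluster_contigs <- function(contig_ids, annotations, min_shared = 2) {
  cluster_graph(shared_gene_graph(contig_ids, annotations, min_shared))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 is
#' perfect agreement, 0 is the expectation under independence. Used to score
#' cluster recovery against planted truth.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
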