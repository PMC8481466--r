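# Independent oracles used to cross-check package implementations.

# All-pairs greedy nonredundancy oracle. Fixtures are built so that
# homologous pairs are exact (possibly reverse-complement) containments,
# which lets the oracle decide homology by plain substring search,
# independently of the package's seeded-alignment route.
greedy_merge_oracle <- function(seqs) {
  ids <- names(seqs)
  ord <- order(-nchar(seqs), ids)
  kept <- character(0)
  for (id in ids[ord]) {
    s <- seqs[[id]]
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    absorbed <- FALSE
    for (k in kept) {
      if (grepl(s, seqs[[k]], fixed = TRUE) ||
          grepl(rc, seqs[[k]], fixed = TRUE)) {
        absorbed <- TRUE
        break
      }
    }
    if (!absorbed) kept <- c(kept, id)
  }
  sort(kept)
}

# brute-force articulation points: node whose removal increases the number
# of connected components among the remaining nodes of its component
components_bfs <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    adj[[edges$from[i]]] <- c(adj[[edges$from[i]]], edges$to[i])
    adj[[edges$to[i]]] <- c(adj[[edges$to[i]]], edges$from[i])
  }
  seen <- character(0)
  comps <- list()
  for (n in nodes) {
    if (n %in% seen) next
    queue <- n
    comp <- character(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      queue <- c(queue, setdiff(adj[[v]], comp))
    }
    seen <- c(seen, comp)
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

articulation_oracle <- function(nodes, edges) {
  base <- length(components_bfs(nodes, edges))
  out <- character(0)
  for (v in nodes) {
    rest <- setdiff(nodes, v)
    e2 <- edges[edges$from != v & edges$to != v, , drop = FALSE]
    if (length(components_bfs(rest, e2)) > base) out <- c(out, v)
  }
  out
}

# direct PERMANOVA R^2 via Gower-centred matrix and hat-matrix traces,
# an algebraic route independent of the package's pairwise-sum formulation
permanova_r2_oracle <- function(d, grouping) {
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (d^2) %*% J
  X <- stats::model.matrix(~ factor(grouping))
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  sum(diag(H %*% G %*% H)) / sum(diag(G))
}

# brute-force median-of-ratios size factors (log-space median, the
# standard convention, so an even number of usable groups interpolates
# geometrically)
size_factors_oracle <- function(tab) {
  geo <- apply(tab, 1, function(r) prod(r)^(1 / length(r)))
  ok <- geo > 0 & is.finite(geo)
  sf <- numeric(ncol(tab))
  for (j in seq_len(ncol(tab)))
    sf[j] <- exp(median(log(tab[ok, j] / geo[ok])))
  sf <- sf / prod(sf)^(1 / length(sf))
  names(sf) <- colnames(tab)
  sf
}

# least-squares Procrustes error after centring, scaling to unit norm and
# optimal rotation/reflection
procrustes_error <- function(A, B) {
  cA <- scale(A, scale = FALSE); cB <- scale(B, scale = FALSE)
  cA <- cA / sqrt(sum(cA^2)); cB <- cB / sqrt(sum(cB^2))
  s <- svd(t(cB) %*% cA)
  sum((cA - cB %*% s$u %*% t(s$v))^2)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
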