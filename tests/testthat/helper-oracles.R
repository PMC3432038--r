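# Fixture builders and independent brute-force oracles. The oracles are
# deliberately naive (double loops, dense eigendecomposition, all-pairs
# AUC) so they share no code with the implementation they check.

rand_network <- function(n, p = 0.2, seed = 1, connected = FALSE,
                         isolated_ok = TRUE) {
  withr::local_seed(seed)
  genes <- sprintf("T%03d", seq_len(n))
  repeat {
    pairs <- t(utils::combn(n, 2))
    keep <- stats::runif(nrow(pairs)) < p
    edges <- tibble::tibble(
      gene_a = genes[pairs[keep, 1]],
      gene_b = genes[pairs[keep, 2]],
      weight = stats::runif(sum(keep))
    )
    if (nrow(edges) == 0) next
    net <- gene_network(edges, genes = genes)
    if (!connected) return(net)
    g <- igraph::graph_from_data_frame(
      net[, 1:2], directed = FALSE, vertices = data.frame(name = genes)
    )
    if (igraph::is_connected(g)) return(net)
  }
}

# O(genes x edges) incident-edge summation
brute_weighted_degree <- function(net) {
  genes <- network_genes(net)
  sapply(genes, function(g) {
    s <- 0
    for (k in seq_len(nrow(net))) {
      if (net$gene_a[k] == g || net$gene_b[k] == g) s <- s + net$weight[k]
    }
    s
  })
}

# dense eigendecomposition leading eigenvector, sign-fixed nonnegative
dense_eigenvector <- function(net) {
  genes <- network_genes(net)
  n <- length(genes)
  a <- matrix(0, n, n, dimnames = list(genes, genes))
  for (k in seq_len(nrow(net))) {
    i <- net$gene_a[k]; j <- net$gene_b[k]
    a[i, j] <- net$weight[k]
    a[j, i] <- net$weight[k]
  }
  v <- eigen(a, symmetric = TRUE)$vectors[, 1]
  if (sum(v) < 0) v <- -v
  stats::setNames(v / sqrt(sum(v^2)), genes)
}

# all-pairs probability AUC with half-credit ties
brute_auc <- function(score, label) {
  pos <- score[label]
  neg <- score[!label]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# definitional Spearman rho on midranks
brute_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# brute-force drug ordering: min target rank over mapped table genes,
# ties by drug name
brute_drug_order <- function(table, catalog) {
  rank_of <- stats::setNames(table$rank, table$gene)
  drugs <- unique(catalog$drug)
  best <- sapply(drugs, function(d) {
    t <- catalog$target[catalog$drug == d]
    r <- rank_of[t[t %in% names(rank_of)]]
    if (length(r) == 0) NA_integer_ else min(r)
  })
  ok <- !is.na(best)
  d <- drugs[ok]; b <- best[ok]
  d[order(b, d, method = "radix")]
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
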