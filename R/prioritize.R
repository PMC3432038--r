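# Ranking metrics. Hub scores (weighted degree, weighted eigenvector
# centrality) are computed on the tumor-specific subnetwork induced by the
# mapped candidates; the seed-gene association score sums direct linkage
# probabilities to the seed set over the FULL network.

#' Build the tumor-specific subnetwork
#'
#' Maps candidate genes onto the gene functional network and takes the
#' induced subgraph: members are the candidates present in the network,
#' edges are exactly the network edges with both endpoints among members.
#' Candidates absent from the network are retained in the `unmapped`
#' attribute so the final ranking can still carry them (score 0, tail).
#'
#' @param network A [gene_network].
#' @param candidates A gene list: character vector or tibble with a `gene`
#'   column (e.g. from [read_gene_list()]).
#' @param quiet Suppress the mapped/unmapped count message.
#' @return A `tumor_subnetwork` (a [gene_network] whose gene set is the
#'   mapped candidates, with attributes `unmapped` and `parent_genes`).
#' @export
build_subnetwork <- function(network, candidates, quiet = FALSE) {
  stopifnot(inherits(network, "gene_network"))
  ids <- unique(as_gene_ids(candidates, "candidates"))
  if (length(ids) == 0) abort("candidate list is empty")
  members <- sort_c(intersect(ids, network_genes(network)))
  unmapped <- sort_c(setdiff(ids, members))
  if (length(members) == 0) {
    abort("no candidate genes found in network")
  }
  keep <- network$gene_a %in% members & network$gene_b %in% members
  edges <- tibble::as_tibble(network[keep, ])
  if (!quiet) {
    inform(sprintf(
      "subnetwork: %d/%d candidates mapped (%d unmapped), %d induced edges",
      length(members), length(ids), length(unmapped), nrow(edges)
    ))
  }
  out <- new_gene_network(edges, members, class = "tumor_subnetwork")
  attr(out, "unmapped") <- unmapped
  attr(out, "parent_genes") <- network_genes(network)
  out
}

#' Unmapped candidate identifiers of a tumor subnetwork
#' @param sub A `tumor_subnetwork`.
#' @return Character vector (possibly empty).
#' @export
unmapped_candidates <- function(sub) {
  stopifnot(inherits(sub, "tumor_subnetwork"))
  attr(sub, "unmapped")
}

new_score_map <- function(gene, score, metric) {
  out <- tibble::tibble(gene = gene, score = score)
  attr(out, "metric") <- metric
  class(out) <- c("score_map", class(tibble::tibble()))
  out
}

#' Weighted degree centrality (hub score)
#'
#' The hub score of a gene is the sum of the linkage probabilities of its
#' incident edges within the given (sub)network. Isolated members score 0.
#'
#' @param sub A [gene_network] or `tumor_subnetwork`.
#' @return A `score_map` tibble with columns `gene`, `score`, one row per
#'   member gene, in C-locale gene order.
#' @export
weighted_degree_centrality <- function(sub) {
  stopifnot(inherits(sub, "gene_network"))
  genes <- network_genes(sub)
  deg <- setNames(numeric(length(genes)), genes)
  if (nrow(sub) > 0) {
    ta <- tapply(sub$weight, sub$gene_a, sum)
    tb <- tapply(sub$weight, sub$gene_b, sum)
    deg[names(ta)] <- deg[names(ta)] + ta
    deg[names(tb)] <- deg[names(tb)] + tb
  }
  new_score_map(genes, unname(deg), "weighted_degree")
}

#' Weighted eigenvector centrality (hub score)
#'
#' The leading eigenvector of the weighted adjacency matrix of the
#' subnetwork, computed by shifted power iteration (`A + I`; the shift
#' leaves the Perron vector unchanged but guarantees convergence on
#' bipartite components, whose unshifted spectrum is symmetric). Entries
#' are nonnegative and L2-normalized over the member genes. With a
#' disconnected subnetwork only the spectrally dominant component receives
#' non-vanishing scores; a warning reports the component count.
#'
#' @param sub A [gene_network] with at least one edge.
#' @param tol Convergence tolerance: L2 distance between successive
#'   normalized iterates. Default `1e-10`.
#' @param max_iter Iteration cap; exceeding it is an error that reports
#'   the last residual.
#' @return A `score_map` tibble (`gene`, `score`).
#' @export
weighted_eigenvector_centrality <- function(sub, tol = 1e-10,
                                            max_iter = 1000L) {
  stopifnot(inherits(sub, "gene_network"))
  if (nrow(sub) == 0) {
    abort("eigenvector centrality undefined on empty graph")
  }
  genes <- network_genes(sub)
  n_comp <- network_component_count(sub)
  if (n_comp > 1) {
    warn(sprintf(
      "subnetwork has %d connected components; eigenvector scores off the dominant component are near zero",
      n_comp
    ))
  }
  a <- network_adjacency(sub)
  n <- length(genes)
  x <- rep(1 / sqrt(n), n)
  converged <- FALSE
  residual <- NA_real_
  for (i in seq_len(max_iter)) {
    y <- as.numeric(a %*% x) + x  # shifted: (A + I) x
    nrm <- sqrt(sum(y^2))
    y <- y / nrm
    residual <- sqrt(sum((y - x)^2))
    x <- y
    if (residual < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    abort(sprintf(
      "power iteration did not converge in %d iterations (residual %.3e)",
      max_iter, residual
    ))
  }
  x <- pmax(x, 0)          # Perron vector; clip numerically-zero negatives
  x <- x / sqrt(sum(x^2))  # restore unit L2 norm after clipping
  new_score_map(genes, x, "weighted_eigenvector")
}

network_component_count <- function(net) {
  genes <- network_genes(net)
  g <- igraph::graph_from_data_frame(
    net[, c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = genes)
  )
  igraph::count_components(g)
}

#' Seed-gene association score
#'
#' Guilt-by-association score of a candidate gene: the sum of its direct
#' linkage probabilities to the seed genes, taken from the full network
#' (an absent edge contributes 0). A candidate that is itself a seed keeps
#' its score from the other seeds; its (nonexistent) self-association is
#' excluded by construction since the network has no self-loops. With
#' `seeds` equal to all network genes this reduces to the full-network
#' weighted degree of each candidate.
#'
#' @param network A [gene_network].
#' @param candidates Gene list of candidates to score.
#' @param seeds Gene list of seed genes (e.g. known cancer genes); at
#'   least one seed must map to the network.
#' @param quiet Suppress the mapping message.
#' @return A `score_map` tibble over the mapped candidates, with
#'   attribute `unmapped` naming candidates absent from the network.
#' @export
seed_association_score <- function(network, candidates, seeds,
                                   quiet = FALSE) {
  stopifnot(inherits(network, "gene_network"))
  cand <- unique(as_gene_ids(candidates, "candidates"))
  seed <- unique(as_gene_ids(seeds, "seeds"))
  if (length(seed) == 0) abort("seed list is empty")
  seed_mapped <- intersect(seed, network_genes(network))
  if (length(seed_mapped) == 0) abort("no seed genes found in network")
  mapped <- sort_c(intersect(cand, network_genes(network)))
  if (length(mapped) == 0) abort("no candidate genes found in network")
  if (!quiet) {
    inform(sprintf(
      "seed association: %d/%d seeds and %d/%d candidates in network",
      length(seed_mapped), length(seed), length(mapped), length(cand)
    ))
  }
  score <- setNames(numeric(length(mapped)), mapped)
  a_in <- network$gene_a %in% mapped & network$gene_b %in% seed_mapped
  b_in <- network$gene_b %in% mapped & network$gene_a %in% seed_mapped
  if (any(a_in)) {
    s <- tapply(network$weight[a_in], network$gene_a[a_in], sum)
    score[names(s)] <- score[names(s)] + s
  }
  if (any(b_in)) {
    s <- tapply(network$weight[b_in], network$gene_b[b_in], sum)
    score[names(s)] <- score[names(s)] + s
  }
  out <- new_score_map(mapped, unname(score), "seed_association")
  attr(out, "unmapped") <- sort_c(setdiff(cand, mapped))
  out
}

#' Rank candidate genes by score
#'
#' Sorts mapped candidates by descending score with lexicographic (C
#' locale) tie-breaks on the gene identifier, then appends the unmapped
#' candidates — lexicographically ordered, score 0, `mapped = FALSE` — so
#' the table always covers the full candidate list. Ranks are contiguous
#' `1..N`. Optionally joins per-gene fold changes (from the candidate
#' list's `value` column) and citation counts (from an annotation table).
#'
#' @param scores A `score_map` from one of the centrality/association
#'   functions.
#' @param candidates The full candidate gene list (character vector or
#'   tibble; a `value` column is carried through as `fold_change`).
#'   Defaults to the scored genes plus any `unmapped` attribute on
#'   `scores`.
#' @param annotations Optional annotation tibble
#'   (`gene`, `description`, `citation_count`) to join.
#' @return A `ranked_genes` tibble: `rank`, `gene`, `score`, `mapped`,
#'   plus `fold_change` / `citation_count` when available. The metric name
#'   is kept in the `metric` attribute.
#' @export
rank_genes <- function(scores, candidates = NULL, annotations = NULL) {
  stopifnot(is.data.frame(scores), all(c("gene", "score") %in% names(scores)))
  if (is.null(candidates)) {
    ids <- c(scores$gene, attr(scores, "unmapped") %||% character())
  } else {
    ids <- unique(as_gene_ids(candidates, "candidates"))
  }
  mapped_tbl <- tibble::tibble(
    gene = scores$gene, score = as.double(scores$score), mapped = TRUE
  )
  mapped_tbl <- mapped_tbl[mapped_tbl$gene %in% ids, ]
  mapped_tbl <- mapped_tbl[
    order(-mapped_tbl$score, mapped_tbl$gene, method = "radix"),
  ]
  tail_ids <- sort_c(setdiff(ids, mapped_tbl$gene))
  out <- dplyr::bind_rows(
    mapped_tbl,
    tibble::tibble(gene = tail_ids, score = 0, mapped = FALSE)
  )
  out <- dplyr::mutate(out, rank = dplyr::row_number(), .before = 1)

  values <- gene_list_values(candidates)
  if (!is.null(values)) {
    out$fold_change <- unname(values[out$gene])
  }
  if (!is.null(annotations)) {
    ann <- tibble::as_tibble(annotations)[, c("gene", "citation_count")]
    ann$gene <- normalize_gene_ids(ann$gene)
    out <- dplyr::left_join(out, ann, by = "gene")
  }
  attr(out, "metric") <- attr(scores, "metric") %||% "unknown"
  class(out) <- c("ranked_genes", class(tibble::tibble()))
  out
}

#' One-call candidate ranking
#'
#' Convenience wrapper chaining subnetwork construction, the chosen
#' metric and [rank_genes()].
#'
#' @param network A [gene_network].
#' @param candidates Candidate gene list (tibble with `gene` and optional
#'   `value` fold-change column, or character vector).
#' @param metric `"degree"` (weighted degree centrality on the induced
#'   subnetwork), `"eigenvector"` (weighted eigenvector centrality on the
#'   induced subnetwork) or `"seed"` (seed-gene association over the full
#'   network).
#' @param seeds Seed gene list, required when `metric = "seed"` unless
#'   `seeds_all_genes = TRUE`.
#' @param seeds_all_genes Use every network gene as a seed (the
#'   whole-genome association mode used for driver-mutation screening).
#' @param annotations Optional annotation tibble to join.
#' @param tol,max_iter Passed to [weighted_eigenvector_centrality()].
#' @param quiet Suppress progress messages.
#' @return A `ranked_genes` tibble.
#' @examples
#' net <- gene_network(tibble::tibble(
#'   gene_a = c("A", "B", "C"), gene_b = c("B", "C", "D"),
#'   weight = c(0.5, 0.3, 0.9)
#' ))
#' rank_candidates(net, c("A", "B", "C"), metric = "degree", quiet = TRUE)
#' @export
rank_candidates <- function(network, candidates,
                            metric = c("degree", "eigenvector", "seed"),
                            seeds = NULL, seeds_all_genes = FALSE,
                            annotations = NULL,
                            tol = 1e-10, max_iter = 1000L, quiet = FALSE) {
  metric <- match.arg(metric)
  if (metric == "seed") {
    if (seeds_all_genes) seeds <- network_genes(network)
    if (is.null(seeds)) {
      abort("metric 'seed' needs a seed list or seeds_all_genes = TRUE")
    }
    scores <- seed_association_score(network, candidates, seeds,
                                     quiet = quiet)
  } else {
    sub <- build_subnetwork(network, candidates, quiet = quiet)
    scores <- switch(metric,
      degree = weighted_degree_centrality(sub),
      eigenvector = weighted_eigenvector_centrality(
        sub, tol = tol, max_iter = max_iter
      )
    )
    attr(scores, "unmapped") <- unmapped_candidates(sub)
  }
  rank_genes(scores, candidates, annotations = annotations)
}

#' Flag novel genes among the top-ranked
#'
#' Returns the genes within the top `ceiling(top_fraction * N)` ranks that
#' have zero cancer-literature citations (a gene missing from the
#' annotation table counts as uncited). These are the ranking's novel
#' target nominations: highly ranked but never tied to this cancer in the
#' literature.
#'
#' @param table A `ranked_genes` tibble.
#' @param annotations Annotation tibble with `gene` and `citation_count`.
#' @param top_fraction Fraction of the ranking to scan, in `(0, 1]`.
#'   Default 0.1 (the top decile).
#' @return A tibble (`rank`, `gene`, `score`) of novel genes, in rank
#'   order.
#' @export
flag_novel <- function(table, annotations, top_fraction = 0.1) {
  stopifnot(is.data.frame(table))
  if (!(top_fraction > 0 && top_fraction <= 1)) {
    abort("top_fraction must be in (0, 1]")
  }
  n_top <- ceiling(top_fraction * nrow(table))
  top <- table[table$rank <= n_top, c("rank", "gene", "score")]
  ann <- tibble::as_tibble(annotations)
  cit <- setNames(as.integer(ann$citation_count),
                  normalize_gene_ids(ann$gene))
  cc <- cit[top$gene]
  cc[is.na(cc)] <- 0L
  tibble::as_tibble(top[cc == 0L, ])
}
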