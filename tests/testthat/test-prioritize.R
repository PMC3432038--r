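# Subnetwork construction, the two hub scores, seed association, ranking.

chain_net <- function() {
  gene_network(tibble::tibble(
    gene_a = c("A", "B", "C"), gene_b = c("B", "C", "D"),
    weight = c(0.5, 0.3, 0.9)
  ))
}

test_that("build_subnetwork induces exactly the candidate-internal edges", {
  net <- chain_net()
  sub <- build_subnetwork(net, c("A", "B", "C"), quiet = TRUE)
  expect_setequal(network_genes(sub), c("A", "B", "C"))
  expect_equal(nrow(sub), 2L)  # A-B and B-C; C-D excluded
  expect_false("D" %in% c(sub$gene_a, sub$gene_b))

  single <- build_subnetwork(net, "A", quiet = TRUE)
  expect_equal(network_genes(single), "A")
  expect_equal(nrow(single), 0L)

  expect_error(build_subnetwork(net, c("X", "Y"), quiet = TRUE),
               "no candidate genes found in network")

  sub2 <- build_subnetwork(net, c("A", "B", "QQ"), quiet = TRUE)
  expect_equal(unmapped_candidates(sub2), "QQ")
})

test_that("weighted degree matches hand and brute-force oracles", {
  sub <- build_subnetwork(chain_net(), c("A", "B", "C"), quiet = TRUE)
  sm <- weighted_degree_centrality(sub)
  expect_equal(stats::setNames(sm$score, sm$gene),
               c(A = 0.5, B = 0.8, C = 0.3))

  edgeless <- build_subnetwork(chain_net(), c("A", "D"), quiet = TRUE)
  expect_true(all(weighted_degree_centrality(edgeless)$score == 0))

  for (seed in 1:10) {
    net <- rand_network(40, p = 0.2, seed = seed)
    sm <- weighted_degree_centrality(net)
    expect_identical(stats::setNames(sm$score, sm$gene),
                     brute_weighted_degree(net))
  }
})

test_that("eigenvector centrality matches closed forms and dense solver", {
  # two nodes, one edge: both 1/sqrt(2) regardless of weight
  pair <- gene_network(tibble::tibble(gene_a = "A", gene_b = "B",
                                      weight = 0.7))
  sm <- weighted_eigenvector_centrality(pair)
  expect_equal(sm$score, rep(1 / sqrt(2), 2), tolerance = 1e-9)

  # star, equal weights: center 1/sqrt(2), each of 4 leaves 1/sqrt(8)
  star <- gene_network(tibble::tibble(
    gene_a = rep("HUB", 4), gene_b = paste0("L", 1:4), weight = 0.6
  ))
  sm <- weighted_eigenvector_centrality(star)
  v <- stats::setNames(sm$score, sm$gene)
  expect_equal(unname(v["HUB"]), 1 / sqrt(2), tolerance = 1e-8)
  expect_equal(unname(v[paste0("L", 1:4)]), rep(1 / sqrt(8), 4),
               tolerance = 1e-8)

  # random connected graphs vs dense eigendecomposition
  for (seed in 1:8) {
    net <- rand_network(20, p = 0.25, seed = seed, connected = TRUE)
    sm <- weighted_eigenvector_centrality(net, max_iter = 50000L)
    got <- stats::setNames(sm$score, sm$gene)
    want <- dense_eigenvector(net)
    expect_lt(sqrt(sum((got - want[names(got)])^2)), 1e-6)
  }
})

test_that("eigenvector centrality errors and warnings are reported", {
  net <- chain_net()
  edgeless <- build_subnetwork(net, c("A", "D"), quiet = TRUE)
  expect_error(weighted_eigenvector_centrality(edgeless),
               "undefined on empty graph")

  # disconnected: two components -> warning naming the count
  disc <- gene_network(tibble::tibble(
    gene_a = c("A", "C"), gene_b = c("B", "D"), weight = c(0.9, 0.2)
  ))
  expect_warning(sm <- weighted_eigenvector_centrality(disc),
                 "2 connected components")
  v <- stats::setNames(sm$score, sm$gene)
  # dominant component (weight 0.9) carries the mass
  expect_gt(v[["A"]], 0.7)
  expect_lt(v[["C"]], 1e-3)

  expect_error(
    weighted_eigenvector_centrality(chain_net(), tol = 0, max_iter = 3),
    "did not converge"
  )
})

test_that("seed association sums direct edge weights over the full network", {
  net <- chain_net()
  sm <- seed_association_score(net, c("A", "C"), "B", quiet = TRUE)
  expect_equal(stats::setNames(sm$score, sm$gene), c(A = 0.5, C = 0.3))

  # candidate with no seed edge scores 0
  sm2 <- seed_association_score(net, c("A", "D"), "A", quiet = TRUE)
  expect_equal(sm2$score[sm2$gene == "D"], 0)

  # a candidate that is itself a seed keeps its other-seed associations
  sm3 <- seed_association_score(net, c("B", "C"), c("B", "C"),
                                quiet = TRUE)
  expect_equal(stats::setNames(sm3$score, sm3$gene), c(B = 0.3, C = 0.3))

  expect_error(seed_association_score(net, "A", "NOPE", quiet = TRUE),
               "no seed genes found")
})

test_that("seeds = all network genes reduces to full-network degree", {
  for (seed in 1:10) {
    net <- rand_network(30, p = 0.2, seed = seed)
    cand <- network_genes(net)[1:15]
    sm <- seed_association_score(net, cand, network_genes(net),
                                 quiet = TRUE)
    deg <- weighted_degree_centrality(net)
    want <- stats::setNames(deg$score, deg$gene)[cand]
    got <- stats::setNames(sm$score, sm$gene)[cand]
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("rank_genes sorts, tie-breaks lexicographically, appends tail", {
  sm <- tibble::tibble(gene = c("B", "A", "C"), score = c(0.8, 0.5, 0.3))
  tab <- rank_genes(sm)
  expect_equal(tab$gene, c("B", "A", "C"))
  expect_equal(tab$rank, 1:3)

  tied <- tibble::tibble(gene = c("B", "A"), score = c(0.5, 0.5))
  expect_equal(rank_genes(tied)$gene, c("A", "B"))

  sm3 <- tibble::tibble(gene = "A", score = 0.9)
  tab3 <- rank_genes(sm3, candidates = c("A", "Z", "Y"))
  expect_equal(tab3$gene, c("A", "Y", "Z"))
  expect_equal(tab3$mapped, c(TRUE, FALSE, FALSE))
  expect_equal(tab3$score[2:3], c(0, 0))
  expect_equal(tab3$rank, 1:3)
})

test_that("edge-list file order never changes scores or ranks", {
  net <- rand_network(25, p = 0.25, seed = 11)
  lines <- sprintf("%s\t%s\t%.17g", net$gene_a, net$gene_b, net$weight)
  withr::local_seed(99)
  shuffled <- sample(lines)
  p1 <- write_lines_tmp(lines)
  p2 <- write_lines_tmp(shuffled)
  n1 <- read_gene_network(p1, quiet = TRUE)
  n2 <- read_gene_network(p2, quiet = TRUE)
  cand <- network_genes(n1)[1:15]
  t1 <- rank_candidates(n1, cand, metric = "degree", quiet = TRUE)
  t2 <- rank_candidates(n2, cand, metric = "degree", quiet = TRUE)
  expect_identical(tidy(t1), tidy(t2))
})

test_that("adding a candidate-seed edge raises the score and the rank", {
  withr::local_seed(4)
  net <- rand_network(30, p = 0.15, seed = 4)
  genes <- network_genes(net)
  seeds <- genes[1:5]
  cand <- genes[6:30]
  base <- rank_candidates(net, cand, metric = "seed", seeds = seeds,
                          quiet = TRUE)
  # first candidate-seed pair with no existing edge (sparse: one exists)
  key <- paste(net$gene_a, net$gene_b)
  pairs <- expand.grid(g = cand, s = seeds, stringsAsFactors = FALSE)
  free <- !paste(pmin(pairs$g, pairs$s), pmax(pairs$g, pairs$s)) %in% key
  stopifnot(any(free))
  g <- pairs$g[free][1]
  s <- pairs$s[free][1]
  net2 <- gene_network(
    dplyr::bind_rows(tibble::as_tibble(net),
                     tibble::tibble(gene_a = g, gene_b = s, weight = 0.8)),
    genes = genes
  )
  bumped <- rank_candidates(net2, cand, metric = "seed", seeds = seeds,
                            quiet = TRUE)
  expect_gt(bumped$score[bumped$gene == g], base$score[base$gene == g])
  expect_lte(bumped$rank[bumped$gene == g], base$rank[base$gene == g])
})

test_that("subnetwork degree never exceeds full-network degree", {
  for (seed in 1:5) {
    net <- rand_network(40, p = 0.2, seed = seed)
    cand <- network_genes(net)[seq(1, 40, by = 2)]
    sub <- build_subnetwork(net, cand, quiet = TRUE)
    sub_deg <- weighted_degree_centrality(sub)
    full_deg <- weighted_degree_centrality(net)
    full <- stats::setNames(full_deg$score, full_deg$gene)
    expect_true(all(sub_deg$score <= full[sub_deg$gene] + 1e-12))
  }
})

test_that("flag_novel returns zero-citation genes in the top fraction", {
  sm <- tibble::tibble(gene = sprintf("G%02d", 1:10),
                       score = seq(1, 0.1, length.out = 10))
  tab <- rank_genes(sm)
  ann <- tibble::tibble(
    gene = sprintf("G%02d", 1:10), description = "",
    citation_count = c(3L, 0L, rep(5L, 8))
  )
  expect_equal(flag_novel(tab, ann, top_fraction = 0.2)$gene, "G02")
  # all cited -> empty
  ann2 <- ann; ann2$citation_count <- 1L
  expect_equal(nrow(flag_novel(tab, ann2, top_fraction = 1)), 0L)
  # missing annotation counts as zero citations
  expect_true("G02" %in% flag_novel(tab, ann[2, ], top_fraction = 1)$gene)
  expect_error(flag_novel(tab, ann, top_fraction = 0), "top_fraction")
})

test_that("rank_candidates metrics agree with their building blocks", {
  net <- rand_network(30, p = 0.2, seed = 21)
  cand <- network_genes(net)[1:20]
  by_seed_all <- rank_candidates(net, cand, metric = "seed",
                                 seeds_all_genes = TRUE, quiet = TRUE)
  # whole-genome seed mode must reproduce full-network degree ordering
  deg <- weighted_degree_centrality(net)
  full <- stats::setNames(deg$score, deg$gene)[cand]
  want <- names(sort(-full))  # radix tie-break irrelevant: continuous
  expect_equal(by_seed_all$gene, want)
})
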