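# Synthetic networks with planted structure. These generators define the
# study conditions for all statistical tests: Erdos-Renyi background edges,
# a handful of planted hubs with a raised connection probability, and
# Beta-distributed weights on [0, 1] mimicking linkage probabilities.
# Everything is a pure function of its parameters plus an integer seed.

with_rng_seed <- function(seed, code) {
  withr::with_seed(
    as.integer(seed), code,
    .rng_kind = "Mersenne-Twister",
    .rng_normal_kind = "Inversion",
    .rng_sample_kind = "Rejection"
  )
}

gene_names <- function(n, prefix = "G") {
  sprintf("%s%04d", prefix, seq_len(n))
}

new_synthetic_truth <- function(network, candidates, planted_hubs,
                                planted_seed_associates, benchmark, seeds,
                                rng_seed, params) {
  structure(
    list(
      network = network,
      candidates = candidates,
      seeds = seeds,
      planted_hubs = planted_hubs,
      planted_seed_associates = planted_seed_associates,
      benchmark = benchmark,
      rng_seed = as.integer(rng_seed),
      params = params
    ),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "synthetic truth: %d genes, %d edges, %d planted positives (seed %d)\n",
    length(network_genes(x$network)), nrow(x$network),
    length(x$benchmark), x$rng_seed
  ))
  invisible(x)
}

#' Generate a network with planted hub genes
#'
#' Background gene pairs are connected independently with probability
#' `base_edge_prob`; pairs touching one of the `n_hubs` planted hub genes
#' connect with probability `hub_edge_prob`. Edge weights are drawn from
#' `Beta(weight_alpha, weight_beta)`, whose support matches the linkage
#' probability scale. The planted hubs double as the benchmark positive
#' set, so a ranking's ability to recover them is directly measurable by
#' AUC. Defaults (500 genes, 10 hubs, probabilities 0.01 vs 0.30,
#' Beta(2, 2) weights) give hub weighted degrees around 75 against a
#' background around 4 — a strong but not degenerate planted signal.
#'
#' @param n_genes Number of genes.
#' @param n_hubs Number of planted hubs (must be `< n_genes`).
#' @param base_edge_prob Background edge probability, in `(0, 1)`.
#' @param hub_edge_prob Edge probability for hub-incident pairs; must
#'   exceed `base_edge_prob` (equality is allowed to build null fixtures).
#' @param weight_alpha,weight_beta Beta parameters for edge weights.
#' @param rng_seed Integer seed; the whole fixture is reproducible from it.
#' @return A `synthetic_truth` list: `network` ([gene_network]),
#'   `candidates` (all genes), `planted_hubs`, `benchmark` (= the hubs),
#'   `rng_seed`, `params`.
#' @export
generate_hub_network <- function(n_genes = 500L, n_hubs = 10L,
                                 base_edge_prob = 0.01,
                                 hub_edge_prob = 0.30,
                                 weight_alpha = 2, weight_beta = 2,
                                 rng_seed = 1L) {
  if (!(n_hubs < n_genes) || n_hubs < 1) {
    abort("need 1 <= n_hubs < n_genes")
  }
  if (!(base_edge_prob > 0 && base_edge_prob <= hub_edge_prob &&
          hub_edge_prob <= 1)) {
    abort("need 0 < base_edge_prob <= hub_edge_prob <= 1")
  }
  genes <- gene_names(n_genes)
  with_rng_seed(rng_seed, {
    hubs <- sort_c(sample(genes, n_hubs))
    pairs <- upper_pairs(n_genes)
    is_hub_pair <- genes[pairs$i] %in% hubs | genes[pairs$j] %in% hubs
    p <- ifelse(is_hub_pair, hub_edge_prob, base_edge_prob)
    keep <- runif(length(p)) < p
    edges <- tibble::tibble(
      gene_a = genes[pairs$i[keep]],
      gene_b = genes[pairs$j[keep]],
      weight = rbeta(sum(keep), weight_alpha, weight_beta)
    )
    net <- gene_network(edges, genes = genes)
    new_synthetic_truth(
      network = net,
      candidates = tibble::tibble(gene = genes),
      planted_hubs = hubs,
      planted_seed_associates = character(0),
      benchmark = hubs,
      seeds = character(0),
      rng_seed = rng_seed,
      params = list(
        n_genes = n_genes, n_hubs = n_hubs,
        base_edge_prob = base_edge_prob, hub_edge_prob = hub_edge_prob,
        weight_alpha = weight_alpha, weight_beta = weight_beta
      )
    )
  })
}

# all unordered index pairs i < j
upper_pairs <- function(n) {
  j <- rep.int(seq_len(n), seq_len(n) - 1L)
  i <- sequence(seq_len(n) - 1L)
  list(i = i, j = j)
}

#' Generate a seed-association scenario
#'
#' Builds a background network, designates `n_seeds` seed genes, and
#' wires a planted set of `n_linked` candidate genes to every seed with
#' edges of weight `link_weight_boost` (overwriting any background edge
#' on those pairs). With `link_weight_boost = 0` no extra edges are added
#' and the planted labels carry no signal. Candidates are all non-seed
#' genes; the benchmark positive set is the planted linked set.
#'
#' @param n_genes Number of genes.
#' @param n_seeds Number of seed genes.
#' @param n_linked Number of planted seed-associated candidates
#'   (`n_seeds + n_linked <= n_genes`).
#' @param link_weight_boost Weight of the planted candidate-seed edges,
#'   in `[0, 1]`; 0 disables the planting (null scenario).
#' @param base_edge_prob Background edge probability.
#' @param weight_alpha,weight_beta Beta parameters for background weights.
#' @param rng_seed Integer seed.
#' @return A `synthetic_truth` with `seeds`, `planted_seed_associates`
#'   and `benchmark` (= the linked set) filled in; `candidates` are the
#'   non-seed genes.
#' @export
generate_seed_scenario <- function(n_genes = 200L, n_seeds = 20L,
                                   n_linked = 10L,
                                   link_weight_boost = 0.9,
                                   base_edge_prob = 0.05,
                                   weight_alpha = 2, weight_beta = 2,
                                   rng_seed = 1L) {
  if (n_seeds + n_linked > n_genes) {
    abort("need n_seeds + n_linked <= n_genes")
  }
  if (link_weight_boost < 0 || link_weight_boost > 1) {
    abort("link_weight_boost must be in [0, 1]")
  }
  genes <- gene_names(n_genes)
  with_rng_seed(rng_seed, {
    seeds <- sort_c(sample(genes, n_seeds))
    non_seed <- setdiff(genes, seeds)
    linked <- sort_c(sample(non_seed, n_linked))

    pairs <- upper_pairs(n_genes)
    keep <- runif(length(pairs$i)) < base_edge_prob
    edges <- tibble::tibble(
      gene_a = genes[pairs$i[keep]],
      gene_b = genes[pairs$j[keep]],
      weight = rbeta(sum(keep), weight_alpha, weight_beta)
    )
    if (link_weight_boost > 0) {
      planted <- tidyr::expand_grid(gene_a = linked, gene_b = seeds)
      planted$weight <- link_weight_boost
      # planted pairs replace any background edge on the same pair
      ka <- paste(pmin(edges$gene_a, edges$gene_b),
                  pmax(edges$gene_a, edges$gene_b), sep = "\t")
      kp <- paste(pmin(planted$gene_a, planted$gene_b),
                  pmax(planted$gene_a, planted$gene_b), sep = "\t")
      edges <- dplyr::bind_rows(edges[!ka %in% kp, ], planted)
    }
    net <- gene_network(edges, genes = genes)
    new_synthetic_truth(
      network = net,
      candidates = tibble::tibble(gene = non_seed),
      planted_hubs = character(0),
      planted_seed_associates = linked,
      benchmark = linked,
      seeds = seeds,
      rng_seed = rng_seed,
      params = list(
        n_genes = n_genes, n_seeds = n_seeds, n_linked = n_linked,
        link_weight_boost = link_weight_boost,
        base_edge_prob = base_edge_prob,
        weight_alpha = weight_alpha, weight_beta = weight_beta
      )
    )
  })
}

#' Generate a drug-target catalog against a synthetic truth
#'
#' A `hit_fraction` of the drugs get one target drawn from the planted
#' benchmark positives (plus background fillers up to `targets_per_drug`);
#' the remaining drugs target only background genes. Drug types alternate
#' approved/experimental by drug index.
#'
#' @param truth A `synthetic_truth`.
#' @param n_drugs Number of drugs.
#' @param targets_per_drug Targets per drug.
#' @param hit_fraction Fraction of drugs targeting at least one planted
#'   positive, in `[0, 1]`.
#' @param rng_seed Integer seed.
#' @return A drug catalog tibble (`drug`, `type`, `target`, `diseases`),
#'   as produced by [read_drug_catalog()].
#' @export
generate_drug_catalog <- function(truth, n_drugs = 20L,
                                  targets_per_drug = 3L,
                                  hit_fraction = 0.5, rng_seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (hit_fraction < 0 || hit_fraction > 1) {
    abort("hit_fraction must be in [0, 1]")
  }
  genes <- network_genes(truth$network)
  planted <- truth$benchmark
  background <- setdiff(genes, planted)
  n_hit <- round(hit_fraction * n_drugs)
  with_rng_seed(rng_seed, {
    rows <- purrr::map_dfr(seq_len(n_drugs), function(d) {
      is_hit <- d <= n_hit
      n_t <- min(targets_per_drug, length(background) + is_hit)
      targets <- if (is_hit) {
        c(sample(planted, 1L),
          sample(background, n_t - 1L))
      } else {
        sample(background, n_t)
      }
      tibble::tibble(
        drug = sprintf("DRUG%03d", d),
        type = if (d %% 2L == 1L) "approved" else "experimental",
        target = unique(targets),
        diseases = list("synthetic indication")
      )
    })
    rows
  })
}

#' Write a complete synthetic fixture directory
#'
#' Materializes a `synthetic_truth` (and optionally a drug catalog) as
#' the TSV files the loaders consume: `network.tsv`, `candidates.tsv`,
#' `seeds.tsv` (if any), `benchmark.tsv`, `annotations.tsv` (planted
#' positives get a positive citation count so citation benchmarks are
#' exercisable), `drugs.tsv`, and `manifest.txt` recording the seed and
#' parameters.
#'
#' @param truth A `synthetic_truth`.
#' @param dir Output directory (created if needed).
#' @param catalog Optional drug catalog tibble.
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(truth, dir, catalog = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed_line <- paste0("# rng_seed\t", truth$rng_seed)

  path <- file.path(dir, "network.tsv")
  write_gene_network(truth$network, path)
  prepend_line(path, seed_line)

  writeLines(c(seed_line, truth$candidates$gene),
             file.path(dir, "candidates.tsv"))
  if (length(truth$seeds) > 0) {
    writeLines(c(seed_line, truth$seeds), file.path(dir, "seeds.tsv"))
  }
  writeLines(c(seed_line, truth$benchmark),
             file.path(dir, "benchmark.tsv"))

  # planted positives get graded citation counts (3, 6, 9, ...) so that
  # citation-cutoff sweeps produce properly nested, shrinking benchmarks
  genes <- network_genes(truth$network)
  cit <- integer(length(genes))
  cit[match(truth$benchmark, genes)] <- 3L * seq_along(truth$benchmark)
  writeLines(
    c(seed_line,
      sprintf("%s\tsynthetic gene\t%d", genes, cit)),
    file.path(dir, "annotations.tsv")
  )
  if (!is.null(catalog)) {
    writeLines(
      c(seed_line,
        sprintf(
          "%s\t%s\t%s\t%s",
          catalog$drug, catalog$type, catalog$target,
          vapply(catalog$diseases, paste, "", collapse = ";")
        )),
      file.path(dir, "drugs.tsv")
    )
  }
  writeLines(
    c(
      "# synthetic fixture manifest",
      paste0("rng_seed=", truth$rng_seed),
      paste0(names(truth$params), "=",
             vapply(truth$params, format, "")),
      paste0("n_genes_emitted=", length(genes)),
      paste0("n_edges_emitted=", nrow(truth$network)),
      paste0("benchmark=", paste(truth$benchmark, collapse = ","))
    ),
    file.path(dir, "manifest.txt")
  )
  invisible(dir)
}

prepend_line <- function(path, line) {
  writeLines(c(line, readr::read_lines(path, progress = FALSE)), path)
}
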