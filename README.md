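# targetrank

Network-based prioritization of candidate cancer genes and drug
candidates.

High-throughput profiling of a tumor produces thousands of candidate
genes — differentially expressed or mutated versus normal tissue — and
the hard part is deciding which few are worth pursuing as drivers or
therapeutic targets. `targetrank` ranks such candidates over a weighted
gene functional network: an undirected graph whose edge weights are
linkage probabilities in [0, 1] quantifying the tendency of two genes to
operate in the same or similar pathways. It is aimed at computational
biologists who already have (or can generate) such a network and a
candidate list, and want reproducible, benchmarkable rankings from the
command line or from R.

## The method

Given the full network *G* with weights *w(i, j)* and a candidate set
*C* mapped onto it (exact, case-insensitive identifier matching),
`targetrank` offers three scores:

* **Hub score, weighted degree** — on the tumor-specific subnetwork
  *G*[*C*] (the subgraph induced by the candidates):
  deg<sub>w</sub>(g) = Σ<sub>h∈C</sub> *w*(g, h). Cancer genes are
  enriched among network hubs, whose perturbation dysregulates many
  pathways at once.
* **Hub score, weighted eigenvector centrality** — the leading
  eigenvector of *G*[*C*]'s weighted adjacency (nonnegative, unit L2
  norm), computed by shifted power iteration; captures global rather
  than merely local connectivity.
* **Seed-gene association** (guilt by association) — assoc(g) =
  Σ<sub>s∈S, s≠g</sub> *w*(g, s) over the **full** network, for a
  user-chosen seed set *S* such as known cancer genes. With *S* = all
  network genes this equals the full-network weighted degree — the mode
  used to screen mutated genes for drivers.

Candidates are ranked by descending score (lexicographic tie-breaks;
unmapped candidates keep score 0 at the tail, flagged). A drug–target
catalog can be joined onto the ranking — drugs ordered by their best
target's rank — and rankings are validated against benchmark gene sets
with tie-corrected ROC/AUC, citation-cutoff sweeps and Spearman
rank–citation correlation. A synthetic generator plants hubs,
seed-linked genes and benchmark truth so the whole pipeline is testable
without any external data.

## Worked example

```r
library(targetrank)

truth  <- generate_hub_network(n_genes = 200, n_hubs = 8, rng_seed = 7)
ranked <- rank_candidates(truth$network, truth$candidates,
                          metric = "degree", quiet = TRUE)
head(tidy(ranked))
#> # A tibble: 6 × 4
#>    rank gene  score mapped
#>   <int> <chr> <dbl> <lgl>
#> 1     1 G0103  33.9 TRUE
#> 2     2 G0159  33.9 TRUE
#> 3     3 G0136  33.2 TRUE
#> 4     4 G0015  30.0 TRUE
#> 5     5 G0067  28.1 TRUE
#> 6     6 G0194  27.8 TRUE
```

The top-ranked genes have subnetwork weighted degrees of ~28–34 versus a
background around 4 — and they are exactly the planted hubs
(`truth$planted_hubs`), whose recovery the ROC quantifies:

```r
roc_auc(ranked, truth$benchmark)
#> ROC: AUC = 1.0000 (8 positives, 192 negatives, 200 curve points)
```

An AUC of 1.0 means every planted hub outranks every background gene.
Joining a drug catalog reports drugs by their best-ranked target:

```r
catalog <- generate_drug_catalog(truth, n_drugs = 10, hit_fraction = 1,
                                 rng_seed = 7)
head(prioritize_drugs(ranked, catalog), 3)
#> # A tibble: 3 × 8
#>   drug    type         n_candidate_targets best_target best_target_rank ...
#> 1 DRUG004 experimental                   3 G0136                      3
#> 2 DRUG010 experimental                   3 G0136                      3
#> 3 DRUG005 approved                       3 G0067                      5
```

Here `DRUG004`'s best target is the rank-3 gene `G0136`, so it heads the
drug list; `best_target_rank` is the minimum rank over each drug's
targets present in the candidate table.

## Command line

```sh
targetrank simulate --out fixture --seed 7 --n-genes 500 --n-hubs 10
targetrank rank --network fixture/network.tsv \
    --candidates fixture/candidates.tsv --metric degree --out run1
targetrank drugs --network fixture/network.tsv \
    --candidates fixture/candidates.tsv \
    --drug-catalog fixture/drugs.tsv --out run1
targetrank evaluate --network fixture/network.tsv \
    --candidates fixture/candidates.tsv \
    --benchmark fixture/benchmark.tsv \
    --annotations fixture/annotations.tsv \
    --citation-cutoffs 1,5,10 --out run1
```

(The script installs to `exec/targetrank` inside the package library;
`targetrank_cli()` exposes the same subcommands from R.) All inputs are
plain TSV; every run writes a `manifest.txt` echoing parameters and
counts. A `--config key=value` file can supply defaults that flags
override.

See `vignettes/targetrank-methods.Rmd` for the model, numerical choices
and the synthetic study conditions in detail.

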