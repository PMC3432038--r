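# Benchmark evaluation: ROC/AUC of a ranking against a positive gene set,
# citation-cutoff benchmark construction, and Spearman rank-citation
# correlation. The evaluation universe is the ranked candidate table;
# benchmark genes inside it are positives, all other candidates negatives.

#' ROC curve and AUC of a ranking against a benchmark gene set
#'
#' Sweeps a confidence threshold down the ranking (higher score = more
#' confident positive call). Tied scores are handled by grouping: the
#' curve gets one vertex per distinct score value, so the score-0 unmapped
#' tail contributes a single diagonal segment rather than an arbitrary
#' ordering. The AUC is computed two ways — trapezoidal integration of the
#' curve and the tie-corrected (midrank) Mann–Whitney statistic — and the
#' two are asserted to agree to within `1e-12`; the probability
#' interpretation (chance a random positive outranks a random negative,
#' ties counting half) therefore holds exactly.
#'
#' @param table A `ranked_genes` tibble (the evaluation universe).
#' @param benchmark Positive gene set: character vector or tibble with a
#'   `gene` column. Only the intersection with the table's genes is used.
#' @return A `roc_result`: list with `points` (tibble `fpr`, `tpr`,
#'   starting at (0,0) and ending at (1,1)), `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(table, benchmark) {
  stopifnot(is.data.frame(table))
  positives <- unique(as_gene_ids(benchmark, "benchmark"))
  label <- table$gene %in% positives
  n_pos <- sum(label)
  n_neg <- sum(!label)
  if (n_pos == 0) abort("no benchmark positives in the ranked universe")
  if (n_neg == 0) abort("no negatives in the ranked universe")

  score <- table$score
  ord <- order(-score, method = "radix")
  s <- score[ord]
  l <- label[ord]
  # one ROC vertex per distinct score group
  grp_end <- which(s != c(s[-1], NA_real_) | seq_along(s) == length(s))
  tp <- cumsum(l)[grp_end]
  fp <- (grp_end - cumsum(l)[grp_end])
  points <- tibble::tibble(
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
  auc_trap <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                                        points$tpr[-1]) / 2)

  # tie-corrected Mann-Whitney with midranks
  r <- rank(score, ties.method = "average")
  auc_mw <- (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  if (abs(auc_trap - auc_mw) > 1e-12) {
    abort(sprintf(
      "internal AUC inconsistency: trapezoid %.15f vs rank-sum %.15f",
      auc_trap, auc_mw
    ))
  }
  structure(
    list(points = points, auc = auc_mw, n_pos = n_pos, n_neg = n_neg),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC = %.4f (%d positives, %d negatives, %d curve points)\n",
    x$auc, x$n_pos, x$n_neg, nrow(x$points)
  ))
  invisible(x)
}

#' Build a benchmark set from citation counts
#'
#' Positives are the genes whose cancer-literature citation count meets
#' the cutoff. Sweeping the cutoff upward yields nested, shrinking
#' positive sets of increasingly well-established cancer genes.
#'
#' @param annotations Annotation tibble (`gene`, `citation_count`).
#' @param cutoff Minimum citation count, at least 1.
#' @return Character vector of positive gene identifiers.
#' @export
benchmark_from_citations <- function(annotations, cutoff) {
  stopifnot(is.data.frame(annotations))
  cutoff <- as.integer(cutoff)
  if (is.na(cutoff) || cutoff < 1) abort("citation cutoff must be >= 1")
  ann <- tibble::as_tibble(annotations)
  pos <- normalize_gene_ids(ann$gene[ann$citation_count >= cutoff])
  if (length(pos) == 0) {
    abort(paste0("no gene meets citation cutoff ", cutoff))
  }
  sort_c(unique(pos))
}

#' Spearman correlation between rank and citation count
#'
#' Tie-corrected Spearman rho between a gene's position in the ranking and
#' its cancer-literature citation count, with a large-sample t
#' approximation for the p-value. The sign convention is chosen so that
#' "better rank goes with more citations" is reported as a positive
#' association (rho is computed against descending rank). An exact
#' permutation p-value is available for small tables.
#'
#' @param table A `ranked_genes` tibble.
#' @param annotations Annotation tibble (`gene`, `citation_count`); only
#'   annotated genes enter the correlation, and at least 3 are required.
#' @param exact Compute the p-value by full permutation enumeration
#'   (supported up to 8 annotated genes; the t approximation is returned
#'   otherwise).
#' @return A tibble with one row: `rho`, `p_value`, `n`, `method`.
#' @export
spearman_rank_citation <- function(table, annotations, exact = FALSE) {
  stopifnot(is.data.frame(table), is.data.frame(annotations))
  ann <- tibble::as_tibble(annotations)
  cit <- setNames(as.double(ann$citation_count),
                  normalize_gene_ids(ann$gene))
  keep <- table$gene %in% names(cit)
  if (sum(keep) < 3) abort("need at least 3 annotated genes")
  x <- -as.double(table$rank[keep])  # descending rank: better = larger
  y <- unname(cit[table$gene[keep]])
  if (length(unique(y)) == 1) {
    abort("correlation undefined: citation counts are constant")
  }
  rho <- spearman_rho(x, y)
  n <- length(x)
  if (exact && n <= 8) {
    p <- spearman_perm_p(x, y)
    method <- "exact permutation"
  } else {
    # large-sample t approximation on midranks
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  tibble::tibble(rho = rho, p_value = p, n = n, method = method)
}

# Pearson correlation of midranks (the tie-corrected Spearman rho)
spearman_rho <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  stats::cor(rx, ry)
}

# two-sided exact permutation p-value by full enumeration (n <= 8)
spearman_perm_p <- function(x, y) {
  obs <- abs(spearman_rho(x, y))
  perms <- all_permutations(length(y))
  rhos <- apply(perms, 1, function(p) spearman_rho(x, y[p]))
  mean(abs(rhos) >= obs - 1e-12)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Evaluate a ranking against several benchmark sets
#'
#' Runs [roc_auc()] for each named benchmark and collects one row per
#' benchmark. A benchmark that fails (e.g. disjoint from the candidate
#' universe) yields a row with `NA` AUC and the error message in `note`
#' rather than aborting the whole sweep.
#'
#' @param table A `ranked_genes` tibble.
#' @param benchmarks Named list of gene sets (character vectors or gene
#'   tibbles).
#' @return An `evaluation_report` tibble: `benchmark`, `n_pos`, `n_neg`,
#'   `auc`, `note`; ROC objects are kept in the `roc` attribute (named
#'   list, `NULL` where evaluation failed).
#' @export
evaluate_benchmarks <- function(table, benchmarks) {
  stopifnot(is.list(benchmarks), length(benchmarks) >= 1)
  if (is.null(names(benchmarks)) || any(!nzchar(names(benchmarks)))) {
    abort("benchmarks must be a named list")
  }
  rocs <- vector("list", length(benchmarks))
  names(rocs) <- names(benchmarks)
  rows <- purrr::imap_dfr(benchmarks, function(bm, name) {
    res <- tryCatch(roc_auc(table, bm), error = function(e) e)
    if (inherits(res, "error")) {
      tibble::tibble(
        benchmark = name, n_pos = NA_integer_, n_neg = NA_integer_,
        auc = NA_real_, note = conditionMessage(res)
      )
    } else {
      rocs[[name]] <<- res
      tibble::tibble(
        benchmark = name, n_pos = res$n_pos, n_neg = res$n_neg,
        auc = res$auc, note = ""
      )
    }
  })
  attr(rows, "roc") <- rocs
  class(rows) <- c("evaluation_report", class(tibble::tibble()))
  rows
}

#' AUC sweep over citation cutoffs
#'
#' Builds one citation benchmark per cutoff with
#' [benchmark_from_citations()] and evaluates each. Mirrors the
#' literature-citation validation in which higher cutoffs select
#' better-established cancer genes.
#'
#' @param table A `ranked_genes` tibble.
#' @param annotations Annotation tibble.
#' @param cutoffs Integer vector of citation cutoffs (default `c(1, 5,
#'   10)`).
#' @return An `evaluation_report` tibble, one row per cutoff
#'   (`citations>=k` naming).
#' @export
citation_cutoff_sweep <- function(table, annotations,
                                  cutoffs = c(1L, 5L, 10L)) {
  benchmarks <- lapply(cutoffs, function(k) {
    tryCatch(benchmark_from_citations(annotations, k),
             error = function(e) character(0))
  })
  names(benchmarks) <- paste0("citations>=", cutoffs)
  evaluate_benchmarks(table, benchmarks)
}

#' Write an evaluation report (and optional ROC point files)
#'
#' @param report An `evaluation_report` from [evaluate_benchmarks()].
#' @param path Output TSV path.
#' @param roc_dir Optional directory; when given, each successful
#'   benchmark's ROC points are written there as
#'   `roc_<benchmark>.tsv` (two columns, `fpr` and `tpr`).
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path, roc_dir = NULL) {
  stopifnot(is.data.frame(report))
  lines <- c(
    "# benchmark\tn_pos\tn_neg\tauc\tnote",
    sprintf(
      "%s\t%s\t%s\t%s\t%s",
      report$benchmark,
      ifelse(is.na(report$n_pos), "NA", report$n_pos),
      ifelse(is.na(report$n_neg), "NA", report$n_neg),
      ifelse(is.na(report$auc), "NA", sprintf("%.12g", report$auc)),
      report$note
    )
  )
  writeLines(lines, path)
  rocs <- attr(report, "roc")
  if (!is.null(roc_dir) && !is.null(rocs)) {
    dir.create(roc_dir, showWarnings = FALSE, recursive = TRUE)
    for (name in names(rocs)) {
      if (is.null(rocs[[name]])) next
      safe <- gsub("[^A-Za-z0-9._-]", "_", name)
      p <- rocs[[name]]$points
      writeLines(
        c("# fpr\ttpr", sprintf("%.12g\t%.12g", p$fpr, p$tpr)),
        file.path(roc_dir, paste0("roc_", safe, ".tsv"))
      )
    }
  }
  invisible(path)
}
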