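# Drug Panel: join a drug-target catalog onto a ranked gene table and order
# drugs by their best (lowest) target rank.

#' Prioritize drugs by their best-ranked candidate target
#'
#' For every drug in the catalog with at least one target among the ranked
#' candidate genes, reports the number of candidate targets, the highest
#' ranked (minimum-rank) target and its rank, and the union of the drug's
#' disease annotations. Drugs with no target in the table are dropped.
#' Rows are ordered by ascending best target rank, ties broken
#' lexicographically by drug name.
#'
#' By default unmapped candidates (the score-0 tail of the ranking) still
#' count as targets, at their tail ranks; set `mapped_only = TRUE` to
#' restrict to candidates that mapped to the network.
#'
#' @param table A `ranked_genes` tibble.
#' @param catalog A drug catalog tibble from [read_drug_catalog()] (columns
#'   `drug`, `type`, `target`, `diseases`).
#' @param type Optional filter: `"approved"` or `"experimental"`.
#' @param max_rank Optional cutoff: keep only drugs whose best target rank
#'   is at most this.
#' @param mapped_only Ignore the unmapped score-0 tail of the ranking.
#' @return A `drug_ranking` tibble: `drug`, `type`, `n_candidate_targets`,
#'   `best_target`, `best_target_rank`, `targets` (list-column of all
#'   candidate target genes, best first), `diseases` (list-column).
#'   An empty result is valid.
#' @export
prioritize_drugs <- function(table, catalog, type = NULL, max_rank = NULL,
                             mapped_only = FALSE) {
  stopifnot(is.data.frame(table), is.data.frame(catalog))
  if (nrow(table) == 0 || nrow(catalog) == 0) {
    abort("ranked table and drug catalog must be nonempty")
  }
  if (!is.null(type)) {
    type <- match.arg(type, c("approved", "experimental"))
  }

  universe <- table[, c("rank", "gene", "mapped")]
  if (mapped_only) universe <- universe[universe$mapped, ]

  hits <- dplyr::inner_join(
    tibble::as_tibble(catalog), universe,
    by = c(target = "gene")
  )
  out <- hits |>
    dplyr::group_by(.data$drug) |>
    dplyr::arrange(.data$rank, .by_group = TRUE) |>
    dplyr::summarise(
      type = .data$type[1],
      n_candidate_targets = dplyr::n(),
      best_target = .data$target[1],
      best_target_rank = as.integer(.data$rank[1]),
      targets = list(.data$target),
      target_ranks = list(as.integer(.data$rank)),
      diseases = list(sort_c(unique(unlist(.data$diseases)))),
      .groups = "drop"
    )
  if (!is.null(type)) out <- out[out$type == type, ]
  if (!is.null(max_rank)) out <- out[out$best_target_rank <= max_rank, ]
  out <- out[order(out$best_target_rank, out$drug, method = "radix"), ]
  class(out) <- c("drug_ranking", class(tibble::tibble()))
  out
}

# "GENE(#rank; fold)" cells, ';'-joined — the Drug Panel's presentation of
# a drug's candidate targets
format_target_cell <- function(targets, ranks, fold_changes) {
  fc <- unname(fold_changes[targets])
  cell <- ifelse(
    is.na(fc),
    sprintf("%s(#%d)", targets, ranks),
    sprintf("%s(#%d; %.3f)", targets, ranks, fc)
  )
  paste(cell, collapse = ";")
}

#' Write a drug report
#'
#' One row per drug: name, type, number of candidate targets, best target
#' and its rank, all candidate targets formatted as `GENE(#rank; fold)`
#' and `;`-joined (fold change shown when the ranked table carries one),
#' and the disease list. An empty ranking yields a header-only file.
#'
#' @param ranking A `drug_ranking` from [prioritize_drugs()].
#' @param table The `ranked_genes` tibble the ranking was computed from
#'   (source of fold changes).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_drug_report <- function(ranking, table, path) {
  stopifnot(is.data.frame(ranking))
  header <- paste0(
    "# drug\ttype\tn_candidate_targets\tbest_target\tbest_target_rank",
    "\ttargets\tdiseases"
  )
  fc <- if ("fold_change" %in% names(table)) {
    setNames(table$fold_change, table$gene)
  } else {
    setNames(rep(NA_real_, nrow(table)), table$gene)
  }
  body <- character(0)
  if (nrow(ranking) > 0) {
    cells <- purrr::map2_chr(
      ranking$targets, ranking$target_ranks,
      function(t, r) format_target_cell(t, r, fc)
    )
    body <- sprintf(
      "%s\t%s\t%d\t%s\t%d\t%s\t%s",
      ranking$drug, ranking$type, ranking$n_candidate_targets,
      ranking$best_target, ranking$best_target_rank, cells,
      vapply(ranking$diseases, paste, "", collapse = ";")
    )
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Parse the target ranks back out of a drug report
#'
#' Round-trip helper: reads a file written by [write_drug_report()] and
#' returns one row per (drug, target) with the rank parsed from the
#' `GENE(#rank; ...)` cells.
#'
#' @param path Path to a drug report TSV.
#' @return A tibble `drug`, `target`, `rank`.
#' @export
read_drug_report_ranks <- function(path) {
  parsed <- read_tsv_lines(path, 7L)
  f <- parsed$fields
  purrr::map_dfr(f, function(x) {
    cells <- strsplit(x[[6L]], ";", fixed = TRUE)[[1]]
    cells <- cells[grepl("\\(#", cells)]
    m <- regmatches(cells, regexec("^([^(]+)\\(#([0-9]+)", cells))
    tibble::tibble(
      drug = x[[1L]],
      target = vapply(m, `[[`, "", 2L),
      rank = as.integer(vapply(m, `[[`, "", 3L))
    )
  })
}
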