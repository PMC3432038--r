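# File formats. Everything is plain TSV, UTF-8, LF or CRLF; lines starting
# with '#' are comments/headers everywhere. Parsing is done line by line so
# that every validation error can name the offending line.

# returns tibble(line = original line number, fields = list of character)
read_tsv_lines <- function(path, n_fields_min, n_fields_max = n_fields_min) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "targetrank_missing_file")
  }
  raw <- readr::read_lines(path, progress = FALSE)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lines <- which(keep)
  fields <- strsplit(raw[keep], "\t", fixed = TRUE)
  n <- lengths(fields)
  bad <- which(n < n_fields_min | n > n_fields_max)
  if (length(bad) > 0) {
    abort(paste0(
      "malformed line ", lines[bad[1]], " in ", basename(path),
      ": expected ", n_fields_min,
      if (n_fields_max > n_fields_min) paste0("-", n_fields_max) else "",
      " tab-separated fields, got ", n[bad[1]]
    ))
  }
  list(line = lines, fields = fields)
}

parse_numeric_field <- function(x, lines, what, path) {
  suppressWarnings(v <- as.double(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad) > 0) {
    abort(paste0(
      "non-numeric ", what, " at line ", lines[bad[1]], " in ",
      basename(path), ": '", x[bad[1]], "'"
    ))
  }
  v
}

#' Read a weighted gene network from an edge-list TSV
#'
#' Expects three tab-separated columns per line: `geneA`, `geneB`,
#' `weight` (a linkage probability in `[0, 1]`). Lines starting with `#`
#' are ignored. Symmetric duplicate records (`A B w` and `B A w`) are
#' deduplicated with a warning when their weights agree to within `1e-12`;
#' unequal weights are an error. Self-loops are an error when
#' `strict = TRUE` and are dropped with a warning otherwise.
#'
#' @param path Path to the edge-list file.
#' @param strict If `TRUE`, self-loops abort instead of being dropped.
#' @param quiet Suppress the parsed gene/edge count message.
#' @return A [gene_network].
#' @export
read_gene_network <- function(path, strict = FALSE, quiet = FALSE) {
  parsed <- read_tsv_lines(path, 3L)
  lines <- parsed$line
  f <- parsed$fields
  gene_a <- normalize_gene_ids(vapply(f, `[[`, "", 1L))
  gene_b <- normalize_gene_ids(vapply(f, `[[`, "", 2L))
  weight <- parse_numeric_field(
    vapply(f, `[[`, "", 3L), lines, "weight", path
  )
  if (length(gene_a) == 0) abort(paste0("empty network file: ", path))

  bad_w <- which(!is.finite(weight) | weight < 0 | weight > 1)
  if (length(bad_w) > 0) {
    abort(paste0(
      "weight outside [0, 1] at line ", lines[bad_w[1]], " in ",
      basename(path), ": ", weight[bad_w[1]]
    ))
  }

  loops <- which(gene_a == gene_b)
  if (length(loops) > 0) {
    if (strict) {
      abort(paste0(
        "self-loop at line ", lines[loops[1]], " in ", basename(path),
        ": ", gene_a[loops[1]]
      ))
    }
    warn(paste0("dropped ", length(loops), " self-loop record(s)"))
    keep <- setdiff(seq_along(gene_a), loops)
    gene_a <- gene_a[keep]; gene_b <- gene_b[keep]
    weight <- weight[keep]; lines <- lines[keep]
  }

  # canonical order, then collapse symmetric/exact duplicates
  a <- pmin(gene_a, gene_b)
  b <- pmax(gene_a, gene_b)
  key <- paste(a, b, sep = "\t")
  dup <- duplicated(key)
  if (any(dup)) {
    first_w <- weight[match(key, key)]
    clash <- which(dup & abs(weight - first_w) > 1e-12)
    if (length(clash) > 0) {
      abort(paste0(
        "conflicting weights for edge ", a[clash[1]], "-", b[clash[1]],
        " at line ", lines[clash[1]], " in ", basename(path)
      ))
    }
    warn(paste0(
      "deduplicated ", sum(dup), " symmetric/repeated edge record(s)"
    ))
    a <- a[!dup]; b <- b[!dup]; weight <- weight[!dup]
  }

  # "#! isolated<TAB>GENE" marker lines keep edge-less genes across round trips
  raw <- readr::read_lines(path, progress = FALSE)
  iso_lines <- grep("^#! isolated\t", raw, value = TRUE)
  isolated <- normalize_gene_ids(sub("^#! isolated\t", "", iso_lines))
  genes <- unique(c(a, b, isolated))

  net <- gene_network(
    tibble::tibble(gene_a = a, gene_b = b, weight = weight),
    genes = genes
  )
  if (!quiet) {
    inform(sprintf(
      "read network: %d genes, %d edges from %s",
      length(network_genes(net)), nrow(net), basename(path)
    ))
  }
  net
}

#' Write a gene network as an edge-list TSV
#'
#' Weights are serialized with `%.17g`, so a write/read cycle reproduces
#' the network exactly (gene set, edge set and weights).
#'
#' @param net A [gene_network].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_network <- function(net, path) {
  validate_gene_network(net)
  isolated <- setdiff(network_genes(net), unique(c(net$gene_a, net$gene_b)))
  header <- "# gene_a\tgene_b\tweight"
  body <- sprintf("%s\t%s\t%.17g", net$gene_a, net$gene_b, net$weight)
  # isolated genes are recorded as comment lines so round-trips keep them
  iso <- if (length(isolated) > 0) paste0("#! isolated\t", isolated)
  writeLines(c(header, iso, body), path)
  invisible(path)
}

#' Read a candidate/seed/benchmark gene list
#'
#' One gene per line; an optional second tab-separated column carries a
#' numeric per-gene value (typically an expression fold change). Duplicate
#' identifiers (after case normalization) are collapsed keeping the first
#' occurrence.
#'
#' @param path Path to the list file.
#' @param quiet Suppress the dropped-duplicate message.
#' @return A tibble with column `gene` and, when present in the file,
#'   `value`.
#' @export
read_gene_list <- function(path, quiet = FALSE) {
  parsed <- read_tsv_lines(path, 1L, 2L)
  f <- parsed$fields
  if (length(f) == 0) abort(paste0("empty gene list: ", path))
  ids <- normalize_gene_ids(vapply(f, `[[`, "", 1L))
  has_value <- lengths(f) == 2L
  values <- rep(NA_real_, length(ids))
  if (any(has_value)) {
    values[has_value] <- parse_numeric_field(
      vapply(f[has_value], `[[`, "", 2L),
      parsed$line[has_value], "value", path
    )
  }
  dup <- duplicated(ids)
  if (any(dup) && !quiet) {
    inform(sprintf("dropped %d duplicate gene id(s)", sum(dup)))
  }
  out <- tibble::tibble(gene = ids[!dup])
  if (any(has_value)) out$value <- values[!dup]
  out
}

#' Read a gene annotation table
#'
#' Three tab-separated columns: gene, free-text description, and a
#' nonnegative integer count of cancer-literature citations for that gene.
#'
#' @param path Path to the annotation TSV.
#' @return A tibble with columns `gene`, `description`, `citation_count`.
#' @export
read_gene_annotations <- function(path) {
  parsed <- read_tsv_lines(path, 3L)
  f <- parsed$fields
  cit <- parse_numeric_field(
    vapply(f, `[[`, "", 3L), parsed$line, "citation count", path
  )
  bad <- which(cit < 0 | cit != floor(cit))
  if (length(bad) > 0) {
    abort(paste0(
      "citation count must be a nonnegative integer at line ",
      parsed$line[bad[1]], " in ", basename(path)
    ))
  }
  tibble::tibble(
    gene = normalize_gene_ids(vapply(f, `[[`, "", 1L)),
    description = vapply(f, `[[`, "", 2L),
    citation_count = as.integer(cit)
  )
}

#' Read a drug-target catalog
#'
#' Four tab-separated columns: drug name, drug type (`approved` or
#' `experimental`), target gene, and a `;`-separated disease list (may be
#' empty). Duplicate (drug, target) pairs are an error.
#'
#' @param path Path to the catalog TSV.
#' @return A tibble with columns `drug`, `type`, `target`, `diseases`
#'   (list-column of character vectors).
#' @export
read_drug_catalog <- function(path) {
  parsed <- read_tsv_lines(path, 3L, 4L)
  f <- parsed$fields
  if (length(f) == 0) abort(paste0("empty drug catalog: ", path))
  type <- tolower(trimws(vapply(f, `[[`, "", 2L)))
  bad <- which(!type %in% c("approved", "experimental"))
  if (length(bad) > 0) {
    abort(paste0(
      "unknown drug type '", type[bad[1]], "' at line ", parsed$line[bad[1]],
      " in ", basename(path), " (expected approved/experimental)"
    ))
  }
  diseases <- vapply(f, function(x) if (length(x) >= 4L) x[[4L]] else "", "")
  out <- tibble::tibble(
    drug = trimws(vapply(f, `[[`, "", 1L)),
    type = type,
    target = normalize_gene_ids(vapply(f, `[[`, "", 3L)),
    diseases = lapply(strsplit(diseases, ";", fixed = TRUE), function(d) {
      d <- trimws(d)
      d[nzchar(d)]
    })
  )
  key <- paste(out$drug, out$target, sep = "\t")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    abort(paste0(
      "duplicate drug-target pair: ", out$drug[i], " / ", out$target[i]
    ))
  }
  out
}

#' Write a ranked gene table
#'
#' Tab-separated with a `#`-prefixed header; scores carry 12 significant
#' digits so re-loading reproduces ranks (and scores) losslessly. The fold
#' change column appears only if the table has one; likewise
#' `citation_count`.
#'
#' @param table A `ranked_genes` tibble from [rank_genes()] or
#'   [rank_candidates()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranked_table <- function(table, path) {
  stopifnot(is.data.frame(table), nrow(table) > 0)
  cols <- c("rank", "gene", "score", "mapped")
  if ("fold_change" %in% names(table)) cols <- c(cols, "fold_change")
  if ("citation_count" %in% names(table)) cols <- c(cols, "citation_count")
  out <- table[, cols]
  out$score <- sprintf("%.12g", out$score)
  if ("fold_change" %in% cols) {
    out$fold_change <- ifelse(
      is.na(out$fold_change), "NA", sprintf("%.12g", out$fold_change)
    )
  }
  out$mapped <- ifelse(out$mapped, "TRUE", "FALSE")
  lines <- c(
    paste0("# ", paste(cols, collapse = "\t")),
    do.call(paste, c(unname(as.list(out)), sep = "\t"))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read back a ranked gene table written by [write_ranked_table()]
#'
#' @param path Path to the ranked TSV.
#' @return A `ranked_genes` tibble.
#' @export
read_ranked_table <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  header <- readr::read_lines(path, n_max = 1L)
  cols <- strsplit(sub("^#\\s*", "", header), "\t", fixed = TRUE)[[1]]
  parsed <- read_tsv_lines(path, length(cols))
  f <- parsed$fields
  out <- tibble::as_tibble(setNames(
    lapply(seq_along(cols), function(i) vapply(f, `[[`, "", i)), cols
  ))
  out$rank <- as.integer(out$rank)
  out$score <- as.double(out$score)
  out$mapped <- out$mapped == "TRUE"
  if ("fold_change" %in% cols) {
    out$fold_change <- suppressWarnings(as.double(out$fold_change))
  }
  if ("citation_count" %in% cols) {
    out$citation_count <- as.integer(out$citation_count)
  }
  class(out) <- c("ranked_genes", class(tibble::tibble()))
  out
}
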