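# gene_network: a tibble of undirected weighted edges plus the full gene set
# (isolated genes carry no edge rows, so the gene vector lives in an attribute).

#' Construct a gene functional network
#'
#' A `gene_network` is a tibble of undirected edges — columns `gene_a`,
#' `gene_b` and `weight` — together with the complete set of member genes
#' (kept in an attribute so that isolated genes survive). Each weight is a
#' linkage probability in `[0, 1]` quantifying the tendency of the two genes
#' to operate in the same or similar pathways. Edges are stored once, in
#' canonical order (`gene_a < gene_b` in the C locale); self-loops are
#' forbidden.
#'
#' @param edges A data frame with columns `gene_a`, `gene_b`, `weight`
#'   (extra columns are dropped). Gene identifiers are uppercased.
#' @param genes Optional character vector of member genes. Defaults to the
#'   genes appearing in `edges`; endpoints absent from `genes` are an error.
#'
#' @return A tibble of class `gene_network`.
#' @examples
#' net <- gene_network(
#'   tibble::tibble(
#'     gene_a = c("A", "B", "C"),
#'     gene_b = c("B", "C", "D"),
#'     weight = c(0.5, 0.3, 0.9)
#'   )
#' )
#' network_genes(net)
#' @export
gene_network <- function(edges, genes = NULL) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) == 0 && is.null(genes)) {
    abort("a gene network needs at least one edge or an explicit gene set")
  }
  edges <- tibble::as_tibble(edges)[, c("gene_a", "gene_b", "weight")]
  edges$gene_a <- normalize_gene_ids(edges$gene_a)
  edges$gene_b <- normalize_gene_ids(edges$gene_b)
  edges$weight <- as.double(edges$weight)

  # canonical endpoint order makes symmetric duplicates collapse trivially
  swap <- edges$gene_a > edges$gene_b
  if (any(swap)) {
    tmp <- edges$gene_a[swap]
    edges$gene_a[swap] <- edges$gene_b[swap]
    edges$gene_b[swap] <- tmp
  }
  edges <- dplyr::arrange(edges, .data$gene_a, .data$gene_b)

  endpoint_genes <- unique(c(edges$gene_a, edges$gene_b))
  if (is.null(genes)) {
    genes <- sort_c(endpoint_genes)
  } else {
    genes <- normalize_gene_ids(genes)
    if (anyDuplicated(genes)) genes <- unique(genes)
    missing <- setdiff(endpoint_genes, genes)
    if (length(missing) > 0) {
      abort(paste0(
        "edge endpoints not in the declared gene set: ",
        paste(head(missing, 5), collapse = ", ")
      ))
    }
    genes <- sort_c(genes)
  }

  out <- new_gene_network(edges, genes)
  validate_gene_network(out)
  out
}

new_gene_network <- function(edges, genes, class = character()) {
  structure(
    edges,
    genes = genes,
    class = c(class, "gene_network", class(tibble::tibble()))
  )
}

#' Validate the invariants of a gene network
#'
#' Checks that weights lie in `[0, 1]`, that there are no self-loops, no
#' duplicate edges, and that every endpoint belongs to the gene set. Called
#' by the constructor and by the loader; exported because the synthetic
#' generators funnel their output through it.
#'
#' @param net A `gene_network`.
#' @return `net`, invisibly; aborts on violation.
#' @export
validate_gene_network <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  if (nrow(net) > 0) {
    bad <- which(!is.finite(net$weight) | net$weight < 0 | net$weight > 1)
    if (length(bad) > 0) {
      abort(paste0(
        "edge weight outside [0, 1]: ", net$gene_a[bad[1]], "-",
        net$gene_b[bad[1]], " = ", net$weight[bad[1]]
      ))
    }
    if (any(net$gene_a == net$gene_b)) {
      i <- which(net$gene_a == net$gene_b)[1]
      abort(paste0("self-loop on gene ", net$gene_a[i]))
    }
    key <- paste(net$gene_a, net$gene_b, sep = "\t")
    if (anyDuplicated(key)) {
      i <- which(duplicated(key))[1]
      abort(paste0(
        "duplicate edge ", net$gene_a[i], "-", net$gene_b[i],
        " (symmetric records with unequal weights?)"
      ))
    }
  }
  genes <- attr(net, "genes")
  if (nrow(net) > 0 && !all(c(net$gene_a, net$gene_b) %in% genes)) {
    abort("edge endpoint missing from gene set")
  }
  invisible(net)
}

#' Genes of a network
#'
#' @param net A `gene_network` (or `tumor_subnetwork`).
#' @return Character vector of member gene identifiers, C-locale sorted;
#'   includes isolated genes.
#' @export
network_genes <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  attr(net, "genes")
}

#' Number of edges in a network
#' @param net A `gene_network`.
#' @return Integer edge count.
#' @export
network_edge_count <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  nrow(net)
}

# Symmetric sparse adjacency over `genes` (defaults to all member genes).
network_adjacency <- function(net, genes = network_genes(net)) {
  idx <- setNames(seq_along(genes), genes)
  keep <- net$gene_a %in% genes & net$gene_b %in% genes
  e <- net[keep, ]
  Matrix::sparseMatrix(
    i = idx[e$gene_a], j = idx[e$gene_b], x = e$weight,
    dims = c(length(genes), length(genes)),
    dimnames = list(genes, genes), symmetric = TRUE
  )
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf(
    "# A gene network: %d genes, %d edges\n",
    length(network_genes(x)), nrow(x)
  ))
  NextMethod()
}

# ---- small shared helpers ---------------------------------------------------

# uppercase, trimmed, opaque identifiers; no symbol <-> Entrez mapping
normalize_gene_ids <- function(x) {
  toupper(trimws(as.character(x)))
}

# platform-stable lexicographic order (C locale radix sort)
sort_c <- function(x) {
  x[order(x, method = "radix")]
}

# accept a character vector, a gene-list tibble (column `gene`) or anything
# data-frame-like whose first column is the identifier
as_gene_ids <- function(x, arg = "gene list") {
  if (is.character(x)) {
    ids <- x
  } else if (is.data.frame(x)) {
    col <- if ("gene" %in% names(x)) x$gene else x[[1]]
    ids <- as.character(col)
  } else {
    abort(paste0(arg, " must be a character vector or a data frame"))
  }
  ids <- normalize_gene_ids(ids)
  ids[ids != ""]
}

# per-gene numeric values (e.g. fold change) if the list carries them
gene_list_values <- function(x) {
  if (is.data.frame(x) && "value" %in% names(x)) {
    setNames(as.double(x$value), normalize_gene_ids(x$gene))
  } else {
    NULL
  }
}
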