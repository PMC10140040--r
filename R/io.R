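#' Read a gene-by-sample expression matrix
#'
#' Reads a tab-separated expression table whose first column holds gene
#' symbols and whose remaining columns are samples. Values are used as
#' supplied (typically log-scale RSEM/TPM); the package never re-normalizes
#' expression, and the downstream median split is invariant to any monotone
#' transform of a gene's values. Symbols are matched case-sensitively after
#' whitespace trimming.
#'
#' @param path Path to a TSV file with a header row.
#' @param transpose If `TRUE` the file is sample-by-gene and is transposed
#'   after reading.
#' @return A tibble with a `gene` character column followed by one numeric
#'   column per sample. Missing cells (`NA`) are preserved.
#' @export
read_expression <- function(path, transpose = FALSE) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, na = c("NA", ""),
                         progress = FALSE)
  if (ncol(tbl) < 2) {
    abort("expression file must have a gene column plus at least one sample column",
          class = "coactmap_format_error")
  }
  if (nrow(tbl) == 0) {
    abort("expression file contains no data rows", class = "coactmap_empty_error")
  }
  ids <- trimws(as.character(tbl[[1]]))
  vals <- as.data.frame(tbl[-1])
  if (transpose) {
    genes <- trimws(colnames(vals))
    m <- t(as.matrix(vals))
    colnames(m) <- ids
    tbl_out <- tibble(gene = genes, as_tibble(m))
  } else {
    tbl_out <- tibble(gene = ids, as_tibble(vals))
  }
  validate_expression(tbl_out)
}

#' @rdname read_expression
#' @param expr A gene-by-sample tibble as returned by [read_expression()].
#' @export
validate_expression <- function(expr) {
  genes <- expr$gene
  dup_g <- unique(genes[duplicated(genes)])
  if (length(dup_g) > 0) {
    abort(paste0("duplicate gene symbols: ", paste(dup_g, collapse = ", ")),
          class = "coactmap_validation_error")
  }
  smp <- colnames(expr)[-1]
  if (anyDuplicated(smp)) {
    abort(paste0("duplicate sample IDs: ",
                 paste(unique(smp[duplicated(smp)]), collapse = ", ")),
          class = "coactmap_validation_error")
  }
  m <- as.matrix(expr[-1])
  if (!is.numeric(m)) {
    abort("expression values must be numeric", class = "coactmap_format_error")
  }
  if (any(is.infinite(m))) {
    abort("expression values must be finite or NA", class = "coactmap_validation_error")
  }
  all_na <- rowSums(!is.na(m)) == 0
  if (any(all_na)) {
    abort(paste0("gene rows entirely missing: ",
                 paste(genes[all_na], collapse = ", ")),
          class = "coactmap_validation_error")
  }
  expr
}

# gene-by-sample tibble -> numeric matrix with dimnames
.expr_matrix <- function(expr) {
  m <- as.matrix(expr[-1])
  rownames(m) <- expr$gene
  m
}

#' Read a sample-by-phenotype table of raw IAP values
#'
#' @param path Path to a TSV whose first column is the sample ID and whose
#'   remaining columns are raw immune-associated phenotype (IAP) values.
#' @return A tibble with a `sample` column plus numeric phenotype columns.
#'   Columns with fewer than two distinct non-missing values are flagged in
#'   the `"degenerate"` attribute.
#' @export
read_phenotypes <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, na = c("NA", ""),
                         progress = FALSE)
  if (ncol(tbl) < 2) {
    abort("phenotype file needs a sample column plus at least one phenotype",
          class = "coactmap_format_error")
  }
  out <- tbl
  colnames(out)[1] <- "sample"
  out$sample <- trimws(as.character(out$sample))
  if (anyDuplicated(out$sample)) {
    abort("duplicate sample IDs in phenotype table", class = "coactmap_validation_error")
  }
  degen <- names(out)[-1][vapply(out[-1], function(v) {
    length(unique(v[!is.na(v)])) < 2
  }, logical(1))]
  if (length(degen) > 0) {
    warn(paste0("degenerate phenotype column(s): ", paste(degen, collapse = ", ")))
  }
  attr(out, "degenerate") <- degen
  out
}

#' Read a gene list (one symbol per line, `#` comments allowed)
#'
#' @param path Path to a plain-text gene list.
#' @return Character vector of unique, trimmed symbols in file order.
#' @export
read_gene_list <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  unique(lines[nzchar(lines)])
}

#' Read a two-column ligand-receptor pair table
#'
#' @param path Path to a TSV with columns `partner_a` and `partner_b`
#'   (column names are not enforced; the first two columns are used).
#' @return A tibble with columns `partner_a`, `partner_b`; self-pairs are
#'   dropped with a warning.
#' @export
read_lr_pairs <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tbl) < 2) {
    abort("ligand-receptor table needs two columns", class = "coactmap_format_error")
  }
  out <- tibble(partner_a = trimws(as.character(tbl[[1]])),
                partner_b = trimws(as.character(tbl[[2]])))
  self <- out$partner_a == out$partner_b
  if (any(self)) {
    warn(paste0("dropping ", sum(self), " self-pair(s) from ligand-receptor table"))
    out <- out[!self, ]
  }
  distinct(out)
}

# the serialized column set for validated interaction tables
.RESULT_COLS <- c("tap", "icp", "iap", "config", "S", "sign", "M_target", "M_E",
                  "R", "p_significance", "Q_significance",
                  "p_specificity", "Q_specificity", "passed")

#' Write / read a validated interaction table
#'
#' One TSV row per TAP-ICP-IAP triple with the combined-action score, its
#' winning configuration, and the robustness / significance / specificity
#' statistics. Missing scores (sign conflicts, unscorable pairs) serialize as
#' `NA`. Numeric values round-trip at full double precision.
#'
#' @param results A tibble of validated interactions (see
#'   [validate_interactions()]); may be empty.
#' @param path Output file path.
#' @return `write_interaction_table()` returns `results` invisibly;
#'   `read_interaction_table()` returns the tibble read from disk.
#' @export
write_interaction_table <- function(results, path) {
  out <- as_tibble(results)
  for (col in .RESULT_COLS) {
    if (!col %in% names(out)) {
      out[[col]] <- if (col %in% c("tap", "icp", "iap", "config")) NA_character_
                    else if (col == "passed") NA else NA_real_
    }
  }
  readr::write_tsv(out[.RESULT_COLS], path, na = "NA", progress = FALSE)
  invisible(results)
}

#' @rdname write_interaction_table
#' @export
read_interaction_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, na = "NA",
                  col_types = readr::cols(
                    tap = "c", icp = "c", iap = "c", config = "c",
                    passed = "l", .default = "d"))
}

#' Write / read an interaction network
#'
#' Serializes a per-IAP interaction network to GraphML (node attributes:
#' `gene`, `class`, `state`; edge attributes: `S`, `Q_significance`,
#' `Q_specificity`, `direction`, `is_ligand_receptor`) and a flat edge-list
#' TSV with the same fields.
#'
#' @param network A `coactmap_network` object from [build_network()].
#' @param path_graphml GraphML output path.
#' @param path_edges Optional edge-list TSV output path.
#' @return `write_network()` returns `network` invisibly; `read_network()`
#'   reconstructs the `coactmap_network` from a GraphML file.
#' @export
write_network <- function(network, path_graphml, path_edges = NULL) {
  g <- as_igraph(network)
  igraph::write_graph(g, path_graphml, format = "graphml")
  if (!is.null(path_edges)) {
    readr::write_tsv(network$edges, path_edges, na = "NA", progress = FALSE)
  }
  invisible(network)
}

#' @rdname write_network
#' @export
read_network <- function(path_graphml) {
  g <- igraph::read_graph(path_graphml, format = "graphml")
  iap <- igraph::graph_attr(g, "iap") %||% NA_character_
  if (identical(iap, "NA")) iap <- NA_character_
  if (igraph::vcount(g) == 0) {
    return(new_coactmap_network(iap, .empty_nodes(), .empty_edges()))
  }
  va <- igraph::vertex_attr(g)
  nodes <- tibble(node = va$name, gene = va$gene, class = va$class, state = va$state)
  if (igraph::ecount(g) == 0) {
    return(new_coactmap_network(iap, nodes, .empty_edges()))
  }
  ends <- igraph::as_edgelist(g)
  ea <- igraph::edge_attr(g)
  edges <- tibble(node_a = ends[, 1], node_b = ends[, 2],
                  tap = ea$tap, icp = ea$icp,
                  S = ea$S, Q_significance = ea$Q_significance,
                  Q_specificity = ea$Q_specificity,
                  direction = ea$direction,
                  is_ligand_receptor = as.logical(ea$is_ligand_receptor))
  new_coactmap_network(iap, nodes, edges)
}

#' Convert a network to an igraph object
#'
#' @param network A `coactmap_network`.
#' @return An undirected `igraph` graph with the attributes described in
#'   [write_network()].
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "coactmap_network"))
  if (nrow(network$nodes) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      d = as.data.frame(network$edges),
      directed = FALSE,
      vertices = as.data.frame(network$nodes))
  }
  igraph::set_graph_attr(g, "iap",
                         if (is.na(network$iap)) "NA" else network$iap)
}
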