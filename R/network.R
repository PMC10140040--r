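.empty_nodes <- function() {
  tibble(node = character(), gene = character(), class = character(),
         state = character())
}

.empty_edges <- function() {
  tibble(node_a = character(), node_b = character(), tap = character(),
         icp = character(), S = numeric(), Q_significance = numeric(),
         Q_specificity = numeric(), direction = character(),
         is_ligand_receptor = logical())
}

new_coactmap_network <- function(iap, nodes, edges) {
  structure(list(iap = iap, nodes = nodes, edges = edges),
            class = "coactmap_network")
}

#' @export
print.coactmap_network <- function(x, ...) {
  cat("<coactmap_network> IAP: ", x$iap, " | ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Build a per-phenotype interaction network from validated pairs
#'
#' Assembles the validated interactions for one IAP into a network whose
#' vertices are genes in an expression state (high or low, taken from the
#' winning configuration's target quadrant: both high for `act_act`, both
#' low for `deact_deact`, and the corresponding mixed states otherwise) and
#' whose edges carry the score, the Q-values, and the direction of IAP
#' change (`up` when the winning sign is +1, `down` when -1). A gene that
#' participates in interactions with opposite winning states appears as two
#' distinct vertices. Only interactions with `passed = TRUE` and
#' `|S| >= score_cutoff` are included, so edge count equals the number of
#' passing interactions at the cutoff.
#'
#' @param validated A `coactmap_validated` tibble, all rows sharing one IAP.
#' @param score_cutoff Minimum `|S|` for an edge (default 0).
#' @return A `coactmap_network` object.
#' @export
build_network <- function(validated, score_cutoff = 0) {
  v <- as_tibble(validated)
  iaps <- unique(v$iap)
  if (length(iaps) > 1) {
    abort("build_network expects interactions for a single IAP",
          class = "coactmap_usage_error")
  }
  iap <- if (length(iaps) == 1) iaps else NA_character_
  keep <- v[!is.na(v$passed) & v$passed & !is.na(v$S) &
              abs(v$S) >= score_cutoff, ]
  if (nrow(keep) == 0) {
    return(new_coactmap_network(iap, .empty_nodes(), .empty_edges()))
  }
  states <- map(keep$config, ~.CONFIG_STATES[[.x]])
  state_a <- map_chr(states, 1)
  state_b <- map_chr(states, 2)
  node_id <- function(gene, state) paste0(gene, "|", state)
  edges <- tibble(
    node_a = node_id(keep$tap, state_a),
    node_b = node_id(keep$icp, state_b),
    tap = keep$tap, icp = keep$icp, S = keep$S,
    Q_significance = keep$Q_significance,
    Q_specificity = keep$Q_specificity,
    direction = ifelse(keep$sign > 0, "up", "down"),
    is_ligand_receptor = FALSE)
  nodes <- distinct(bind_rows(
    tibble(node = edges$node_a, gene = keep$tap, class = "TAP", state = state_a),
    tibble(node = edges$node_b, gene = keep$icp, class = "ICP", state = state_b)))
  new_coactmap_network(iap, arrange(nodes, .data$node), edges)
}

#' Flag ligand-receptor edges in a network
#'
#' Sets `is_ligand_receptor = TRUE` on edges whose unordered gene pair
#' occurs in the pair table; all other fields are unchanged, and the
#' operation is idempotent.
#'
#' @param network A `coactmap_network`.
#' @param lr_pairs Tibble with columns `partner_a`, `partner_b` (see
#'   [read_lr_pairs()]).
#' @return The annotated `coactmap_network`.
#' @export
annotate_ligand_receptor <- function(network, lr_pairs) {
  stopifnot(inherits(network, "coactmap_network"))
  if (nrow(network$edges) == 0 || nrow(lr_pairs) == 0) {
    if (nrow(network$edges) > 0) network$edges$is_ligand_receptor <- FALSE
    return(network)
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  lr_keys <- key(lr_pairs$partner_a, lr_pairs$partner_b)
  network$edges$is_ligand_receptor <-
    key(network$edges$tap, network$edges$icp) %in% lr_keys
  network
}

#' Expand gene lists with ligand-receptor partners
#'
#' For every gene in the TAP (ICP) list, partner genes found in the
#' ligand-receptor table are appended to that same list; duplicates are
#' removed and partners absent from the expression matrix are dropped with
#' a warning.
#'
#' @param tap_genes,icp_genes Character vectors of gene symbols.
#' @param lr_pairs Ligand-receptor pair tibble.
#' @param expr_genes Character vector of genes available in the expression
#'   matrix; when `NULL`, no availability filter is applied.
#' @return List with elements `tap_genes` and `icp_genes`.
#' @export
expand_gene_lists <- function(tap_genes, icp_genes, lr_pairs,
                              expr_genes = NULL) {
  partners_of <- function(genes) {
    hits <- lr_pairs[lr_pairs$partner_a %in% genes | lr_pairs$partner_b %in% genes, ]
    setdiff(unique(c(hits$partner_a, hits$partner_b)), genes)
  }
  grow <- function(genes) {
    add <- partners_of(genes)
    if (!is.null(expr_genes)) {
      absent <- setdiff(add, expr_genes)
      if (length(absent) > 0) {
        warn(paste0("ligand-receptor partners absent from matrix, not added: ",
                    paste(absent, collapse = ", ")))
      }
      add <- intersect(add, expr_genes)
    }
    unique(c(genes, add))
  }
  list(tap_genes = grow(tap_genes), icp_genes = grow(icp_genes))
}
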