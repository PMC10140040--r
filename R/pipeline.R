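#' Run the full interaction-mapping pipeline
#'
#' Orchestrates the end-to-end analysis for one IAP: load and validate the
#' inputs, optionally expand the gene lists with ligand-receptor partners,
#' scale the phenotype, score all TAP-ICP pairs, run the staged statistical
#' validation, build and annotate the network, and write the results table,
#' the network (GraphML + edge list), a stage-count log (JSON lines), and a
#' run manifest recording input hashes and every parameter. Given the same
#' inputs and seed, the results table is byte-identical across runs.
#'
#' @param expr_path Expression TSV (genes x samples).
#' @param phenotype_path Phenotype TSV (samples x IAPs).
#' @param iap Name of the phenotype column to analyze.
#' @param tap_path,icp_path Gene-list files (one symbol per line).
#' @param lr_path Optional ligand-receptor pair TSV.
#' @param out_dir Output directory (created if absent).
#' @param model Additivity reference, `"hsa"` or `"bliss"`.
#' @param min_group_size,n_boot,coverage,n_random,q_threshold,score_cutoff,seed
#'   Validation parameters, see [validate_interactions()].
#' @param expand_lists Expand gene lists with ligand-receptor partners
#'   before scoring (default `TRUE` when `lr_path` is given).
#' @return Invisibly, a list with `validated`, `network`, `stage_counts`,
#'   and the output paths.
#' @export
run_pipeline <- function(expr_path, phenotype_path, iap, tap_path, icp_path,
                         lr_path = NULL, out_dir = ".",
                         model = c("hsa", "bliss"), min_group_size = 10,
                         n_boot = 1000, coverage = 0.7, n_random = 1000,
                         q_threshold = 0.1, score_cutoff = 0, seed = 1,
                         expand_lists = !is.null(lr_path)) {
  model <- match.arg(tolower(model), c("hsa", "bliss"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  expr <- read_expression(expr_path)
  phenotypes <- read_phenotypes(phenotype_path)
  if (!iap %in% names(phenotypes)) {
    abort(paste0("unknown IAP: ", iap), class = "coactmap_config_error")
  }
  tap_genes <- read_gene_list(tap_path)
  icp_genes <- read_gene_list(icp_path)
  lr <- if (!is.null(lr_path)) read_lr_pairs(lr_path) else NULL
  if (expand_lists && !is.null(lr)) {
    ex <- expand_gene_lists(tap_genes, icp_genes, lr, expr$gene)
    tap_genes <- ex$tap_genes
    icp_genes <- ex$icp_genes
  }

  shared <- intersect(colnames(expr)[-1], phenotypes$sample)
  if (length(shared) < 4 * min_group_size) {
    abort("too few samples shared between expression and phenotype tables",
          class = "coactmap_consistency_error")
  }
  expr <- expr[c("gene", shared)]
  phenotypes <- phenotypes[match(shared, phenotypes$sample), ]

  iap_scaled <- scale_iap(setNames(phenotypes[[iap]], phenotypes$sample),
                          name = iap)
  scores <- score_pairs(expr, iap_scaled, tap_genes, icp_genes,
                        model = model, min_group_size = min_group_size)
  validated <- validate_interactions(expr, iap_scaled, scores,
                                     n_boot = n_boot, coverage = coverage,
                                     n_random = n_random,
                                     q_threshold = q_threshold,
                                     score_cutoff = score_cutoff, seed = seed)
  network <- build_network(validated, score_cutoff = score_cutoff)
  if (!is.null(lr)) network <- annotate_ligand_receptor(network, lr)

  stage_counts <- list(
    scored = sum(!is.na(validated$S) & abs(validated$S) > 0),
    robust = sum(validated$robust),
    significant = sum(validated$stage %in% c("specificity", "passed")),
    specific = sum(validated$passed),
    in_network = nrow(network$edges))

  results_path <- file.path(out_dir, "interactions.tsv")
  graphml_path <- file.path(out_dir, "network.graphml")
  edges_path <- file.path(out_dir, "network_edges.tsv")
  log_path <- file.path(out_dir, "stages.jsonl")
  manifest_path <- file.path(out_dir, "manifest.json")

  write_interaction_table(validated, results_path)
  write_network(network, graphml_path, edges_path)
  writeLines(vapply(names(stage_counts), function(nm) {
    jsonlite::toJSON(list(stage = nm, count = stage_counts[[nm]]),
                     auto_unbox = TRUE)
  }, character(1)), log_path)

  inputs <- c(expr = expr_path, phenotypes = phenotype_path,
              tap = tap_path, icp = icp_path,
              if (!is.null(lr_path)) c(lr = lr_path))
  manifest <- list(
    inputs = lapply(seq_along(inputs), function(i) {
      list(role = names(inputs)[i], path = unname(inputs[i]),
           md5 = unname(tools::md5sum(inputs[i])))
    }),
    params = list(iap = iap, model = model, min_group_size = min_group_size,
                  n_boot = n_boot, coverage = coverage, n_random = n_random,
                  q_threshold = q_threshold, score_cutoff = score_cutoff,
                  seed = seed, expand_lists = expand_lists),
    tool_version = as.character(utils::packageVersion("coactmap")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  message(paste0("stage counts: ",
                 paste(names(stage_counts), unlist(stage_counts),
                       sep = "=", collapse = " ")))
  invisible(list(validated = validated, network = network,
                 stage_counts = stage_counts,
                 paths = list(results = results_path, graphml = graphml_path,
                              edges = edges_path, log = log_path,
                              manifest = manifest_path)))
}
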