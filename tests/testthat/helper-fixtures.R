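# programmatic fixtures shared across test files

`%||%` <- function(a, b) if (is.null(a)) b else a

# small gene-by-sample expression tibble from a named list of gene vectors
toy_expr <- function(gene_values, samples = NULL) {
  n <- length(gene_values[[1]])
  samples <- samples %||% sprintf("s%02d", seq_len(n))
  m <- do.call(rbind, gene_values)
  colnames(m) <- samples
  tibble::tibble(gene = names(gene_values), tibble::as_tibble(m))
}

# wrap scaled values (already in [0,1]) as a coactmap_iap without rescaling
as_iap <- function(values, samples = NULL, name = "iap") {
  if (!is.null(samples)) names(values) <- samples
  structure(list(name = name, values = values, sigma = stats::sd(values),
                 branch = "identity"),
            class = "coactmap_iap")
}

# random continuous cohort for oracle-equivalence checks
random_cohort <- function(seed, n_samples = NULL, n_genes = NULL) {
  set.seed(seed)
  n <- n_samples %||% sample(20:60, 1)
  g <- n_genes %||% sample(5:10, 1)
  genes <- sprintf("g%02d", seq_len(g))
  vals <- lapply(genes, function(.) rnorm(n))
  names(vals) <- genes
  expr <- toy_expr(vals)
  # sprinkle a few missing expression values
  if (n > 30) {
    expr[[2]][1] <- NA
    expr[[3]][2] <- NA
  }
  iap <- as_iap(runif(n), samples = colnames(expr)[-1])
  list(expr = expr, iap = iap, genes = genes, n = n)
}

# quadrant-structured cohort: expression defines quadrants, IAP is an exact
# function of the quadrant plus optional jitter (defaults to none)
quadrant_cohort <- function(n_per_quad = 25, means = c(LL = 0.1, LH = 0.3,
                                                       HL = 0.3, HH = 0.9),
                            jitter = 0, seed = 1) {
  set.seed(seed)
  n <- 4 * n_per_quad
  quad <- rep(c("LL", "LH", "HL", "HH"), each = n_per_quad)
  x1 <- ifelse(substr(quad, 1, 1) == "H", 1, -1) + rnorm(n, 0, 0.1)
  x2 <- ifelse(substr(quad, 2, 2) == "H", 1, -1) + rnorm(n, 0, 0.1)
  y <- unname(means[quad]) + (if (jitter > 0) rnorm(n, 0, jitter) else 0)
  samples <- sprintf("s%03d", seq_len(n))
  expr <- toy_expr(list(gA = x1, gB = x2), samples = samples)
  list(expr = expr, iap = as_iap(y, samples = samples), quad = quad)
}

# simulated planted cohort plus its TAP/ICP lists, as used in recovery runs
recovery_setup <- function(seed, n_null_pairs = 30, n_null_genes = 60,
                           config = "act_act") {
  cohort <- coactmap::simulate_cohort(coactmap::sim_config(
    n_samples = 400, n_null_genes = n_null_genes,
    planted = coactmap::planted_pair(config = config),
    noise_sd = 0.5, seed = seed))
  iap <- coactmap::scale_iap(
    stats::setNames(cohort$phenotypes$sim_iap, cohort$phenotypes$sample),
    name = "sim_iap")
  list(cohort = cohort, iap = iap,
       tap = c("TAP1", sprintf("G%03d", seq_len(n_null_pairs))),
       icp = "ICP1")
}
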