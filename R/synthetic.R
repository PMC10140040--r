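#' Describe a planted gene-pair interaction
#'
#' A planted interaction adds, on the raw IAP scale, a single-gene effect
#' for each gene whose expression is on its active side (high for an
#' activating gene, low for a deactivating one, relative to that gene's own
#' cohort median) and an extra interaction effect for samples in the pair's
#' target quadrant. The defaults plant a clearly super-additive
#' both-activating pair: single effects equal to the noise sd and an
#' interaction effect of three noise sds.
#'
#' @param gene1,gene2 Names for the planted genes.
#' @param config Planted configuration id.
#' @param effect_single1,effect_single2 Raw-IAP shift per active single gene.
#' @param effect_interaction Extra raw-IAP shift in the target quadrant.
#' @return A one-row tibble describing the planted pair.
#' @export
planted_pair <- function(gene1 = "TAP1", gene2 = "ICP1", config = "act_act",
                         effect_single1 = 0.5, effect_single2 = 0.5,
                         effect_interaction = 1.5) {
  config <- match.arg(config, names(.CONFIGS))
  tibble(gene1 = gene1, gene2 = gene2, config = config,
         effect_single1 = effect_single1, effect_single2 = effect_single2,
         effect_interaction = effect_interaction)
}

#' Simulation configuration for a synthetic cohort
#'
#' @param n_samples Cohort size (default 400; must be at least
#'   `4 * min_group_size` of downstream analyses).
#' @param n_null_genes Number of null genes (no IAP effect) in the matrix.
#' @param planted Tibble of planted pairs (rows as from [planted_pair()]);
#'   may have zero rows for an all-null cohort.
#' @param noise_sd Gaussian noise sd on the raw IAP (default 0.5).
#' @param expression_log_sd Log-scale sd of each gene's log-normal
#'   expression (default 1).
#' @param seed Integer seed; the same configuration regenerates the cohort
#'   exactly.
#' @return A `coactmap_sim_config` list.
#' @export
sim_config <- function(n_samples = 400, n_null_genes = 60,
                       planted = planted_pair(), noise_sd = 0.5,
                       expression_log_sd = 1, seed = 1) {
  stopifnot(n_samples >= 4, noise_sd > 0, expression_log_sd > 0)
  planted <- as_tibble(planted)
  structure(list(n_samples = n_samples, n_null_genes = n_null_genes,
                 planted = planted, noise_sd = noise_sd,
                 expression_log_sd = expression_log_sd, seed = seed),
            class = "coactmap_sim_config")
}

#' Simulate a cohort with known planted interactions
#'
#' Expression for every gene is drawn i.i.d. log-normal (per-gene log-mean
#' uniform on \[2, 6\] for a realistic dynamic range, log-sd
#' `expression_log_sd`). The raw IAP is the sum, over planted pairs, of
#' single-gene effects for samples on each gene's active side and the
#' interaction effect for samples in the pair's target quadrant, plus
#' Gaussian noise; null genes contribute nothing. Active sides are defined
#' against each gene's own realized median, so the planted quadrant is
#' exactly the one the median-split stratification recovers. The generator
#' is fully deterministic given the seed (R's default Mersenne-Twister).
#'
#' @param config A `coactmap_sim_config` from [sim_config()].
#' @return A `coactmap_cohort` list: `expr` (gene-by-sample tibble),
#'   `phenotypes` (tibble with `sample` and `sim_iap` columns), `truth`
#'   (config plus realized per-quadrant raw-IAP means per planted pair).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "coactmap_sim_config"))
  set.seed(config$seed)
  planted_genes <- unique(c(config$planted$gene1, config$planted$gene2))
  null_genes <- sprintf("G%03d", seq_len(config$n_null_genes))
  if (any(planted_genes %in% null_genes)) {
    abort("planted gene names collide with null-gene names",
          class = "coactmap_config_error")
  }
  genes <- c(planted_genes, null_genes)
  n <- config$n_samples
  samples <- sprintf("S%04d", seq_len(n))
  m <- vapply(genes, function(g) {
    exp(rnorm(n, mean = runif(1, 2, 6), sd = config$expression_log_sd))
  }, numeric(n))
  m <- t(m)  # genes x samples
  colnames(m) <- samples

  raw <- rnorm(n, 0, config$noise_sd)
  active_side <- function(g, activating) {
    med <- median(m[g, ])
    if (activating) m[g, ] > med else m[g, ] <= med
  }
  sides <- list()
  if (nrow(config$planted) > 0) {
    for (i in seq_len(nrow(config$planted))) {
      pl <- config$planted[i, ]
      cfg <- .CONFIGS[[pl$config]]
      a1 <- active_side(pl$gene1, substr(cfg$target, 1, 1) == "H")
      a2 <- active_side(pl$gene2, substr(cfg$target, 2, 2) == "H")
      raw <- raw + pl$effect_single1 * a1 + pl$effect_single2 * a2 +
        pl$effect_interaction * (a1 & a2)
      sides[[i]] <- list(a1 = a1, a2 = a2)
    }
  }
  # realized per-quadrant means of the final raw IAP
  truth_rows <- imap(sides, function(sd, i) {
    pl <- config$planted[i, ]
    tibble(gene1 = pl$gene1, gene2 = pl$gene2, config = pl$config,
           mean_baseline = mean(raw[!sd$a1 & !sd$a2]),
           mean_single1 = mean(raw[sd$a1 & !sd$a2]),
           mean_single2 = mean(raw[!sd$a1 & sd$a2]),
           mean_target = mean(raw[sd$a1 & sd$a2]))
  })
  expr <- tibble(gene = genes, as_tibble(m))
  phenotypes <- tibble(sample = samples, sim_iap = raw)
  structure(list(expr = expr, phenotypes = phenotypes,
                 truth = list(config = config,
                              quadrant_means = list_rbind(truth_rows))),
            class = "coactmap_cohort")
}

#' @export
print.coactmap_cohort <- function(x, ...) {
  cat("<coactmap_cohort> ", nrow(x$expr), " genes x ",
      nrow(x$phenotypes), " samples, ",
      nrow(x$truth$config$planted), " planted pair(s)\n", sep = "")
  invisible(x)
}

#' Recovery report for a validated synthetic cohort
#'
#' Compares a validated interaction table computed on a synthetic cohort
#' against the cohort's planted truth: per planted pair, the rank of its
#' score among all scored pairs, whether it passed every validation stage,
#' and whether its winning configuration matches the planted one (or its
#' mirror under swapped gene order); per null pair, the pass flag for
#' false-positive-rate estimation.
#'
#' @param cohort A `coactmap_cohort`.
#' @param validated A `coactmap_validated` tibble computed on the cohort.
#' @return Tibble with one row per scored pair: `tap`, `icp`, `planted`,
#'   `S`, `rank`, `passed`, `config`, `config_match`.
#' @export
evaluate_recovery <- function(cohort, validated) {
  v <- as_tibble(validated)
  pl <- cohort$truth$config$planted
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  pl_keys <- if (nrow(pl) > 0) key(pl$gene1, pl$gene2) else character(0)
  v_key <- key(v$tap, v$icp)
  S_for_rank <- ifelse(is.na(v$S), -Inf, v$S)
  out <- tibble(
    tap = v$tap, icp = v$icp,
    planted = v_key %in% pl_keys,
    S = v$S,
    rank = rank(-S_for_rank, ties.method = "min"),
    passed = v$passed,
    config = v$config)
  out$config_match <- NA
  if (nrow(pl) > 0) {
    idx <- match(v_key, pl_keys)
    for (i in which(!is.na(idx))) {
      planted_cfg <- pl$config[idx[i]]
      same_order <- v$tap[i] == pl$gene1[idx[i]]
      expect_cfg <- if (same_order) planted_cfg else .MIRROR_CONFIG[[planted_cfg]]
      out$config_match[i] <- identical(v$config[i], expect_cfg)
    }
  }
  out
}
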