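#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted Q-values, order-preserving with the
#' input vector.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted Q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  p.adjust(p, method = "BH")
}

# two-sided rank-sum p-value; exact null when both groups are small and
# untied, normal approximation with tie correction otherwise
.ranksum_p <- function(x, y) {
  if (length(unique(c(x, y))) < 2) return(1)
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 25 && length(y) <= 25 && !has_ties
  suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = !exact)$p.value
  )
}

#' Significance of a scored configuration
#'
#' Compares the scaled IAP values of the winning configuration's target
#' sub-cohort against each of the three remaining sub-cohorts with two-sided
#' unpaired Wilcoxon rank-sum (Mann-Whitney) tests. The reported p-value is
#' the maximum of the three, i.e. an interaction is only as significant as
#' its weakest contrast. (The sub-cohorts are disjoint patient groups, so
#' the unpaired rank-sum test is the applicable Wilcoxon variant.)
#'
#' @inheritParams median_deviation
#' @param config Winning configuration id (fixes the target quadrant).
#' @return List with `p_by_group` (named p-values, one per non-target
#'   quadrant) and `p` (their maximum).
#' @export
significance_test <- function(iap, strat, config) {
  config <- match.arg(config, names(.CONFIGS))
  y <- .strat_aligned_values(iap, strat)
  labels <- unname(strat$labels)
  target <- .CONFIGS[[config]]$target
  others <- setdiff(.QUADRANTS, target)
  tv <- y[!is.na(labels) & labels == target & !is.na(y)]
  p_by_group <- vapply(setNames(others, others), function(q) {
    qv <- y[!is.na(labels) & labels == q & !is.na(y)]
    .ranksum_p(tv, qv)
  }, numeric(1))
  list(p_by_group = p_by_group, p = max(p_by_group))
}

#' Normalized RMSD between a complete-cohort score and partial-cohort scores
#'
#' The robustness ratio `R = sqrt(mean((S_complete - S_partial)^2)) /
#' |S_complete|`, computed over the non-missing partial scores.
#'
#' @param S_complete Score on the full cohort (nonzero).
#' @param partial_scores Scores from resampled partial cohorts; `NA` entries
#'   are dropped.
#' @return The ratio `R` (`NA` if no valid partial scores).
#' @export
robustness_ratio <- function(S_complete, partial_scores) {
  v <- partial_scores[!is.na(partial_scores)]
  if (length(v) == 0) return(NA_real_)
  sqrt(mean((S_complete - v)^2)) / abs(S_complete)
}

# resampling core shared by robustness() and validate_interactions()
.robustness_core <- function(x1, x2, y, S_complete, model, min_group_size,
                             n_boot, coverage, seed) {
  n <- length(x1)
  k <- floor(coverage * n)
  set.seed(seed)
  partial <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, k)
    .score_core(x1[idx], x2[idx], y[idx], model, min_group_size)$S
  }, numeric(1))
  n_valid <- sum(!is.na(partial))
  R <- robustness_ratio(S_complete, partial)
  list(R = R, n_valid = n_valid, partial_scores = partial,
       robust = n_valid >= 0.5 * n_boot && !is.na(R) && R < 1)
}

#' Robustness of a combined-action score to cohort resampling
#'
#' Re-stratifies and re-scores the pair on partial cohorts (default 70%
#' coverage, drawn without replacement) and reports the normalized
#' root-mean-square deviation `R` between the complete-cohort score and the
#' partial-cohort scores, `R = RMSD / |S_complete|`. A score is robust when
#' `-log(R) > 0`, i.e. `R < 1`. Resamples whose score is missing (sign
#' conflicts) are dropped; if fewer than half the resamples are valid the
#' pair is flagged non-robust regardless of `R`.
#'
#' @inheritParams combined_action_score
#' @param n_boot Number of resamples (default 1000).
#' @param coverage Fraction of the cohort per resample (default 0.7).
#' @param seed Integer seed for the resampling.
#' @return List with `S_complete`, `R`, `robust`, `n_valid`, `n_boot`,
#'   `coverage`, and the vector of `partial_scores`.
#' @export
robustness <- function(expr, iap, gene1, gene2, model = c("hsa", "bliss"),
                       n_boot = 1000, coverage = 0.7, seed = 1,
                       min_group_size = 10) {
  model <- match.arg(tolower(model), c("hsa", "bliss"))
  m <- .expr_matrix(expr)
  y <- .align_iap(iap, colnames(m))
  S_complete <- .score_core(m[gene1, ], m[gene2, ], y, model, min_group_size)$S
  if (is.na(S_complete) || S_complete == 0) {
    abort("robustness is undefined for a missing or zero score",
          class = "coactmap_undefined_error")
  }
  res <- .robustness_core(m[gene1, ], m[gene2, ], y, S_complete, model,
                          min_group_size, n_boot, coverage, seed)
  c(list(S_complete = S_complete, n_boot = n_boot, coverage = coverage), res)
}

# null combined-action scores of one focal gene vs sampled partner genes
.null_scores <- function(m, y, focal, exclude, model, min_group_size,
                         n_random, seed) {
  candidates <- setdiff(rownames(m), c(focal, exclude))
  if (length(candidates) < n_random) {
    warn(paste0("only ", length(candidates), " partner genes available for ",
                focal, "; reducing n_random"))
    n_random <- length(candidates)
  }
  set.seed(seed)
  partners <- sample(candidates, n_random)
  xf <- m[focal, ]
  scores <- vapply(partners, function(g) {
    .score_core(xf, m[g, ], y, model, min_group_size)$S
  }, numeric(1))
  setNames(scores, partners)
}

#' Specificity of a pair's score against random partners
#'
#' Builds, for each gene of the pair, an empirical null of combined-action
#' scores against partner genes sampled uniformly without replacement from
#' the supplied expression matrix (the working "genome"), excluding the
#' focal pair. Each gene's one-sided add-one empirical p-value is
#' `(1 + #\{null >= S_observed\}) / (1 + #valid null scores)`; the reported
#' p is the larger of the two (the least specific side). Missing null
#' scores are dropped; with fewer than `min_valid_null` valid null scores
#' for either gene the specificity is undefined and the interaction fails
#' this stage.
#'
#' @inheritParams robustness
#' @param S_observed Observed score; computed from the data when `NULL`.
#' @param n_random Partner genes sampled per focal gene (default 1000;
#'   reduced with a warning when the matrix is smaller).
#' @param min_valid_null Minimum valid null scores per gene (default 50).
#' @return List with `p_g1`, `p_g2`, `p_max`, the null score vectors, the
#'   valid-null counts, and `defined`.
#' @export
specificity_test <- function(expr, iap, gene1, gene2, S_observed = NULL,
                             model = c("hsa", "bliss"), n_random = 1000,
                             seed = 1, min_group_size = 10,
                             min_valid_null = 50) {
  model <- match.arg(tolower(model), c("hsa", "bliss"))
  m <- .expr_matrix(expr)
  y <- .align_iap(iap, colnames(m))
  if (is.null(S_observed)) {
    S_observed <- .score_core(m[gene1, ], m[gene2, ], y, model, min_group_size)$S
  }
  if (is.na(S_observed)) {
    abort("specificity is undefined for a missing score",
          class = "coactmap_undefined_error")
  }
  nulls <- lapply(setNames(c(gene1, gene2), c(gene1, gene2)), function(g) {
    .null_scores(m, y, g, setdiff(c(gene1, gene2), g), model,
                 min_group_size, n_random, seed + match(g, rownames(m)))
  })
  emp_p <- function(ns) {
    v <- ns[!is.na(ns)]
    if (length(v) < 1) return(NA_real_)
    (1 + sum(v >= S_observed)) / (1 + length(v))
  }
  n_valid <- vapply(nulls, function(ns) sum(!is.na(ns)), numeric(1))
  p1 <- emp_p(nulls[[1]])
  p2 <- emp_p(nulls[[2]])
  defined <- all(n_valid >= min_valid_null) && !is.na(p1) && !is.na(p2)
  list(p_g1 = p1, p_g2 = p2,
       p_max = if (defined) max(p1, p2) else NA_real_,
       null_scores_g1 = nulls[[1]], null_scores_g2 = nulls[[2]],
       n_valid = n_valid, defined = defined)
}

#' Staged statistical validation of scored pairs
#'
#' Applies the three validation stages in order, mirroring the staged
#' filtering of the method: (1) score stage — the pair must have a
#' non-missing score with `|S| > 0` and `|S| >= score_cutoff`; (2)
#' robustness — resampled scores must give `-log(R) > 0`; (3) significance —
#' BH-adjusted max rank-sum p over the robust set must satisfy
#' `Q_significance < q_threshold`; (4) specificity — BH-adjusted random-
#' partner p over the robust-and-significant set must satisfy
#' `Q_specificity < q_threshold`. Null partner scores are cached per focal
#' gene per IAP, with any score against the pair's other gene excluded at
#' p-value time.
#'
#' @inheritParams robustness
#' @inheritParams specificity_test
#' @param scores A `coactmap_scores` tibble from [score_pairs()].
#' @param q_threshold FDR threshold for both Q-value stages (default 0.1).
#' @param score_cutoff Minimum `|S|` for a pair to enter validation
#'   (default 0, i.e. any nonzero score).
#' @return A tibble (class `coactmap_validated`): the score columns plus
#'   `R`, `n_valid_boot`, `robust`, `p_significance`, `Q_significance`,
#'   `p_g1`, `p_g2`, `p_specificity`, `Q_specificity`, `passed`, and
#'   `stage` (the first failed stage, or `"passed"`).
#' @export
validate_interactions <- function(expr, iap, scores,
                                  n_boot = 1000, coverage = 0.7,
                                  n_random = 1000, q_threshold = 0.1,
                                  score_cutoff = 0, seed = 1,
                                  min_valid_null = 50,
                                  min_group_size = NULL, model = NULL) {
  model <- model %||% attr(scores, "model") %||% "hsa"
  min_group_size <- min_group_size %||% attr(scores, "min_group_size") %||% 10
  m <- .expr_matrix(expr)
  y <- .align_iap(iap, colnames(m))
  res <- as_tibble(scores)
  nr <- nrow(res)

  res$R <- NA_real_
  res$n_valid_boot <- NA_real_
  res$robust <- FALSE
  res$p_significance <- NA_real_
  res$Q_significance <- NA_real_
  res$p_g1 <- NA_real_
  res$p_g2 <- NA_real_
  res$p_specificity <- NA_real_
  res$Q_specificity <- NA_real_

  ok_score <- !is.na(res$S) & abs(res$S) > 0 & abs(res$S) >= score_cutoff

  # robustness
  for (i in which(ok_score)) {
    rb <- .robustness_core(m[res$tap[i], ], m[res$icp[i], ], y, res$S[i],
                           model, min_group_size, n_boot, coverage,
                           seed = seed + i)
    res$R[i] <- rb$R
    res$n_valid_boot[i] <- rb$n_valid
    res$robust[i] <- rb$robust
  }
  ok_rob <- ok_score & res$robust

  # significance (BH over the robust set)
  for (i in which(ok_rob)) {
    st <- .stratify_core(m[res$tap[i], ], m[res$icp[i], ], min_group_size)
    st$labels <- setNames(st$labels, colnames(m))
    st$pair <- c(res$tap[i], res$icp[i])
    sig <- significance_test(structure(list(values = setNames(y, colnames(m)),
                                            name = res$iap[i]),
                                       class = "coactmap_iap"),
                             structure(st, class = "coactmap_strat"),
                             res$config[i])
    res$p_significance[i] <- sig$p
  }
  res$Q_significance[ok_rob] <- bh_adjust(res$p_significance[ok_rob])
  ok_sig <- ok_rob & !is.na(res$Q_significance) & res$Q_significance < q_threshold

  # specificity (null scores cached per focal gene, BH over survivors)
  null_cache <- new.env(parent = emptyenv())
  gene_null <- function(g) {
    if (!exists(g, envir = null_cache)) {
      assign(g, .null_scores(m, y, g, character(0), model, min_group_size,
                             n_random, seed + 10000L + match(g, rownames(m))),
             envir = null_cache)
    }
    get(g, envir = null_cache)
  }
  spec_defined <- rep(NA, nr)
  for (i in which(ok_sig)) {
    emp <- function(focal, other) {
      ns <- gene_null(focal)
      ns <- ns[names(ns) != other]
      v <- ns[!is.na(ns)]
      list(p = if (length(v)) (1 + sum(v >= res$S[i])) / (1 + length(v))
               else NA_real_,
           n_valid = length(v))
    }
    e1 <- emp(res$tap[i], res$icp[i])
    e2 <- emp(res$icp[i], res$tap[i])
    res$p_g1[i] <- e1$p
    res$p_g2[i] <- e2$p
    spec_defined[i] <- e1$n_valid >= min_valid_null &&
      e2$n_valid >= min_valid_null && !is.na(e1$p) && !is.na(e2$p)
    if (isTRUE(spec_defined[i])) {
      res$p_specificity[i] <- max(e1$p, e2$p)
    }
  }
  tested <- ok_sig & !is.na(res$p_specificity)
  res$Q_specificity[tested] <- bh_adjust(res$p_specificity[tested])
  ok_spec <- tested & res$Q_specificity < q_threshold

  res$passed <- ok_spec
  res$stage <- case_when(
    !ok_score ~ "score",
    !res$robust ~ "robustness",
    !ok_sig ~ "significance",
    !ok_spec ~ "specificity",
    TRUE ~ "passed"
  )
  attr(res, "params") <- list(model = model, min_group_size = min_group_size,
                              n_boot = n_boot, coverage = coverage,
                              n_random = n_random, q_threshold = q_threshold,
                              score_cutoff = score_cutoff, seed = seed,
                              min_valid_null = min_valid_null)
  class(res) <- c("coactmap_validated", class(res))
  res
}
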