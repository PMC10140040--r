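#' Median-split quadrant stratification of a gene pair
#'
#' Splits the cohort into four sub-cohorts (LL, LH, HL, HH; first letter is
#' gene1's level, second gene2's) at each gene's median expression, computed
#' over samples where both genes are non-missing. Values at or below the
#' median are labeled L (deterministic tie rule). Because only ranks matter,
#' the stratification is invariant to any strictly increasing transform of a
#' gene's values.
#'
#' @param expr Gene-by-sample expression tibble.
#' @param gene1,gene2 Gene symbols present in `expr`.
#' @param min_group_size Minimum samples per quadrant for the pair to be
#'   scorable (default 10; medians and their standard errors are unstable
#'   below this).
#' @return A `coactmap_strat` object: list with `pair`, `labels` (named by
#'   sample; `NA` where either gene is missing), `cut1`, `cut2`,
#'   `quadrant_sizes`, and `scorable`.
#' @export
stratify_pair <- function(expr, gene1, gene2, min_group_size = 10) {
  m <- .expr_matrix(expr)
  for (g in c(gene1, gene2)) {
    if (!g %in% rownames(m)) {
      abort(paste0("gene not in expression matrix: ", g),
            class = "coactmap_lookup_error")
    }
  }
  st <- .stratify_core(m[gene1, ], m[gene2, ], min_group_size)
  st$pair <- c(gene1, gene2)
  names(st$labels) <- colnames(m)
  structure(st, class = "coactmap_strat")
}

.stratify_core <- function(x1, x2, min_group_size) {
  keep <- !is.na(x1) & !is.na(x2)
  labels <- rep(NA_character_, length(x1))
  if (sum(keep) < 4 * min_group_size) {
    return(list(labels = labels, cut1 = NA_real_, cut2 = NA_real_,
                quadrant_sizes = setNames(rep(0L, 4), .QUADRANTS),
                scorable = FALSE))
  }
  cut1 <- median(x1[keep])
  cut2 <- median(x2[keep])
  labels[keep] <- paste0(ifelse(x1[keep] > cut1, "H", "L"),
                         ifelse(x2[keep] > cut2, "H", "L"))
  sizes <- setNames(vapply(.QUADRANTS, function(q) sum(labels == q, na.rm = TRUE),
                           integer(1)), .QUADRANTS)
  list(labels = labels, cut1 = cut1, cut2 = cut2, quadrant_sizes = sizes,
       scorable = all(sizes >= min_group_size))
}

#' @export
print.coactmap_strat <- function(x, ...) {
  cat("<coactmap_strat> ", paste(x$pair, collapse = " x "),
      " | cuts: ", format(x$cut1, digits = 4), ", ", format(x$cut2, digits = 4),
      " | ", paste(names(x$quadrant_sizes), x$quadrant_sizes,
                   sep = "=", collapse = " "),
      if (!x$scorable) " (unscorable)", "\n", sep = "")
  invisible(x)
}

# standard error of the median, asymptotic normal-theory form
.sem_median <- function(v) {
  n <- length(v)
  if (n < 2) return(NA_real_)
  1.2533 * sd(v) / sqrt(n)
}

# per-quadrant IAP summaries: n, median, sem of median
.quadrant_stats <- function(y, labels) {
  lapply(setNames(.QUADRANTS, .QUADRANTS), function(q) {
    v <- y[!is.na(labels) & labels == q & !is.na(y)]
    list(n = length(v),
         med = if (length(v)) median(v) else NA_real_,
         sem = .sem_median(v))
  })
}

#' Thresholded median deviation of a quadrant from baseline
#'
#' The deviation of a sub-cohort's median scaled IAP from the baseline
#' sub-cohort's median, set to zero when it is smaller in magnitude than its
#' standard error `sem_M = sqrt(sem_quadrant^2 + sem_baseline^2)` (the sems
#' of the two medians combined in quadrature). The zeroing suppresses noise
#' so that the direction of change is estimated reliably.
#'
#' @param iap A `coactmap_iap` (scaled phenotype) whose values are named by
#'   sample, or a plain named numeric vector of scaled values.
#' @param strat A `coactmap_strat` from [stratify_pair()].
#' @param quadrant,baseline Quadrant labels among `"LL", "LH", "HL", "HH"`.
#' @return List with `M` (thresholded), `M_raw`, `sem_quadrant`,
#'   `sem_baseline`, `sem_M`, and the two group sizes.
#' @export
median_deviation <- function(iap, strat, quadrant, baseline) {
  y <- .strat_aligned_values(iap, strat)
  qs <- .quadrant_stats(y, unname(strat$labels))
  a <- qs[[quadrant]]
  b <- qs[[baseline]]
  if (a$n == 0 || b$n == 0) {
    abort("empty quadrant in median_deviation", class = "coactmap_unscorable")
  }
  M_raw <- a$med - b$med
  sem_M <- sqrt(a$sem^2 + b$sem^2)
  list(M = if (!is.na(sem_M) && abs(M_raw) > sem_M) M_raw else 0,
       M_raw = M_raw, sem_quadrant = a$sem, sem_baseline = b$sem,
       sem_M = sem_M, n_quadrant = a$n, n_baseline = b$n)
}

#' Expected combined effect under an additivity reference
#'
#' The reference additivity models against which the observed target-quadrant
#' deviation is compared: Highest Single Agent (`"hsa"`) takes the larger of
#' the two single-gene deviations, `max(M1, M2)`; Bliss independence
#' (`"bliss"`) combines them as `M1 + M2 - M1 * M2`.
#'
#' @param M1,M2 Single-gene median deviations (finite numerics; vectorized).
#' @param model `"hsa"` or `"bliss"`.
#' @return The expected deviation `M_E`.
#' @export
expected_additive <- function(M1, M2, model = c("hsa", "bliss")) {
  model <- match.arg(tolower(model), c("hsa", "bliss"))
  if (model == "hsa") pmax(M1, M2) else M1 + M2 - M1 * M2
}

.strat_aligned_values <- function(iap, strat) {
  y <- if (inherits(iap, "coactmap_iap")) iap$values else iap
  if (!is.null(names(y)) && !is.null(names(strat$labels))) {
    y <- y[match(names(strat$labels), names(y))]
  } else if (length(y) != length(strat$labels)) {
    abort("IAP values do not align with the stratification",
          class = "coactmap_consistency_error")
  }
  unname(y)
}

#' Score one configuration of a stratified pair
#'
#' Evaluates a single activating/deactivating configuration: computes the
#' thresholded median deviations of the target and the two single-gene
#' quadrants from the configuration's baseline, checks that their nonzero
#' directions agree, and forms the combined-action score against the
#' additivity reference. Returns `NULL` when the nonzero deviations disagree
#' in direction (missing score for this configuration).
#'
#' @inheritParams median_deviation
#' @param config A configuration id: `"act_act"`, `"deact_deact"`,
#'   `"act_deact"`, or `"deact_act"`.
#' @param model `"hsa"` or `"bliss"`.
#' @return List with `S`, `sign`, `M_target`, `M1`, `M2`, `M_E`, or `NULL`
#'   on a sign conflict.
#' @export
config_score <- function(iap, strat, config, model = c("hsa", "bliss")) {
  model <- match.arg(tolower(model), c("hsa", "bliss"))
  config <- match.arg(config, names(.CONFIGS))
  y <- .strat_aligned_values(iap, strat)
  qs <- .quadrant_stats(y, unname(strat$labels))
  .eval_config(qs, .CONFIGS[[config]], model)
}

# evaluate one configuration from precomputed quadrant stats.
# returns NULL on sign conflict (missing score for this config).
.eval_config <- function(qs, cfg, model) {
  b <- qs[[cfg$baseline]]
  dev <- function(q) {
    a <- qs[[q]]
    M_raw <- a$med - b$med
    sem_M <- sqrt(a$sem^2 + b$sem^2)
    if (!is.na(sem_M) && abs(M_raw) > sem_M) M_raw else 0
  }
  Mt <- dev(cfg$target)
  M1 <- dev(cfg$single1)
  M2 <- dev(cfg$single2)
  sg <- unique(sign(c(Mt, M1, M2)))
  sg <- sg[sg != 0]
  if (length(sg) > 1) return(NULL)        # opposing directions: no score
  sg <- if (length(sg) == 0) 1 else sg    # all-zero: S will be 0, sign +1
  M_E <- expected_additive(M1, M2, model)
  d <- Mt - M_E
  S <- if (d > 0) sg * d else 0
  list(S = S, sign = sg, M_target = Mt, M1 = M1, M2 = M2, M_E = M_E)
}

# full combined-action evaluation for one pair; x1, x2 expression vectors,
# y scaled IAP values, all sample-aligned.
.score_core <- function(x1, x2, y, model = "hsa", min_group_size = 10) {
  st <- .stratify_core(x1, x2, min_group_size)
  empty <- list(S = NA_real_, config = NA_character_, sign = NA_real_,
                M_target = NA_real_, M1 = NA_real_, M2 = NA_real_,
                M_E = NA_real_, quadrant_sizes = st$quadrant_sizes,
                scorable = FALSE, strat = st)
  if (!st$scorable) return(empty)
  qs <- .quadrant_stats(y, st$labels)
  n_iap <- vapply(qs, function(q) q$n, integer(1))
  if (any(n_iap < min_group_size)) {
    empty$quadrant_sizes <- n_iap
    return(empty)
  }
  best <- NULL
  best_id <- NA_character_
  for (id in names(.CONFIGS)) {
    res <- .eval_config(qs, .CONFIGS[[id]], model)
    if (!is.null(res) && (is.null(best) || res$S > best$S)) {
      best <- res
      best_id <- id
    }
  }
  if (is.null(best)) {
    empty$scorable <- TRUE
    return(empty)
  }
  list(S = best$S, config = best_id, sign = best$sign,
       M_target = best$M_target, M1 = best$M1, M2 = best$M2, M_E = best$M_E,
       quadrant_sizes = st$quadrant_sizes, scorable = TRUE, strat = st)
}

#' Combined-action score of a gene pair on a phenotype
#'
#' Evaluates all four activating/deactivating configurations of the pair
#' (both activating, both deactivating, and the two mixed cases; each fixes
#' a baseline and a target quadrant) and reports the configuration with the
#' highest score. For each configuration the score is
#' `S = sign(M) * (M_target - M_E)` when the target deviation exceeds the
#' additivity reference and 0 otherwise, where `sign(M)` is the shared
#' direction of the nonzero deviations; if the nonzero deviations disagree
#' in direction the configuration yields no score, and if all four do the
#' pair's score is missing. Ties on the maximal score resolve by the fixed
#' order `act_act`, `deact_deact`, `act_deact`, `deact_act`.
#'
#' @inheritParams stratify_pair
#' @param iap A `coactmap_iap` scaled phenotype (values named by sample).
#' @param model Additivity reference, `"hsa"` (default) or `"bliss"`.
#' @return One-row tibble: `tap`, `icp`, `iap`, `config`, `S`, `sign`,
#'   `M_target`, `M1`, `M2`, `M_E`, quadrant sizes `n_LL` ... `n_HH`,
#'   `scorable`, `model`.
#' @export
combined_action_score <- function(expr, iap, gene1, gene2,
                                  model = c("hsa", "bliss"),
                                  min_group_size = 10) {
  model <- match.arg(tolower(model), c("hsa", "bliss"))
  m <- .expr_matrix(expr)
  for (g in c(gene1, gene2)) {
    if (!g %in% rownames(m)) {
      abort(paste0("gene not in expression matrix: ", g),
            class = "coactmap_lookup_error")
    }
  }
  y <- .align_iap(iap, colnames(m))
  core <- .score_core(m[gene1, ], m[gene2, ], y, model, min_group_size)
  .core_row(gene1, gene2, iap$name, core, model)
}

.core_row <- function(gene1, gene2, iap_name, core, model) {
  tibble(tap = gene1, icp = gene2, iap = iap_name,
         config = core$config, S = core$S, sign = core$sign,
         M_target = core$M_target, M1 = core$M1, M2 = core$M2, M_E = core$M_E,
         n_LL = core$quadrant_sizes[["LL"]], n_LH = core$quadrant_sizes[["LH"]],
         n_HL = core$quadrant_sizes[["HL"]], n_HH = core$quadrant_sizes[["HH"]],
         scorable = core$scorable, model = model)
}

#' Score all TAP-ICP pairs against one phenotype
#'
#' @inheritParams combined_action_score
#' @param tap_genes,icp_genes Character vectors of tumor-associated-process
#'   and immune-checkpoint gene symbols. Genes absent from the matrix are
#'   dropped with a warning; self-pairs (a symbol in both lists) are never
#'   scored.
#' @return A tibble (class `coactmap_scores`) with one row per ordered
#'   (tap, icp) pair, lexicographically sorted; columns as in
#'   [combined_action_score()].
#' @export
score_pairs <- function(expr, iap, tap_genes, icp_genes,
                        model = c("hsa", "bliss"), min_group_size = 10) {
  model <- match.arg(tolower(model), c("hsa", "bliss"))
  m <- .expr_matrix(expr)
  drop_absent <- function(genes, what) {
    absent <- setdiff(genes, rownames(m))
    if (length(absent) > 0) {
      warn(paste0(what, " genes absent from matrix, dropped: ",
                  paste(absent, collapse = ", ")))
    }
    intersect(genes, rownames(m))
  }
  tap_genes <- drop_absent(unique(tap_genes), "TAP")
  icp_genes <- drop_absent(unique(icp_genes), "ICP")
  if (length(tap_genes) == 0 || length(icp_genes) == 0) {
    abort("empty gene list after intersecting with the expression matrix",
          class = "coactmap_config_error")
  }
  pairs <- crossing(tap = tap_genes, icp = icp_genes)
  pairs <- pairs[pairs$tap != pairs$icp, ]
  pairs <- arrange(pairs, .data$tap, .data$icp)
  y <- .align_iap(iap, colnames(m))
  rows <- pmap(list(pairs$tap, pairs$icp), function(a, b) {
    core <- .score_core(m[a, ], m[b, ], y, model, min_group_size)
    .core_row(a, b, iap$name, core, model)
  })
  out <- list_rbind(rows)
  attr(out, "model") <- model
  attr(out, "min_group_size") <- min_group_size
  class(out) <- c("coactmap_scores", class(out))
  out
}
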