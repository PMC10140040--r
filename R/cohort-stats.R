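#' Spearman partial correlation
#'
#' Rank-based partial correlation of `x` and `y` given control columns:
#' all variables are rank-transformed (average ranks for ties) and the
#' partial correlation is obtained either by correlating the residuals of
#' the two focal rank vectors after linear regression on the controls
#' (`method = "residual"`) or from the inverse of the rank correlation
#' matrix (`method = "precision"`); the two routes agree up to numerical
#' error. With no controls this reduces to the ordinary Spearman
#' correlation. The p-value uses the t approximation with
#' `n - 2 - k` degrees of freedom (`k` controls); a permutation p-value is
#' available via `n_perm`.
#'
#' @param x,y Numeric vectors.
#' @param controls Data frame / tibble of control columns (may have zero
#'   columns). Collinear control columns are dropped with a warning.
#' @param method `"residual"` (default) or `"precision"`.
#' @param n_perm If > 0, also compute a permutation p-value with this many
#'   permutations (`seed` fixes them).
#' @param seed Seed for the permutation p-value.
#' @return List with `rho`, `p`, `n`, `k`, and `p_perm` when requested.
#' @export
spearman_partial <- function(x, y, controls = NULL,
                             method = c("residual", "precision"),
                             n_perm = 0, seed = 1) {
  method <- match.arg(method)
  controls <- if (is.null(controls)) data.frame(row.names = seq_along(x))
              else as.data.frame(controls)
  cc <- if (ncol(controls) > 0) complete.cases(x, y, controls)
        else complete.cases(x, y)
  x <- x[cc]; y <- y[cc]
  controls <- controls[cc, , drop = FALSE]
  n <- length(x)
  if (n < 10) abort("need at least 10 complete samples", class = "coactmap_config_error")
  rx <- rank(x); ry <- rank(y)
  rc <- if (ncol(controls) > 0) {
    rcm <- vapply(controls, rank, numeric(n))
    qrc <- qr(cbind(1, rcm))
    if (qrc$rank < ncol(rcm) + 1) {
      keep_idx <- (qrc$pivot[seq_len(qrc$rank)] - 1)
      keep_idx <- keep_idx[keep_idx > 0]
      warn("dropping collinear control column(s)")
      rcm <- rcm[, keep_idx, drop = FALSE]
    }
    rcm
  } else {
    matrix(numeric(0), nrow = n, ncol = 0)
  }
  k <- ncol(rc)
  rho_of <- function(rx, ry) {
    if (k == 0) return(cor(rx, ry))
    if (method == "residual") {
      X <- cbind(1, rc)
      ex <- rx - X %*% qr.coef(qr(X), rx)
      ey <- ry - X %*% qr.coef(qr(X), ry)
      cor(ex, ey)[1, 1]
    } else {
      Rm <- cor(cbind(rx, ry, rc))
      P <- solve(Rm)
      -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
    }
  }
  rho <- rho_of(rx, ry)
  df <- n - 2 - k
  tstat <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  out <- list(rho = rho, p = p, n = n, k = k)
  if (n_perm > 0) {
    set.seed(seed)
    null_rho <- vapply(seq_len(n_perm), function(i) {
      rho_of(rank(x)[sample.int(n)], ry)
    }, numeric(1))
    out$p_perm <- (1 + sum(abs(null_rho) >= abs(rho))) / (1 + n_perm)
  }
  out
}

#' Partial correlations of a gene with immune cell-type fractions
#'
#' For each cell type, computes the Spearman partial correlation of the
#' gene's expression with that cell type's fraction while controlling for
#' all remaining cell-type columns, with Bonferroni adjustment across the
#' cell types tested.
#'
#' @param gene_values Named (by sample) or sample-aligned numeric vector of
#'   the gene's expression.
#' @param fractions Tibble with a `sample` column plus one numeric column
#'   per cell type.
#' @param gene Label for the gene (carried into the output).
#' @return Tibble with columns `gene`, `cell_type`, `rho`, `p`, `p_adj`,
#'   `n`.
#' @export
partial_cor_fractions <- function(gene_values, fractions, gene = "gene") {
  stopifnot("sample" %in% names(fractions))
  cell_types <- setdiff(names(fractions), "sample")
  if (length(cell_types) < 2) {
    abort("need at least 2 cell-type columns", class = "coactmap_config_error")
  }
  gv <- if (!is.null(names(gene_values))) {
    gene_values[match(fractions$sample, names(gene_values))]
  } else {
    gene_values
  }
  rows <- map(cell_types, function(ct) {
    res <- spearman_partial(gv, fractions[[ct]],
                            fractions[setdiff(cell_types, ct)])
    tibble(gene = gene, cell_type = ct, rho = res$rho, p = res$p,
           p_adj = min(1, res$p * length(cell_types)), n = res$n)
  })
  list_rbind(rows)
}

#' Log-rank survival comparison of expression-stratified groups
#'
#' Standard (unweighted) log-rank test of survival across the four quadrant
#' sub-cohorts of a gene pair, plus an optional two-group test between a
#' target and a baseline quadrant (e.g. the winning configuration's).
#'
#' @param strat A `coactmap_strat` from [stratify_pair()].
#' @param survival_tbl Tibble with columns `sample`, `time` (> 0), `event`
#'   (0/1).
#' @param target,baseline Optional quadrant labels for the pairwise test.
#' @return List with `statistic` (log-rank chi-square), `df`, `p`,
#'   `groups` (per-sample labels used), `n`, and when requested
#'   `p_pairwise`.
#' @export
logrank_survival <- function(strat, survival_tbl, target = NULL,
                             baseline = NULL) {
  stopifnot(all(c("sample", "time", "event") %in% names(survival_tbl)))
  if (any(survival_tbl$time <= 0, na.rm = TRUE)) {
    abort("survival times must be positive", class = "coactmap_validation_error")
  }
  if (!all(survival_tbl$event %in% c(0, 1, NA))) {
    abort("event must be 0/1", class = "coactmap_validation_error")
  }
  lab <- strat$labels[match(survival_tbl$sample, names(strat$labels))]
  ok <- !is.na(lab) & !is.na(survival_tbl$time) & !is.na(survival_tbl$event)
  d <- data.frame(time = survival_tbl$time[ok], event = survival_tbl$event[ok],
                  group = lab[ok])
  if (sum(d$event) == 0) {
    warn("no events observed; log-rank p set to 1")
    return(list(statistic = NA_real_, df = NA_integer_, p = 1,
                groups = setNames(lab, survival_tbl$sample), n = nrow(d)))
  }
  fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  df <- length(fit$n) - 1
  out <- list(statistic = fit$chisq, df = df,
              p = pchisq(fit$chisq, df, lower.tail = FALSE),
              groups = setNames(lab, survival_tbl$sample), n = nrow(d))
  if (!is.null(target) && !is.null(baseline)) {
    d2 <- d[d$group %in% c(target, baseline), ]
    if (sum(d2$event) == 0 || length(unique(d2$group)) < 2) {
      out$p_pairwise <- 1
    } else {
      fit2 <- survival::survdiff(survival::Surv(time, event) ~ group, data = d2)
      out$p_pairwise <- pchisq(fit2$chisq, 1, lower.tail = FALSE)
    }
  }
  out
}
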