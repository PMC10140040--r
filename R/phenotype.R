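#' Signature-based phenotype score
#'
#' Quantifies an immune-associated phenotype (IAP) from expression as the
#' mean, over the signature genes, of per-gene z-scores of log-scaled
#' expression: for each gene, values are transformed with `log2(x + 1)` and
#' standardized across samples (mean 0, sd 1); a sample's score is the mean
#' of its z-values across the signature genes. Genes that are constant
#' across samples contribute 0; signature genes absent from the matrix are
#' dropped with a warning.
#'
#' @param expr Gene-by-sample expression tibble (see [read_expression()]).
#' @param genes Character vector of signature gene symbols.
#' @param name Name of the resulting phenotype column.
#' @return A tibble with columns `sample` and `<name>` (the raw score).
#' @export
signature_score <- function(expr, genes, name = "signature") {
  m <- .expr_matrix(expr)
  if (ncol(m) < 3) abort("need at least 3 samples", class = "coactmap_config_error")
  present <- intersect(genes, rownames(m))
  missing <- setdiff(genes, rownames(m))
  if (length(missing) > 0) {
    warn(paste0("signature genes absent from matrix: ",
                paste(missing, collapse = ", ")))
  }
  if (length(present) == 0) {
    abort("no signature gene present in the expression matrix",
          class = "coactmap_config_error")
  }
  lg <- log2(m[present, , drop = FALSE] + 1)
  z <- t(apply(lg, 1, function(v) {
    mu <- mean(v, na.rm = TRUE)
    s <- sd(v, na.rm = TRUE)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mu) / s
  }))
  score <- colMeans(z, na.rm = TRUE)
  out <- tibble(sample = colnames(m))
  out[[name]] <- unname(score)
  out
}

#' Rescale a raw phenotype onto \[0, 1\]
#'
#' Applies the branchwise logistic-sigmoidal rescaling that puts every IAP on
#' a common \[0, 1\] scale so that combined-action scores are comparable
#' across phenotypes:
#' * `identity`: raw values already all in \[0, 1\] are returned unchanged;
#' * `real_line`: values spanning the real line map to
#'   `(tanh(x / sigma) + 1) / 2` (used whenever any value is negative);
#' * `nonnegative`: nonnegative values with some above 1 map to
#'   `tanh(x / sigma)`.
#'
#' `sigma` is the sample standard deviation (n - 1 denominator) of the
#' non-missing raw values. Missing values stay missing and are excluded from
#' `sigma`.
#'
#' @param raw Numeric vector of raw IAP values, optionally named by sample.
#' @param name Phenotype name carried on the result.
#' @return A `coactmap_iap` object: list with `name`, `values` (scaled,
#'   same names/length as `raw`), `sigma`, and `branch`.
#' @export
scale_iap <- function(raw, name = "iap") {
  v <- raw[!is.na(raw)]
  if (length(unique(v)) < 2) {
    abort("degenerate phenotype: fewer than 2 distinct non-missing values",
          class = "coactmap_degenerate_error")
  }
  sigma <- sd(v)
  if (sigma == 0) {
    abort("constant phenotype cannot be scaled", class = "coactmap_degenerate_error")
  }
  if (all(v >= 0 & v <= 1)) {
    branch <- "identity"
    scaled <- raw
  } else if (any(v < 0)) {
    branch <- "real_line"
    scaled <- (tanh(raw / sigma) + 1) / 2
  } else {
    branch <- "nonnegative"
    scaled <- tanh(raw / sigma)
  }
  structure(list(name = name, values = scaled, sigma = sigma, branch = branch),
            class = "coactmap_iap")
}

#' @export
print.coactmap_iap <- function(x, ...) {
  cat("<coactmap_iap> ", x$name, ": ", sum(!is.na(x$values)),
      " samples, branch = ", x$branch,
      ", sigma = ", format(x$sigma, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Scale every phenotype column of a phenotype table
#'
#' @param phenotypes A sample-by-phenotype tibble (see [read_phenotypes()]).
#' @return Named list of `coactmap_iap` objects, one per phenotype column,
#'   each with values named by sample.
#' @export
scale_phenotypes <- function(phenotypes) {
  stopifnot("sample" %in% names(phenotypes))
  cols <- setdiff(names(phenotypes), "sample")
  setNames(lapply(cols, function(cn) {
    scale_iap(setNames(phenotypes[[cn]], phenotypes$sample), name = cn)
  }), cols)
}

# align an IAP's values to an expression matrix's samples (by name when
# available, else positionally with a length check)
.align_iap <- function(iap, samples) {
  v <- iap$values
  if (!is.null(names(v))) {
    out <- v[match(samples, names(v))]
  } else {
    if (length(v) != length(samples)) {
      abort("unnamed IAP values must match the number of samples",
            class = "coactmap_consistency_error")
    }
    out <- v
  }
  unname(out)
}
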