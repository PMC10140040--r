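# Independent brute-force oracles, written as plain loops against the
# method's defining formulas.  They deliberately share no code with the
# package internals.

# combined-action score of one pair: median-split quadrants, thresholded
# median deviations from baseline, additivity reference, best of the four
# configurations.  Returns per-config scores plus the winner.
oracle_score <- function(x1, x2, y, model = "hsa", min_group_size = 3) {
  quads <- c("LL", "LH", "HL", "HH")
  ok <- !is.na(x1) & !is.na(x2)
  out <- list(S = NA_real_, config = NA_character_,
              per_config = setNames(rep(NA_real_, 4),
                                    c("act_act", "deact_deact",
                                      "act_deact", "deact_act")))
  if (sum(ok) < 4 * min_group_size) return(out)
  c1 <- stats::median(x1[ok])
  c2 <- stats::median(x2[ok])
  lab <- rep(NA_character_, length(x1))
  for (i in seq_along(x1)) {
    if (ok[i]) {
      lab[i] <- paste0(if (x1[i] > c1) "H" else "L",
                       if (x2[i] > c2) "H" else "L")
    }
  }
  vals <- list()
  for (q in quads) vals[[q]] <- y[which(lab == q & !is.na(y))]
  if (any(vapply(vals, length, integer(1)) < min_group_size)) return(out)
  med <- vapply(vals, stats::median, numeric(1))
  semm <- vapply(vals, function(v) 1.2533 * stats::sd(v) / sqrt(length(v)),
                 numeric(1))
  # (baseline, target, single1, single2) per configuration
  cfgs <- list(act_act     = c("LL", "HH", "HL", "LH"),
               deact_deact = c("HH", "LL", "LH", "HL"),
               act_deact   = c("LH", "HL", "HH", "LL"),
               deact_act   = c("HL", "LH", "LL", "HH"))
  best <- NULL
  best_id <- NA_character_
  for (id in names(cfgs)) {
    qn <- cfgs[[id]]
    b <- qn[1]
    Ms <- numeric(3)
    for (j in 1:3) {
      Mr <- med[[qn[j + 1]]] - med[[b]]
      se <- sqrt(semm[[qn[j + 1]]]^2 + semm[[b]]^2)
      Ms[j] <- if (abs(Mr) > se) Mr else 0
    }
    sg <- unique(sign(Ms))
    sg <- sg[sg != 0]
    if (length(sg) > 1) next
    sgv <- if (length(sg) == 0) 1 else sg
    ME <- if (model == "hsa") max(Ms[2], Ms[3]) else Ms[2] + Ms[3] - Ms[2] * Ms[3]
    d <- Ms[1] - ME
    S <- if (d > 0) sgv * d else 0
    out$per_config[[id]] <- S
    if (is.null(best) || S > best) {
      best <- S
      best_id <- id
    }
  }
  if (!is.null(best)) {
    out$S <- best
    out$config <- best_id
  }
  out
}

# exact two-sided rank-sum p by full enumeration of group assignments
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  combs <- utils::combn(n, n1)
  ws <- colSums(matrix(r[combs], nrow = n1))
  p_le <- mean(ws <= w)
  p_ge <- mean(ws >= w)
  min(1, 2 * min(p_le, p_ge))
}

# BH step-up from its definition: sort, p * m / rank, cumulative minimum
# from the largest p down, cap at 1, restore input order
oracle_bh <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) {
    if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  }
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# textbook observed-minus-expected log-rank statistic for two groups with
# hypergeometric variance at each distinct event time
oracle_logrank_chisq <- function(time, event, group) {
  g1 <- sort(unique(group))[1]
  O1 <- 0; E1 <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    nj <- sum(at_risk)
    n1j <- sum(at_risk & group == g1)
    dj <- sum(time == t & event == 1)
    d1j <- sum(time == t & event == 1 & group == g1)
    O1 <- O1 + d1j
    E1 <- E1 + dj * n1j / nj
    if (nj > 1) V <- V + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
  }
  (O1 - E1)^2 / V
}
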