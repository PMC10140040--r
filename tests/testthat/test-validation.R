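test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.005, 0.04, 0.5)), c(0.015, 0.06, 0.5))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  set.seed(31)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("significance is the worst of the three target contrasts", {
  # perfectly separated 5 vs 5 groups: exact two-sided p = 2/252
  qc <- quadrant_cohort(n_per_quad = 5,
                        means = c(LL = 0.1, LH = 0.2, HL = 0.3, HH = 0.9),
                        jitter = 0.01, seed = 8)
  st <- stratify_pair(qc$expr, "gA", "gB", min_group_size = 5)
  sig <- significance_test(qc$iap, st, "act_act")
  expect_equal(length(sig$p_by_group), 3)
  expect_equal(unname(sig$p_by_group), rep(2 / 252, 3), tolerance = 1e-12)
  expect_equal(sig$p, 2 / 252, tolerance = 1e-12)

  # identical IAP everywhere: p = 1
  qc2 <- quadrant_cohort(n_per_quad = 6,
                         means = c(LL = 0.5, LH = 0.5, HL = 0.5, HH = 0.5))
  st2 <- stratify_pair(qc2$expr, "gA", "gB", min_group_size = 5)
  sig2 <- significance_test(qc2$iap, st2, "act_act")
  expect_equal(sig2$p, 1)

  # the reported p is the max of the three per-contrast p values
  qc3 <- quadrant_cohort(n_per_quad = 8,
                         means = c(LL = 0.1, LH = 0.6, HL = 0.2, HH = 0.7),
                         jitter = 0.15, seed = 12)
  st3 <- stratify_pair(qc3$expr, "gA", "gB", min_group_size = 5)
  sig3 <- significance_test(qc3$iap, st3, "act_act")
  expect_equal(sig3$p, max(sig3$p_by_group))
  expect_gt(sig3$p, min(sig3$p_by_group))
})

test_that("rank-sum p-values agree with exact enumeration for small groups", {
  set.seed(17)
  for (n1 in 2:7) {
    for (n2 in n1:(14 - n1)) {
      x <- rnorm(n1)
      y <- rnorm(n2, 0.5)
      expect_equal(coactmap:::.ranksum_p(x, y), oracle_ranksum_p(x, y),
                   tolerance = 1e-12)
    }
  }
})

test_that("robustness is the normalized RMSD of resampled scores", {
  # Eq arithmetic on a known partial-score set
  expect_equal(robustness_ratio(0.2, c(0.1, 0.3)), 0.5)
  expect_gt(-log(0.5), 0)
  expect_equal(robustness_ratio(0.2, c(0.1, NA, 0.3)), 0.5)
  expect_true(is.na(robustness_ratio(0.2, c(NA_real_, NA_real_))))

  # quadrant-constant IAP: every resample reproduces the same medians,
  # so every partial score equals the complete score and R = 0
  qc <- quadrant_cohort(n_per_quad = 50,
                        means = c(LL = 0.1, LH = 0.3, HL = 0.3, HH = 0.9))
  rb <- robustness(qc$expr, qc$iap, "gA", "gB", n_boot = 50, seed = 5,
                   min_group_size = 10)
  expect_equal(rb$R, 0)
  expect_true(rb$robust)
  expect_equal(rb$n_valid, 50)
  expect_true(all(rb$partial_scores == rb$S_complete))

  # a zero or missing complete score has no defined robustness
  qc2 <- quadrant_cohort(n_per_quad = 30,
                         means = c(LL = 0.5, LH = 0.5, HL = 0.5, HH = 0.5),
                         jitter = 0, seed = 2)
  expect_error(robustness(qc2$expr, qc2$iap, "gA", "gB", n_boot = 20),
               class = "coactmap_undefined_error")

  # planted synthetic pair: robust under default coverage
  su <- recovery_setup(seed = 33)
  rb2 <- robustness(su$cohort$expr, su$iap, "TAP1", "ICP1",
                    n_boot = 100, seed = 3)
  expect_lt(rb2$R, 1)
  expect_true(rb2$robust)
})

test_that("specificity uses add-one empirical tails and the max rule", {
  su <- recovery_setup(seed = 44)
  sp <- suppressWarnings(
    specificity_test(su$cohort$expr, su$iap, "TAP1", "ICP1",
                     n_random = 61, seed = 9))
  expect_true(sp$defined)
  expect_equal(sp$p_max, max(sp$p_g1, sp$p_g2))
  expect_true(sp$p_g1 > 0 && sp$p_g1 <= 1)
  n_valid <- sum(!is.na(sp$null_scores_g1))
  # manual recomputation of the add-one tail for gene 1
  S_obs <- combined_action_score(su$cohort$expr, su$iap, "TAP1", "ICP1")$S
  v <- sp$null_scores_g1[!is.na(sp$null_scores_g1)]
  expect_equal(sp$p_g1, (1 + sum(v >= S_obs)) / (1 + n_valid))

  # monotone non-increasing in the observed score for a fixed null sample
  p_at <- function(s) {
    r <- suppressWarnings(
      specificity_test(su$cohort$expr, su$iap, "TAP1", "ICP1",
                       S_observed = s, n_random = 61, seed = 9))
    r$p_max
  }
  ps <- vapply(c(0.01, 0.1, 0.3, 1), p_at, numeric(1))
  expect_true(all(diff(ps) <= 0))
  # a score above every null score gives the minimal add-one p
  expect_equal(p_at(2), 1 / (1 + n_valid))

  # an unreachable validity threshold makes specificity undefined
  sp2 <- suppressWarnings(
    specificity_test(su$cohort$expr, su$iap, "TAP1", "ICP1",
                     n_random = 61, seed = 9, min_valid_null = 1e6))
  expect_false(sp2$defined)
  expect_true(is.na(sp2$p_max))
})

test_that("staged validation passes a planted pair and stages are ordered", {
  su <- recovery_setup(seed = 7)
  sc <- score_pairs(su$cohort$expr, su$iap, su$tap, su$icp)
  v <- suppressWarnings(
    validate_interactions(su$cohort$expr, su$iap, sc,
                          n_boot = 200, n_random = 200, seed = 11))
  planted <- v[v$tap == "TAP1", ]
  expect_true(planted$passed)
  expect_equal(planted$stage, "passed")
  expect_lt(-log(planted$R), Inf)
  expect_gt(-log(planted$R), 0)
  expect_lt(planted$Q_significance, 0.1)
  expect_lt(planted$Q_specificity, 0.1)

  # stage counts never increase along the pipeline
  g <- glance(v)
  expect_true(g$n_scored >= g$n_robust)
  expect_true(g$n_robust >= g$n_significant)
  expect_true(g$n_significant >= g$n_passed)

  # stage labels are consistent with the pass flags
  expect_true(all(v$stage[v$passed] == "passed"))
  expect_true(all(!v$robust[v$stage == "robustness"]))

  # tidy() exposes the serializable view
  td <- tidy(v)
  expect_true(all(c("tap", "icp", "S", "R", "Q_significance",
                    "Q_specificity", "passed") %in% names(td)))
})

test_that("validation fails everything when no pair has a usable score", {
  # constant-per-quadrant IAP equal everywhere: every score is 0
  expr <- toy_expr(lapply(stats::setNames(1:4, paste0("g", 1:4)),
                          function(.) rnorm(60)))
  iap <- as_iap(rep(0.5, 60), samples = colnames(expr)[-1])
  sc <- score_pairs(expr, iap, c("g1", "g2"), c("g3", "g4"),
                    min_group_size = 5)
  v <- validate_interactions(expr, iap, sc, n_boot = 10, n_random = 10,
                             min_group_size = 5)
  expect_true(all(!v$passed))
  expect_true(all(v$stage == "score"))
})
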