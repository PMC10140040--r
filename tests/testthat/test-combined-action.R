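test_that("median-split stratification labels quadrants with ties going low", {
  expr <- toy_expr(list(g1 = c(1, 1, 5, 5), g2 = c(1, 5, 1, 5)))
  st <- stratify_pair(expr, "g1", "g2", min_group_size = 1)
  expect_equal(unname(st$labels), c("LL", "LH", "HL", "HH"))

  # a value exactly at the median is labeled L on that axis
  expr2 <- toy_expr(list(g1 = c(1, 2, 3, 4, 5), g2 = c(5, 4, 3, 2, 1)))
  st2 <- stratify_pair(expr2, "g1", "g2", min_group_size = 1)
  expect_equal(st2$cut1, 3)
  expect_equal(substr(st2$labels[["s03"]], 1, 1), "L")
  expect_equal(substr(st2$labels[["s03"]], 2, 2), "L")

  # 8-sample toy: counts match exhaustive enumeration
  g1 <- c(1, 2, 3, 4, 5, 6, 7, 8)   # median 4.5
  g2 <- c(3, 1, 2, 4, 1, 2, 3, 1)   # median 2.0
  expr3 <- toy_expr(list(g1 = g1, g2 = g2))
  st3 <- stratify_pair(expr3, "g1", "g2", min_group_size = 1)
  counts <- c(LL = 0, LH = 0, HL = 0, HH = 0)
  for (i in 1:8) {
    lab <- paste0(if (g1[i] > 4.5) "H" else "L", if (g2[i] > 2) "H" else "L")
    counts[lab] <- counts[lab] + 1
  }
  expect_equal(st3$quadrant_sizes, counts[c("LL", "LH", "HL", "HH")])

  expect_error(stratify_pair(expr, "nope", "g2"), class = "coactmap_lookup_error")
  # below min group size: flagged unscorable, not an error
  st4 <- stratify_pair(expr, "g1", "g2", min_group_size = 10)
  expect_false(st4$scorable)
})

test_that("median deviations threshold at the quadrature-combined sem", {
  qc <- quadrant_cohort(n_per_quad = 10,
                        means = c(LL = 0.2, LH = 0.3, HL = 0.3, HH = 0.5))
  st <- stratify_pair(qc$expr, "gA", "gB", min_group_size = 5)
  md <- median_deviation(qc$iap, st, "HH", "LL")
  # noise-free quadrants: sems are zero, M is the raw median difference
  expect_equal(md$M, 0.3, tolerance = 1e-12)
  expect_equal(md$sem_M, 0)

  # Pythagorean sem combination and the zeroing rule, checked directly
  expect_equal(sqrt(0.3^2 + 0.4^2), 0.5)
  qc2 <- quadrant_cohort(n_per_quad = 20,
                         means = c(LL = 0.5, LH = 0.5, HL = 0.5, HH = 0.5),
                         jitter = 0.2, seed = 4)
  st2 <- stratify_pair(qc2$expr, "gA", "gB", min_group_size = 5)
  md2 <- median_deviation(qc2$iap, st2, "HH", "LL")
  expect_equal(md2$sem_M,
               sqrt(md2$sem_quadrant^2 + md2$sem_baseline^2), tolerance = 1e-12)
  if (abs(md2$M_raw) < md2$sem_M) expect_identical(md2$M, 0)
})

test_that("additivity references follow HSA and Bliss formulas", {
  expect_equal(expected_additive(0.2, 0.3, "hsa"), 0.3)
  expect_equal(expected_additive(0.2, 0.3, "bliss"), 0.44)
  for (M2 in c(-0.5, 0, 0.3, 1)) {
    expect_equal(expected_additive(0, M2, "bliss"), M2)
  }
  # HSA reference never exceeds Bliss for deviations in [0,1]
  set.seed(9)
  m1 <- runif(100); m2 <- runif(100)
  expect_true(all(expected_additive(m1, m2, "hsa") <=
                    expected_additive(m1, m2, "bliss") + 1e-12))
})

test_that("configuration scores implement the signed excess over additivity", {
  # near-noise-free quadrants with known medians
  qc <- quadrant_cohort(n_per_quad = 12,
                        means = c(LL = 0.2, LH = 0.5, HL = 0.4, HH = 0.8))
  st <- stratify_pair(qc$expr, "gA", "gB", min_group_size = 5)
  cs <- config_score(qc$iap, st, "act_act", model = "bliss")
  # M1 (HL) = 0.2, M2 (LH) = 0.3, M_target = 0.6; Bliss M_E = 0.44
  expect_equal(cs$M1, 0.2, tolerance = 1e-12)
  expect_equal(cs$M2, 0.3, tolerance = 1e-12)
  expect_equal(cs$M_target, 0.6, tolerance = 1e-12)
  expect_equal(cs$M_E, 0.44, tolerance = 1e-12)
  expect_equal(cs$S, 0.16, tolerance = 1e-12)
  expect_equal(cs$sign, 1)

  # target deviation below the reference: score clamps to zero
  qc2 <- quadrant_cohort(n_per_quad = 12,
                         means = c(LL = 0.2, LH = 0.5, HL = 0.4, HH = 0.6))
  st2 <- stratify_pair(qc2$expr, "gA", "gB", min_group_size = 5)
  cs2 <- config_score(qc2$iap, st2, "act_act", model = "bliss")
  expect_equal(cs2$M_target - cs2$M_E, 0.4 - 0.44, tolerance = 1e-12)
  expect_equal(cs2$S, 0)

  # opposing nonzero directions: the configuration yields no score
  qc3 <- quadrant_cohort(n_per_quad = 12,
                         means = c(LL = 0.5, LH = 0.2, HL = 0.7, HH = 0.9))
  st3 <- stratify_pair(qc3$expr, "gA", "gB", min_group_size = 5)
  expect_null(config_score(qc3$iap, st3, "act_act", model = "bliss"))
})

test_that("the best of four configurations is reported deterministically", {
  su <- recovery_setup(seed = 21)
  res <- combined_action_score(su$cohort$expr, su$iap, "TAP1", "ICP1")
  expect_equal(res$config, "act_act")
  expect_gt(res$S, 0)

  # constant IAP: every deviation is zero, score 0 via the first config
  expr <- toy_expr(lapply(list(a = 1, b = 2), function(.) rnorm(40)))
  const_iap <- as_iap(rep(0.5, 40), samples = colnames(expr)[-1])
  res2 <- combined_action_score(expr, const_iap, "a", "b", min_group_size = 5)
  expect_equal(res2$S, 0)
  expect_equal(res2$config, "act_act")
})

test_that("pipeline scores equal the brute-force oracle on random cohorts", {
  for (seed in 1:40) {
    rc <- random_cohort(seed)
    m <- as.matrix(rc$expr[-1])
    rownames(m) <- rc$expr$gene
    pairs <- utils::combn(rc$genes, 2)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      for (model in c("hsa", "bliss")) {
        got <- combined_action_score(rc$expr, rc$iap, a, b, model = model,
                                     min_group_size = 3)
        want <- oracle_score(m[a, ], m[b, ], unname(rc$iap$values),
                             model = model, min_group_size = 3)
        if (is.na(want$S)) {
          expect_true(is.na(got$S))
        } else {
          expect_equal(got$S, want$S, tolerance = 1e-12)
          expect_equal(got$config, want$config)
        }
      }
    }
  }
})

test_that("scores are symmetric in gene order and invariant to relabeling", {
  for (seed in c(3, 14)) {
    rc <- random_cohort(seed, n_samples = 48, n_genes = 6)
    for (j in 1:5) {
      a <- rc$genes[j]; b <- rc$genes[j + 1]
      r1 <- combined_action_score(rc$expr, rc$iap, a, b, min_group_size = 3)
      r2 <- combined_action_score(rc$expr, rc$iap, b, a, min_group_size = 3)
      expect_equal(r1$S, r2$S, tolerance = 1e-12)
      if (!is.na(r1$config)) {
        mirror <- c(act_act = "act_act", deact_deact = "deact_deact",
                    act_deact = "deact_act", deact_act = "act_deact")
        # equal scores may tie across configs; accept the mirrored winner
        expect_true(r2$config %in% c(mirror[[r1$config]], r1$config))
      }
    }
    # strictly increasing transform of one gene leaves stratification alone
    expr2 <- rc$expr
    expr2[expr2$gene == rc$genes[1], -1] <-
      exp(expr2[expr2$gene == rc$genes[1], -1])
    s1 <- stratify_pair(rc$expr, rc$genes[1], rc$genes[2], min_group_size = 3)
    s2 <- stratify_pair(expr2, rc$genes[1], rc$genes[2], min_group_size = 3)
    expect_equal(s1$labels, s2$labels)
    r1 <- combined_action_score(rc$expr, rc$iap, rc$genes[1], rc$genes[2],
                                min_group_size = 3)
    r2 <- combined_action_score(expr2, rc$iap, rc$genes[1], rc$genes[2],
                                min_group_size = 3)
    expect_equal(r1$S, r2$S, tolerance = 1e-12)
  }
})

test_that("all-pairs scoring enumerates ordered pairs minus self-pairs", {
  rc <- random_cohort(5, n_samples = 48, n_genes = 8)
  iap <- rc$iap
  tap <- rc$genes[1:3]
  icp <- rc$genes[4:5]
  sc <- score_pairs(rc$expr, iap, tap, icp, min_group_size = 3)
  expect_equal(nrow(sc), 6)
  expect_equal(order(sc$tap, sc$icp), 1:6)

  # one shared symbol between the lists: the self-pair is skipped
  sc2 <- score_pairs(rc$expr, iap, rc$genes[1:3], rc$genes[c(1, 4, 5)],
                     min_group_size = 3)
  expect_equal(nrow(sc2), 8)
  expect_false(any(sc2$tap == sc2$icp))

  # permutation of the sample order leaves results unchanged
  set.seed(99)
  cols <- c(1, sample(2:ncol(rc$expr)))
  expr_c <- rc$expr[, cols]
  sc3 <- score_pairs(expr_c, iap, tap, icp, min_group_size = 3)
  expect_equal(sc3$S, sc$S, tolerance = 1e-12)
  expect_equal(sc3$config, sc$config)

  expect_warning(score_pairs(rc$expr, iap, c(tap, "ABSENT"), icp,
                             min_group_size = 3), "ABSENT")
})
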