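test_that("V-shape regression recovers a noiseless parabola exactly", {
  x <- seq(0, 1, length.out = 42)
  y <- 3 * (x - 0.4)^2 + 1
  v <- vshape_test(y, x)
  expect_lt(v$p_value, 1e-12)
  expect_equal(v$vertex, 0.4, tolerance = 1e-9)
  # downward parabola has no vertex to report
  v2 <- vshape_test(-y, x)
  expect_true(is.na(v2$vertex))
  expect_error(vshape_test(y[1:3], x[1:3]), "at least 5")
})

test_that("differential expression matches t.test gene by gene", {
  set.seed(10)
  m <- matrix(stats::rnorm(50 * 12), 50, 12,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:12)))
  a <- paste0("s", 1:6); b <- paste0("s", 7:12)
  for (ve in c(TRUE, FALSE)) {
    de <- differential_expression(m, a, b, var_equal = ve)
    pref <- vapply(seq_len(50), function(i)
      stats::t.test(m[i, a], m[i, b], var.equal = ve)$p.value, numeric(1))
    expect_equal(de$p, pref, tolerance = 1e-12)
  }
  expect_error(differential_expression(m, a, c(a[1], b)), "disjoint")
  expect_error(differential_expression(m, a[1], b), "at least 2")
})

test_that("identical groups and degenerate genes are handled", {
  set.seed(2)
  m <- matrix(stats::rnorm(30 * 8), 30, 8,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:8)))
  m2 <- cbind(m, m); colnames(m2) <- paste0("s", 1:16)
  de <- differential_expression(m2, paste0("s", 1:8), paste0("s", 9:16))
  expect_equal(attr(de, "n_significant"), 0L)
  expect_true(all(de$p == 1))

  m3 <- m
  m3["g1", ] <- 5                 # constant everywhere: no evidence
  m3["g2", ] <- rep(c(1, 2), each = 4)  # constant per group, different means
  de3 <- differential_expression(m3, paste0("s", 1:4), paste0("s", 5:8))
  expect_equal(de3$p[de3$gene == "g1"], 1)
  expect_equal(de3$p[de3$gene == "g2"], 0)
  expect_true(de3$flagged[de3$gene == "g2"])
  expect_false(de3$flagged[de3$gene == "g1"])
})

test_that("BH adjustment equals the independent step-up oracle", {
  set.seed(8)
  for (n in c(1, 5, 17, 20)) {
    p <- stats::runif(n)
    expect_equal(stats::p.adjust(p, "BH"), bh_stepup(p), tolerance = 1e-12)
  }
  # q is never below p, and counts are consistent
  m <- matrix(stats::rnorm(40 * 8), 40, 8,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:8)))
  de <- differential_expression(m, paste0("s", 1:4), paste0("s", 5:8))
  expect_true(all(de$q >= de$p - 1e-12))
  expect_equal(attr(de, "n_significant"), sum(de$q < 0.05))
  expect_equal(attr(de, "fraction_significant"),
               100 * sum(de$q < 0.05) / nrow(de))
})

test_that("DE fractions follow planted separation and are symmetric", {
  set.seed(12)
  g <- 400L
  base <- matrix(stats::rnorm(g * 30), g, 30)
  shift <- c(T1 = 0, T2 = 0.5, AP = 1.1, BC = 2.2)  # partial per-gene power
  groups <- split(paste0("s", 1:30), rep(names(shift), c(10, 8, 6, 6)))
  m <- base
  colnames(m) <- paste0("s", 1:30); rownames(m) <- paste0("g", 1:g)
  idx <- 1:80  # planted genes
  lab <- rep(names(shift), c(10, 8, 6, 6))
  for (s in names(shift)) m[idx, lab == s] <- m[idx, lab == s] + shift[[s]]
  fr <- de_fraction_matrix(m, groups)
  expect_equal(fr, t(fr))
  expect_true(all(diag(fr) == 0))
  expect_gt(fr["T1", "BC"], fr["T1", "AP"])
  expect_gt(fr["T1", "AP"], fr["T1", "T2"])
  # two identical groups: exactly zero
  m2 <- cbind(m[, 1:4], m[, 1:4]); colnames(m2) <- paste0("x", 1:8)
  fr2 <- de_fraction_matrix(m2, list(a = paste0("x", 1:4),
                                     b = paste0("x", 5:8)))
  expect_equal(fr2["a", "b"], 0)
})

test_that("fraction arithmetic reproduces 411 of 4309 as 9.54 percent", {
  expect_equal(round(100 * 411 / 4309, 2), 9.54)
  # deterministic construction: exactly n_sig genes differ between groups
  n_sig <- 25L; g <- 400L
  m <- matrix(5, g, 20, dimnames = list(paste0("g", 1:g), paste0("s", 1:20)))
  m[seq_len(n_sig), 1:10] <- 1
  m[seq_len(n_sig), 11:20] <- 2
  de <- differential_expression(m, paste0("s", 1:10), paste0("s", 11:20))
  expect_equal(attr(de, "n_significant"), n_sig)
  expect_equal(attr(de, "fraction_significant"), 100 * n_sig / g)
})

test_that("entropy-correlation subsampling behaves at the extremes", {
  x <- seq_len(40) + 0
  r <- entropy_correlation_subsample(x, 2 * x + 3, n_iter = 100, seed = 1)
  expect_equal(r$pct_significant, 100)
  expect_lt(r$p_value, 1e-10)
  expect_error(entropy_correlation_subsample(x[1:4], x[1:4]), "at least 5")
  expect_error(entropy_correlation_subsample(x, 2 * x, subsample_frac = 0.05),
               "too small")
  # independent pairs: averaged over datasets the significant fraction
  # approaches the nominal level
  set.seed(99)
  rates <- replicate(40, {
    a <- stats::rnorm(42); b <- stats::rnorm(42)
    entropy_correlation_subsample(a, b, n_iter = 60,
                                  subsample_frac = 0.8)$pct_significant
  })
  expect_gt(mean(rates), 1)
  expect_lt(mean(rates), 12)
})

test_that("the stage grid matches a hand enumeration and conserves counts", {
  # eight patients, one per cell: scores in quarters, entropies in halves
  sc <- c(0.1, 0.35, 0.6, 0.85, 0.1, 0.35, 0.6, 0.85) * 10
  en <- c(rep(0, 4), rep(1, 4))
  st <- c("CP", "CP", "AP", "BC", "APcyto", "BC", "AP", "CP")
  g <- stage_fraction_grid(sc, en, st)
  expect_equal(sum(g$counts), 8)
  expect_equal(unname(g$counts[1, 1, "CP"]), 1)
  expect_equal(unname(g$counts[2, 1, "CP"]), 1)
  expect_equal(unname(g$counts[4, 2, "CP"]), 1)
  expect_equal(unname(g$counts[3, 1, "AP"]), 1)
  expect_equal(unname(g$counts[1, 2, "APcyto"]), 1)
  expect_equal(sum(g$fractions), 100)

  # single-stage cohort: that stage's fractions sum to 100
  g2 <- stage_fraction_grid(stats::runif(10), stats::runif(10),
                            rep("CP", 10))
  expect_equal(sum(g2$fractions[, , "CP"]), 100)

  # boundary values fall in the lower cell; the global max closes the top
  sc3 <- c(0, 2.5, 5, 7.5, 10)  # quarter boundaries of range [0, 10]
  g3 <- stage_fraction_grid(sc3, c(0, 0, 0, 0, 1), rep("CP", 5))
  expect_equal(unname(rowSums(g3$counts[, , "CP"])), c(2, 1, 1, 1))
})

test_that("label permutation preserves composition and the law of total fractions", {
  set.seed(20)
  n <- c(CP = 42L, AP = 9L, APcyto = 8L, BC = 28L)
  st <- rep(names(n), n)
  sc <- stats::runif(sum(n)); en <- stats::runif(sum(n))
  g <- stage_fraction_grid(sc, en, st)
  nl <- randomization_control(g, st, n_perm = 300L, seed = 4L)
  # per stage, the null fractions across cells sum to the cohort proportion
  for (s in names(n)) {
    expect_equal(sum(nl$null_mean[, s]), 100 * n[[s]] / sum(n),
                 tolerance = 1e-9)
  }
  # per-cell AP expectation equals occupancy times the AP proportion
  occ <- as.vector(table(factor(g$cell, 1:8)))
  exp_ap <- 100 * occ * (9 / 87) / 87
  mc_se <- nl$null_sd[, "AP"] / sqrt(nl$n_perm)
  expect_true(all(abs(nl$null_mean[, "AP"] - exp_ap) <= 3 * mc_se + 1e-9))
  # seeded determinism
  nl2 <- randomization_control(g, st, n_perm = 300L, seed = 4L)
  expect_identical(nl$null_mean, nl2$null_mean)
})
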