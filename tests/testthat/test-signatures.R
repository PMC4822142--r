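test_that("signature sizes follow the floor arithmetic", {
  set.seed(1)
  m20 <- matrix(rnorm(20 * 4), 20, 4,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:4)))
  sig <- build_signature(m20, "s1")
  expect_length(sig$up_genes, 1L)
  expect_length(sig$down_genes, 1L)
  expect_length(intersect(sig$up_genes, sig$down_genes), 0L)

  m <- matrix(rnorm(4309 * 3), 4309, 3,
              dimnames = list(paste0("g", 1:4309), paste0("s", 1:3)))
  sig <- build_signature(m, "s1")
  expect_length(sig$up_genes, 215L)   # floor(0.05 * 4309)
  expect_length(sig$down_genes, 215L)
})

test_that("ties are broken deterministically by gene identifier", {
  m <- matrix(1, 20, 3, dimnames = list(sprintf("g%02d", 1:20),
                                        paste0("s", 1:3)))
  s1 <- build_signature(m, "s1", top_frac = 0.1)
  s2 <- build_signature(m, "s1", top_frac = 0.1)
  expect_identical(s1$up_genes, s2$up_genes)
  expect_identical(s1$down_genes, s2$down_genes)
  expect_length(intersect(s1$up_genes, s1$down_genes), 0L)
  expect_error(build_signature(m[1:3, ], "s1", top_frac = 0.9), "too few")
})

test_that("fully separated 5 vs 5 sets give the exact enumeration p-value", {
  sig <- fake_signature(paste0("u", 1:5), paste0("d", 1:5))
  vals <- c(stats::setNames(6:10, paste0("u", 1:5)),
            stats::setNames(1:5, paste0("d", 1:5)))
  s <- similarity_score(vals, sig)
  expect_equal(s$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(s$score, -log10(2 / choose(10, 5)), tolerance = 1e-10)
  expect_equal(s$direction, 1)

  swapped <- fake_signature(paste0("d", 1:5), paste0("u", 1:5))
  s2 <- similarity_score(vals, swapped)
  expect_equal(s2$score, -s$score, tolerance = 1e-12)
})

test_that("identical up and down values give a null score", {
  sig <- fake_signature(paste0("u", 1:3), paste0("d", 1:3))
  vals <- c(stats::setNames(c(1, 2, 3), paste0("u", 1:3)),
            stats::setNames(c(1, 2, 3), paste0("d", 1:3)))
  s <- similarity_score(vals, sig)
  expect_equal(s$p_value, 1)
  expect_equal(s$score, 0)
  expect_equal(s$direction, 0)
})

test_that("scores agree with the exact rank-sum enumeration oracle for small sets", {
  set.seed(42)
  for (rep in 1:12) {
    n <- sample(3:8, 1); m <- sample(3:8, 1)
    x <- round(stats::rnorm(n), 4); y <- round(stats::rnorm(m), 4)
    if (anyDuplicated(c(x, y))) next
    sig <- fake_signature(paste0("u", seq_len(n)), paste0("d", seq_len(m)))
    vals <- c(stats::setNames(x, sig$up_genes),
              stats::setNames(y, sig$down_genes))
    s <- similarity_score(vals, sig)
    expect_equal(s$p_value, enum_ranksum_p(x, y), tolerance = 1e-12,
                 info = paste("rep", rep))
  }
})

test_that("swapping the gene sets negates every score", {
  set.seed(7)
  for (rep in 1:8) {
    n <- sample(c(5L, 30L), 1)  # exercises exact and approximate branches
    x <- stats::rnorm(n); y <- stats::rnorm(n)
    sig <- fake_signature(paste0("u", seq_len(n)), paste0("d", seq_len(n)))
    rev_sig <- fake_signature(sig$down_genes, sig$up_genes)
    vals <- c(stats::setNames(x, sig$up_genes),
              stats::setNames(y, sig$down_genes))
    expect_equal(similarity_score(vals, sig)$score,
                 -similarity_score(vals, rev_sig)$score, tolerance = 1e-12)
  }
})

test_that("raising all up-set values never decreases the score", {
  set.seed(11)
  n <- 12L
  sig <- fake_signature(paste0("u", 1:n), paste0("d", 1:n))
  base_vals <- c(stats::setNames(stats::rnorm(n), sig$up_genes),
                 stats::setNames(stats::rnorm(n), sig$down_genes))
  shifts <- c(0, 0.2, 0.5, 1, 2, 5)
  scores <- vapply(shifts, function(d) {
    v <- base_vals
    v[sig$up_genes] <- v[sig$up_genes] + d
    similarity_score(v, sig)$score
  }, numeric(1))
  expect_true(all(diff(scores) >= -1e-9))
})

test_that("coverage below the threshold is rejected", {
  sig <- fake_signature(paste0("u", 1:10), paste0("d", 1:10))
  vals <- c(stats::setNames(stats::rnorm(5), paste0("u", 1:5)),
            stats::setNames(stats::rnorm(10), paste0("d", 1:10)))
  expect_error(similarity_score(vals, sig), "coverage")
  expect_silent(similarity_score(vals, sig, min_coverage = 0.4))
})

test_that("cohort scoring matches per-sample scoring and flags failures", {
  set.seed(3)
  m <- matrix(stats::rnorm(40 * 6), 40, 6,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:6)))
  sig <- build_signature(m, c("s1", "s2"), top_frac = 0.2)
  tab <- score_cohort(m, sig)
  expect_equal(tab$sample_id, colnames(m))
  centered <- m - rowMeans(m)
  direct <- similarity_score(centered[, "s3"], sig)
  expect_equal(tab$score[tab$sample_id == "s3"], direct$score)

  m2 <- m
  m2[c(sig$up_genes, sig$down_genes), "s4"] <- NA
  tab2 <- score_cohort(m2, sig)
  expect_true(tab2$flagged[tab2$sample_id == "s4"])
  expect_false(any(tab2$flagged[tab2$sample_id != "s4"]))
})
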