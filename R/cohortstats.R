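#' V-shape regression of entropy on the CD34 axis
#'
#' Ordinary least squares of entropy on the CD34+ similarity score and its
#' square. The reported p-value is the two-sided test of the quadratic
#' coefficient; a significant positive quadratic term indicates the V shape
#' (entropy first falls, then rises along the CD34 axis). The vertex
#' \eqn{-\beta_1 / (2 \beta_2)} locates the entropy minimum on the score
#' axis when the parabola opens upwards.
#'
#' @param entropy Per-sample observed entropy (response).
#' @param cd34_scores Per-sample CD34+ similarity scores (predictor).
#' @return Object of class `"vshape_test"`: list with `coefficients`
#'   (intercept, linear, quadratic), `p_value` (quadratic term), `vertex`
#'   (`NA` when the quadratic term is not positive) and the underlying
#'   [stats::lm()] `fit`.
#' @export
vshape_test <- function(entropy, cd34_scores) {
  if (length(entropy) != length(cd34_scores))
    stop("'entropy' and 'cd34_scores' must have equal length", call. = FALSE)
  if (length(entropy) < 5L)
    stop("need at least 5 samples for the V-shape regression", call. = FALSE)
  d <- data.frame(y = entropy, x = cd34_scores)
  fit <- stats::lm(y ~ x + I(x^2), data = d)
  cf <- stats::coef(fit)
  if (anyNA(cf)) stop("degenerate (collinear) design", call. = FALSE)
  p <- suppressWarnings(stats::coef(summary(fit))["I(x^2)", "Pr(>|t|)"])
  vertex <- if (cf[[3L]] > 0) -cf[[2L]] / (2 * cf[[3L]]) else NA_real_
  structure(list(coefficients = stats::setNames(cf, c("intercept", "linear",
                                                      "quadratic")),
                 p_value = p, vertex = vertex, fit = fit),
            class = "vshape_test")
}

#' @export
print.vshape_test <- function(x, ...) {
  cat(sprintf("V-shape regression: quadratic coefficient %.4g (p = %.4g)\n",
              x$coefficients[["quadratic"]], x$p_value))
  cat(if (is.finite(x$vertex))
    sprintf("  vertex (entropy minimum) at score %.4g\n", x$vertex)
    else "  parabola does not open upwards: no vertex\n")
  invisible(x)
}

#' Per-gene differential expression between two groups
#'
#' Two-sided two-sample t-test per gene (pooled variance by default, Welch
#' optional), with Benjamini-Hochberg adjustment. Genes with zero variance
#' in both groups are short-circuited: p = 1 when the group means agree
#' exactly, otherwise the difference is deterministic (p = 0) and the gene
#' is flagged. The tests are computed from row-wise moments, vectorized over
#' genes.
#'
#' @param expr Genes x samples matrix with dimnames.
#' @param group_a,group_b Disjoint character vectors of sample ids (or
#'   column indices), at least two samples each.
#' @param alpha FDR threshold defining significance (default 0.05).
#' @param var_equal Pooled-variance t-test (default) or Welch (`FALSE`).
#' @return Object of class `"cml_de"`: a data.frame (one row per gene:
#'   `gene`, `mean_diff` (A minus B), `t`, `p`, `q`, `direction`,
#'   `flagged`) with `n_significant`, `fraction_significant` (percent of
#'   tested genes) and `alpha` attributes.
#' @export
differential_expression <- function(expr, group_a, group_b, alpha = 0.05,
                                    var_equal = TRUE) {
  expr <- .check_expr_matrix(expr)
  a <- expr[, group_a, drop = FALSE]
  b <- expr[, group_b, drop = FALSE]
  if (length(intersect(colnames(a), colnames(b))) > 0L)
    stop("groups must be disjoint", call. = FALSE)
  na <- ncol(a); nb <- ncol(b)
  if (na < 2L || nb < 2L)
    stop("need at least 2 samples per group", call. = FALSE)

  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1L)
  vb <- rowSums((b - mb)^2) / (nb - 1L)
  d <- ma - mb
  if (var_equal) {
    sp2 <- ((na - 1L) * va + (nb - 1L) * vb) / (na + nb - 2L)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2L, length(d))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
  }
  tstat <- d / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- se == 0
  flagged <- degenerate & d != 0
  p[degenerate & d == 0] <- 1
  p[flagged] <- 0
  tstat[degenerate] <- ifelse(d[degenerate] == 0, 0,
                              sign(d[degenerate]) * Inf)
  q <- stats::p.adjust(p, method = "BH")

  out <- data.frame(gene = rownames(expr), mean_diff = d, t = tstat, p = p,
                    q = q, direction = ifelse(d >= 0, "up", "down"),
                    flagged = flagged, row.names = NULL)
  class(out) <- c("cml_de", "data.frame")
  attr(out, "n_significant") <- sum(q < alpha)
  attr(out, "fraction_significant") <- 100 * mean(q < alpha)
  attr(out, "alpha") <- alpha
  out
}

#' @export
print.cml_de <- function(x, ...) {
  cat(sprintf("Differential expression: %d of %d genes at FDR < %g (%.2f%%)\n",
              attr(x, "n_significant"), nrow(x), attr(x, "alpha"),
              attr(x, "fraction_significant")))
  invisible(x)
}

#' Pairwise differentially-expressed gene fractions
#'
#' For every pair of groups, the percentage of tested genes significant at
#' the FDR threshold (via [differential_expression()]).
#'
#' @param expr Genes x samples matrix.
#' @param groups Named list mapping group label to sample ids.
#' @param alpha FDR threshold.
#' @param var_equal Passed through.
#' @return Symmetric numeric matrix (percent), zero diagonal.
#' @export
de_fraction_matrix <- function(expr, groups, alpha = 0.05,
                               var_equal = TRUE) {
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  labs <- names(groups)
  m <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (i in seq_along(labs)[-length(labs)]) {
    for (j in seq.int(i + 1L, length(labs))) {
      de <- differential_expression(expr, groups[[i]], groups[[j]],
                                    alpha = alpha, var_equal = var_equal)
      m[i, j] <- m[j, i] <- attr(de, "fraction_significant")
    }
  }
  m
}

#' Sub-sampling challenge of the observed/simulated entropy correlation
#'
#' Tests the correlation between observed per-patient entropy and the
#' matched simulated entropy on the full pairing, then re-tests it on many
#' random subsamples (without replacement) and reports how often the
#' correlation stays significant.
#'
#' @param observed,simulated Paired numeric vectors (length >= 5).
#' @param n_iter Number of subsampling iterations (default 1000).
#' @param subsample_frac Fraction of pairs per iteration (default 0.8);
#'   subsamples of fewer than 4 pairs are rejected.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param alpha Per-iteration significance level (default 0.05).
#' @param seed Optional seed for the subsampling.
#' @return List with `p_value` (full pairing), `estimate`,
#'   `pct_significant` (percent of iterations with p < `alpha`) and
#'   `iteration_p` (vector).
#' @export
entropy_correlation_subsample <- function(observed, simulated,
                                          n_iter = 1000L,
                                          subsample_frac = 0.8,
                                          method = c("pearson", "spearman"),
                                          alpha = 0.05, seed = NULL) {
  method <- match.arg(method)
  n <- length(observed)
  if (length(simulated) != n) stop("vectors must be paired", call. = FALSE)
  if (n < 5L) stop("need at least 5 pairs", call. = FALSE)
  m <- max(2L, round(subsample_frac * n))
  if (m < 4L) stop("subsample too small (< 4 pairs)", call. = FALSE)
  full <- suppressWarnings(stats::cor.test(observed, simulated,
                                           method = method))
  if (!is.null(seed)) { old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed) }
  it <- vapply(seq_len(n_iter), function(i) {
    s <- sample.int(n, m)
    suppressWarnings(stats::cor.test(observed[s], simulated[s],
                                     method = method)$p.value)
  }, numeric(1))
  list(p_value = full$p.value, estimate = unname(full$estimate),
       pct_significant = 100 * mean(it < alpha), iteration_p = it)
}

#' Stage fractions over the CD34-entropy plane
#'
#' Divides the observed CD34+ similarity range into quarters and the
#' entropy range into halves (low/high), yielding eight rectangular
#' subsets, and tabulates per subset the number of patients of each disease
#' stage and its fraction of the whole cohort. Interval boundaries belong
#' to the lower cell except the global maximum, which closes the top cell.
#'
#' @param scores,entropies Per-sample values.
#' @param stages Factor or character vector of stage labels per sample.
#' @return Object of class `"stage_grid"`: list with `counts` and
#'   `fractions` (percent), both `4 x 2 x stage` arrays
#'   (`cd34_quarter x entropy_half x stage`), plus `cell` (per-sample cell
#'   index, 1..8) and `n_total`.
#' @export
stage_fraction_grid <- function(scores, entropies, stages) {
  n <- length(scores)
  if (n == 0L) stop("empty cohort", call. = FALSE)
  if (length(entropies) != n || length(stages) != n)
    stop("inputs must have one entry per sample", call. = FALSE)
  stages <- as.factor(stages)
  qs <- .interval_bin(scores, 4L)
  hs <- .interval_bin(entropies, 2L)
  counts <- table(cd34_quarter = factor(qs, 1:4),
                  entropy_half = factor(hs, 1:2,
                                        labels = c("low", "high")),
                  stage = stages)
  counts <- unclass(counts)
  structure(list(counts = counts, fractions = 100 * counts / n,
                 cell = (hs - 1L) * 4L + qs, n_total = n),
            class = "stage_grid")
}

# equal-width bins on the observed range; boundaries to the lower bin,
# global max into the top bin
.interval_bin <- function(x, k) {
  rg <- range(x)
  if (diff(rg) == 0) return(rep(1L, length(x)))
  b <- seq(rg[1L], rg[2L], length.out = k + 1L)
  i <- findInterval(x, b, left.open = TRUE, all.inside = TRUE)
  as.integer(i)
}

#' @export
print.stage_grid <- function(x, ...) {
  cat(sprintf("Stage-fraction grid over %d patients (4 CD34 quarters x 2 entropy halves)\n",
              x$n_total))
  cat("Fractions of total cohort (%):\n")
  for (s in dimnames(x$fractions)[[3L]]) {
    cat(sprintf("  %s:\n", s))
    print(round(x$fractions[, , s], 1))
  }
  invisible(x)
}

#' Stage-label permutation control for the grid fractions
#'
#' Keeps every patient's position in the CD34-entropy plane fixed and
#' permutes the disease-stage labels (preserving the overall stage
#' composition exactly), rebuilding the stage-fraction grid each time. The
#' null distributions describe the fractions expected when stage carries no
#' positional information.
#'
#' @param grid A [stage_fraction_grid()] result (holds the fixed cell
#'   assignments).
#' @param stages The observed stage labels (same order as the grid input).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed for the permutation stream.
#' @return Object of class `"stage_grid_null"`: list with `null_mean` and
#'   `null_sd` (`4 x 2 x stage` arrays of percent fractions),
#'   `exceedance` (two-sided empirical p of the observed fraction per cell
#'   and stage) and `n_perm`.
#' @export
randomization_control <- function(grid, stages, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(grid, "stage_grid"))
  stages <- as.factor(stages)
  if (length(stages) != grid$n_total)
    stop("'stages' must match the cohort the grid was built from",
         call. = FALSE)
  cell <- factor(grid$cell, levels = 1:8)
  lv <- levels(stages)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  sims <- array(0, dim = c(8L, length(lv), n_perm))
  for (p in seq_len(n_perm)) {
    perm <- sample(stages)
    sims[, , p] <- unclass(table(cell, perm))
  }
  sims <- 100 * sims / grid$n_total
  obs <- matrix(0, 8L, length(lv))
  for (s in seq_along(lv))
    obs[, s] <- as.vector(grid$counts[, , s]) / grid$n_total * 100
  null_mean <- apply(sims, c(1, 2), mean)
  null_sd <- apply(sims, c(1, 2), stats::sd)
  exceed <- matrix(0, 8L, length(lv))
  for (s in seq_along(lv)) for (ce in 1:8) {
    lo <- mean(sims[ce, s, ] <= obs[ce, s])
    hi <- mean(sims[ce, s, ] >= obs[ce, s])
    exceed[ce, s] <- min(1, 2 * min(lo, hi))
  }
  dn <- list(cell = paste0("cell", 1:8), stage = lv)
  dimnames(null_mean) <- dimnames(null_sd) <- dimnames(exceed) <- dn
  structure(list(null_mean = null_mean, null_sd = null_sd,
                 observed = `dimnames<-`(obs, dn),
                 exceedance = exceed, n_perm = n_perm),
            class = "stage_grid_null")
}

#' @export
print.stage_grid_null <- function(x, ...) {
  cat(sprintf("Stage-label permutation control (%d permutations)\n", x$n_perm))
  cat("Mean null fraction per cell (%):\n")
  print(round(x$null_mean, 2))
  invisible(x)
}
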