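#' Shannon entropy of an expression distribution
#'
#' Estimates the Shannon entropy of a sample's expression value distribution
#' from a fixed-count equal-width histogram:
#' \deqn{H = -\sum_b p_b \log p_b,}
#' where \eqn{p_b} is the fraction of values in bin \eqn{b} and empty bins
#' contribute zero. By default the 64 bins span the per-sample value range;
#' a fixed global range can be supplied to make samples directly comparable
#' on an absolute scale. The absolute entropy value depends on the binning
#' scheme, so thresholds on it should be treated as estimator-specific.
#'
#' @param values Numeric vector of expression values (length >= `n_bins`
#'   finite values).
#' @param n_bins Number of histogram bins (>= 2), default 64.
#' @param log_base Logarithm base; `exp(1)` (nats, default) or 2 (bits).
#' @param range Optional fixed `c(min, max)` binning range; default is the
#'   per-sample range.
#' @return Entropy value (nonnegative scalar, at most `log(n_bins)`).
#' @examples
#' sample_entropy(rep(1:4, 25), n_bins = 4, log_base = 2)  # = 2 bits
#' @export
sample_entropy <- function(values, n_bins = 64L, log_base = exp(1),
                           range = NULL) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("'n_bins' must be >= 2", call. = FALSE)
  values <- values[is.finite(values)]
  if (length(values) < n_bins)
    stop(sprintf("need at least %d finite values, got %d",
                 n_bins, length(values)), call. = FALSE)
  if (is.null(range)) range <- base::range(values)
  if (diff(range) == 0) {
    warning("degenerate value range: all values identical; entropy is 0",
            call. = FALSE)
    return(0)
  }
  breaks <- seq(range[1L], range[2L], length.out = n_bins + 1L)
  idx <- findInterval(values, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  p <- tabulate(idx, nbins = n_bins)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p, base = log_base))
}

#' Random simulated gene-expression matrix (SGEM)
#'
#' Generates the random per-population expression matrix used to simulate
#' the entropy of a mixed cell population: one row per cell population
#' (healthy and leukemic cells of each compartment; 64 rows under the
#' default 32-compartment model), one column per gene. Entries are i.i.d.
#' uniform on \[0, 1\] by default; a log-normal alternative is provided to
#' probe robustness of the curve's shape to the entry distribution.
#'
#' @param n_genes Number of genes (columns). Ignored when `gene_ids` given.
#' @param gene_ids Optional character vector of gene identifiers; its length
#'   sets the number of columns.
#' @param n_rows Number of populations (rows), default 64.
#' @param seed Random seed (required for reproducibility).
#' @param distribution `"uniform"` (default) or `"lognormal"`
#'   (`meanlog = 0, sdlog = 1`).
#' @return Object of class `"sgem"`: the matrix with the seed and
#'   distribution recorded as attributes.
#' @export
generate_sgem <- function(n_genes = 6384L, gene_ids = NULL, n_rows = 64L,
                          seed, distribution = c("uniform", "lognormal")) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  distribution <- match.arg(distribution)
  if (!is.null(gene_ids)) n_genes <- length(gene_ids)
  if (n_genes < 1L) stop("empty gene list", call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  vals <- switch(distribution,
                 uniform = stats::runif(n_rows * n_genes),
                 lognormal = stats::rlnorm(n_rows * n_genes))
  m <- matrix(vals, nrow = n_rows, ncol = n_genes)
  if (!is.null(gene_ids)) colnames(m) <- gene_ids
  structure(m, class = c("sgem", class(m)), seed = seed,
            distribution = distribution)
}

#' Simulated gene-expression entropy curve
#'
#' Weights the SGEM rows by the cell-population dynamics and computes, per
#' time point, (i) the Shannon entropy of the resulting mixture expression
#' distribution \eqn{m_g(t) = \sum_c w_c(t)\, \mathrm{SGEM}[c, g]}, (ii) the
#' mixing entropy of the population weight vector itself, and (iii) the CD34
#' ratio. When the weights concentrate on a single population the mixture
#' distribution is as broad as the SGEM entries (high entropy); at maximal
#' population mixing the weighted sum concentrates (central-limit
#' narrowing), so the expression entropy attains a minimum where the mixing
#' entropy peaks.
#'
#' @param sgem A [generate_sgem()] matrix with `2 K` rows.
#' @param traj A [simulate_trajectories()] result with `K` compartments.
#' @param n_bins,log_base Histogram settings, see [sample_entropy()].
#' @return Object of class `"entropy_curve"`: list with `times`, `entropy`
#'   (\eqn{s_t}), `mixing_entropy` and `cd34_ratio` (raw scale).
#' @export
simulated_entropy_curve <- function(sgem, traj, n_bins = 64L,
                                    log_base = exp(1)) {
  stopifnot(inherits(traj, "cml_trajectories"))
  W <- .population_weights(traj)
  if (ncol(W) != nrow(sgem))
    stop(sprintf("SGEM has %d rows but the model has %d populations",
                 nrow(sgem), ncol(W)), call. = FALSE)
  M <- W %*% unclass(sgem)
  s_t <- apply(M, 1L, sample_entropy, n_bins = n_bins, log_base = log_base)
  ratio <- tryCatch(cd34_ratio(traj)$ratio,
                    error = function(e) rep(NA_real_, length(traj$times)))
  structure(list(times = traj$times,
                 entropy = s_t,
                 mixing_entropy = .weight_entropy(W, log_base),
                 cd34_ratio = ratio),
            class = "entropy_curve")
}

.weight_entropy <- function(W, log_base = exp(1)) {
  apply(W, 1L, function(w) {
    w <- w[w > 0]
    -sum(w * log(w, base = log_base))
  })
}

#' Mixing entropy of the cell-population weights
#'
#' Shannon entropy of the population weight vector over time,
#' \eqn{-\sum_c w_c \log w_c}: zero when a single population dominates and
#' maximal (log of the number of populations) for uniform mixing.
#'
#' @param traj A [simulate_trajectories()] result.
#' @param log_base Logarithm base.
#' @return Numeric vector aligned with `traj$times`.
#' @export
mixing_entropy_curve <- function(traj, log_base = exp(1)) {
  stopifnot(inherits(traj, "cml_trajectories"))
  .weight_entropy(.population_weights(traj), log_base)
}

#' @export
print.entropy_curve <- function(x, ...) {
  i <- which.min(x$entropy)
  cat(sprintf("Simulated entropy curve: %d points (0..%g d)\n",
              length(x$times), max(x$times)))
  cat(sprintf("  raw entropy minimum %.4f at t = %g d; mixing entropy max at t = %g d\n",
              x$entropy[i], x$times[i],
              x$times[which.max(x$mixing_entropy)]))
  invisible(x)
}

#' @export
plot.entropy_curve <- function(x, ...) {
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  plot(x$times, x$entropy, type = "l", lwd = 2, xlab = "time (days)",
       ylab = "simulated expression entropy",
       main = "Simulated entropy and population mixing", ...)
  graphics::par(new = TRUE)
  plot(x$times, x$mixing_entropy, type = "l", lwd = 2, col = "steelblue",
       axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4, col.axis = "steelblue")
  graphics::mtext("mixing entropy", side = 4, line = 2.5, col = "steelblue")
  invisible(x)
}

#' Locate the singular minimum of an entropy curve
#'
#' Finds the argmin of the simulated entropy after optional moving-average
#' smoothing. A minimum attained on the boundary of the time window is
#' flagged as non-singular; a flat curve has no singular minimum and raises
#' an error.
#'
#' @param curve An [simulated_entropy_curve()] result (or any list with
#'   `times` and `entropy`).
#' @param smoothing_window Odd moving-average window length (1 = none).
#' @return List with `t_min` (days), `value` (smoothed entropy at the
#'   minimum) and `singular` (`TRUE` for a strict interior minimum).
#' @export
find_entropy_minimum <- function(curve, smoothing_window = 11L) {
  s <- curve$entropy
  t <- curve$times
  if (length(s) < 3L) stop("need at least 3 time points", call. = FALSE)
  if (diff(range(s)) == 0) stop("flat curve: no singular minimum", call. = FALSE)
  smoothing_window <- as.integer(smoothing_window)
  if (smoothing_window > 1L) {
    if (smoothing_window %% 2L == 0L)
      stop("'smoothing_window' must be odd", call. = FALSE)
    sm <- stats::filter(s, rep(1 / smoothing_window, smoothing_window),
                        sides = 2)
    keep <- !is.na(sm)
    s <- as.numeric(sm[keep]); t <- t[keep]
  }
  i <- which.min(s)
  singular <- i > 1L && i < length(s)
  list(t_min = t[i], value = s[i], singular = singular)
}

#' Average entropy-minimum time over SGEM seeds
#'
#' The argmin of a single-seed entropy curve is noisy; this helper averages
#' the smoothed argmin over several independently seeded SGEMs (default 10)
#' for a stable boundary estimate.
#'
#' @param traj A [simulate_trajectories()] result.
#' @param n_seeds Number of SGEM replicates (>= 1).
#' @param seed Base seed; replicate `i` uses `seed + i - 1`.
#' @param n_genes SGEM gene count.
#' @param smoothing_window Passed to [find_entropy_minimum()].
#' @param n_bins,log_base Passed to [simulated_entropy_curve()].
#' @param distribution SGEM entry distribution.
#' @return List with `t_min` (mean over seeds), `sd`, `per_seed` (vector)
#'   and `curve` (an entropy curve whose `entropy` is the pointwise mean
#'   over the seeds; less noisy than any single-seed curve).
#' @export
entropy_minimum_time <- function(traj, n_seeds = 10L, seed = 1L,
                                 n_genes = 6384L, smoothing_window = 11L,
                                 n_bins = 64L, log_base = exp(1),
                                 distribution = "uniform") {
  stopifnot(n_seeds >= 1L)
  K2 <- 2L * dim(traj$counts)[3L]
  per_seed <- numeric(n_seeds)
  acc <- NULL
  for (i in seq_len(n_seeds)) {
    sg <- generate_sgem(n_genes = n_genes, n_rows = K2, seed = seed + i - 1L,
                        distribution = distribution)
    cv <- simulated_entropy_curve(sg, traj, n_bins = n_bins,
                                  log_base = log_base)
    if (i == 1L) acc <- cv else acc$entropy <- acc$entropy + cv$entropy
    per_seed[i] <- find_entropy_minimum(cv, smoothing_window)$t_min
  }
  acc$entropy <- acc$entropy / n_seeds
  list(t_min = mean(per_seed), sd = stats::sd(per_seed),
       per_seed = per_seed, curve = acc)
}

# save/restore global RNG so seeded helpers do not disturb the caller's stream
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
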