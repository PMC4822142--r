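#' Simulate healthy and leukemic population trajectories
#'
#' Integrates the deterministic mean-field compartment model
#' \deqn{dN_k/dt = 2 \epsilon r_{k-1} N_{k-1} + (1 - 2\epsilon) r_k N_k,
#'   \quad k \ge 2,}
#' with \eqn{r_k = r_1 \rho^{k-1}}, for two independent lineages: a healthy
#' lineage initialised at its steady state (compartment 1 held constant) and
#' a leukemic lineage seeded with `cml_init_cells` in compartment 1 (also
#' held constant there) and empty elsewhere. Competition between the
#' lineages is deliberately not modelled. The system is linear but stiff
#' across 32 compartments (rates span four orders of magnitude), so it is
#' integrated with [deSolve::lsoda()] and reported on the daily output grid.
#'
#' @param params A [model_params()] object.
#' @param rtol,atol Solver tolerances passed to [deSolve::lsoda()].
#' @return An object of class `"cml_trajectories"`: a list with `times`
#'   (days) and `counts`, a `time x lineage x compartment` array with
#'   lineages `"healthy"` and `"cml"`.
#' @examples
#' traj <- simulate_trajectories(model_params(t_max_days = 200))
#' traj
#' @seealso [cd34_ratio()], [population_fractions()]
#' @export
simulate_trajectories <- function(params, rtol = 1e-10, atol = 1e-8) {
  stopifnot(inherits(params, "cml_model_params"))
  K <- params$n_compartments
  r <- .replication_rates(params)
  eh <- params$epsilon_healthy
  ec <- params$epsilon_cml
  times <- seq(0, params$t_max_days, by = params$dt_days)

  healthy0 <- .healthy_steady_state(params)
  cascade <- function(eps, seed_comp1, y0) {
    force(eps); force(seed_comp1)
    deriv <- function(t, y, p) {
      N <- c(seed_comp1, y)
      list(2 * eps * r[1:(K - 1)] * N[1:(K - 1)] +
             (1 - 2 * eps) * r[2:K] * N[2:K])
    }
    sol <- deSolve::lsoda(y = y0, times = times, func = deriv, parms = NULL,
                          rtol = rtol, atol = atol)
    cbind(rep(seed_comp1, length(times)), sol[, -1, drop = FALSE],
          deparse.level = 0)
  }

  healthy <- cascade(eh, healthy0[1], healthy0[-1])
  if (params$cml_init_cells > 0) {
    cml <- cascade(ec, params$cml_init_cells, numeric(K - 1))
  } else {
    cml <- matrix(0, nrow = length(times), ncol = K)
  }

  counts <- array(0, dim = c(length(times), 2L, K),
                  dimnames = list(NULL, c("healthy", "cml"), NULL))
  counts[, "healthy", ] <- healthy
  counts[, "cml", ] <- cml
  bad <- which(!is.finite(counts), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    b <- bad[1L, ]
    stop(sprintf(paste0("non-finite cell count at t = %g d, lineage '%s', ",
                        "compartment %d (parameter blow-up?)"),
                 times[b[1L]], dimnames(counts)[[2L]][b[2L]], b[3L]),
         call. = FALSE)
  }
  counts[counts < 0 & counts > -atol] <- 0  # clip solver round-off

  structure(list(times = times, counts = counts, params = params),
            class = "cml_trajectories")
}

#' @export
print.cml_trajectories <- function(x, ...) {
  n <- length(x$times)
  tot <- rowSums(x$counts[c(1L, n), , , drop = FALSE], dims = 2L)
  cat(sprintf("CML compartment-model trajectories: %d time points (0..%g d), %d compartments\n",
              n, max(x$times), dim(x$counts)[3L]))
  cat(sprintf("  t = %-6g  healthy %.4g cells, leukemic %.4g cells\n",
              x$times[1L], tot[1L, "healthy"], tot[1L, "cml"]))
  cat(sprintf("  t = %-6g  healthy %.4g cells, leukemic %.4g cells (%.1f%% leukemic)\n",
              x$times[n], tot[2L, "healthy"], tot[2L, "cml"],
              100 * tot[2L, "cml"] / sum(tot[2L, ])))
  invisible(x)
}

#' @export
plot.cml_trajectories <- function(x, ...) {
  tot <- rowSums(x$counts, dims = 2L)
  graphics::matplot(x$times, tot, type = "l", lty = 1, lwd = 2,
                    col = c("grey40", "firebrick"), log = "y",
                    xlab = "time (days)", ylab = "cells",
                    main = "Healthy and leukemic population size", ...)
  graphics::legend("bottomright", c("healthy", "CML"), lwd = 2,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' CD34 ratio over time
#'
#' Ratio of CD34+ to CD34- cell counts per time point. Healthy cells are
#' CD34+ in compartments `1..cutoff`; leukemic cells are CD34+ in
#' compartments `1..cml_cutoff`. The default `cml_cutoff` comes from the
#' model parameters (all leukemic cells CD34+, reflecting the
#' differentiation block); pass `cml_cutoff = cutoff` for a strictly
#' compartment-indexed assignment that ignores lineage.
#'
#' @param traj A [simulate_trajectories()] result.
#' @param cutoff Last CD34+ compartment for healthy cells
#'   (default from the model parameters).
#' @param cml_cutoff Last CD34+ compartment for leukemic cells.
#' @return Object of class `"cd34_ratio_series"`: list with `times`, `ratio`
#'   and the cutoffs used.
#' @examples
#' traj <- simulate_trajectories(model_params(t_max_days = 100))
#' head(cd34_ratio(traj)$ratio)
#' @export
cd34_ratio <- function(traj, cutoff = traj$params$cd34_cutoff,
                       cml_cutoff = traj$params$cml_cd34_cutoff) {
  stopifnot(inherits(traj, "cml_trajectories"))
  K <- dim(traj$counts)[3L]
  cutoff <- as.integer(cutoff)
  if (cutoff < 1L || cutoff >= K)
    stop("'cutoff' must satisfy 1 <= cutoff < n_compartments", call. = FALSE)
  cml_cutoff <- as.integer(cml_cutoff)
  if (cml_cutoff < 1L || cml_cutoff > K)
    stop("'cml_cutoff' must satisfy 1 <= cml_cutoff <= n_compartments",
         call. = FALSE)

  h <- traj$counts[, "healthy", , drop = TRUE]
  c_ <- traj$counts[, "cml", , drop = TRUE]
  if (is.null(dim(h))) { h <- matrix(h, nrow = 1L); c_ <- matrix(c_, nrow = 1L) }
  pos <- rowSums(h[, seq_len(cutoff), drop = FALSE]) +
    rowSums(c_[, seq_len(cml_cutoff), drop = FALSE])
  neg <- rowSums(h[, seq.int(cutoff + 1L, K), drop = FALSE])
  if (cml_cutoff < K)
    neg <- neg + rowSums(c_[, seq.int(cml_cutoff + 1L, K), drop = FALSE])
  if (any(neg == 0))
    stop("empty CD34- pool: all cells lie in CD34+ compartments",
         call. = FALSE)
  if (any(pos == 0))
    stop("empty CD34+ pool", call. = FALSE)
  structure(list(times = traj$times, ratio = pos / neg,
                 cutoff = cutoff, cml_cutoff = cml_cutoff),
            class = "cd34_ratio_series")
}

#' @export
print.cd34_ratio_series <- function(x, ...) {
  cat(sprintf("CD34 ratio series (cutoff %d, leukemic cutoff %d): %d points, range %.4g .. %.4g\n",
              x$cutoff, x$cml_cutoff, length(x$times),
              min(x$ratio), max(x$ratio)))
  invisible(x)
}

#' Population weight vector at a time point
#'
#' Returns the relative abundance of each of the `2 K` cell populations
#' (healthy and leukemic, compartments `1..K`) at a grid time `t`. These
#' weights drive the simulated gene-expression mixture.
#'
#' @param traj A [simulate_trajectories()] result.
#' @param t Time in days; must lie on the simulation grid.
#' @return Numeric vector of length `2 K`, nonnegative, summing to 1, named
#'   `healthy.1 .. healthy.K, cml.1 .. cml.K`.
#' @export
population_fractions <- function(traj, t) {
  stopifnot(inherits(traj, "cml_trajectories"))
  i <- match(t, traj$times)
  if (is.na(i)) {
    near <- traj$times[order(abs(traj$times - t))[1:2]]
    stop(sprintf("t = %g is not on the simulation grid; nearest grid times: %g, %g",
                 t, near[1L], near[2L]), call. = FALSE)
  }
  K <- dim(traj$counts)[3L]
  w <- c(traj$counts[i, "healthy", ], traj$counts[i, "cml", ])
  names(w) <- c(paste0("healthy.", seq_len(K)), paste0("cml.", seq_len(K)))
  w / sum(w)
}

# weight matrix (time x 2K) for all grid times; internal fast path
.population_weights <- function(traj) {
  K <- dim(traj$counts)[3L]
  W <- cbind(traj$counts[, "healthy", , drop = TRUE],
             traj$counts[, "cml", , drop = TRUE])
  colnames(W) <- c(paste0("healthy.", seq_len(K)),
                   paste0("cml.", seq_len(K)))
  W / rowSums(W)
}

#' T1/T2 boundary robustness across CD34 cutoffs
#'
#' Recomputes the simulated-entropy minimum time for a range of CD34
#' counting cutoffs, using identical SGEM seeds throughout so the table is
#' reproducible. The population dynamics (and hence the entropy curves) do
#' not depend on how CD34 status is counted, so the spread across cutoffs
#' isolates the effect of the cutoff on the reported boundary.
#'
#' @param params A [model_params()] object.
#' @param cutoffs Integer vector of CD34 cutoffs to scan.
#' @param n_seeds Number of SGEM seeds averaged per cutoff.
#' @param seed Base random seed.
#' @param n_genes Number of SGEM genes.
#' @param smoothing_window Odd moving-average window for the argmin search.
#' @return A data.frame with one row per cutoff: `cutoff`,
#'   `t_min_days` (mean over seeds), `t_min_sd`, and `cd34_ratio_at_min`
#'   (normalized). The spread of `t_min_days` is attached as attribute
#'   `"spread"` (min, max, range).
#' @export
boundary_robustness_sweep <- function(params, cutoffs = 20:26,
                                      n_seeds = 10L, seed = 1L,
                                      n_genes = 6384L,
                                      smoothing_window = 11L) {
  stopifnot(inherits(params, "cml_model_params"))
  traj <- simulate_trajectories(params)
  curves <- lapply(seq_len(n_seeds), function(i) {
    sg <- generate_sgem(n_genes = n_genes, n_rows = 2L * params$n_compartments,
                        seed = seed + i - 1L)
    simulated_entropy_curve(sg, traj)
  })
  res <- lapply(cutoffs, function(co) {
    ratio <- cd34_ratio(traj, cutoff = co)$ratio
    rn <- normalize_unit_interval(ratio)$values
    mins <- vapply(curves, function(cv)
      find_entropy_minimum(cv, smoothing_window = smoothing_window)$t_min,
      numeric(1))
    data.frame(cutoff = co, t_min_days = mean(mins), t_min_sd = stats::sd(mins),
               cd34_ratio_at_min = rn[which.min(abs(traj$times - mean(mins)))])
  })
  out <- do.call(rbind, res)
  attr(out, "spread") <- c(min = min(out$t_min_days), max = max(out$t_min_days),
                           range = diff(range(out$t_min_days)))
  out
}
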