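# shared heavy fixtures, computed lazily and cached across test files
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

default_traj <- function() {
  cached("traj", simulate_trajectories(model_params()))
}

# a hand-built trajectory object for contract tests: counts are set freely
fake_traj <- function(times, healthy, cml, params = NULL) {
  K <- ncol(healthy)
  if (is.null(params))
    params <- model_params(n_compartments = K, cd34_cutoff = max(1L, K - 1L),
                           t_max_days = max(times), dt_days = diff(times[1:2]))
  counts <- array(0, dim = c(length(times), 2L, K),
                  dimnames = list(NULL, c("healthy", "cml"), NULL))
  counts[, "healthy", ] <- healthy
  counts[, "cml", ] <- cml
  structure(list(times = times, counts = counts, params = params),
            class = "cml_trajectories")
}

# signature object without going through build_signature
fake_signature <- function(up, down) {
  structure(list(up_genes = up, down_genes = down,
                 reference_label = "fake", centering = "none",
                 n_reference_genes = length(up) + length(down)),
            class = "cd34_signature")
}

# exact two-sided rank-sum p-value by full enumeration (independent oracle)
enum_ranksum_p <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2  # Mann-Whitney U of x
  combs <- utils::combn(n + m, n)
  r_all <- rank(c(x, y))
  w_all <- apply(combs, 2L, function(ix) sum(r_all[ix]) - n * (n + 1) / 2)
  mu <- n * m / 2
  p <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
  min(1, p)
}

# Benjamini-Hochberg step-up, written independently of stats::p.adjust
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in seq(n, 1)) {
    val <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# small synthetic cohort for fast end-to-end tests
small_cohort <- function(seed = 1L, n_genes = 1500L, stages = NULL,
                         noise_sd = 0.5) {
  p <- model_params()
  traj <- default_traj()
  n_per <- if (is.null(stages)) c(CP = 42L, AP = 9L, APcyto = 8L, BC = 28L)
  else stages
  cfg <- synthetic_cohort_config(n_per_stage = n_per, n_genes = n_genes,
                                 noise_sd = noise_sd, rng_seed = seed)
  base <- generate_compartment_profiles(n_genes,
                                        seq_len(cfg$n_signature_genes),
                                        cfg$signature_effect_size, p,
                                        seed = seed + 1000L)
  c(generate_cohort(cfg, traj, base), list(cfg = cfg, params = p))
}
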