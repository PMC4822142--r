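test_that("parameter validation rejects degenerate settings", {
  expect_error(model_params(n_compartments = 1), "n_compartments")
  expect_error(model_params(epsilon_healthy = 1), "epsilon_healthy")
  expect_error(model_params(epsilon_cml = 0), "epsilon_cml")
  expect_error(model_params(cd34_cutoff = 32), "cd34_cutoff")
  expect_error(model_params(t_max_days = -1), "t_max_days")
  expect_error(model_params(dt_days = 0), "dt_days")
})

test_that("without a leukemic seed the system sits at the healthy steady state", {
  p <- model_params(cml_init_cells = 0, t_max_days = 2200)
  traj <- simulate_trajectories(p)
  expect_true(all(traj$counts[, "cml", ] == 0))
  h0 <- traj$counts[1L, "healthy", ]
  drift <- apply(traj$counts[, "healthy", ], 2L,
                 function(x) max(abs(x - x[1L]) / x[1L]))
  expect_lt(max(drift), 1e-6)
  # flux balance at the fixed point: influx equals net outflux per compartment
  r <- p$replication_rate_base *
    p$replication_rate_ratio ^ (0:(p$n_compartments - 1L))
  e <- p$epsilon_healthy
  net <- 2 * e * r[-length(r)] * h0[-length(h0)] +
    (1 - 2 * e) * r[-1L] * h0[-1L]
  expect_lt(max(abs(net) / (r[-1L] * h0[-1L])), 1e-12)
})

test_that("leukemic lineage starts as a single seeded cell", {
  traj <- default_traj()
  expect_equal(unname(traj$counts[1L, "cml", 1L]), 1)
  expect_true(all(traj$counts[1L, "cml", -1L] == 0))
  # with defaults the clone only grows
  tot_cml <- rowSums(traj$counts[, "cml", ])
  expect_true(all(diff(tot_cml) > -1e-9))
})

test_that("downstream compartment matches the closed-form linear solution", {
  # K = 2: compartment 2 fed by a constant compartment-1 clone obeys
  # dN/dt = b + a N with a = (1 - 2e) r2, b = 2 e r1 c1, N(0) = 0,
  # whose solution is (b/a) (exp(a t) - 1)
  for (eps in c(0.25, 0.72)) {
    p <- model_params(n_compartments = 2, cd34_cutoff = 1,
                      epsilon_cml = eps, t_max_days = 400)
    traj <- simulate_trajectories(p)
    r1 <- p$replication_rate_base
    r2 <- r1 * p$replication_rate_ratio
    a <- (1 - 2 * eps) * r2
    b <- 2 * eps * r1 * 1
    t <- traj$times[-1L]
    analytic <- (b / a) * (exp(a * t) - 1)
    numeric <- traj$counts[-1L, "cml", 2L]
    expect_lt(max(abs(numeric - analytic) / analytic), 1e-6)
  }
})

test_that("halving the output step leaves counts essentially unchanged", {
  p1 <- model_params(t_max_days = 600, dt_days = 1)
  p2 <- model_params(t_max_days = 600, dt_days = 0.5)
  t1 <- simulate_trajectories(p1)
  t2 <- simulate_trajectories(p2)
  common <- match(t1$times, t2$times)
  c1 <- t1$counts[, "cml", ]
  c2 <- t2$counts[common, "cml", ]
  nz <- c1 > 1e-3  # compare meaningful cell counts, not sub-atol noise
  expect_lt(max(abs(c1[nz] - c2[nz]) / c1[nz]), 1e-3)
})

test_that("cd34_ratio follows its counting contract", {
  # equal mass below and above the cutoff, lineage-blind counting
  times <- 0:2
  h <- matrix(c(3, 1), nrow = 3, ncol = 2, byrow = TRUE)
  c_ <- matrix(c(1, 3), nrow = 3, ncol = 2, byrow = TRUE)
  traj <- fake_traj(times, h, c_)
  rs <- cd34_ratio(traj, cutoff = 1, cml_cutoff = 1)
  expect_equal(rs$ratio, rep(1, 3))

  # all cells CD34+ -> explicit empty-pool error
  traj2 <- fake_traj(times, matrix(c(1, 0), 3, 2, byrow = TRUE),
                     matrix(0, 3, 2))
  expect_error(cd34_ratio(traj2, cutoff = 1, cml_cutoff = 1), "CD34- pool")
  expect_error(cd34_ratio(default_traj(), cutoff = 40), "cutoff")
})

test_that("default CD34 ratio rises monotonically across the window", {
  traj <- default_traj()
  for (co in c(20L, 23L, 26L)) {
    rs <- cd34_ratio(traj, cutoff = co)
    expect_true(all(diff(rs$ratio) > 0), info = paste("cutoff", co))
  }
})

test_that("population fractions are a probability vector with growing leukemic mass", {
  traj <- default_traj()
  w0 <- population_fractions(traj, 0)
  w2200 <- population_fractions(traj, 2200)
  expect_equal(sum(w0), 1, tolerance = 1e-12)
  expect_equal(sum(w2200), 1, tolerance = 1e-12)
  cml_ix <- grepl("^cml\\.", names(w0))
  expect_gt(sum(w2200[cml_ix]), sum(w0[cml_ix]))
  expect_error(population_fractions(traj, 17.3), "nearest grid times")

  p0 <- model_params(cml_init_cells = 0, t_max_days = 50)
  w <- population_fractions(simulate_trajectories(p0), 25)
  expect_true(all(w[grepl("^cml\\.", names(w))] == 0))
})

test_that("boundary sweep is deterministic and consistent with the direct estimate", {
  p <- model_params()
  tab <- boundary_robustness_sweep(p, cutoffs = c(22L, 23L), n_seeds = 2L,
                                   seed = 5L, n_genes = 800L)
  tab2 <- boundary_robustness_sweep(p, cutoffs = c(22L, 23L), n_seeds = 2L,
                                    seed = 5L, n_genes = 800L)
  expect_identical(tab$t_min_days, tab2$t_min_days)
  direct <- entropy_minimum_time(default_traj(), n_seeds = 2L, seed = 5L,
                                 n_genes = 800L)
  expect_equal(tab$t_min_days[tab$cutoff == 23L], direct$t_min)
  expect_true(all(is.finite(attr(tab, "spread"))))
})
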