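test_that("EM chains are monotone and the fit recovers the simulation", {
  sim <- fixture_sim()
  fit <- fixture_fit()
  expect_s3_class(fit, "traj_fit")
  # monotone ELBO trace up to tolerance
  tr <- fit$elbo_trace
  expect_true(all(diff(tr) > -1e-6 * abs(tr[-1])))
  # recovery on this well-posed simulation
  m <- evaluation_metrics(sim$truth, fit)
  expect_lt(m$time_rmse, 0.1)
  expect_gt(m$time_cor, 0.95)
  expect_gt(m$lineage_accuracy, 0.9)
  expect_lt(m$beta_error, 0.5)
  expect_lt(m$gamma_error, 0.5)
})

test_that("warm start from the truth is not degraded by EM", {
  sim <- fixture_sim()
  st <- bifurcation_structure()
  prior <- sampling_prior(st, 50)
  ll <- log_likelihood_grid(sim$data, st, sim$truth$kinetics, prior)
  elbo_truth <- sum(e_step(ll, prior)$log_marginal)
  cfg <- traj_config(n_restarts = 1, n_iterations = 30, grid_M = 50,
                     seed = 9)
  wf <- fit_trajectory(sim$data, st, cfg,
                       init_kinetics = sim$truth$kinetics,
                       init_posterior = e_step(ll, prior)$posterior)
  expect_gte(wf$elbo, elbo_truth - 1e-6 * abs(elbo_truth))
  # and the random-restart fit lands within a small gap of the warm one
  expect_gt(fixture_fit()$elbo, wf$elbo - 0.01 * abs(wf$elbo))
})

test_that("fits are deterministic under seed and config", {
  sim <- small_sim(n_cells = 150, n_genes = 20, seed = 3)
  cfg <- traj_config(n_restarts = 2, n_iterations = 10, grid_M = 20,
                     seed = 77)
  f1 <- fit_trajectory(sim$data, bifurcation_structure(), cfg)
  f2 <- fit_trajectory(sim$data, bifurcation_structure(), cfg)
  expect_identical(f1$elbo, f2$elbo)
  expect_identical(f1$kinetics$alpha, f2$kinetics$alpha)
  expect_identical(f1$restart_table$seed, f2$restart_table$seed)
  expect_identical(f1$best_chain, f2$best_chain)
})

test_that("label warm starts build block-uniform responsibilities", {
  st <- bifurcation_structure()
  prior <- sampling_prior(st, 10)
  labels <- c("early", "lateA", "lateB", "early")
  map <- list(early = list(lineages = 1:2, segments = 1L),
              lateA = list(lineages = 1L, segments = 2L),
              lateB = list(lineages = 2L, segments = 2L))
  q <- warm_start_from_labels(labels, st, prior, map)
  expect_equal(rowSums(q), rep(1, 4))
  # early cells: uniform over segment-1 grid points of both lineages
  seg1_cols <- c(1:5, 11:15)
  expect_true(all(q[1, seg1_cols] == 1 / 10))
  expect_true(all(q[1, -seg1_cols] == 0))
  # lateA: lineage 1, second segment only
  expect_true(all(q[2, 6:10] == 1 / 5))
  expect_true(all(q[2, -(6:10)] == 0))
  expect_error(warm_start_from_labels(c("early", "zzz"), st, prior, map),
               "zzz")
})

test_that("the desynchronized refinement improves the ELBO and honors the penalty", {
  sim <- cached("sim_desync",
                small_sim(n_cells = 400, n_genes = 40, seed = 31,
                          desync = TRUE))
  cfg <- traj_config(n_restarts = 2, n_iterations = 25, grid_M = 40,
                     seed = 32)
  sync_fit <- cached("fit_sync_for_desync",
                     fit_trajectory(sim$data, bifurcation_structure(), cfg))
  de <- fit_desynchronized(sync_fit, cfg)
  expect_equal(de$mode, "desync")
  expect_gte(de$elbo, sync_fit$elbo - 1e-6 * abs(sync_fit$elbo))
  expect_true(is.matrix(de$kinetics$tau))
  # gene-wise switch times recovered within half the jitter width
  dtau <- min(diff(colMeans(sim$truth$kinetics$tau)))
  err <- mean(abs(de$kinetics$tau[, 2] - sim$truth$kinetics$tau[, 2]))
  expect_lt(err, dtau / 2)
  # a huge penalty collapses gene-wise times onto the consensus
  cfg_pen <- cfg
  cfg_pen$desync_penalty <- 1e9
  de_pen <- fit_desynchronized(sync_fit, cfg_pen)
  dev <- sweep(de_pen$kinetics$tau, 2L, colMeans(de_pen$kinetics$tau))
  expect_lt(max(abs(dev)), 1e-3)
})

test_that("fast dynamics degenerate to the Poisson mixture model", {
  # beta, gamma scaled far up: cells sit at segment steady states, so the
  # trajectory model's best likelihood approaches a mixture of the state
  # steady states with interval-length weights
  st <- trajectory_structure("[[0,0,1]]")
  set.seed(12)
  p <- 12
  kin <- gene_kinetics(alpha = matrix(rlnorm(p * 2, 2, 1), p, 2) * 100,
                       beta = rlnorm(p, 2, .5) * 100,
                       gamma = rlnorm(p, .5, .5) * 100,
                       tau = c(0, 0.4, 1))
  lat <- list(lineage = rep(1L, 500), time = runif(500))
  set.seed(13)
  sim <- simulate_counts(kin, st, lat, depth_var = 0)
  cfg <- traj_config(n_restarts = 2, n_iterations = 25, grid_M = 40,
                     seed = 14)
  fit <- fit_trajectory(sim$data, st, cfg)
  mix <- fit_poisson_mixture(sim$data, 2, n_restarts = 4, seed = 15)
  # per-cell gap between the two models' log-likelihoods is small
  expect_lt(abs(fit$elbo - mix$loglik) / 500, 1.0)
  # and the mixture weights approach the interval lengths
  expect_lt(max(abs(sort(mix$weights) - c(0.4, 0.6))), 0.12)
})

test_that("degenerate inputs are rejected with clear errors", {
  sim <- small_sim(n_cells = 50, n_genes = 5, seed = 1)
  empty <- count_dataset(sim$data$unspliced[, 0, drop = FALSE],
                         sim$data$spliced[, 0, drop = FALSE],
                         sim$data$read_depth)
  expect_error(fit_trajectory(empty, bifurcation_structure(),
                              quick_config(seed = 1)), "no genes")
})
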