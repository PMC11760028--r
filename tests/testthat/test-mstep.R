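mstep_fixture <- function(n = 60, p = 8, M = 15, seed = 4) {
  st <- bifurcation_structure()
  sim <- simulate_trajectory(st, n_cells = n, n_genes = p, seed = seed)
  prior <- sampling_prior(st, M)
  ll <- log_likelihood_grid(sim$data, st, sim$truth$kinetics, prior)
  q <- e_step(ll, prior)$posterior
  list(st = st, sim = sim, prior = prior,
       suff = ptraj:::suff_stats(q, sim$data), q = q)
}

test_that("the M-step objective gradient matches finite differences", {
  fx <- mstep_fixture()
  st <- fx$st; prior <- fx$prior; suff <- fx$suff
  S <- st$n_states
  kin <- random_kinetics(st, 8, seed = 11)
  # log-rate coordinates of one gene, all others held fixed
  j <- 3L
  f_of <- function(v) {
    k2 <- kin
    k2$alpha[j, ] <- exp(v[1:S])
    k2$beta[j] <- exp(v[S + 1]); k2$gamma[j] <- exp(v[S + 2])
    ptraj:::traj_F(k2, st, prior, suff)$F[j]
  }
  v0 <- c(log(kin$alpha[j, ]), log(kin$beta[j]), log(kin$gamma[j]))
  tf <- ptraj:::traj_F(kin, st, prior, suff,
                       want_grad = ptraj:::rate_cols(st))
  analytic <- tf$grad[j, ] * c(kin$alpha[j, ], kin$beta[j], kin$gamma[j])
  fd <- fd_grad(f_of, v0)
  expect_lt(max(abs(analytic - fd) / pmax(1, abs(fd))), 1e-5)
})

test_that("a concentrated steady-state posterior recovers the weighted Poisson MLE", {
  # all posterior mass on one steady-state grid point of a single-state
  # trajectory: the M-step must return the closed-form weighted MLE
  st <- trajectory_structure("[[0,0]]")
  set.seed(8)
  n <- 200
  U <- matrix(rpois(n * 3, 4), n, 3)
  S <- matrix(rpois(n * 3, 9), n, 3)
  data <- count_dataset(U, S, read_depth = runif(n, 0.5, 1.5))
  prior <- sampling_prior(st, M = 5)
  q <- matrix(0, n, 5)
  q[, 3] <- 1
  suff <- ptraj:::suff_stats(q, data)
  kin0 <- ptraj:::init_kinetics(data, st, c(0, 1))
  ms <- ptraj:::m_step_rates(kin0, st, prior, suff, maxit = 200L)
  r <- data$read_depth
  lam_u_hat <- ms$kinetics$alpha[, 1] / ms$kinetics$beta
  lam_s_hat <- ms$kinetics$alpha[, 1] / ms$kinetics$gamma
  expect_equal(lam_u_hat, colSums(U) / sum(r), tolerance = 1e-4)
  expect_equal(lam_s_hat, colSums(S) / sum(r), tolerance = 1e-4)
})

test_that("re-running the M-step from its optimum is a fixed point", {
  fx <- mstep_fixture()
  kin <- random_kinetics(fx$st, 8, seed = 12)
  ms1 <- ptraj:::m_step_rates(kin, fx$st, fx$prior, fx$suff, maxit = 2000L)
  ms2 <- ptraj:::m_step_rates(ms1$kinetics, fx$st, fx$prior, fx$suff,
                              maxit = 2000L)
  expect_lt(abs(sum(ms2$F) - sum(ms1$F)), 1e-6)
  # and the M-step never decreases any gene's objective
  F0 <- ptraj:::traj_F(kin, fx$st, fx$prior, fx$suff)$F
  expect_true(all(ms1$F >= F0 - 1e-8 * abs(F0)))
})

test_that("the shared switch-time update ascends and is a no-op for K = 1", {
  fx <- mstep_fixture()
  kin <- fx$sim$truth$kinetics
  kin$tau <- c(0, 0.35, 1)  # perturbed away from the truth (0.5)
  F0 <- sum(ptraj:::traj_F(kin, fx$st, fx$prior, fx$suff)$F)
  kin2 <- update_global_tau(kin, fx$st, fx$prior, fx$suff)
  F1 <- sum(attr(kin2, "F"))
  expect_gte(F1, F0 - 1e-8)
  # with posteriors from the truth, tau moves toward the true 0.5
  expect_lt(abs(kin2$tau[2] - 0.5), 0.15)
  # K = 1: nothing to optimize
  st1 <- trajectory_structure("[[0,1]]")
  sim1 <- simulate_trajectory(st1, n_cells = 40, n_genes = 5, seed = 2)
  prior1 <- sampling_prior(st1, 8)
  q1 <- matrix(1 / 16, 40, 8)
  q1 <- q1 / rowSums(q1)
  suff1 <- ptraj:::suff_stats(q1, sim1$data)
  kin1 <- sim1$truth$kinetics
  expect_equal(update_global_tau(kin1, st1, prior1, suff1)$tau, kin1$tau)
})

test_that("switch-time recovery from informative genes", {
  st <- bifurcation_structure()
  sim <- simulate_trajectory(st, n_cells = 800, n_genes = 60, seed = 21,
                             frac_variable = 1)
  prior <- sampling_prior(st, 40)
  ll <- log_likelihood_grid(sim$data, st, sim$truth$kinetics, prior)
  q <- e_step(ll, prior)$posterior
  suff <- ptraj:::suff_stats(q, sim$data)
  kin <- sim$truth$kinetics
  kin$tau <- c(0, 0.3, 1)
  kin2 <- update_global_tau(kin, st, prior, suff, maxit = 50L)
  expect_lt(abs(kin2$tau[2] - 0.5), 0.05)
})

test_that("prior weight updates average the posterior and respect the flag", {
  st <- bifurcation_structure()
  prior <- sampling_prior(st, 10)
  q <- matrix(0, 20, 20)
  q[1:6, 3] <- 1     # lineage 1
  q[7:20, 15] <- 1   # lineage 2
  up <- update_prior_weights(q, prior, enabled = TRUE)
  expect_equal(up$lineage_weights, c(0.3, 0.7))
  expect_equal(sum(exp(up$log_weights)), 1, tolerance = 1e-12)
  expect_identical(update_prior_weights(q, prior, enabled = FALSE), prior)
  # t0 atom mass follows the posterior average
  prior0 <- sampling_prior(st, 10, t0_mass = 0.1)
  q0 <- cbind(matrix(0, 10, 20), 0)
  q0[1:2, 21] <- 1
  q0[3:10, 5] <- 1
  up0 <- update_prior_weights(q0, prior0, enabled = TRUE)
  expect_equal(up0$t0_mass, 0.2)
})
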