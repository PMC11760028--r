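test_that("kinetic parameters follow the stated lognormal laws", {
  st <- bifurcation_structure()
  set.seed(61)
  par <- sample_parameters(st, n_genes = 10000, frac_variable = 0.5)
  kin <- par$kinetics
  expect_lt(abs(mean(log(kin$beta)) - 2), 0.05)
  expect_lt(abs(sd(log(kin$beta)) - 0.5), 0.05)
  expect_lt(abs(mean(log(kin$gamma)) - 0.5), 0.05)
  expect_lt(abs(mean(log(kin$alpha[par$variable, ])) - 2), 0.05)
  expect_true(all(kin$alpha > 0) && all(kin$beta > 0) && all(kin$gamma > 0))
  # non-variable genes share one alpha across states
  rng <- apply(kin$alpha[!par$variable, ], 1L, function(a) diff(range(a)))
  expect_true(all(rng == 0))
  # variable genes essentially never do
  rngv <- apply(kin$alpha[par$variable, ], 1L, function(a) diff(range(a)))
  expect_gt(mean(rngv > 0), 0.999)
})

test_that("latent draws are uniform, optionally Gaussian-contaminated", {
  st <- bifurcation_structure()
  set.seed(62)
  lat0 <- sample_latents(10000, st, blend = 0)
  expect_lt(abs(mean(lat0$time) - 0.5), 0.02)
  expect_true(all(lat0$time >= 0 & lat0$time <= 1))
  # lineage occupancy uniform at the 1% chi-square level
  tab <- tabulate(lat0$lineage, 2)
  expect_gt(chisq.test(tab)$p.value, 0.01)
  # full contamination: narrow spread around the random center
  lat1 <- sample_latents(10000, st, blend = 1, blend_sd = 0.05)
  expect_lt(sd(lat1$time), 0.08)
  expect_lt(abs(mean(lat1$time) - lat1$blend_center), 0.03)
  expect_true(all(lat1$time >= 0 & lat1$time <= 1))
})

test_that("simulated counts match the closed-form means and variance laws", {
  st <- bifurcation_structure()
  kin <- random_kinetics(st, 20, seed = 63)
  # many cells at one fixed (lineage, time): empirical means vs solution
  set.seed(64)
  lat <- list(lineage = rep(2L, 4000), time = rep(0.73, 4000))
  sim <- simulate_counts(kin, st, lat, depth_var = 0)
  mu <- mean_solution(st, kin, 2, 0.73)
  se_u <- sqrt(pmax(mu$lambda_u, 1e-9) / 4000)
  expect_true(all(abs(colMeans(sim$data$unspliced) - mu$lambda_u) <
                    4 * se_u + 1e-6))
  # Gamma noise at steady state: var ~ lambda + cv2 lambda^2
  st1 <- trajectory_structure("[[0,0]]")
  kin1 <- gene_kinetics(alpha = rbind(8, 20), beta = c(2, 2),
                        gamma = c(1, 1), tau = c(0, 1))
  set.seed(65)
  lat1 <- list(lineage = rep(1L, 20000), time = runif(20000))
  sim1 <- simulate_counts(kin1, st1, lat1, depth_var = 0, gamma_cv2 = 0.5)
  lam <- kin1$alpha[, 1] / kin1$gamma
  v <- apply(sim1$data$spliced, 2, var)
  expect_equal(v, lam + 0.5 * lam^2, tolerance = 0.1)
})

test_that("the steady-state unspliced:spliced ratio is near 0.2", {
  set.seed(66)
  alpha <- rlnorm(10000, 2, 1)
  beta <- rlnorm(10000, 2, 0.5)
  gamma <- rlnorm(10000, 0.5, 0.5)
  ratio <- sum(alpha / beta) / sum(alpha / gamma)
  expect_gt(ratio, 0.15)
  expect_lt(ratio, 0.30)
  # and the simulator's aggregate counts agree
  sim <- small_sim(n_cells = 2000, n_genes = 300, seed = 67)
  agg <- mean(sim$data$unspliced) / mean(sim$data$spliced)
  expect_gt(agg, 0.1)
  expect_lt(agg, 0.35)
})

test_that("desynchronized switch times stay ordered around the global ones", {
  tau <- c(0, 0.3, 0.5, 1)
  set.seed(68)
  taum <- desynchronize_tau(tau, 10000)
  expect_true(all(apply(taum, 1, function(v) all(diff(v) > 0))))
  expect_true(all(taum[, 1] == 0) && all(taum[, 4] == 1))
  dtau <- min(diff(tau))  # 0.2
  expect_lt(abs(mean(taum[, 2]) - 0.3), dtau / 20)
  expect_lt(abs(mean(taum[, 3]) - 0.5), dtau / 20)
  expect_true(all(abs(taum[, 2] - 0.3) <= dtau / 2 + 1e-12))
  # degenerate spacing: no jitter possible
  expect_equal(desynchronize_tau(c(0, 1), 5), cbind(0, rep(1, 5)))
})

test_that("degrading study conditions degrade recovery in the expected order", {
  st <- bifurcation_structure()
  cfg <- traj_config(n_restarts = 4, n_iterations = 40, grid_M = 40,
                     seed = 73)
  # sampling concentration: time RMSE worsens as the Gaussian blend grows
  rmse <- vapply(c(0, 0.5, 1), function(f) {
    sim <- simulate_trajectory(st, n_cells = 400, n_genes = 60, blend = f,
                               seed = 74)
    fit <- fit_trajectory(sim$data, st, cfg)
    evaluation_metrics(sim$truth, fit)$time_rmse
  }, 0)
  expect_lt(rmse[1], rmse[2])
  expect_lt(rmse[1], rmse[3])
  expect_gt(cor(rmse, c(0, 0.5, 1), method = "spearman"), 0)
  # fast dynamics: scaling beta, gamma x100 ruins rate recovery
  mk <- function(scale) {
    sim <- simulate_trajectory(st, n_cells = 400, n_genes = 60, seed = 75,
                               beta_meanlog = 2 + log(scale),
                               gamma_meanlog = 0.5 + log(scale))
    fit <- fit_trajectory(sim$data, st, cfg)
    evaluation_metrics(sim$truth, fit)$gamma_error
  }
  expect_gt(mk(100), 2 * mk(1))
  # blend raises realized-time concentration (entropy drops)
  set.seed(76)
  e0 <- sample_latents(5000, st, blend = 0)$entropy
  e1 <- sample_latents(5000, st, blend = 1)$entropy
  expect_gt(e0, e1)
  expect_lt(abs(e0 - log(20)), 0.05)
})

test_that("the simulator is deterministic under a fixed seed", {
  s1 <- small_sim(n_cells = 100, n_genes = 15, seed = 99)
  s2 <- small_sim(n_cells = 100, n_genes = 15, seed = 99)
  expect_identical(s1$data$unspliced, s2$data$unspliced)
  expect_identical(s1$truth$time, s2$truth$time)
  s3 <- small_sim(n_cells = 100, n_genes = 15, seed = 100)
  expect_false(identical(s1$data$unspliced, s3$data$unspliced))
})

test_that("evaluation metrics are exact for a perfect fit and by definition", {
  sim <- small_sim(n_cells = 200, n_genes = 20, seed = 71)
  st <- bifurcation_structure()
  prior <- sampling_prior(st, 50)
  ll <- log_likelihood_grid(sim$data, st, sim$truth$kinetics, prior)
  q <- e_step(ll, prior)$posterior
  fake_fit <- structure(
    list(kinetics = sim$truth$kinetics, prior = prior, posterior = q,
         structure = st, data = sim$data), class = "traj_fit")
  m <- evaluation_metrics(sim$truth, fake_fit)
  expect_equal(m$alpha_error, 0)
  expect_equal(m$beta_error, 0)
  expect_equal(m$gamma_error, 0)
  expect_gt(m$time_cor, 0.85)
  # normalized alpha error definition: |9 - 4| / sqrt(4) = 2.5
  truth2 <- sim$truth
  fit2 <- fake_fit
  fit2$kinetics$alpha <- truth2$kinetics$alpha * 0 + 9
  truth2$kinetics$alpha <- truth2$kinetics$alpha * 0 + 4
  truth2$variable <- rep(TRUE, 20)
  expect_equal(evaluation_metrics(truth2, fit2)$alpha_error, 2.5)
})
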