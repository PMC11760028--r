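test_that("trajectory gene scores decompose the ELBO and select true dynamics", {
  sim <- fixture_sim()
  fit <- fixture_fit()
  mix <- fixture_mixture()
  ts <- trajectory_gene_likelihood(fit)
  expect_equal(sum(ts), fit$elbo, tolerance = 1e-9 * abs(fit$elbo))
  # permutation of cells leaves scores unchanged
  perm <- rev(seq_len(nrow(fit$posterior)))
  fitp <- fit
  fitp$posterior <- fit$posterior[perm, ]
  dp <- count_dataset(sim$data$unspliced[perm, ], sim$data$spliced[perm, ],
                      sim$data$read_depth[perm])
  expect_equal(trajectory_gene_likelihood(fitp, dp), ts, tolerance = 1e-8)
  # relative-likelihood selection: only truly variable genes survive
  cs <- mixture_gene_likelihood(mix)
  sel <- select_dynamic_genes(ts, cs)
  expect_gt(length(sel), 0.6 * sum(sim$truth$variable))
  expect_equal(sum(!sim$truth$variable[sel]), 0)
  # strict inequality at ties; invariance to common shifts
  expect_length(select_dynamic_genes(c(1, 2), c(1, 1)), 1)
  expect_equal(select_dynamic_genes(ts + 5, cs + 5), sel)
  expect_error(select_dynamic_genes(ts, cs[-1]), "length")
})

test_that("information criteria follow their formulas", {
  fit <- fixture_fit()
  ic <- information_criteria(fit)
  k <- fit$n_parameters
  n <- nrow(fit$posterior)
  expect_equal(ic[["aic"]], 2 * k - 2 * fit$elbo)
  expect_equal(ic[["bic"]], k * log(n) - 2 * fit$elbo)
  # parameter count: S alphas + beta + gamma per gene, K-1 shared taus
  st <- fit$structure
  expect_equal(k, nrow(fit$kinetics$alpha) * (st$n_states + 2) +
                 (st$n_seg - 1))
  # AIC/BIC accessible through the standard generics too
  expect_equal(AIC(fit), ic[["aic"]])
  expect_equal(BIC(fit), ic[["bic"]])
})

test_that("held-out ELBO equals the training ELBO on the training set", {
  fit <- fixture_fit()
  expect_equal(test_elbo(fit, fit$data), fit$elbo,
               tolerance = 1e-9 * abs(fit$elbo))
  # additive over disjoint cell subsets
  d <- fit$data
  d1 <- count_dataset(d$unspliced[1:100, ], d$spliced[1:100, ],
                      d$read_depth[1:100])
  d2 <- count_dataset(d$unspliced[-(1:100), ], d$spliced[-(1:100), ],
                      d$read_depth[-(1:100)])
  # read-depth renormalization must be bypassed for exact additivity
  d1$read_depth <- d$read_depth[1:100]
  d2$read_depth <- d$read_depth[-(1:100)]
  expect_equal(test_elbo(fit, d1) + test_elbo(fit, d2), fit$elbo,
               tolerance = 1e-8 * abs(fit$elbo))
  bad <- count_dataset(d$unspliced[, 1:3], d$spliced[, 1:3], d$read_depth)
  expect_error(test_elbo(fit, bad), "gene")
})

test_that("the empirical Fisher information matches the Poisson closed form", {
  # single state: both species at steady state; the log-alpha diagonal of
  # the FIM is Var(x_u + x_s - r*lambda_tot) = E[r] * lambda_tot
  st <- trajectory_structure("[[0,0]]")
  set.seed(31)
  n <- 20000
  alpha <- 4; beta <- 2; gamma <- 1
  lam_tot <- alpha / beta + alpha / gamma
  r <- rbeta(n, 2.75, 8.25); r <- r / mean(r)
  U <- matrix(rpois(n, r * alpha / beta), n, 1)
  S <- matrix(rpois(n, r * alpha / gamma), n, 1)
  d <- count_dataset(U, S, r)
  prior <- sampling_prior(st, 5)
  kin <- gene_kinetics(alpha = rbind(alpha), beta = beta, gamma = gamma,
                       tau = c(0, 1))
  fit <- structure(list(structure = st, kinetics = kin, prior = prior,
                        data = d), class = "traj_fit")
  fi <- fisher_information(fit)
  expect_equal(dim(fi$fim), c(3, 3, 1))
  I <- fi$fim[, , 1]
  expect_equal(I, t(I))
  expect_true(all(eigen(I, symmetric = TRUE)$values > -1e-8))
  expect_equal(I[1, 1], lam_tot, tolerance = 0.02)
})

test_that("average precision matches a brute-force precision-recall oracle", {
  brute_ap <- function(scores, labels) {
    if (!any(labels)) return(0)
    ths <- sort(unique(scores), decreasing = TRUE)
    prev_rec <- 0; ap <- 0
    for (th in ths) {
      sel <- scores >= th
      prec <- sum(labels[sel]) / sum(sel)
      rec <- sum(labels[sel]) / sum(labels)
      ap <- ap + prec * (rec - prev_rec)
      prev_rec <- rec
    }
    ap
  }
  scores <- c(3, 2, 1, 0); labels <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(ptraj:::average_precision(scores, labels),
               brute_ap(scores, labels))
  expect_equal(ptraj:::average_precision(scores, labels), 5 / 6)
  expect_equal(ptraj:::average_precision(scores, rep(TRUE, 4)), 1)
  expect_equal(ptraj:::average_precision(scores, rep(FALSE, 4)), 0)
  set.seed(9)
  for (rep in 1:20) {
    sc <- rnorm(8); lb <- runif(8) > 0.5
    expect_equal(ptraj:::average_precision(sc, lb), brute_ap(sc, lb),
                 tolerance = 1e-12)
  }
  # invariant under monotone transformations of the scores
  sc <- rnorm(10); lb <- runif(10) > 0.4
  expect_equal(ptraj:::average_precision(exp(sc), lb),
               ptraj:::average_precision(sc, lb))
})

test_that("restart AP flags a stable fit as stable", {
  fit <- fixture_fit()
  ap <- restart_average_precision(fit)
  expect_true(ap$average_precision >= 0 && ap$average_precision <= 1)
  expect_true(all(ap$correlations >= -1 & ap$correlations <= 1,
                  na.rm = TRUE))
  # constant mean-time restarts are labeled incorrect
  fake <- list(scores = c(2, 1),
               mean_times = cbind(seq(0, 1, length.out = 10), rep(0.5, 10)))
  ap2 <- restart_average_precision(fake)
  expect_false(ap2$labels[2])
})

test_that("bootstrap correlations are valid and high in a stable regime", {
  fit <- cached("fit_boot", {
    sim <- small_sim(n_cells = 300, n_genes = 40, seed = 51)
    fit_trajectory(sim$data, bifurcation_structure(),
                   traj_config(n_restarts = 2, n_iterations = 25,
                               grid_M = 30, seed = 52))
  })
  cors <- bootstrap_stability(fit, n_boot = 3,
                              config = traj_config(n_restarts = 2,
                                                   n_iterations = 20,
                                                   grid_M = 30, seed = 53),
                              seed = 54)
  expect_true(all(abs(cors) <= 1, na.rm = TRUE))
  expect_gt(median(abs(cors), na.rm = TRUE), 0.8)
})

test_that("DE ranking orders genes by transcription-rate fold change", {
  kin <- gene_kinetics(alpha = rbind(c(1, 1, 1, 1), c(1, 10, 2, 3),
                                     c(2, 4, 2, 2)),
                       beta = c(1, 1, 1), gamma = c(1, 1, 1),
                       tau = c(0, .5, 1))
  de <- rank_de_genes(kin)
  expect_equal(de$gene, c(2, 3, 1))
  expect_equal(de$fold_change, c(10, 2, 1))
  # flat gene ranks last with fold change exactly 1
  expect_equal(de$fold_change[de$gene == 1], 1)
  # invariant to gene order
  de2 <- rank_de_genes(kin, genes = c(3, 1, 2))
  expect_equal(de2$fold_change, de$fold_change)
})

test_that("posterior entropy behaves at its extremes", {
  st <- bifurcation_structure()
  prior <- sampling_prior(st, 100)
  n <- 7
  q_unif <- matrix(1 / 200, n, 200)
  expect_equal(average_posterior_entropy(q_unif, prior), log(100),
               tolerance = 1e-12)
  q_point <- matrix(0, n, 200)
  q_point[, 37] <- 1
  expect_equal(average_posterior_entropy(q_point, prior), 0)
  # splitting identical time profiles across lineages changes nothing
  q_split <- q_point / 2
  q_split[, 137] <- 0.5
  expect_equal(average_posterior_entropy(q_split, prior), 0)
})
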