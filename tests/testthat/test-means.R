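test_that("piecewise rates follow the half-open-left segment convention", {
  st <- bifurcation_structure()
  kin <- gene_kinetics(alpha = rbind(c(1, 2, 3, 4)), beta = 1, gamma = 1,
                       tau = c(0, 0.4, 1))
  # t = 0 maps to the initial state of the lineage
  expect_equal(piecewise_rate(st, kin, 1, 0)[1, 1], 1)
  expect_equal(piecewise_rate(st, kin, 2, 0)[1, 1], 1)
  # t exactly at tau_1 belongs to segment 1 (interval (tau_0, tau_1])
  expect_equal(piecewise_rate(st, kin, 1, 0.4)[1, 1], 2)
  expect_equal(piecewise_rate(st, kin, 1, 0.41)[1, 1], 3)
  expect_equal(piecewise_rate(st, kin, 2, 1)[1, 1], 4)
  # single-state structure: the same rate everywhere
  st1 <- trajectory_structure("[[0,0]]")
  kin1 <- gene_kinetics(alpha = rbind(5), beta = 1, gamma = 1, tau = c(0, 1))
  expect_true(all(piecewise_rate(st1, kin1, 1, c(0, .3, .7, 1)) == 5))
})

test_that("constant-rate kinetics stay at the steady-state fixed point", {
  st <- trajectory_structure("[[0,1]]")
  kin <- gene_kinetics(alpha = cbind(c(3, 7), c(3, 7)), beta = c(2, 5),
                       gamma = c(1, 0.5), tau = c(0, 1))
  m <- mean_solution(st, kin, 1, seq(0, 1, 0.1))
  expect_equal(m$lambda_u, matrix(kin$alpha[, 1] / kin$beta, 2, 11),
               tolerance = 1e-12)
  expect_equal(m$lambda_s, matrix(kin$alpha[, 1] / kin$gamma, 2, 11),
               tolerance = 1e-12)
})

test_that("closed-form means match a segment-wise RK4 integration", {
  skip_if_not_installed("deSolve")
  st <- bifurcation_structure()
  p <- 5
  kin <- random_kinetics(st, p, seed = 1)
  kin$tau <- c(0, 0.4, 1)
  for (lineage in 1:2) {
    y <- cbind(kin$alpha[, st$paths[lineage, 1] + 1] / kin$beta,
               kin$alpha[, st$paths[lineage, 1] + 1] / kin$gamma)
    err <- 0
    for (k in 1:2) {
      tseq <- seq(kin$tau[k], kin$tau[k + 1], by = 1e-4)
      ms <- mean_solution(st, kin, lineage, tseq[-1])
      for (j in 1:p) {
        a <- kin$alpha[j, st$paths[lineage, k + 1] + 1]
        f <- function(t, yy, parms)
          list(c(a - kin$beta[j] * yy[1],
                 kin$beta[j] * yy[1] - kin$gamma[j] * yy[2]))
        out <- deSolve::ode(y[j, ], tseq, f, NULL, method = "rk4")
        err <- max(err, abs(out[-1, 2] - ms$lambda_u[j, ]),
                   abs(out[-1, 3] - ms$lambda_s[j, ]))
        y[j, ] <- out[nrow(out), 2:3]
      }
    }
    expect_lt(err, 1e-6)
  }
})

test_that("the beta ~ gamma degeneracy is finite and continuous", {
  st <- bifurcation_structure()
  mk <- function(gam) gene_kinetics(alpha = rbind(c(2, 8, 3, 1)), beta = 2,
                                    gamma = gam, tau = c(0, 0.4, 1))
  tt <- seq(0, 1, 0.05)
  exact_deg <- mean_solution(st, mk(2 * (1 + 1e-12)), 1, tt)
  near_deg <- mean_solution(st, mk(2.0001), 1, tt)
  expect_true(all(is.finite(exact_deg$lambda_u)))
  expect_true(all(is.finite(exact_deg$lambda_s)))
  expect_lt(max(abs(exact_deg$lambda_s - near_deg$lambda_s)), 1e-3)
  skip_if_not_installed("deSolve")
  # degenerate point against the ODE oracle
  kin <- mk(2 * (1 + 1e-12))
  y <- c(kin$alpha[1, 1] / kin$beta, kin$alpha[1, 1] / kin$gamma)
  err <- 0
  for (k in 1:2) {
    a <- kin$alpha[1, st$paths[1, k + 1] + 1]
    f <- function(t, yy, parms)
      list(c(a - kin$beta * yy[1], kin$beta * yy[1] - kin$gamma * yy[2]))
    tseq <- seq(kin$tau[k], kin$tau[k + 1], by = 1e-4)
    out <- deSolve::ode(y, tseq, f, NULL, method = "rk4")
    ms <- mean_solution(st, kin, 1, tseq[-1])
    err <- max(err, abs(out[-1, 2] - ms$lambda_u[1, ]),
               abs(out[-1, 3] - ms$lambda_s[1, ]))
    y <- as.numeric(out[nrow(out), 2:3])
  }
  expect_lt(err, 1e-6)
})

test_that("means are continuous across switch times", {
  st <- oversplit_structure()
  kin <- random_kinetics(st, 6, seed = 3)
  kin$tau <- c(0, 0.3, 0.7, 1)
  for (k in 2:3) {
    left <- mean_solution(st, kin, 2, kin$tau[k])
    right <- mean_solution(st, kin, 2, kin$tau[k] + 1e-9)
    expect_lt(max(abs(left$lambda_u - right$lambda_u)), 1e-6)
    expect_lt(max(abs(left$lambda_s - right$lambda_s)), 1e-6)
  }
})

test_that("long final segments approach the last state's steady state", {
  st <- trajectory_structure("[[0,1]]")
  # rates scaled up so that t - tau_0 is many mean lifetimes
  kin <- gene_kinetics(alpha = cbind(c(1, 5), c(9, 2)), beta = c(80, 120),
                       gamma = c(60, 90), tau = c(0, 1))
  m <- mean_solution(st, kin, 1, 1)
  expect_equal(as.vector(m$lambda_u), kin$alpha[, 2] / kin$beta,
               tolerance = 1e-8)
  expect_equal(as.vector(m$lambda_s), kin$alpha[, 2] / kin$gamma,
               tolerance = 1e-8)
})

test_that("mean Jacobians match central finite differences", {
  st <- oversplit_structure()  # S = 5, K = 3: all parameter kinds exercised
  p <- 4
  mkkin <- function(th, desync) {
    tau <- if (desync) cbind(0, th[, 8], th[, 9], 1) else
      c(0, th[1, 8], th[1, 9], 1)
    ptraj:::kin_raw(th[, 1:5], th[, 6], th[, 7], tau)
  }
  set.seed(2)
  th <- cbind(matrix(rlnorm(p * 5, 2, 1), p, 5), rlnorm(p, 2, .5),
              rlnorm(p, .5, .5), matrix(rep(c(.32, .71), each = p), p, 2))
  tt <- c(0, 0.15, 0.3, 0.45, 0.62, 0.85, 1)
  h <- 1e-6
  for (desync in c(FALSE, TRUE)) {
    kin <- mkkin(th, desync)
    mg <- ptraj:::lineage_means(st, kin, 2, tt, want_grad = TRUE)
    for (dd in 1:9) {
      thp <- th; thm <- th
      thp[, dd] <- thp[, dd] + h; thm[, dd] <- thm[, dd] - h
      fdU <- (ptraj:::lineage_means(st, mkkin(thp, desync), 2, tt)$lambda_u -
                ptraj:::lineage_means(st, mkkin(thm, desync), 2, tt)$lambda_u) /
        (2 * h)
      fdS <- (ptraj:::lineage_means(st, mkkin(thp, desync), 2, tt)$lambda_s -
                ptraj:::lineage_means(st, mkkin(thm, desync), 2, tt)$lambda_s) /
        (2 * h)
      expect_lt(max(abs(fdU - mg$grad_u[, , dd]) / pmax(1, abs(fdU))), 1e-5)
      expect_lt(max(abs(fdS - mg$grad_s[, , dd]) / pmax(1, abs(fdS))), 1e-5)
    }
    # restricted gradient columns agree with the full Jacobian
    mg2 <- ptraj:::lineage_means(st, kin, 2, tt, want_grad = c(8L, 9L))
    expect_equal(mg2$grad_u[, , 1], mg$grad_u[, , 8])
    expect_equal(mg2$grad_s[, , 2], mg$grad_s[, , 9])
  }
})
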