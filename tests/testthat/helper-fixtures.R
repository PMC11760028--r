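# Shared fixtures: tiny structures, kinetics and simulations built in code.

bifurcation_structure <- function() trajectory_structure("[[0,1,2],[0,1,3]]")

oversplit_structure <- function() trajectory_structure("[[0,1,2,3],[0,1,2,4]]")

single_path_structure <- function() trajectory_structure("[[0,1]]")

random_kinetics <- function(structure, p, seed = 1, desync = FALSE) {
  set.seed(seed)
  S <- structure$n_states
  K <- structure$n_seg
  tau <- seq(0, 1, length.out = K + 1)
  if (desync) {
    tau <- t(apply(matrix(stats::runif(p * (K - 1), 0.2, 0.8), p),
                   1, sort))
    tau <- cbind(0, tau, 1)
  }
  gene_kinetics(alpha = matrix(rlnorm(p * S, 2, 1), p, S),
                beta = rlnorm(p, 2, 0.5),
                gamma = rlnorm(p, 0.5, 0.5),
                tau = tau)
}

small_sim <- function(n_cells = 400, n_genes = 50, seed = 5, ...) {
  simulate_trajectory(bifurcation_structure(), n_cells = n_cells,
                      n_genes = n_genes, seed = seed, ...)
}

quick_config <- function(...) {
  traj_config(n_restarts = 2, n_iterations = 30, grid_M = 40, ...)
}

# shared fitted models, computed once per test run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

fixture_sim <- function() {
  cached("sim", small_sim(n_cells = 600, n_genes = 80, seed = 41))
}

fixture_fit <- function() {
  cached("fit", {
    sim <- fixture_sim()
    fit_trajectory(sim$data, bifurcation_structure(),
                   traj_config(n_restarts = 6, n_iterations = 40,
                               grid_M = 50, seed = 42))
  })
}

fixture_mixture <- function() {
  cached("mix", fit_poisson_mixture(fixture_sim()$data, 4, n_restarts = 5,
                                    seed = 43))
}

# independent finite-difference gradient of a scalar function
fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, 0)
}
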