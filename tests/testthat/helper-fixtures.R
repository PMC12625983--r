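# shared fixtures: the two-neuron worked example and small seeded networks

toy_frame <- function() build_eta_frame(toy_task()$X)

# a small random network with currents placed strictly inside the linear
# regime, for finite-difference gradient checks
interior_task <- function(seed = 1, Ny = 6L, Nx = 5L, P = 3L) {
  set.seed(seed)
  X <- matrix(rnorm(Nx * P), Nx, P)
  W <- matrix(rnorm(Ny), 1, Ny)
  b <- rep(2.5, Ny)
  U <- matrix(rnorm(Ny * Nx, 0, 0.05), Ny, Nx)
  Z <- matrix(rnorm(P, 0, 2), 1, P)
  list(task = task_spec(X, W, Z, alpha = 5, b = b), U = U)
}

# brute-force line-search oracle for the threshold rescaling: largest grid
# gamma in [0, 1] keeping all currents inside [0, alpha]
gamma_grid_oracle <- function(current, delta, alpha, grid = 1e-4) {
  gammas <- seq(0, 1, by = grid)
  # evaluate feasibility for all grid points at once
  cur_mat <- matrix(current, length(current), length(gammas))
  d_mat <- matrix(delta, length(delta), length(gammas))
  g_mat <- matrix(gammas, length(current), length(gammas), byrow = TRUE)
  vals <- cur_mat + g_mat * d_mat
  feas <- colSums(vals < -1e-12 | vals > alpha + 1e-12) == 0
  max(gammas[feas])
}

# central finite-difference gradient of a scalar function of a matrix
fd_grad <- function(f, M, h = 1e-6) {
  G <- M
  for (k in seq_along(M)) {
    Mp <- M; Mm <- M
    Mp[k] <- M[k] + h
    Mm[k] <- M[k] - h
    G[k] <- (f(Mp) - f(Mm)) / (2 * h)
  }
  G
}
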