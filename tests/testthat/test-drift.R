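test_that("threshold rescaling picks the maximal feasible step and flags crossers", {
  # one neuron driven to the 0 bound: gamma = 2/3
  rs <- rescale_to_threshold(c(2, 2), c(-3, 3), 5)
  expect_equal(rs$gamma, 2 / 3)
  expect_equal(rs$crossers, 1L)
  expect_equal(rs$to, 1L)  # becomes inactive
  # interior proposal: gamma 1, no crossers
  rs2 <- rescale_to_threshold(c(2, 2), c(0.5, -0.5), 5)
  expect_equal(rs2$gamma, 1)
  expect_length(rs2$crossers, 0)
  # simultaneous tie: both neurons land exactly on opposite bounds
  rs3 <- rescale_to_threshold(c(2, 3), c(-2, 2), 5)
  expect_equal(rs3$gamma, 1)
  expect_equal(rs3$crossers, c(1L, 2L))
  expect_equal(rs3$to, c(1L, 3L))
})

test_that("threshold rescaling agrees with a brute-force line search", {
  set.seed(20)
  for (i in 1:1000) {
    ne <- sample(2:6, 1)
    cur <- runif(ne, 0, 5)
    delta <- rnorm(ne, 0, 2)
    rs <- rescale_to_threshold(cur, delta, 5)
    g_or <- gamma_grid_oracle(cur, delta, 5, grid = 1e-4)
    expect_lt(abs(rs$gamma - g_or), 1.01e-4)
    # rescaled currents feasible, crossers exactly at a bound
    v <- cur + rs$gamma * delta
    expect_true(all(v >= -1e-9 & v <= 5 + 1e-9))
  }
  # a finer grid on a handful of cases
  set.seed(21)
  for (i in 1:20) {
    cur <- runif(4, 0, 5); delta <- rnorm(4, 0, 3)
    rs <- rescale_to_threshold(cur, delta, 5)
    expect_lt(abs(rs$gamma - gamma_grid_oracle(cur, delta, 5, 1e-6)), 1.01e-6)
  }
})

test_that("a drift step on the toy solution stays on the solution line with exact clamping", {
  task <- toy_task()
  fr <- toy_frame()
  # solution for mapping 1 at currents (2, 2); kernel direction (1,-1)/sqrt(2)
  U <- from_eta(cbind(c(2, 2), c(0, 0)), fr)
  st <- drift_state(U, task, learned = 1L, frame = fr)
  cfg <- drift_config(sigma = 0.3, n_steps = 1L)
  set.seed(30)
  for (i in 1:200) {
    st <- drift_step(st, cfg)
    eta1 <- st$eta[, 1]
    lab1 <- st$labels[, 1]
    # readout of the stored mapping is conserved
    zhat <- sum(phi(eta1, 5))
    expect_equal(zhat, 4, tolerance = 1e-10)
    # set-consistency: engaged in [0, alpha], inactive <= 0, saturated >= alpha
    expect_true(all(eta1[lab1 == 2L] >= 0 & eta1[lab1 == 2L] <= 5))
    expect_true(all(eta1[lab1 == 1L] <= 0))
    expect_true(all(eta1[lab1 == 3L] >= 5))
  }
})

test_that("inactive coordinates clamp exactly at threshold and transition to engaged", {
  task <- toy_task()
  fr <- toy_frame()
  # neuron 1 barely inactive for condition 1; neuron 2 engaged
  U <- from_eta(cbind(c(-1e-4, 2), c(0, 0)), fr)
  st <- drift_state(U, task, learned = 1L, frame = fr)
  expect_equal(as.vector(unclass(st$labels[, 1])), c(1L, 2L))
  cfg <- drift_config(sigma = 0.5, n_steps = 1L)
  set.seed(31)
  crossed <- FALSE
  for (i in 1:100) {
    lab_before <- st$labels[, 1]
    st <- drift_step(st, cfg)
    if (lab_before[1] == 1L && st$labels[1, 1] == 2L) {
      crossed <- TRUE
      expect_identical(st$eta[1, 1], 0)  # exactly -b with b = 0
      break
    }
  }
  expect_true(crossed)
})

test_that("an engaged set of size Nz receives no drift increment", {
  task <- toy_task()
  fr <- toy_frame()
  # only neuron 2 engaged for condition 1: |E| = Nz = 1, empty kernel
  U <- from_eta(cbind(c(-3, 2), c(0, 0)), fr)
  st <- drift_state(U, task, learned = 1L, frame = fr)
  set.seed(32)
  st2 <- drift_step(st, drift_config(sigma = 0.05, n_steps = 1L))
  expect_identical(st2$eta[2, 1], st$eta[2, 1])
})

test_that("the norm bound reverts offending rows and is the identity when unbounded", {
  fr <- toy_frame()
  prev <- matrix(0.1, 2, 2)
  cand <- matrix(c(10, 0.2, 10, 0.2), 2, 2)  # row 1 blows up
  out <- enforce_norm_bound(cand, prev, fr, Umax = 1)
  expect_equal(out[1, ], prev[1, ])
  expect_equal(out[2, ], cand[2, ])
  expect_equal(attr(out, "rejected"), 1L)
  # all rows within bound: unchanged
  ok <- enforce_norm_bound(prev * 1.1, prev, fr, Umax = 100)
  expect_equal(unclass(ok)[, ], prev * 1.1, ignore_attr = TRUE)
  expect_length(attr(ok, "rejected"), 0)
  # unbounded: identity
  inf_out <- enforce_norm_bound(cand, prev, fr, Umax = Inf)
  expect_equal(unclass(inf_out)[, ], cand, ignore_attr = TRUE)
})

test_that("drift under a tight norm bound keeps every row at or below the bound", {
  task <- generate_task(network_config(), seed = 7)
  set.seed(11)
  sol <- learn_solution(task)
  st <- drift_state(sol$U, task, frame = sol$frame)
  set.seed(33)
  traj <- run_drift(st, drift_config(sigma = 0.05, Umax = 10,
                                     n_steps = 5000L, record_every = 250L))
  expect_true(all(traj$row_norms <= 10 * (1 + 1e-9)))
  # norms climb toward the bound and fluctuate near it
  expect_gt(mean(traj$row_norms[nrow(traj$row_norms), ]), 8)
})

test_that("an empty run returns a single snapshot equal to the input", {
  task <- toy_task()
  U <- from_eta(cbind(c(2, 2), c(0, 0)), toy_frame())
  st <- drift_state(U, task, learned = 1L)
  traj <- run_drift(st, drift_config(n_steps = 0L))
  expect_length(traj$times, 1L)
  expect_equal(traj$etas[, , 1], st$eta)
  expect_equal(traj$zhat_drift, 0)
})

test_that("the compiled and reference drift engines produce the same trajectory", {
  task <- generate_task(network_config(), seed = 7)
  set.seed(11)
  sol <- learn_solution(task)
  st <- drift_state(sol$U, task, frame = sol$frame)
  for (um in c(Inf, 15)) {
    cfg <- drift_config(sigma = 0.05, Umax = um, n_steps = 300L,
                        record_every = 100L)
    set.seed(40)
    a <- run_drift(st, cfg, engine = "r")
    set.seed(40)
    b <- run_drift(st, cfg, engine = "cpp")
    expect_equal(a$state$eta, b$state$eta, tolerance = 1e-10)
    expect_equal(matrix(as.integer(unclass(a$state$labels)), 12, 8),
                 matrix(as.integer(unclass(b$state$labels)), 12, 8))
    expect_equal(a$fractions, b$fractions, tolerance = 1e-12)
  }
})

test_that("drift conserves stored readouts while eta moves and set labels stay consistent", {
  task <- generate_task(network_config(), seed = 12)
  set.seed(13)
  sol <- learn_solution(task)
  st <- drift_state(sol$U, task, frame = sol$frame)
  set.seed(41)
  traj <- run_drift(st, drift_config(sigma = 0.05, Umax = 350,
                                     n_steps = 2000L, record_every = 100L))
  expect_lt(max(traj$zhat_drift), 1e-8)
  # eta displacement is macroscopic
  expect_gt(sqrt(sum((traj$etas[, , length(traj$times)] - traj$etas[, , 1])^2)),
            10 * 0.05)
  # labels of the final state agree with its currents (boundaries excepted)
  fin <- traj$state
  cur <- fin$eta[, 1:8] + task$b
  lab <- unclass(fin$labels)
  expect_true(all(cur[lab == 2L] >= 0 & cur[lab == 2L] <= 5))
  expect_true(all(cur[lab == 1L] <= 0))
  expect_true(all(cur[lab == 3L] >= 5))
  # fractions always sum to one
  expect_equal(rowSums(traj$fractions), rep(1, length(traj$times)))
})

test_that("pooled weight increments during drift are zero-mean with SD near sigma", {
  task <- generate_task(network_config(), seed = 14)
  set.seed(15)
  sol <- learn_solution(task)
  st <- drift_state(sol$U, task, frame = sol$frame)
  set.seed(42)
  traj <- run_drift(st, drift_config(sigma = 0.05, Umax = 350,
                                     n_steps = 3000L, record_every = 3000L,
                                     track_dU = TRUE))
  expect_lt(abs(traj$dU_stats$mean), 0.05 * 0.05)
  expect_lt(abs(traj$dU_stats$sd - 0.05) / 0.05, 0.25)
})
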