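test_that("allocation centers one eta column in the engaged regime and touches nothing else", {
  set.seed(50)
  eta <- matrix(rnorm(12 * 15, 0, 20), 12, 15)
  eta2 <- allocate(eta, 3L, alpha = 5, alloc_sd = 0.1)
  expect_identical(eta2[, -3], eta[, -3])
  expect_true(all(abs(eta2[, 3] - 2.5) < 1))  # ~N(2.5, 0.1)
  # the allocated condition is densely engaged
  lab <- partition_neurons(eta2[, 3, drop = FALSE], 5)
  expect_true(all(lab == 2L))
})

test_that("analytic gradients match central finite differences at interior points", {
  fx <- interior_task(seed = 51)
  task <- fx$task; U <- fx$U
  # weight-coordinate gradient
  f_U <- function(M) grad_U(M, task, 1:3)$loss
  expect_equal(grad_U(U, task, 1:3)$grad, fd_grad(f_U, U), tolerance = 1e-6)
  # eta-coordinate gradient (column 2)
  fr <- build_eta_frame(task$X)
  eta <- to_eta(fx$U, fr)
  g <- grad_eta(eta, task, 2L)
  f_eta <- function(col) {
    e2 <- eta; e2[, 2] <- col
    grad_eta(e2, task, 2L)$loss
  }
  expect_equal(g$grad, as.vector(fd_grad(f_eta, eta[, 2])), tolerance = 1e-6)
})

test_that("zero initial error means zero gradient and unchanged weights", {
  fx <- interior_task(seed = 52)
  task <- fx$task
  # make the targets exactly realizable at U
  Zfit <- forward(fx$U, task)$Zhat
  t2 <- task_spec(task$X, task$W, Zfit, alpha = 5, b = task$b)
  fit <- learn_gd_U(fx$U, t2, 1:3, learn_config(tol = 1e-12))
  expect_identical(fit$U, fx$U)
  expect_true(fit$report$converged)
  expect_equal(fit$report$steps_used, 0L)
})

test_that("a fully disengaged condition has vanished gradients and cannot be learned", {
  task <- toy_task()
  eta <- cbind(c(-1, -1), c(0, 0))  # both neurons inactive for condition 1
  fit <- learn_gd_eta(eta, task, 1L, learn_config(optimizer = "gd", lr = 0.05))
  expect_false(fit$report$converged)
  expect_identical(fit$eta, eta)
  g <- grad_eta(eta, task, 1L)
  expect_identical(max(abs(g$grad)), 0)
})

test_that("eta learning on the toy converges from the allocation point onto the solution line", {
  task <- toy_task()
  eta <- cbind(c(4, 4), c(0, 0))
  fit <- learn_gd_eta(eta, task, 1L,
                      learn_config(optimizer = "gd", lr = 0.05, tol = 1e-6))
  expect_true(fit$report$converged)
  expect_equal(fit$eta[, 1], c(2, 2), tolerance = 1e-4)
})

test_that("eta learning is exactly local: other columns never move", {
  task <- toy_task()
  set.seed(53)
  eta <- matrix(rnorm(4), 2, 2)
  eta[, 2] <- c(4, 4)
  fit <- learn_gd_eta(eta, task, 2L,
                      learn_config(optimizer = "gd", lr = 0.05, tol = 1e-6))
  expect_identical(fit$eta[, 1], eta[, 1])
  # and at full scale
  task2 <- generate_task(network_config(), seed = 54)
  fr <- build_eta_frame(task2$X)
  set.seed(55)
  eta2 <- allocate(to_eta(matrix(rnorm(12 * 15, 0, 15), 12, 15), fr), 5L, 5)
  fit2 <- learn_gd_eta(eta2, task2, 5L)
  expect_identical(fit2$eta[, -5], eta2[, -5])
})

test_that("batch learning reaches the solution space from small weights at full scale", {
  task <- generate_task(network_config(), seed = 56)
  set.seed(57)
  sol <- learn_solution(task, init_sd = 0.1)
  expect_true(sol$report$converged)
  expect_lte(sol$report$final_rms, sol$report$tol)
})

test_that("sequentially eta-learning all conditions is interference-free", {
  task <- generate_task(network_config(), seed = 58)
  fr <- build_eta_frame(task$X)
  set.seed(59)
  eta <- to_eta(matrix(rnorm(12 * 15, 0, 15), 12, 15), fr)
  lcfg <- learn_config(tol = 1e-3 * sqrt(mean(task$Z^2)))
  for (mu in 1:8) {
    set.seed(60 + mu)
    eta <- allocate(eta, mu, 5)
    fit <- learn_gd_eta(eta, task, mu, lcfg)
    expect_true(fit$report$converged)
    eta <- fit$eta
  }
  zhat <- task$W %*% phi(eta[, 1:8] + task$b, 5)
  for (mu in 1:8)
    expect_lte(sqrt(mean((zhat[, mu] - task$Z[, mu])^2)), lcfg$tol)
})

test_that("learnability falls with the initial weight norm and allocation restores it", {
  rep_no <- learnability_protocol(network_config(P = 15L),
                                  init_norm_grid = c(1, 100),
                                  use_allocation = FALSE, n_seeds = 3L,
                                  seed = 61)
  m <- rep_no$summary$mean_learned
  expect_true(all(diff(m) <= 0))
  rep_al <- learnability_protocol(network_config(P = 15L),
                                  init_norm_grid = 15 * sqrt(15),
                                  use_allocation = TRUE, n_seeds = 3L,
                                  seed = 61)
  expect_gt(rep_al$summary$mean_learned, max(m))
  # an empty protocol learns nothing
  rep_0 <- learnability_protocol(network_config(P = 0L), init_norm_grid = 1,
                                 n_seeds = 2L, seed = 61)
  expect_true(all(rep_0$detail$learned == 0))
})
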