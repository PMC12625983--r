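test_that("the two-neuron extended basis is the input matrix itself", {
  fr <- toy_frame()
  expect_equal(fr$Xext, matrix(c(1, -1, -0.5, 1), 2, 2))
  expect_equal(det(fr$Xext), 0.5)
  expect_equal(fr$Xinv, matrix(c(2, 2, 1, 2), 2, 2))
  # scales from the inverse row norms
  expect_equal(fr$scales, c(1 / sqrt(5), 1 / (2 * sqrt(2))))
})

test_that("standard-basis inputs complete to the identity basis", {
  X <- diag(15)[, 1:8]
  fr <- build_eta_frame(X)
  expect_equal(fr$Xext, diag(15), tolerance = 1e-12)
  expect_equal(fr$scales, rep(1, 15))
})

test_that("the completion is orthonormal, orthogonal to the inputs, and the frame inverts", {
  task <- generate_task(network_config(), seed = 3)
  fr <- build_eta_frame(task$X)
  expect_identical(fr$Xext[, 1:8], task$X)       # inputs verbatim
  comp <- fr$Xext[, 9:15]
  expect_equal(crossprod(comp), diag(7), tolerance = 1e-10)
  expect_equal(max(abs(crossprod(task$X, comp))), 0, tolerance = 1e-10)
  expect_equal(fr$Xext %*% fr$Xinv, diag(15), tolerance = 1e-10)
  # deterministic: rebuilt frame identical
  expect_identical(fr$Xext, build_eta_frame(task$X)$Xext)
  expect_error(build_eta_frame(cbind(task$X[, 1], task$X[, 1])), "rank")
})

test_that("eta round-trips with the weights and exposes the input currents", {
  task <- generate_task(network_config(), seed = 4)
  fr <- build_eta_frame(task$X)
  set.seed(1)
  U <- matrix(rnorm(12 * 15), 12, 15)
  eta <- to_eta(U, fr)
  expect_equal(eta[, 1:8], U %*% task$X, tolerance = 1e-12)
  expect_equal(from_eta(eta, fr), U, tolerance = 1e-10)
  expect_equal(to_eta(from_eta(eta, fr), fr), eta, tolerance = 1e-10)
  expect_equal(from_eta(matrix(0, 12, 15), fr), matrix(0, 12, 15))
  # identity weights on the toy: eta equals the basis
  toy <- toy_frame()
  expect_equal(to_eta(diag(2), toy), toy$Xext)
})

test_that("current coordinates are completion-independent and completion coordinates are current-silent", {
  task <- generate_task(network_config(), seed = 6)
  fr <- build_eta_frame(task$X)
  # an alternative completion: rotate the completion columns by a random
  # orthogonal matrix; still spans the same complement
  set.seed(9)
  Q <- qr.Q(qr(matrix(rnorm(49), 7, 7)))
  fr2 <- fr
  fr2$Xext <- cbind(task$X, fr$Xext[, 9:15] %*% Q)
  fr2$Xinv <- solve(fr2$Xext)
  U <- matrix(rnorm(12 * 15), 12, 15)
  expect_equal(to_eta(U, fr)[, 1:8], to_eta(U, fr2)[, 1:8], tolerance = 1e-12)
  # perturbing only completion coordinates never changes U X
  eta <- to_eta(U, fr)
  eta2 <- eta
  eta2[, 9:15] <- eta2[, 9:15] + matrix(rnorm(12 * 7, 0, 10), 12, 7)
  expect_equal(from_eta(eta2, fr) %*% task$X, from_eta(eta, fr) %*% task$X,
               tolerance = 1e-10)
  # dimension audit: Ny * (Nx - P) unconstrained coordinates
  expect_equal(length(eta[, 9:15]), 12 * (15 - 8))
})

test_that("noise scales satisfy the equal-variance contract for weight fluctuations", {
  # orthonormal frame: all scales are 1
  fr_id <- build_eta_frame(diag(6)[, 1:3])
  expect_equal(noise_scales(fr_id, 2), rep(2, 6))
  # Monte Carlo: independent eta noise at sigma * s_mu induces delta U with
  # pooled SD sigma
  task <- generate_task(network_config(), seed = 8)
  fr <- build_eta_frame(task$X)
  sigma <- 0.05
  sds <- noise_scales(fr, sigma)
  set.seed(10)
  n <- 2000L
  deta <- matrix(rnorm(n * 15), n, 15) %*% diag(sds)
  dU <- deta %*% fr$Xinv
  expect_lt(abs(mean(dU)), 0.005)
  expect_lt(abs(sd(as.vector(dU)) - sigma) / sigma, 0.25)
})

test_that("the engaged kernel annihilates the engaged readout submatrix", {
  # single readout (1, 1): kernel is the anti-symmetric direction
  K <- engaged_kernel(matrix(c(1, 1), 1, 2), c(1, 2))
  expect_equal(abs(K), matrix(1 / sqrt(2), 2, 1), tolerance = 1e-12)
  # |E| = Nz: zero-dimensional basis
  K0 <- engaged_kernel(matrix(c(3, 1), 1, 2), 2L)
  expect_equal(dim(K0), c(1L, 0L))
  # generic contract: orthonormal columns, annihilated by Wmu
  set.seed(11)
  W <- matrix(rnorm(12, 0, 10), 1, 12)
  ie <- c(2L, 3L, 7L, 9L, 11L)
  K5 <- engaged_kernel(W, ie)
  expect_equal(dim(K5), c(5L, 4L))
  expect_equal(max(abs(W[, ie, drop = FALSE] %*% K5)), 0, tolerance = 1e-10)
  expect_equal(crossprod(K5), diag(4), tolerance = 1e-10)
  # any engaged activity change in span(K) leaves the readout unchanged
  y <- runif(5, 1, 4)
  dy <- K5 %*% rnorm(4)
  expect_equal(W[, ie] %*% (y + dy), W[, ie] %*% y, tolerance = 1e-10)
  expect_error(engaged_kernel(W, integer(0)), "nonempty")
})
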