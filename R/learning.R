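#' Learning configuration
#'
#' @param lr learning rate (default 0.001).
#' @param max_steps iteration cap for gradient descent.
#' @param tol convergence tolerance on the RMS readout error over the target
#'   conditions. \code{NULL} means the relative default
#'   \code{1e-3 * RMS(Z)} over the targets, the criterion used to call a
#'   mapping successfully learned.
#' @param optimizer \code{"adam"} (adaptive, used for full-scale networks)
#'   or \code{"gd"} (plain gradient descent, used for the two-neuron worked
#'   example where the descent path itself is of interest).
#' @param alloc_sd SD of the allocation draw around \code{alpha/2}.
#' @return object of class \code{learn_config}.
#' @export
learn_config <- function(lr = 0.001, max_steps = 20000L, tol = NULL,
                         optimizer = c("adam", "gd"), alloc_sd = 0.1) {
  optimizer <- match.arg(optimizer)
  stopifnot(lr > 0, max_steps >= 1, is.null(tol) || tol > 0, alloc_sd >= 0)
  structure(list(lr = lr, max_steps = as.integer(max_steps), tol = tol,
                 optimizer = optimizer, alloc_sd = alloc_sd),
            class = "learn_config")
}

.default_tol <- function(cfg, Ztargets) {
  if (!is.null(cfg$tol)) return(cfg$tol)
  1e-3 * sqrt(mean(Ztargets^2))
}

#' Allocate the eta column of a condition into the engaged regime
#'
#' Resamples column \code{mu} of the eta matrix i.i.d.
#' \code{N(alpha/2, alloc_sd)}, placing the input currents of that condition
#' near the center of the engaged regime so that gradients are available for
#' learning. All other columns are untouched, so stored memories are
#' unaffected.
#'
#' @param eta eta-coordinate matrix (\code{Ny x Nx}).
#' @param mu condition column to allocate (\code{<= P}).
#' @param alpha saturation threshold.
#' @param alloc_sd SD of the draw (default 0.1).
#' @return the eta matrix with column \code{mu} resampled.
#' @export
allocate <- function(eta, mu, alpha = 5, alloc_sd = 0.1) {
  eta <- as.matrix(eta)
  stopifnot(mu >= 1, mu <= ncol(eta))
  eta[, mu] <- stats::rnorm(nrow(eta), alpha / 2, alloc_sd)
  eta
}

#' Gradient of the squared readout error with respect to U
#'
#' Hand-coded gradient of \code{sum_mu ||W Phi(U x_mu + b) - z_mu||^2} over
#' the target conditions: \code{dJ2/dU = (t(W) (2 E) * Phi'(C)) t(X)}, where
#' \code{E = Zhat - Z}. Disengaged neurons (current outside the open
#' interval \code{(0, alpha)}) contribute zero.
#'
#' @param U weight matrix.
#' @param task a \code{task_spec}.
#' @param targets integer vector of target conditions.
#' @return list with \code{grad} (\code{Ny x Nx}), \code{err} (residual
#'   matrix), \code{loss} (sum of squared errors).
#' @export
grad_U <- function(U, task, targets) {
  Xt <- task$X[, targets, drop = FALSE]
  Zt <- task$Z[, targets, drop = FALSE]
  C <- U %*% Xt + task$b
  E <- task$W %*% phi(C, task$cfg$alpha) - Zt
  G <- (crossprod(task$W, 2 * E) * phi_deriv(C, task$cfg$alpha)) %*% t(Xt)
  list(grad = G, err = E, loss = sum(E^2))
}

#' Gradient of the squared readout error with respect to one eta column
#'
#' For condition \code{mu}, \code{dJ2/deta_mu = t(W) (2 e_mu) * Phi'(eta_mu
#' + b)}; every other eta column has exactly zero gradient because the error
#' of condition \code{mu} depends only on its own input currents.
#'
#' @param eta eta matrix.
#' @param task a \code{task_spec}.
#' @param mu target condition.
#' @return list with \code{grad} (length-\code{Ny} vector for column
#'   \code{mu}), \code{err}, \code{loss}.
#' @export
grad_eta <- function(eta, task, mu) {
  cur <- eta[, mu] + task$b
  E <- task$W %*% phi(cur, task$cfg$alpha) - task$Z[, mu, drop = FALSE]
  g <- as.vector(crossprod(task$W, 2 * E)) * phi_deriv(cur, task$cfg$alpha)
  list(grad = g, err = E, loss = sum(E^2))
}

.gd_loop <- function(par, gradfun, cfg, tol) {
  # shared optimizer core; par is a matrix or vector
  m <- 0 * par; v <- 0 * par
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  steps <- 0L; converged <- FALSE; loss <- Inf
  for (it in seq_len(cfg$max_steps)) {
    g <- gradfun(par)
    loss <- g$loss
    if (!is.finite(loss) || loss > 1e12)
      stop("gradient descent diverged (loss not finite)")
    rms <- sqrt(loss / length(g$err))
    if (rms <= tol) { converged <- TRUE; steps <- it - 1L; break }
    if (all(g$grad == 0)) { steps <- it - 1L; break }  # vanished gradient
    if (cfg$optimizer == "adam") {
      m <- b1 * m + (1 - b1) * g$grad
      v <- b2 * v + (1 - b2) * g$grad^2
      mh <- m / (1 - b1^it)
      vh <- v / (1 - b2^it)
      par <- par - cfg$lr * mh / (sqrt(vh) + eps)
    } else {
      par <- par - cfg$lr * g$grad
    }
    steps <- it
  }
  list(par = par, loss = loss, steps = steps, converged = converged)
}

#' Gradient-descent learning in weight coordinates
#'
#' Minimizes the summed squared readout error of the target conditions over
#' \code{U}, with the readout weights and biases held fixed. Plain gradient
#' descent or Adam, per the configuration. Stops when the RMS readout error
#' over the targets reaches \code{tol}, when the gradient vanishes (all
#' relevant neurons disengaged), or at \code{max_steps}.
#'
#' @param U initial weight matrix.
#' @param task a \code{task_spec}.
#' @param targets conditions to fit (nonempty).
#' @param cfg a \code{\link{learn_config}}.
#' @return list with \code{U}, and a report: \code{converged},
#'   \code{final_loss}, \code{final_rms}, \code{steps_used}, \code{tol}.
#' @export
learn_gd_U <- function(U, task, targets = seq_len(task$cfg$P),
                       cfg = learn_config()) {
  stopifnot(length(targets) >= 1)
  tol <- .default_tol(cfg, task$Z[, targets, drop = FALSE])
  res <- .gd_loop(as.matrix(U), function(p) grad_U(p, task, targets), cfg, tol)
  nerr <- length(targets) * task$cfg$Nz
  list(U = res$par,
       report = list(converged = res$converged, final_loss = res$loss,
                     final_rms = sqrt(res$loss / nerr),
                     steps_used = res$steps, tol = tol))
}

#' Gradient-descent learning in eta-coordinates
#'
#' Updates only column \code{mu} of the eta matrix by gradient descent on
#' that condition's squared readout error; all other columns are provably
#' untouched, so previously stored mappings suffer exactly zero
#' interference.
#'
#' @param eta initial eta matrix.
#' @param task a \code{task_spec}.
#' @param mu condition to learn (\code{<= P}).
#' @param cfg a \code{\link{learn_config}}.
#' @return list with \code{eta}, and a report as in
#'   \code{\link{learn_gd_U}}.
#' @export
learn_gd_eta <- function(eta, task, mu, cfg = learn_config()) {
  stopifnot(mu >= 1, mu <= task$cfg$P)
  eta <- as.matrix(eta)
  tol <- .default_tol(cfg, task$Z[, mu, drop = FALSE])
  col0 <- eta[, mu]
  tsub <- task
  res <- .gd_loop(col0, function(p) {
    e2 <- eta; e2[, mu] <- p
    g <- grad_eta(e2, tsub, mu)
    list(grad = g$grad, err = g$err, loss = g$loss)
  }, cfg, tol)
  eta[, mu] <- res$par
  list(eta = eta,
       report = list(converged = res$converged, final_loss = res$loss,
                     final_rms = sqrt(res$loss / task$cfg$Nz),
                     steps_used = res$steps, tol = tol))
}

#' Reach the solution space by allocation plus batch learning
#'
#' The standard pipeline used to initialize drift simulations: initialize
#' \code{U} i.i.d. \code{N(0, init_sd)}, allocate every stored condition's
#' eta column into the engaged regime, then fit all stored conditions
#' jointly by gradient descent (Adam by default).
#'
#' @param task a \code{task_spec}.
#' @param init_sd SD of the weight initialization (default 0.1).
#' @param cfg a \code{\link{learn_config}}.
#' @param frame optional \code{\link{eta_frame}} (built from the task
#'   otherwise).
#' @return list with \code{U}, \code{report}, \code{frame}.
#' @export
learn_solution <- function(task, init_sd = 0.1, cfg = learn_config(),
                           frame = NULL) {
  if (is.null(frame)) frame <- build_eta_frame(task$X)
  ncfg <- task$cfg
  U0 <- matrix(stats::rnorm(ncfg$Ny * ncfg$Nx, 0, init_sd), ncfg$Ny, ncfg$Nx)
  eta <- to_eta(U0, frame)
  for (mu in seq_len(ncfg$P))
    eta <- allocate(eta, mu, ncfg$alpha, cfg$alloc_sd)
  fit <- learn_gd_U(from_eta(eta, frame), task, seq_len(ncfg$P), cfg)
  list(U = fit$U, report = fit$report, frame = frame)
}

#' Sequential learnability protocol
#'
#' Measures how many input--readout mappings can be learned one after
#' another as a function of the initial weight scale. For each initial row
#' norm in \code{init_norm_grid} and each seed, weights are initialized
#' i.i.d. \code{N(0, norm / sqrt(Nx))} (expected row norm approximately the
#' grid value) and mappings \code{mu = 1, 2, ...} are added sequentially:
#' optionally allocate the new eta column, then learn. With
#' \code{learner = "eta"} each mapping is fit in its own eta column
#' (interference-free); with \code{learner = "U"} the new mapping is fit by
#' gradient descent on the full weight matrix. A mapping counts as learned
#' when the post-learning RMS readout error over all stored mappings is at
#' or below the success tolerance; the count for a run is the number of
#' mappings added before the first failure.
#'
#' @param ncfg a \code{\link{network_config}}; the protocol stores up to
#'   \code{P} mappings (use \code{P = Nx} for the full-capacity question).
#' @param init_norm_grid numeric vector of initial per-row weight norms.
#' @param use_allocation allocate each new eta column before learning?
#' @param n_seeds replicate seeds per grid point.
#' @param seed base seed (tasks and initializations are derived from it).
#' @param lcfg a \code{\link{learn_config}}.
#' @param learner \code{"eta"} (default) or \code{"U"}.
#' @return object of class \code{learnability_report}: data frame of counts
#'   per (norm, seed) plus a summary with mean and standard error.
#' @export
learnability_protocol <- function(ncfg = network_config(P = 15L),
                                  init_norm_grid = c(1, 25, 100, 350),
                                  use_allocation = FALSE, n_seeds = 5L,
                                  seed = 1L, lcfg = learn_config(),
                                  learner = c("eta", "U")) {
  learner <- match.arg(learner)
  stopifnot(length(init_norm_grid) >= 1)
  rows <- list()
  for (s in seq_len(n_seeds)) {
    task <- generate_task(ncfg, seed = substream_seed(seed, 1000L + s))
    frame <- build_eta_frame(task$X)
    tolv <- .default_tol(lcfg, task$Z)
    # train each mapping to the same pooled success tolerance
    lcfg_s <- lcfg; lcfg_s$tol <- tolv
    for (nn in init_norm_grid) {
      set.seed(substream_seed(seed, 2000L + s))
      U <- matrix(stats::rnorm(ncfg$Ny * ncfg$Nx, 0, nn / sqrt(ncfg$Nx)),
                  ncfg$Ny, ncfg$Nx)
      eta <- to_eta(U, frame)
      count <- 0L
      for (mu in seq_len(ncfg$P)) {
        if (use_allocation)
          eta <- allocate(eta, mu, ncfg$alpha, lcfg$alloc_sd)
        if (learner == "eta") {
          fit <- learn_gd_eta(eta, task, mu, lcfg_s)
          eta <- fit$eta
        } else {
          fit <- learn_gd_U(from_eta(eta, frame), task, mu, lcfg_s)
          eta <- to_eta(fit$U, frame)
        }
        stored <- seq_len(mu)
        zh <- task$W %*% phi(eta[, stored, drop = FALSE] + task$b, ncfg$alpha)
        rms <- sqrt(mean((zh - task$Z[, stored, drop = FALSE])^2))
        if (rms <= tolv) count <- mu else break
      }
      rows[[length(rows) + 1L]] <-
        data.frame(init_norm = nn, seed = s, learned = count)
    }
  }
  detail <- do.call(rbind, rows)
  agg <- stats::aggregate(learned ~ init_norm, detail, function(v)
    c(mean = mean(v), se = stats::sd(v) / sqrt(length(v))))
  summary <- data.frame(init_norm = agg$init_norm,
                        mean_learned = agg$learned[, "mean"],
                        se_learned = agg$learned[, "se"])
  structure(list(detail = detail, summary = summary,
                 use_allocation = use_allocation, learner = learner),
            class = "learnability_report")
}

#' @export
print.learnability_report <- function(x, ...) {
  cat(sprintf("learnability_report (%s-learning, allocation %s):\n",
              x$learner, if (x$use_allocation) "on" else "off"))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
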