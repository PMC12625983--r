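#' Readout robustness to weight perturbations
#'
#' Draws \code{n} perturbation matrices with i.i.d. \code{N(0, rho)} entries,
#' adds each to \code{U}, and collects the signed readout errors
#' \code{W Phi((U + dU) X + B) - Z} across all conditions. No norm-bound
#' clipping is applied to the perturbed weights. Reusing the same
#' \code{seed} pairs the perturbation draws across states, isolating the
#' effect of the state itself.
#'
#' @param U weight matrix to perturb.
#' @param task a \code{task_spec}.
#' @param rho perturbation SD (default 1).
#' @param n number of perturbation samples (default 100).
#' @param seed seed for the perturbation draws.
#' @return list with \code{rms}, \code{errors} (signed errors, length
#'   \code{n * Nz * P}), \code{rho}, \code{n}.
#' @export
robustness_eval <- function(U, task, rho = 1, n = 100L, seed = 1L) {
  stopifnot(n >= 1)
  ncfg <- task$cfg
  set.seed(as.integer(seed))
  errors <- numeric(0)
  if (rho == 0) {
    E <- forward(U, task)$Zhat - task$Z
    errors <- rep(as.vector(E), n)
  } else {
    for (k in seq_len(n)) {
      dU <- matrix(stats::rnorm(ncfg$Ny * ncfg$Nx, 0, rho), ncfg$Ny, ncfg$Nx)
      E <- forward(U + dU, task)$Zhat - task$Z
      errors <- c(errors, as.vector(E))
    }
  }
  list(rms = sqrt(mean(errors^2)), errors = errors, rho = rho, n = as.integer(n))
}

#' Robustness gain from drift across weight-norm bounds
#'
#' For each seed: generate a task, reach the solution space via allocation
#' plus batch learning, and measure the perturbation RMS error before drift;
#' then, for each bound in \code{umax_grid}, drift from that same learned
#' state under the bound and re-measure with the identical perturbation
#' draws. The scaled improvement is
#' \code{(rms_before - rms_after) / rms_before}.
#'
#' @param umax_grid numeric vector of per-row weight-norm bounds.
#' @param ncfg a \code{\link{network_config}}.
#' @param n_seeds replicate seeds.
#' @param seed base seed.
#' @param n_steps drift steps per bound.
#' @param sigma drift step scale.
#' @param rho,n_perturb perturbation SD and sample count.
#' @param lcfg a \code{\link{learn_config}} for the initial learning.
#' @return object of class \code{robustness_report}: \code{detail} data
#'   frame (seed, Umax, rms_before, rms_after, scaled_improvement) and a
#'   \code{summary} of means per bound.
#' @export
robustness_sweep <- function(umax_grid = c(1, 5, 25, 100, 350),
                             ncfg = network_config(), n_seeds = 10L,
                             seed = 1L, n_steps = 10000L, sigma = 0.05,
                             rho = 1, n_perturb = 100L,
                             lcfg = learn_config()) {
  stopifnot(length(umax_grid) >= 1)
  rows <- list()
  for (s in seq_len(n_seeds)) {
    task <- generate_task(ncfg, seed = substream_seed(seed, 100L + s))
    set.seed(substream_seed(seed, 200L + s))
    sol <- learn_solution(task, init_sd = 0.1, cfg = lcfg)
    pseed <- substream_seed(seed, 300L + s)
    before <- robustness_eval(sol$U, task, rho, n_perturb, seed = pseed)
    for (um in umax_grid) {
      st <- drift_state(sol$U, task, frame = sol$frame)
      set.seed(substream_seed(seed, 400L + s))
      traj <- run_drift(st, drift_config(sigma = sigma, Umax = um,
                                         n_steps = n_steps,
                                         record_every = max(1L, n_steps)))
      after <- robustness_eval(weights(traj$state), task, rho, n_perturb,
                               seed = pseed)
      rows[[length(rows) + 1L]] <- data.frame(
        seed = s, Umax = um, rms_before = before$rms, rms_after = after$rms,
        scaled_improvement = (before$rms - after$rms) / before$rms)
    }
  }
  detail <- do.call(rbind, rows)
  summary <- stats::aggregate(
    cbind(rms_before, rms_after, scaled_improvement) ~ Umax, detail, mean)
  structure(list(detail = detail, summary = summary, rho = rho,
                 n_perturb = as.integer(n_perturb)),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat("robustness_report (scaled improvement = (before - after)/before):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Continual-learning interference with and without interleaved drift
#'
#' Starting from large random weights, memories \code{nu = 1..P} are added
#' sequentially: allocate the new eta column, learn the new mapping by
#' gradient descent on the full weight matrix (the new memory's loss only),
#' and optionally drift (constrained to the memories stored so far) before
#' the next addition. After each addition the protocol records, for every
#' previously stored memory \code{mu < nu}, the input-current perturbation
#' caused by the learning step, the change in the stored representation,
#' and the stored memory's readout RMS error. Drift between additions never
#' changes stored readouts, so all recorded interference is attributable to
#' learning. Running both arms with the same \code{seed} pairs the task and
#' allocation randomness.
#'
#' @param ncfg a \code{\link{network_config}}.
#' @param with_drift interleave drift between additions?
#' @param drift_steps drift steps between additions (default 10000).
#' @param sigma drift step scale.
#' @param Umax per-row norm bound during interleaved drift.
#' @param init_sd SD of the large initial weights (default 15).
#' @param seed base seed (shared across arms for pairing).
#' @param lcfg a \code{\link{learn_config}} (Adam by default).
#' @return object of class \code{continual_report}: \code{errors} data
#'   frame (nu, mu, readout_rms), pooled \code{current_perturbation} and
#'   \code{repr_change} samples, and the arm label.
#' @export
continual_experiment <- function(ncfg = network_config(), with_drift = TRUE,
                                 drift_steps = 10000L, sigma = 0.05,
                                 Umax = 350, init_sd = 15, seed = 1L,
                                 lcfg = learn_config()) {
  task <- generate_task(ncfg, seed = substream_seed(seed, 10L))
  frame <- build_eta_frame(task$X)
  set.seed(substream_seed(seed, 20L))
  U <- matrix(stats::rnorm(ncfg$Ny * ncfg$Nx, 0, init_sd), ncfg$Ny, ncfg$Nx)
  eta <- to_eta(U, frame)
  err_rows <- list(); dC_all <- numeric(0); dY_all <- numeric(0)
  for (nu in seq_len(ncfg$P)) {
    set.seed(substream_seed(seed, 30L + nu))
    eta <- allocate(eta, nu, ncfg$alpha, lcfg$alloc_sd)
    U_pre <- from_eta(eta, frame)
    fwd_pre <- forward(U_pre, task)
    fit <- learn_gd_U(U_pre, task, targets = nu, cfg = lcfg)
    eta <- to_eta(fit$U, frame)
    fwd_post <- forward(fit$U, task)
    if (nu > 1L) {
      stored <- seq_len(nu - 1L)
      dC_all <- c(dC_all, as.vector(fwd_post$C[, stored] - fwd_pre$C[, stored]))
      dY_all <- c(dY_all, as.vector(fwd_post$Y[, stored] - fwd_pre$Y[, stored]))
      for (mu in stored) {
        rms <- sqrt(mean((fwd_post$Zhat[, mu] - task$Z[, mu])^2))
        err_rows[[length(err_rows) + 1L]] <-
          data.frame(nu = nu, mu = mu, readout_rms = rms)
      }
    }
    if (with_drift && nu < ncfg$P && drift_steps > 0L) {
      st <- drift_state(from_eta(eta, frame), task, learned = seq_len(nu),
                        frame = frame)
      set.seed(substream_seed(seed, 60L + nu))
      traj <- run_drift(st, drift_config(sigma = sigma, Umax = Umax,
                                         n_steps = drift_steps,
                                         record_every = max(1L, drift_steps)))
      eta <- traj$state$eta
    }
  }
  structure(list(errors = do.call(rbind, err_rows),
                 current_perturbation = dC_all, repr_change = dY_all,
                 arm = if (with_drift) "with_drift" else "without_drift",
                 seed = as.integer(seed)),
            class = "continual_report")
}

#' @export
print.continual_report <- function(x, ...) {
  cat(sprintf("continual_report (%s): %d stored-memory evaluations\n",
              x$arm, nrow(x$errors)))
  cat(sprintf("  current perturbation RMS %.3g | repr change RMS %.3g | mean readout RMS %.3g\n",
              sqrt(mean(x$current_perturbation^2)),
              sqrt(mean(x$repr_change^2)), mean(x$errors$readout_rms)))
  invisible(x)
}

#' Engagement statistics of a drift trajectory
#'
#' Per recorded time: fractions of engaged, inactive and saturated
#' (neuron, condition) pairs pooled over the stored conditions, plus
#' per-condition engaged-set membership rasters recomputed from the
#' recorded eta snapshots.
#'
#' @param traj a \code{drift_trajectory}.
#' @return list with \code{fractions} (data frame: time, inactive, engaged,
#'   saturated) and \code{raster} (logical array n_times x Ny x
#'   n_stored: engaged membership).
#' @export
engagement_stats <- function(traj) {
  stopifnot(inherits(traj, "drift_trajectory"))
  learned <- traj$state$learned
  task <- traj$state$task
  n_rec <- length(traj$times)
  fr <- data.frame(time = traj$times,
                   inactive = traj$fractions[, "inactive"],
                   engaged = traj$fractions[, "engaged"],
                   saturated = traj$fractions[, "saturated"])
  raster <- array(NA, c(n_rec, nrow(traj$etas), length(learned)))
  for (k in seq_len(n_rec)) {
    C <- matrix(traj$etas[, learned, k], nrow(traj$etas), length(learned)) +
      task$b
    raster[k, , ] <- C > 0 & C < task$cfg$alpha
  }
  list(fractions = fr, raster = raster)
}

#' The two-neuron worked-example task
#'
#' Two inputs, two representation neurons, one readout with fixed weights
#' \code{w = (1, 1)}, zero bias, saturation threshold 5, and two mappings:
#' input \code{(1, -1)} must read out 4 and input \code{(-0.5, 1)} must
#' read out 2. With \code{P = Nx = 2} the extended basis is the input
#' matrix itself.
#'
#' @return a \code{task_spec}.
#' @export
toy_task <- function() {
  task_spec(X = matrix(c(1, -1, -0.5, 1), 2, 2),
            W = matrix(c(1, 1), 1, 2),
            Z = matrix(c(4, 2), 1, 2), alpha = 5)
}

#' Allocation / learning / drift transcript on the two-neuron example
#'
#' Runs the full continual pipeline on \code{\link{toy_task}}: allocate the
#' first mapping's eta column at the densely engaged point \code{(4, 4)},
#' learn it by plain gradient descent in eta-coordinates (converging onto
#' the solution line through \code{(2, 2)}), drift with exploration
#' constrained to the first mapping's solution space, allocate the second
#' column, and learn the second mapping in its own eta column. Emits all
#' intermediate eta states and readouts.
#'
#' @param alloc1,alloc2 allocation points for the two eta columns.
#' @param drift_steps drift steps between the two memories.
#' @param sigma drift step scale.
#' @param lr plain-GD learning rate.
#' @param tol RMS convergence tolerance of the learners.
#' @param seed seed for the drift randomness.
#' @return list of class \code{toy_transcript} with the eta matrix after
#'   every stage, the final readouts, the learning reports, and
#'   \code{max_change_col1_during_learn2} (computed from the recorded
#'   states; exactly 0 by the eta-learning locality).
#' @export
toy_demo <- function(alloc1 = c(4, 4), alloc2 = c(4, 4), drift_steps = 2000L,
                     sigma = 0.05, lr = 0.05, tol = 1e-5, seed = 1L) {
  task <- toy_task()
  frame <- build_eta_frame(task$X)
  lcfg <- learn_config(lr = lr, tol = tol, optimizer = "gd")
  eta0 <- matrix(0, 2, 2)
  eta_a1 <- eta0; eta_a1[, 1] <- alloc1
  fit1 <- learn_gd_eta(eta_a1, task, 1L, lcfg)
  eta_l1 <- fit1$eta
  st <- drift_state(from_eta(eta_l1, frame), task, learned = 1L, frame = frame)
  set.seed(as.integer(seed))
  traj <- run_drift(st, drift_config(sigma = sigma, n_steps = drift_steps,
                                     record_every = max(1L, drift_steps)))
  eta_d <- traj$state$eta
  eta_a2 <- eta_d; eta_a2[, 2] <- alloc2
  fit2 <- learn_gd_eta(eta_a2, task, 2L, lcfg)
  eta_l2 <- fit2$eta
  zhat <- task$W %*% phi(eta_l2 + task$b, task$cfg$alpha)
  structure(list(task = task, frame = frame,
                 eta_start = eta0, eta_after_alloc1 = eta_a1,
                 eta_after_learn1 = eta_l1, eta_after_drift = eta_d,
                 eta_after_alloc2 = eta_a2, eta_after_learn2 = eta_l2,
                 readouts = as.vector(zhat),
                 report1 = fit1$report, report2 = fit2$report,
                 max_change_col1_during_learn2 =
                   max(abs(eta_l2[, 1] - eta_a2[, 1]))),
            class = "toy_transcript")
}

#' @export
print.toy_transcript <- function(x, ...) {
  cat("two-neuron worked example:\n")
  cat(sprintf("  eta column 1 after learning: (%.4f, %.4f)\n",
              x$eta_after_learn1[1, 1], x$eta_after_learn1[2, 1]))
  cat(sprintf("  final readouts: (%.4f, %.4f)  [targets (4, 2)]\n",
              x$readouts[1], x$readouts[2]))
  cat(sprintf("  change in stored column during second learning: %g\n",
              x$max_change_col1_during_learn2))
  invisible(x)
}
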