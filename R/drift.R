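#' Drift configuration
#'
#' @param sigma scale (SD, weight units) of the per-step weight
#'   fluctuations. Eta increments are drawn with per-column SDs
#'   \code{sigma * s_mu} (see \code{\link{noise_scales}}).
#' @param Umax per-postsynaptic-neuron bound on the Euclidean norm of the
#'   incoming weight row; \code{Inf} disables the bound.
#' @param n_steps number of drift steps.
#' @param record_every recording cadence (steps).
#' @param cons_tol permitted cumulative change of the stored readouts over a
#'   run; a recorded violation aborts with a diagnostic.
#' @param track_dU if \code{TRUE}, accumulate running mean/SD statistics of
#'   the pooled physical weight increments \code{delta U} over the run.
#' @return object of class \code{drift_config}.
#' @export
drift_config <- function(sigma = 0.05, Umax = Inf, n_steps = 50000L,
                         record_every = 100L, cons_tol = 1e-6,
                         track_dU = FALSE) {
  stopifnot(sigma > 0, Umax > 0, n_steps >= 0, record_every >= 1)
  structure(list(sigma = sigma, Umax = Umax, n_steps = as.integer(n_steps),
                 record_every = as.integer(record_every), cons_tol = cons_tol,
                 track_dU = isTRUE(track_dU)),
            class = "drift_config")
}

#' Drifting network state
#'
#' Bundles the eta-coordinates of the weights, the engagement labels of the
#' stored (learned) conditions, the eta frame and the task. The labels of
#' learned columns evolve statefully during drift: a neuron clamped at a
#' threshold by a transition sits exactly at the boundary under its new
#' label and participates in the next step as such.
#'
#' @param U weight matrix (\code{Ny x Nx}).
#' @param task a \code{task_spec}.
#' @param learned integer vector of stored condition columns (subset of
#'   \code{1..P}) whose readouts drift must preserve.
#' @param frame optional \code{\link{eta_frame}}; built from \code{task$X}
#'   when omitted.
#' @return object of class \code{drift_state} with elements \code{eta},
#'   \code{labels}, \code{learned}, \code{frame}, \code{task}.
#' @export
drift_state <- function(U, task, learned = seq_len(task$cfg$P), frame = NULL) {
  stopifnot(inherits(task, "task_spec"))
  if (is.null(frame)) frame <- build_eta_frame(task$X)
  eta <- to_eta(as.matrix(U), frame)
  P <- task$cfg$P
  labels <- if (P > 0L) {
    partition_neurons(eta[, seq_len(P), drop = FALSE] + task$b, task$cfg$alpha)
  } else matrix(integer(0), task$cfg$Ny, 0L)
  kc <- new.env(parent = emptyenv())
  structure(list(eta = eta, labels = labels, learned = as.integer(learned),
                 frame = frame, task = task, kcache = kc,
                 kkeys = sprintf("m%d", seq_len(frame$Nx))),
            class = "drift_state")
}

#' @export
print.drift_state <- function(x, ...) {
  cat(sprintf("drift_state: Ny=%d Nx=%d, %d stored condition(s)\n",
              nrow(x$eta), ncol(x$eta), length(x$learned)))
  if (length(x$learned)) {
    fr <- partition_fractions(x$labels[, x$learned, drop = FALSE])
    cat(sprintf("  engaged %.2f | inactive %.2f | saturated %.2f\n",
                fr["engaged"], fr["inactive"], fr["saturated"]))
  }
  invisible(x)
}

#' Weight matrix of a drift state
#' @param state a \code{drift_state}.
#' @return the \code{Ny x Nx} weight matrix \code{U = eta Xinv}.
#' @export
weights <- function(state) from_eta(state$eta, state$frame)

#' Rescale a kernel drift proposal to the nearest threshold
#'
#' Given the engaged currents of one condition and a proposed increment
#' (already in the kernel of the engaged readout submatrix), finds the
#' largest \code{gamma} in \code{[0, 1]} such that all currents
#' \code{current + gamma * delta} remain inside \code{[0, alpha]}. Neurons
#' whose current sits exactly at a bound at that \code{gamma} are reported
#' as crossers (several can tie; all transition), together with the set they
#' move to. When no bound is hit, \code{gamma = 1} with no crossers.
#'
#' @param current engaged input currents (inside \code{[0, alpha]}).
#' @param delta proposed current increments, same length.
#' @param alpha saturation threshold.
#' @return list with \code{gamma}, integer \code{crossers} (positions into
#'   \code{current}), and \code{to} (1 = inactive, 3 = saturated per
#'   crosser).
#' @export
rescale_to_threshold <- function(current, delta, alpha = 5) {
  stopifnot(length(current) == length(delta))
  g <- rep(Inf, length(delta))
  up <- delta > 0
  dn <- delta < 0
  g[up] <- (alpha - current[up]) / delta[up]
  g[dn] <- -current[dn] / delta[dn]
  graw <- if (length(g)) min(g) else Inf
  if (!is.finite(graw) || graw > 1)
    return(list(gamma = 1, crossers = integer(0), to = integer(0)))
  gamma <- max(0, graw)
  crossers <- which(g <= graw + 1e-12 * max(1, gamma))
  list(gamma = gamma, crossers = crossers,
       to = ifelse(delta[crossers] > 0, 3L, 1L))
}

#' Per-row weight-norm bound as a rejection boundary
#'
#' Rows of \code{U = eta Xinv} whose Euclidean norm exceeds \code{Umax} are
#' fully reverted to their previous-step values; rows within the bound keep
#' the candidate. This implements a reflecting (rejection) boundary for the
#' diffusion. \code{\link{drift_step}} additionally reverts the whole
#' engaged-block update of any stored condition in which a rejected row took
#' part, so that the accepted update stays inside the readout kernel.
#'
#' @param candidate_eta proposed eta matrix.
#' @param previous_eta eta matrix before the step (same frame).
#' @param frame the shared \code{\link{eta_frame}}.
#' @param Umax per-row norm bound; \code{Inf} is the identity operation.
#' @return the enforced eta matrix, with integer attribute \code{"rejected"}
#'   listing the reverted rows.
#' @export
enforce_norm_bound <- function(candidate_eta, previous_eta, frame, Umax) {
  if (!is.finite(Umax)) {
    attr(candidate_eta, "rejected") <- integer(0)
    return(candidate_eta)
  }
  U <- candidate_eta %*% frame$Xinv
  viol <- which(rowSums(U^2) > Umax^2 * (1 + 1e-12))
  if (length(viol))
    candidate_eta[viol, ] <- previous_eta[viol, , drop = FALSE]
  attr(candidate_eta, "rejected") <- viol
  candidate_eta
}

.kernel_cached <- function(state, mu, ie) {
  key <- state$kkeys[mu]
  ent <- state$kcache[[key]]
  if (!is.null(ent) && identical(ent$ie, ie)) return(ent$K)
  K <- engaged_kernel(state$task$W, ie)
  state$kcache[[key]] <- list(ie = ie, K = K)
  K
}

#' One restricted-diffusion drift step
#'
#' Combines the four increment types: (a) free i.i.d. increments for the
#' unconstrained columns (completion columns and stored-range columns not
#' yet learned); (b) one-sided increments for inactive coordinates of stored
#' conditions, clamped exactly at the zero-current bound with an
#' inactive-to-engaged transition when the proposal would cross; (c) the
#' symmetric rule for saturated coordinates at \code{alpha}; (d) for engaged
#' coordinates, a random combination of the kernel basis of the engaged
#' readout submatrix, rescaled via \code{\link{rescale_to_threshold}} so no
#' engaged neuron crosses a threshold, with crossers transitioning out of
#' the engaged set. Set membership is taken from the labels at the start of
#' the step. Finally the per-row weight-norm bound is enforced as a
#' rejection boundary (see \code{\link{enforce_norm_bound}}), cascading to
#' the engaged blocks the rejected rows took part in.
#'
#' The realized readouts of the stored conditions are unchanged by the step
#' up to floating-point error.
#'
#' @param state a \code{\link{drift_state}}.
#' @param cfg a \code{\link{drift_config}}.
#' @param detail if \code{TRUE} (default), attach the full transition table;
#'   the trajectory runner switches it off and uses the counter only.
#' @return the updated state, with attribute \code{"info"}: a list with
#'   \code{n_transitions}, \code{rejected_rows}, and (when \code{detail})
#'   \code{transitions}, a matrix with columns neuron, condition, from, to.
#' @export
drift_step <- function(state, cfg, detail = TRUE) {
  frame <- state$frame; task <- state$task
  eta0 <- state$eta; lab0 <- state$labels
  Ny <- nrow(eta0); Nx <- frame$Nx
  alpha <- task$cfg$alpha; Nz <- task$cfg$Nz
  b <- task$b
  sds <- cfg$sigma * frame$scales
  learned <- state$learned
  eta <- eta0; lab <- lab0

  free_cols <- setdiff(seq_len(Nx), learned)
  if (length(free_cols)) {
    eta[, free_cols] <- eta[, free_cols] +
      matrix(rnorm(Ny * length(free_cols)), Ny) *
        rep(sds[free_cols], each = Ny)
  }

  eng_sets <- vector("list", Nx)
  eng_updated <- logical(Nx)
  for (mu in learned) {
    l0 <- lab0[, mu]
    smu <- sds[mu]
    ii <- which(l0 == 1L)
    if (length(ii)) {
      newv <- eta0[ii, mu] + rnorm(length(ii)) * smu
      eta[ii, mu] <- newv
      nc <- ii[newv + b[ii] > 0]
      if (length(nc)) { eta[nc, mu] <- -b[nc]; lab[nc, mu] <- 2L }
    }
    is_ <- which(l0 == 3L)
    if (length(is_)) {
      newv <- eta0[is_, mu] + rnorm(length(is_)) * smu
      eta[is_, mu] <- newv
      nc <- is_[newv + b[is_] < alpha]
      if (length(nc)) { eta[nc, mu] <- alpha - b[nc]; lab[nc, mu] <- 2L }
    }
    ie <- which(l0 == 2L)
    ne <- length(ie)
    if (ne > Nz) {
      K <- .kernel_cached(state, mu, ie)
      d <- as.vector(K %*% (rnorm(ne - Nz) * smu))
      rs <- rescale_to_threshold(eta0[ie, mu] + b[ie], d, alpha)
      eta[ie, mu] <- eta0[ie, mu] + rs$gamma * d
      if (length(rs$crossers)) {
        ic <- ie[rs$crossers]
        eta[ic, mu] <- ifelse(rs$to == 1L, -b[ic], alpha - b[ic])
        lab[ic, mu] <- rs$to
      }
      eng_sets[[mu]] <- ie
      eng_updated[mu] <- TRUE
    }
  }

  rejected <- integer(0)
  if (is.finite(cfg$Umax)) {
    repeat {
      U <- eta %*% frame$Xinv
      viol <- setdiff(which(rowSums(U * U) > cfg$Umax^2 * (1 + 1e-12)),
                      rejected)
      if (!length(viol)) break
      rejected <- c(rejected, viol)
      eta[viol, ] <- eta0[viol, , drop = FALSE]
      if (ncol(lab)) lab[viol, ] <- lab0[viol, , drop = FALSE]
      for (mu in learned) {
        if (eng_updated[mu] && any(eng_sets[[mu]] %in% viol)) {
          ie <- eng_sets[[mu]]
          eta[ie, mu] <- eta0[ie, mu]
          lab[ie, mu] <- lab0[ie, mu]
          eng_updated[mu] <- FALSE
        }
      }
    }
  }

  n_trans <- sum(lab != lab0)
  info <- list(n_transitions = n_trans, rejected_rows = sort(rejected))
  if (detail) {
    chg <- which(lab != lab0)
    info$transitions <- if (length(chg)) {
      cbind(neuron = (chg - 1L) %% Ny + 1L,
            condition = (chg - 1L) %/% Ny + 1L,
            from = lab0[chg], to = lab[chg])
    } else matrix(integer(0), 0L, 4L,
                  dimnames = list(NULL, c("neuron", "condition", "from", "to")))
  }

  state$eta <- eta
  state$labels <- lab
  attr(state, "info") <- info
  state
}

#' Run a drift trajectory
#'
#' Iterates \code{\link{drift_step}}, recording snapshots every
#' \code{record_every} steps (plus the initial and final state). At every
#' recorded time the stored-condition readouts are compared with their
#' values at step 0; a cumulative change beyond \code{cfg$cons_tol} aborts
#' with a diagnostic, since it would indicate leaving the solution space.
#'
#' @param state a \code{\link{drift_state}} whose stored conditions satisfy
#'   their readout constraints.
#' @param cfg a \code{\link{drift_config}}.
#' @param engine \code{"cpp"} (default; compiled runner) or \code{"r"}
#'   (reference implementation iterating \code{\link{drift_step}}). The two
#'   engines implement identical update rules; the compiled runner exists
#'   because trajectories of tens of thousands of steps are routine.
#' @return object of class \code{drift_trajectory}: list with \code{times},
#'   \code{etas} (Ny x Nx x n_rec array), \code{fractions} (n_rec x 3,
#'   pooled over stored conditions), \code{row_norms} (n_rec x Ny),
#'   \code{readout_error} (max abs error vs. targets per time),
#'   \code{zhat_drift} (max cumulative readout change per time),
#'   \code{transition_count}, \code{dU_stats} (if tracked), \code{state}
#'   (final), \code{cfg}.
#' @export
run_drift <- function(state, cfg = drift_config(), engine = c("cpp", "r")) {
  stopifnot(inherits(state, "drift_state"), inherits(cfg, "drift_config"))
  engine <- match.arg(engine)
  task <- state$task; frame <- state$frame
  Ny <- nrow(state$eta)
  learned <- state$learned
  rec_steps <- sort(unique(c(0L, seq.int(0L, cfg$n_steps, by = cfg$record_every),
                             cfg$n_steps)))
  if (engine == "cpp") return(.run_drift_cpp(state, cfg, rec_steps))
  rec_at <- logical(max(cfg$n_steps, 1L))
  rec_at[rec_steps[rec_steps > 0L]] <- TRUE
  n_rec <- length(rec_steps)
  etas <- array(NA_real_, c(Ny, frame$Nx, n_rec))
  fractions <- matrix(NA_real_, n_rec, 3L,
                      dimnames = list(NULL, c("inactive", "engaged", "saturated")))
  row_norms <- matrix(NA_real_, n_rec, Ny)
  readout_error <- numeric(n_rec)
  zhat_drift <- numeric(n_rec)
  n_transitions <- 0L

  zhat_of <- function(eta) {
    if (!length(learned)) return(matrix(0, task$cfg$Nz, 0L))
    task$W %*% phi(eta[, learned, drop = FALSE] + task$b, task$cfg$alpha)
  }
  zhat0 <- zhat_of(state$eta)

  dU_n <- 0; dU_sum <- 0; dU_sumsq <- 0
  U_prev <- if (cfg$track_dU) from_eta(state$eta, frame) else NULL

  record <- function(k, st) {
    etas[, , k] <<- st$eta
    fractions[k, ] <<- if (length(learned)) {
      partition_fractions(st$labels[, learned, drop = FALSE])
    } else {
      P <- task$cfg$P
      if (P > 0L)
        partition_fractions(partition_neurons(
          st$eta[, seq_len(P), drop = FALSE] + task$b, task$cfg$alpha))
      else c(inactive = NA_real_, engaged = NA_real_, saturated = NA_real_)
    }
    U <- from_eta(st$eta, frame)
    row_norms[k, ] <<- sqrt(rowSums(U^2))
    zh <- zhat_of(st$eta)
    readout_error[k] <<- if (length(learned))
      max(abs(zh - task$Z[, learned, drop = FALSE])) else 0
    zhat_drift[k] <<- if (length(learned)) max(abs(zh - zhat0)) else 0
  }

  k <- 1L
  record(k, state)
  if (cfg$n_steps > 0L) {
    for (step in seq_len(cfg$n_steps)) {
      state <- drift_step(state, cfg, detail = FALSE)
      info <- attr(state, "info")
      n_transitions <- n_transitions + info$n_transitions
      if (cfg$track_dU) {
        U_now <- from_eta(state$eta, frame)
        dU <- U_now - U_prev
        dU_n <- dU_n + length(dU)
        dU_sum <- dU_sum + sum(dU)
        dU_sumsq <- dU_sumsq + sum(dU * dU)
        U_prev <- U_now
      }
      if (rec_at[step]) {
        k <- k + 1L
        record(k, state)
        if (zhat_drift[k] > cfg$cons_tol)
          stop(sprintf(paste0("readout conservation violated at step %d: ",
                              "cumulative readout change %.3g > %.3g"),
                       step, zhat_drift[k], cfg$cons_tol))
      }
    }
  }

  dU_stats <- if (cfg$track_dU && dU_n > 0) {
    m <- dU_sum / dU_n
    list(n = dU_n, mean = m, sd = sqrt(max(dU_sumsq / dU_n - m^2, 0)))
  } else NULL

  structure(list(times = rec_steps, etas = etas, fractions = fractions,
                 row_norms = row_norms, readout_error = readout_error,
                 zhat_drift = zhat_drift, transition_count = n_transitions,
                 dU_stats = dU_stats, state = state, cfg = cfg),
            class = "drift_trajectory")
}

.run_drift_cpp <- function(state, cfg, rec_steps) {
  task <- state$task; frame <- state$frame
  learned <- state$learned
  rec_pos <- rec_steps[rec_steps > 0L]
  Zl <- if (length(learned)) task$Z[, learned, drop = FALSE]
        else matrix(0, task$cfg$Nz, 0L)
  lab <- state$labels
  storage.mode(lab) <- "integer"
  res <- .drift_run_cpp(state$eta, lab, as.integer(learned),
                        frame$Xinv, frame$scales, task$W, task$b, Zl,
                        task$cfg$alpha, cfg$sigma, cfg$Umax, cfg$n_steps,
                        as.integer(rec_pos), cfg$cons_tol, cfg$track_dU)
  state$eta <- res$eta
  labels <- res$labels
  if (ncol(state$labels)) {
    labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
    class(labels) <- c("engagement_partition", "matrix")
  } else labels <- state$labels
  state$labels <- labels
  fractions <- res$fractions
  colnames(fractions) <- c("inactive", "engaged", "saturated")
  if (!length(learned)) {
    # pooled fractions over the stored range are undefined without stored
    # conditions; report the instantaneous classification instead
    P <- task$cfg$P
    for (k in seq_len(dim(res$snaps)[3])) {
      fractions[k, ] <- if (P > 0L)
        partition_fractions(partition_neurons(
          res$snaps[, seq_len(P), k, drop = FALSE] + task$b, task$cfg$alpha))
      else NA_real_
    }
  }
  dU_stats <- if (cfg$track_dU && res$dU_n > 0) {
    m <- res$dU_sum / res$dU_n
    list(n = res$dU_n, mean = m,
         sd = sqrt(max(res$dU_sumsq / res$dU_n - m^2, 0)))
  } else NULL
  structure(list(times = rec_steps, etas = res$snaps, fractions = fractions,
                 row_norms = res$row_norms,
                 readout_error = as.vector(res$readout_error),
                 zhat_drift = as.vector(res$zhat_drift),
                 transition_count = res$n_transitions,
                 dU_stats = dU_stats, state = state, cfg = cfg),
            class = "drift_trajectory")
}

#' @export
print.drift_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("drift_trajectory: %d steps, %d records\n", max(x$times), n))
  cat(sprintf("  engaged fraction: %.3f (start) -> %.3f (end)\n",
              x$fractions[1, "engaged"], x$fractions[n, "engaged"]))
  cat(sprintf("  max cumulative readout change: %.3g\n", max(x$zhat_drift)))
  invisible(x)
}
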