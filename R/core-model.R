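#' Network configuration
#'
#' Bundle of the architectural parameters of the drifting network: sizes of
#' the input, representation and readout layers, the number of stored input
#' conditions, and the saturation threshold of the activation function.
#' Defaults are the standard simulation sizes used throughout the package.
#'
#' @param Nx number of input neurons.
#' @param Ny number of representation-layer neurons.
#' @param Nz number of readout dimensions.
#' @param P number of input conditions (must not exceed \code{Nx}; the
#'   eta-coordinate construction requires the inputs to leave free directions
#'   in weight space).
#' @param alpha saturation threshold of the clipped-threshold-linear
#'   activation (activity units, > 0). The activity threshold is fixed at 0.
#' @return an object of class \code{network_config}.
#' @export
network_config <- function(Nx = 15L, Ny = 12L, Nz = 1L, P = 8L, alpha = 5) {
  Nx <- as.integer(Nx); Ny <- as.integer(Ny); Nz <- as.integer(Nz)
  P <- as.integer(P)
  stopifnot(Nx >= 1L, Ny >= 1L, Nz >= 1L, P >= 0L)
  if (Nz > Ny) stop("Nz must not exceed Ny")
  if (P > Nx) stop("P must not exceed Nx (solution-space construction assumes P <= Nx)")
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be positive and finite")
  structure(list(Nx = Nx, Ny = Ny, Nz = Nz, P = P, alpha = alpha),
            class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("network_config: Nx=%d Ny=%d Nz=%d P=%d alpha=%g\n",
              x$Nx, x$Ny, x$Nz, x$P, x$alpha))
  invisible(x)
}

#' Clipped-threshold-linear activation
#'
#' \code{phi(v) = 0} for \code{v <= 0}, \code{v} for \code{0 < v < alpha},
#' and \code{alpha} for \code{v >= alpha}. Applied elementwise.
#'
#' @param v input currents (numeric scalar, vector or matrix).
#' @param alpha saturation threshold (> 0).
#' @return activities with the same shape as \code{v}.
#' @export
phi <- function(v, alpha = 5) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be positive and finite")
  if (any(!is.finite(v))) stop("non-finite input current")
  pmin(pmax(v, 0), alpha)
}

#' Derivative of the clipped-threshold-linear activation
#'
#' 1 strictly inside the linear regime \code{(0, alpha)} and 0 elsewhere.
#' The derivative at exactly 0 and exactly \code{alpha} is taken as 0 (the
#' disengaged side), so neurons clamped at a threshold contribute no
#' gradient.
#'
#' @inheritParams phi
#' @return elementwise slope, same shape as \code{v}.
#' @export
phi_deriv <- function(v, alpha = 5) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be positive and finite")
  if (any(!is.finite(v))) stop("non-finite input current")
  out <- (v > 0 & v < alpha) * 1
  if (is.matrix(v)) dim(out) <- dim(v)
  out
}

#' Generate a random teacher-defined task
#'
#' Draws an input matrix \code{X} (\code{Nx x P}, i.i.d. N(0, 1)), a fixed
#' readout matrix \code{W} (\code{Nz x Ny}, i.i.d. N(0, 10)), a teacher
#' weight matrix \code{T} (\code{Ny x Nx}, i.i.d. N(0, teacher_sd)), and
#' target readouts \code{Z = W Phi(T X + B)}. The second argument of every
#' N(mean, s) here is a standard deviation. If the sampled \code{X} is
#' column-rank-deficient it is resampled with a warning.
#'
#' @param cfg a \code{\link{network_config}}.
#' @param seed integer seed; the task is reproducible given \code{seed}.
#' @param teacher_sd SD of the teacher weight entries (default 1).
#' @param b bias vector of length \code{Ny} (default zero).
#' @return an object of class \code{task_spec} with elements \code{X},
#'   \code{W}, \code{Z}, \code{T}, \code{b}, \code{cfg}, \code{seed}.
#' @export
generate_task <- function(cfg = network_config(), seed = 1L, teacher_sd = 1,
                          b = NULL) {
  stopifnot(inherits(cfg, "network_config"))
  if (is.null(b)) b <- rep(0, cfg$Ny)
  stopifnot(length(b) == cfg$Ny)
  set.seed(as.integer(seed))
  X <- matrix(stats::rnorm(cfg$Nx * cfg$P, 0, 1), cfg$Nx, cfg$P)
  tries <- 0L
  while (cfg$P > 0L && qr(X)$rank < cfg$P) {
    warning("rank-deficient input matrix X; resampling")
    X <- matrix(stats::rnorm(cfg$Nx * cfg$P, 0, 1), cfg$Nx, cfg$P)
    tries <- tries + 1L
    if (tries > 100L) stop("could not sample a full-column-rank X")
  }
  W <- matrix(stats::rnorm(cfg$Nz * cfg$Ny, 0, 10), cfg$Nz, cfg$Ny)
  Tw <- matrix(stats::rnorm(cfg$Ny * cfg$Nx, 0, teacher_sd), cfg$Ny, cfg$Nx)
  Z <- W %*% phi(Tw %*% X + b, cfg$alpha)
  structure(list(X = X, W = W, Z = Z, T = Tw, b = b, cfg = cfg,
                 seed = as.integer(seed)),
            class = "task_spec")
}

#' Construct a task from explicit matrices
#'
#' Builds a \code{task_spec} without a teacher, from user-supplied inputs,
#' readout weights and target readouts.
#'
#' @param X input matrix (\code{Nx x P}), full column rank.
#' @param W readout matrix (\code{Nz x Ny}).
#' @param Z target readout matrix (\code{Nz x P}).
#' @param alpha saturation threshold.
#' @param b bias vector of length \code{Ny} (default zero).
#' @return a \code{task_spec}.
#' @export
task_spec <- function(X, W, Z, alpha = 5, b = NULL) {
  X <- as.matrix(X); W <- as.matrix(W); Z <- as.matrix(Z)
  cfg <- network_config(Nx = nrow(X), Ny = ncol(W), Nz = nrow(W),
                        P = ncol(X), alpha = alpha)
  if (ncol(Z) != cfg$P || nrow(Z) != cfg$Nz) stop("Z has inconsistent shape")
  if (qr(X)$rank < cfg$P) stop("X must have full column rank")
  if (is.null(b)) b <- rep(0, cfg$Ny)
  stopifnot(length(b) == cfg$Ny)
  structure(list(X = X, W = W, Z = Z, T = NULL, b = b, cfg = cfg, seed = NA_integer_),
            class = "task_spec")
}

#' @export
print.task_spec <- function(x, ...) {
  cat(sprintf("task_spec: Nx=%d Ny=%d Nz=%d P=%d alpha=%g%s\n",
              x$cfg$Nx, x$cfg$Ny, x$cfg$Nz, x$cfg$P, x$cfg$alpha,
              if (is.null(x$T)) " (explicit targets)" else " (teacher-defined)"))
  invisible(x)
}

#' Forward pass of the network
#'
#' Computes input currents \code{C = U X + B}, activities
#' \code{Y = Phi(C)}, and realized readouts \code{Zhat = W Y}.
#'
#' @param U synaptic weight matrix (\code{Ny x Nx}).
#' @param task a \code{task_spec}.
#' @return a list with matrices \code{C} (\code{Ny x P}), \code{Y}
#'   (\code{Ny x P}) and \code{Zhat} (\code{Nz x P}).
#' @export
forward <- function(U, task) {
  stopifnot(inherits(task, "task_spec"))
  U <- as.matrix(U)
  if (nrow(U) != task$cfg$Ny || ncol(U) != task$cfg$Nx)
    stop("U has inconsistent shape")
  C <- U %*% task$X + task$b
  Y <- phi(C, task$cfg$alpha)
  list(C = C, Y = Y, Zhat = task$W %*% Y)
}

#' Classify neurons as engaged, inactive or saturated
#'
#' For each (neuron, condition) pair, labels the neuron by where its input
#' current sits relative to the activity threshold 0 and the saturation
#' threshold \code{alpha}: strictly below 0 is inactive, strictly above
#' \code{alpha} is saturated, strictly between is engaged. A current exactly
#' at a threshold is assigned to the adjacent disengaged set (the stateful
#' transition rules during drift can place a just-transitioned neuron at a
#' boundary with the engaged label instead).
#'
#' @param C input-current matrix (\code{Ny x P}).
#' @param alpha saturation threshold.
#' @return integer matrix of the same shape with values 1 (inactive),
#'   2 (engaged), 3 (saturated); class \code{engagement_partition}.
#' @export
partition_neurons <- function(C, alpha = 5) {
  if (any(!is.finite(C))) stop("non-finite input current")
  lab <- matrix(2L, nrow(C), ncol(C))
  lab[C <= 0] <- 1L
  lab[C >= alpha] <- 3L
  structure(lab, class = c("engagement_partition", "matrix"))
}

#' Engagement-set fractions of a partition
#'
#' @param labels an integer label matrix as returned by
#'   \code{\link{partition_neurons}} (1 inactive, 2 engaged, 3 saturated).
#' @return named numeric vector with the fractions of inactive, engaged and
#'   saturated (neuron, condition) pairs; sums to 1.
#' @export
partition_fractions <- function(labels) {
  n <- length(labels)
  c(inactive  = sum(labels == 1L) / n,
    engaged   = sum(labels == 2L) / n,
    saturated = sum(labels == 3L) / n)
}
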