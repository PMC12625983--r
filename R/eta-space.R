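#' Build the extended input basis and eta-coordinate frame
#'
#' Extends the input matrix \code{X} (\code{Nx x P}, full column rank) to an
#' invertible \code{Nx x Nx} basis \code{Xext = [X | Q]} whose last
#' \code{Nx - P} columns \code{Q} are an orthonormal basis of the orthogonal
#' complement of \code{col(X)} (equivalently, directions along which weight
#' changes leave every stored input current untouched). The completion is
#' computed by a QR factorization and made deterministic by flipping each
#' completion column so that its largest-magnitude entry is positive.
#'
#' Per-column noise scales \code{s_mu = 1 / ||row mu of Xext^{-1}||_2} are
#' cached with the frame; independent eta increments with SD
#' \code{sigma * s_mu} induce weight increments whose pooled SD is
#' approximately \code{sigma} (see \code{\link{noise_scales}}).
#'
#' @param X input matrix, \code{Nx x P} with \code{P <= Nx} and full column
#'   rank.
#' @return an object of class \code{eta_frame} with elements \code{Xext},
#'   \code{Xinv}, \code{scales}, \code{P}, \code{Nx}.
#' @export
build_eta_frame <- function(X) {
  X <- as.matrix(X)
  Nx <- nrow(X); P <- ncol(X)
  if (P > Nx) stop("X must have at most as many columns as rows")
  if (P > 0L && qr(X)$rank < P) stop("X must have full column rank")
  if (P < Nx) {
    Qfull <- qr.Q(qr(X), complete = TRUE)
    comp <- Qfull[, (P + 1L):Nx, drop = FALSE]
    # fixed sign convention: largest-|entry| of each completion column positive
    for (j in seq_len(ncol(comp))) {
      i <- which.max(abs(comp[, j]))
      if (comp[i, j] < 0) comp[, j] <- -comp[, j]
    }
    Xext <- cbind(X, comp)
  } else {
    Xext <- X
  }
  Xinv <- solve(Xext)
  scales <- 1 / sqrt(rowSums(Xinv^2))
  structure(list(Xext = Xext, Xinv = Xinv, scales = scales, P = P, Nx = Nx),
            class = "eta_frame")
}

#' @export
print.eta_frame <- function(x, ...) {
  cat(sprintf("eta_frame: Nx=%d, P=%d constrained columns, %d completion columns\n",
              x$Nx, x$P, x$Nx - x$P))
  invisible(x)
}

#' Weight matrix to eta-coordinates
#'
#' \code{eta = U Xext}. The first \code{P} columns of \code{eta} are the
#' input currents \code{U X} of the stored conditions; the remaining columns
#' are coordinates along the unconstrained completion directions.
#'
#' @param U weight matrix (\code{Ny x Nx}).
#' @param frame an \code{\link{eta_frame}}.
#' @return eta-coordinate matrix (\code{Ny x Nx}).
#' @export
to_eta <- function(U, frame) {
  stopifnot(inherits(frame, "eta_frame"))
  U <- as.matrix(U)
  if (ncol(U) != frame$Nx) stop("U has inconsistent shape")
  U %*% frame$Xext
}

#' Eta-coordinates back to the weight matrix
#'
#' \code{U = eta Xext^{-1}}. All eta columns, including the unconstrained
#' ones, contribute to the physical synaptic weights.
#'
#' @param eta eta-coordinate matrix (\code{Ny x Nx}).
#' @param frame an \code{\link{eta_frame}}.
#' @return weight matrix (\code{Ny x Nx}).
#' @export
from_eta <- function(eta, frame) {
  stopifnot(inherits(frame, "eta_frame"))
  eta <- as.matrix(eta)
  if (ncol(eta) != frame$Nx) stop("eta has inconsistent shape")
  eta %*% frame$Xinv
}

#' Per-column eta noise scales
#'
#' Standard deviations \code{sigma * s_mu} of the per-coordinate eta
#' increments, with \code{s_mu = 1 / ||row mu of Xext^{-1}||_2}. The scales
#' are chosen so that independent eta noise at these SDs induces weight
#' increments \code{delta U = delta eta \%*\% Xinv} that are approximately
#' zero-mean normal with pooled SD \code{sigma} in physical coordinates
#' (exactly so when pooled over all entries for free diffusion in every
#' column).
#'
#' @param frame an \code{\link{eta_frame}}.
#' @param sigma weight-fluctuation scale (SD in weight units).
#' @return numeric vector of length \code{Nx} of per-column SDs.
#' @export
noise_scales <- function(frame, sigma = 1) {
  stopifnot(inherits(frame, "eta_frame"), sigma >= 0)
  sigma * frame$scales
}

#' Orthonormal kernel basis of the engaged readout submatrix
#'
#' Extracts the columns of the readout matrix \code{W} belonging to the
#' engaged neurons of a condition (the engaged submatrix \code{Wmu},
#' \code{Nz x |E|}) and returns a column-orthonormal basis \code{K}
#' (\code{|E| x (|E| - Nz)}) of its kernel. Activity changes of the engaged
#' neurons lying in \code{span(K)} leave the readout \code{W Y} unchanged.
#' When \code{|E| <= Nz} the basis is empty (zero columns).
#'
#' @param W readout matrix (\code{Nz x Ny}).
#' @param engaged integer indices of the engaged neurons (nonempty).
#' @return matrix \code{K} with \code{length(engaged)} rows and
#'   \code{max(length(engaged) - Nz, 0)} orthonormal columns satisfying
#'   \code{Wmu \%*\% K = 0}.
#' @export
engaged_kernel <- function(W, engaged) {
  W <- as.matrix(W)
  engaged <- as.integer(engaged)
  if (length(engaged) == 0L) stop("engaged set must be nonempty")
  Nz <- nrow(W)
  ne <- length(engaged)
  if (ne <= Nz) return(matrix(0, ne, 0))
  Wmu <- W[, engaged, drop = FALSE]
  Qfull <- qr.Q(qr(t(Wmu)), complete = TRUE)
  Qfull[, (Nz + 1L):ne, drop = FALSE]
}
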