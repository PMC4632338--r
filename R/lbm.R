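#' BGK relaxation parameter from the dilute diffusion coefficient
#'
#' Chapman-Enskog relation for the D2Q5 diffusion scheme,
#' \deqn{\omega = \frac{2}{1 + 4 D^0 \Delta t / \Delta x^2}.}
#' \eqn{\omega = 1} recovers the finite-difference stencil at its stability
#' limit and gives the most accurate crowding-corrected results; the engines
#' therefore require \eqn{0 < \omega \le 1} (i.e.
#' \eqn{\Delta t \ge \Delta x^2 / 4 D^0}).
#'
#' @param D0 dilute diffusion coefficient (nm^2/ms).
#' @param dt time step (ms).
#' @param dx voxel side (nm).
#' @return Dimensionless relaxation parameter.
#' @examples
#' computeOmega(500, 5, 100)     # 1
#' computeOmega(1000, 0.625, 50) # 1
#' @export
computeOmega <- function(D0, dt, dx) {
  stopifnot(dx > 0, dt > 0, all(D0 >= 0))
  2 / (1 + 4 * D0 * dt / dx^2)
}

#' Time step pinning the relaxation parameter to one
#'
#' Convenience inverse of \code{\link{computeOmega}}: the \eqn{\Delta t}
#' for which \eqn{\omega = 1} given \code{D0} and \code{dx}.
#'
#' @param D0 dilute diffusion coefficient (nm^2/ms), > 0.
#' @param dx voxel side (nm).
#' @return Time step in ms.
#' @export
dtForUnitOmega <- function(D0, dx) {
  stopifnot(D0 > 0, dx > 0)
  dx^2 / (4 * D0)
}

#' Equilibrium distribution field
#'
#' The fluid-at-rest D2Q5 equilibrium \eqn{F^{eq}_d = w_d \rho / m} with
#' weights 0, 1/4, 1/4, 1/4, 1/4.
#'
#' @param rho n x n density matrix (must be >= 0).
#' @param mass mass per molecule.
#' @return n x n x 5 equilibrium population array.
#' @examples
#' Feq <- equilibriumField(matrix(100, 2, 2))
#' Feq[1, 1, ]  # 0 then 25 25 25 25
#' @export
equilibriumField <- function(rho, mass = 1) {
  if (any(rho < 0)) stop("negative density")
  n <- nrow(rho)
  Feq <- array(0, dim = c(n, n, 5L))
  q <- rho / (4 * mass)
  for (d in 2:5) Feq[, , d] <- q
  Feq
}

#' BGK collision step
#'
#' Relaxes the populations toward equilibrium,
#' \eqn{F^{LB}_d = F_d + \omega (F^{eq}_d - F_d)}. The per-voxel direction sum
#' (and hence the density) is conserved. \eqn{\omega} outside \eqn{(0, 1]} is
#' rejected by default because overrelaxation can drive populations negative,
#' which breaks the crowding correction's \eqn{P \in [0,1]} contract; values
#' up to (but below) 2 can be allowed explicitly.
#'
#' @param F n x n x 5 population array.
#' @param omega relaxation parameter.
#' @param mass mass per molecule.
#' @param allowOver1 allow 1 < omega < 2 (with a warning).
#' @return Post-collision array \code{F^LB}.
#' @export
collideField <- function(F, omega, mass = 1, allowOver1 = FALSE) {
  if (omega <= 0 || omega > 2 - 1e-12 || (!allowOver1 && omega > 1))
    stop(sprintf("omega = %g outside (0, 1]%s", omega,
                 if (allowOver1) " (even with allowOver1, omega must be < 2)" else
                   "; set allowOver1 = TRUE to permit omega < 2"))
  if (allowOver1 && omega > 1)
    warning(sprintf("omega = %g > 1: populations may go negative", omega))
  Feq <- equilibriumField(fieldDensity(F, mass), mass)
  F + omega * (Feq - F)
}

#' Streaming step
#'
#' Shifts each moving population to its neighbour voxel with periodic wrap:
#' d = 1 to (i, j+1), d = 2 to (i-1, j), d = 3 to (i, j-1), d = 4 to
#' (i+1, j); the rest population d = 0 stays. Streaming is a permutation of
#' voxel contents per direction, so grid totals are exactly conserved.
#'
#' @param F n x n x 5 population array.
#' @return Streamed array.
#' @export
streamField <- function(F) {
  for (d in 2:5)
    F[, , d] <- .shiftGrid(F[, , d], .D2Q5_DI[d], .D2Q5_DJ[d])
  F
}
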