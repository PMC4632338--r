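#' Scaled Particle Theory moment grids
#'
#' Per-voxel moments of the radius distribution weighted by number density,
#' \deqn{S_x = \frac{\pi}{\Delta x^2} \sum_i \rho_i r_i^x, \quad x = 0, 1, 2,}
#' summed over all species present in the voxel (including the species whose
#' insertion is being evaluated; self-crowding is physical). \eqn{S_2} is the
#' occupied area fraction of the voxel.
#'
#' @param densities list of n x n density matrices, one per species.
#' @param radii numeric vector of hard-disk radii (nm), same length/order.
#' @param dx voxel side (nm).
#' @return List with matrices \code{S0}, \code{S1}, \code{S2}.
#' @examples
#' m <- sptMoments(list(matrix(59.6825, 1, 1)), radii = 2, dx = 50)
#' m$S2  # ~0.30: a 30% occupied voxel
#' @export
sptMoments <- function(densities, radii, dx) {
  stopifnot(length(densities) == length(radii), dx > 0, all(radii >= 0))
  n <- nrow(densities[[1L]])
  S0 <- S1 <- S2 <- matrix(0, n, n)
  for (k in seq_along(densities)) {
    rho <- densities[[k]]
    S0 <- S0 + rho
    S1 <- S1 + rho * radii[k]
    S2 <- S2 + rho * radii[k]^2
  }
  f <- pi / dx^2
  list(S0 = f * S0, S1 = f * S1, S2 = f * S2)
}

#' Hard-disk activity coefficient (Scaled Particle Theory)
#'
#' Work of inserting a hard disk of radius \code{r} into the 2D hard-disk
#' mixture described by the moment grids:
#' \deqn{\ln\gamma = -\ln(1 - S_2) + \frac{2 S_1}{1 - S_2} r +
#'   \left[\frac{S_0}{1 - S_2} + \frac{S_1^2}{(1 - S_2)^2}\right] r^2.}
#' Voxels with \eqn{S_2 \ge 1} are saturated; they are returned as
#' \code{Inf} (zero insertion probability) rather than evaluated.
#'
#' For a point-like tracer (\code{r = 0}) this reduces to
#' \eqn{-\ln(1 - S_2)}, i.e. the insertion probability equals the free area
#' fraction \eqn{1 - S_2}.
#'
#' @param moments list with grids \code{S0}, \code{S1}, \code{S2}
#'   (see \code{\link{sptMoments}}).
#' @param r tracer radius (nm), >= 0.
#' @return Matrix of \eqn{\ln\gamma} (>= 0, possibly \code{Inf}).
#' @examples
#' m <- list(S0 = 0.075, S1 = 0.15, S2 = 0.30)
#' lnGammaDisks(lapply(m, function(x) matrix(x, 1, 1)), r = 1.5) # ~1.3439
#' @export
lnGammaDisks <- function(moments, r) {
  if (length(r) != 1L || is.na(r) || r < 0) stop("'r' must be a single number >= 0")
  S0 <- moments$S0; S1 <- moments$S1; S2 <- moments$S2
  out <- matrix(Inf, nrow(S2), ncol(S2))
  ok <- S2 < 1
  om <- 1 - S2[ok]
  out[ok] <- -log(om) + (2 * S1[ok] / om) * r +
    (S0[ok] / om + (S1[ok] / om)^2) * r^2
  out
}

#' Lattice-model activity coefficient (square uniform packing)
#'
#' Simplification of the hard-disk expression for same-size square molecules
#' in square uniform packing order: \eqn{\ln\gamma = -\ln(1 - S_2)} with
#' \eqn{S_2 = \Delta x^{-2} \sum_i \rho_i A_i}. The result is independent of
#' the moving species; fully packed voxels (\eqn{S_2 \ge 1}) admit no
#' entrants and are returned as \code{Inf}.
#'
#' @param densities list of n x n density matrices.
#' @param areas molecule areas (nm^2), > 0, same length/order.
#' @param dx voxel side (nm).
#' @return Matrix of \eqn{\ln\gamma}.
#' @export
lnGammaLattice <- function(densities, areas, dx) {
  stopifnot(length(densities) == length(areas), all(areas > 0), dx > 0)
  S2 <- Reduce(`+`, Map(`*`, densities, as.list(areas))) / dx^2
  out <- matrix(Inf, nrow(S2), ncol(S2))
  ok <- S2 < 1
  out[ok] <- -log(1 - S2[ok])
  out
}

#' Insertion probability from the activity coefficient
#'
#' \eqn{P = 1/\gamma = e^{-\ln\gamma}}, the probability that the moving
#' species finds free space in the target voxel. Saturated voxels
#' (\code{lnGamma = Inf}) map to 0. Values are clamped into [0, 1] to absorb
#' floating-point drift; a violation beyond 1e-9 signals a bug
#' (\eqn{\gamma \ge 1} analytically) and raises an error.
#'
#' @param lnGamma matrix of \eqn{\ln\gamma} values.
#' @return Matrix of probabilities in [0, 1].
#' @examples
#' insertionProbability(matrix(c(0, Inf, 1.3439), 1, 3))
#' @export
insertionProbability <- function(lnGamma) {
  P <- exp(-lnGamma)
  if (any(P > 1 + 1e-9 | P < -1e-9))
    stop("insertion probability outside [0, 1] by more than 1e-9; gamma < 1 indicates a bug")
  P[P > 1] <- 1
  P[P < 0] <- 0
  P
}

# Per-species insertion probability grids at time t, from the densities of
# ALL species (mobile and immobile). In lattice mode P is species-independent;
# in disk mode one grid is computed per distinct radius.
.crowdingProbabilities <- function(densities, species, mode, dx) {
  nms <- vapply(species, function(s) s@name, character(1))
  if (mode == "lattice") {
    areas <- vapply(species, function(s) s@area, numeric(1))
    P <- insertionProbability(lnGammaLattice(densities[nms], areas, dx))
    out <- rep(list(P), length(species))
  } else {
    radii <- vapply(species, function(s) ifelse(is.na(s@radius), 0, s@radius),
                    numeric(1))
    mom <- sptMoments(densities[nms], radii, dx)
    byR <- lapply(unique(radii), function(r)
      insertionProbability(lnGammaDisks(mom, r)))
    names(byR) <- as.character(unique(radii))
    out <- byR[as.character(radii)]
  }
  names(out) <- nms
  out
}

#' Tabulate activity coefficient and insertion probability vs area fraction
#'
#' Characterization table of the Scaled Particle Theory correction for a
#' single crowder species: for each occupied area fraction, the activity
#' coefficient and insertion probability of a tracer of radius
#' \code{rTracer} in a uniform sea of crowders of radius \code{rCrowder}.
#'
#' @param areaFractions numeric vector in [0, 1).
#' @param rTracer tracer radius (nm).
#' @param rCrowder crowder radius (nm), > 0.
#' @param dx voxel side (nm).
#' @return data.frame (area_fraction, ln_gamma, gamma, P).
#' @export
sptTable <- function(areaFractions, rTracer, rCrowder, dx = 50) {
  stopifnot(all(areaFractions >= 0), all(areaFractions < 1), rCrowder > 0)
  rho <- areaFractions * dx^2 / (pi * rCrowder^2)
  lg <- vapply(rho, function(x) {
    m <- sptMoments(list(matrix(x, 1, 1)), rCrowder, dx)
    lnGammaDisks(m, rTracer)[1, 1]
  }, numeric(1))
  data.frame(area_fraction = areaFractions, ln_gamma = lg, gamma = exp(lg),
             P = exp(-lg))
}
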