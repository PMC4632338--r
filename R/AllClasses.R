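#' @import methods
NULL

#' Molecular species description
#'
#' Physical description of one molecular species: hard-disk radius and/or
#' molecular area, dilute-solution diffusion coefficient, mass per molecule
#' and mobility flag. For hard-disk species the area is \eqn{\pi r^2};
#' for the square lattice model only the area is used and the radius may be
#' left unset (\code{NA}).
#'
#' @slot name species label.
#' @slot radius hard-disk radius in nm (\code{NA} for square lattice species).
#' @slot area molecular area in nm^2.
#' @slot D0 dilute-solution diffusion coefficient in nm^2/ms.
#' @slot mass mass of one molecule in g/molecule (default 1, so densities
#'   count molecules per voxel).
#' @slot mobile logical; immobile species act as fixed crowders.
#'
#' @exportClass Species
setClass("Species",
  representation(name = "character", radius = "numeric", area = "numeric",
                 D0 = "numeric", mass = "numeric", mobile = "logical"))

setValidity("Species", function(object) {
  msg <- NULL
  one <- function(x) length(x) == 1L
  if (!one(object@name) || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (!one(object@radius) || !one(object@area) || !one(object@D0) ||
      !one(object@mass) || !one(object@mobile))
    msg <- c(msg, "all slots must have length 1")
  if (!is.na(object@radius) && object@radius < 0)
    msg <- c(msg, "'radius' must be >= 0")
  if (is.na(object@area) || object@area < 0)
    msg <- c(msg, "'area' must be a number >= 0")
  if (is.na(object@D0) || object@D0 < 0)
    msg <- c(msg, "'D0' must be >= 0")
  if (is.na(object@mass) || object@mass <= 0)
    msg <- c(msg, "'mass' must be > 0")
  # disk species carry both descriptors consistently
  if (!is.na(object@radius) && object@radius > 0 && object@area > 0 &&
      abs(object@area - pi * object@radius^2) > 1e-8 * max(1, object@area))
    msg <- c(msg, "for disk species 'area' must equal pi * radius^2")
  if (is.null(msg)) TRUE else msg
})

#' Construct a Species
#'
#' @param name species label.
#' @param radius hard-disk radius (nm). If given and \code{area} is missing,
#'   the area is set to \eqn{\pi r^2}.
#' @param area molecular area (nm^2); for the square lattice model this is
#'   the side-squared area of the square molecule.
#' @param D0 dilute diffusion coefficient (nm^2/ms).
#' @param mass mass per molecule (g/molecule).
#' @param mobile logical mobility flag.
#' @return A \linkS4class{Species} object.
#' @examples
#' Species("tracer", radius = 1.5, D0 = 1000)
#' Species("A", area = 100, D0 = 500)
#' @export
Species <- function(name, radius = NA_real_, area = NA_real_, D0,
                    mass = 1, mobile = TRUE) {
  if (is.na(area) && !is.na(radius)) area <- pi * radius^2
  if (is.na(area)) stop("one of 'radius' or 'area' is required")
  new("Species", name = as.character(name), radius = as.numeric(radius),
      area = as.numeric(area), D0 = as.numeric(D0), mass = as.numeric(mass),
      mobile = as.logical(mobile))
}

setMethod("show", "Species", function(object) {
  cat(sprintf("Species \"%s\": r = %s nm, A = %.4g nm^2, D0 = %g nm^2/ms, m = %g g, %s\n",
              object@name,
              if (is.na(object@radius)) "NA" else format(object@radius),
              object@area, object@D0, object@mass,
              if (object@mobile) "mobile" else "immobile"))
})

#' Square lattice geometry for the D2Q5 scheme
#'
#' The simulation domain is a periodic square of side \code{L} nm divided
#' into \code{n = L/dx} voxels per side; \code{dt} is the Lattice-Boltzmann
#' time step. The five D2Q5 directions are d = 0 (rest) and d = 1..4 with
#' unit voxel displacements (0,+1), (-1,0), (0,-1), (+1,0) in (row, column)
#' coordinates and weights 0, 1/4, 1/4, 1/4, 1/4.
#'
#' @slot L domain side length (nm).
#' @slot dx voxel side (nm); \code{L/dx} must be an exact integer.
#' @slot dt time step (ms).
#' @slot n integer number of voxels per side.
#' @exportClass LatticeGeometry
setClass("LatticeGeometry",
  representation(L = "numeric", dx = "numeric", dt = "numeric", n = "integer"))

setValidity("LatticeGeometry", function(object) {
  msg <- NULL
  if (object@dx <= 0) msg <- c(msg, "'dx' must be > 0")
  if (object@dt <= 0) msg <- c(msg, "'dt' must be > 0")
  if (object@L <= 0) msg <- c(msg, "'L' must be > 0")
  r <- object@L / object@dx
  if (abs(r - round(r)) > 1e-9) msg <- c(msg, "L/dx must be an exact integer")
  if (object@n != round(r)) msg <- c(msg, "'n' inconsistent with L/dx")
  if (is.null(msg)) TRUE else msg
})

#' Construct a LatticeGeometry
#'
#' @param L domain side (nm).
#' @param dx voxel side (nm).
#' @param dt time step (ms).
#' @return A \linkS4class{LatticeGeometry}.
#' @examples
#' latticeGeometry(L = 1000, dx = 100, dt = 5)
#' @export
latticeGeometry <- function(L, dx, dt) {
  new("LatticeGeometry", L = as.numeric(L), dx = as.numeric(dx),
      dt = as.numeric(dt), n = as.integer(round(L / dx)))
}

setMethod("show", "LatticeGeometry", function(object) {
  cat(sprintf("LatticeGeometry: (%g nm)^2, dx = %g nm (%d x %d voxels), dt = %g ms, periodic\n",
              object@L, object@dx, object@n, object@n, object@dt))
})

#' Simulation scenario
#'
#' A complete description of one diffusion experiment: geometry, species,
#' initial placement, crowding model mode and recording schedule. Scenarios
#' in \code{"lattice"} mode describe same-size square molecules on a fine
#' site lattice of side \code{siteSide} nm (one molecule per site, the kinetic
#' Monte Carlo representation); \code{"disk"} mode describes hard-disk
#' mixtures at voxel resolution (Lattice-Boltzmann only).
#'
#' @slot geometry a \linkS4class{LatticeGeometry}.
#' @slot species list of \linkS4class{Species}.
#' @slot densities named list of n x n matrices of initial molecules/voxel.
#' @slot mode \code{"lattice"} or \code{"disk"}.
#' @slot siteSide side of one kMC site (nm); \code{NA} in disk mode.
#' @slot placement data.frame (species, si, sj) of 0-based site coordinates
#'   of every molecule (lattice mode; empty otherwise).
#' @slot origins data.frame (species, oi, oj) mapping origin-labeled tracer
#'   subspecies to their 0-based origin voxel (see \code{\link{labelOrigins}}).
#' @slot placementSpec named list of per-species placement descriptors
#'   (type \code{"fill-voxels"} or \code{"random-uniform"}), the canonical
#'   form serialized by \code{\link{writeScenarioConfig}}.
#' @slot seed integer seed used for any random placement.
#' @slot tEnd default simulation horizon (ms).
#' @slot recordEvery default recording interval in steps.
#' @slot title short description.
#' @exportClass Scenario
setClass("Scenario",
  representation(geometry = "LatticeGeometry", species = "list",
                 densities = "list", mode = "character", siteSide = "numeric",
                 placement = "data.frame", origins = "data.frame",
                 placementSpec = "list",
                 seed = "integer", tEnd = "numeric", recordEvery = "integer",
                 title = "character"))

setValidity("Scenario", function(object) {
  msg <- NULL
  n <- object@geometry@n
  nms <- vapply(object@species, function(s) s@name, character(1))
  if (anyDuplicated(nms)) msg <- c(msg, "duplicated species names")
  if (!identical(sort(names(object@densities)), sort(nms)))
    msg <- c(msg, "'densities' must be named after the species")
  for (d in object@densities) {
    if (!is.matrix(d) || !all(dim(d) == n))
      msg <- c(msg, "each density grid must be an n x n matrix")
    else if (any(d < 0)) msg <- c(msg, "negative initial density")
  }
  if (!object@mode %in% c("lattice", "disk"))
    msg <- c(msg, "'mode' must be \"lattice\" or \"disk\"")
  # total occupied area fraction must stay below 1
  tot <- 0
  for (s in object@species) tot <- tot + sum(object@densities[[s@name]]) * s@area
  if (tot >= object@geometry@L^2)
    msg <- c(msg, "total occupied area fraction must be < 1")
  if (object@mode == "lattice") {
    for (s in object@species) {
      cap <- floor(object@geometry@dx^2 / s@area)
      if (any(object@densities[[s@name]] > cap + 1e-9))
        msg <- c(msg, sprintf("species '%s' exceeds voxel capacity %d", s@name, cap))
    }
  }
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "Scenario", function(object) {
  cat(sprintf("Scenario: %s\n", object@title))
  show(object@geometry)
  cat(sprintf("  mode: %s%s, seed: %d, horizon: %g ms\n", object@mode,
              if (object@mode == "lattice")
                sprintf(" (site %g nm)", object@siteSide) else "",
              object@seed, object@tEnd))
  for (s in object@species)
    cat(sprintf("  %-12s N = %-7g r = %-4s A = %-6.4g D0 = %g\n", s@name,
                sum(object@densities[[s@name]]),
                if (is.na(s@radius)) "NA" else format(s@radius), s@area, s@D0))
})

#' Result of a Lattice-Boltzmann run
#'
#' Recorded voxel densities of every species along a classical (\code{lbm})
#' or crowding-corrected (\code{clbm}) run.
#'
#' @slot engine \code{"lbm"} or \code{"clbm"}.
#' @slot times recorded times (ms), starting at 0.
#' @slot densities named list (one per species) of n x n x length(times)
#'   arrays of molecules per voxel.
#' @slot omega named numeric relaxation parameter per species.
#' @slot overfill number of (voxel, step) pairs at which the post-step
#'   occupied area fraction exceeded 1 (the voxel's P is clamped to 0 on the
#'   following step).
#' @slot scenario the \linkS4class{Scenario} that was run.
#' @exportClass DiffusionRun
setClass("DiffusionRun",
  representation(engine = "character", times = "numeric", densities = "list",
                 omega = "numeric", overfill = "integer", scenario = "Scenario"))

setMethod("show", "DiffusionRun", function(object) {
  cat(sprintf("DiffusionRun [%s]: %d species, %d recorded times (0..%g ms)%s\n",
              object@engine, length(object@densities), length(object@times),
              max(object@times),
              if (object@overfill > 0)
                sprintf(", %d overfilled voxel-steps", object@overfill) else ""))
})

#' Result of a kinetic Monte Carlo ensemble
#'
#' Ensemble-averaged voxel occupancies (coarse-grained to the
#' Lattice-Boltzmann voxels) and mean squared displacements.
#'
#' @slot times recorded times (ms), starting at 0.
#' @slot densities named list of n x n x length(times) arrays of mean
#'   molecules per voxel.
#' @slot msd data.frame (time, species, msd, msdEffective, n): per-species
#'   net mean squared displacement from unwrapped site displacements and the
#'   accumulated-hop effective displacement (both nm^2; see
#'   \code{\link{runKmcEnsemble}}).
#' @slot reps number of repetitions averaged.
#' @slot scenario the \linkS4class{Scenario} that was run.
#' @exportClass KmcRun
setClass("KmcRun",
  representation(times = "numeric", densities = "list", msd = "data.frame",
                 reps = "integer", scenario = "Scenario"))

setMethod("show", "KmcRun", function(object) {
  cat(sprintf("KmcRun: %d repetitions, %d species, %d recorded times (0..%g ms)\n",
              object@reps, length(object@densities), length(object@times),
              max(object@times)))
})
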