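# D2Q5 stencil: directions d = 0..4 with (row, column) unit displacements.
# d = 1 shifts j -> j+1, d = 2 shifts i -> i-1, d = 3 shifts j -> j-1,
# d = 4 shifts i -> i+1; the rest direction d = 0 does not move.
.D2Q5_DI <- c(0L, 0L, -1L, 0L, 1L)
.D2Q5_DJ <- c(0L, 1L, 0L, -1L, 0L)
.D2Q5_W  <- c(0, 0.25, 0.25, 0.25, 0.25)

#' D2Q5 stencil constants
#'
#' @return A list with integer displacement vectors \code{di}, \code{dj}
#'   (indexed d = 0..4 as positions 1..5) and weights \code{w}.
#' @examples
#' d2q5Stencil()$w  # 0, then 1/4 four times
#' @export
d2q5Stencil <- function() list(di = .D2Q5_DI, dj = .D2Q5_DJ, w = .D2Q5_W)

# Periodic shift of a grid by (di, dj): new[i + di, j + dj] = old[i, j].
.shiftGrid <- function(M, di, dj) {
  n <- nrow(M)
  if (di != 0L) M <- M[((seq_len(n) - 1L - di) %% n) + 1L, , drop = FALSE]
  if (dj != 0L) M <- M[, ((seq_len(n) - 1L - dj) %% n) + 1L, drop = FALSE]
  M
}

#' Maximum number of square molecules per voxel
#'
#' Capacity of a voxel of side \code{dx} for same-size square molecules of
#' area \code{area} under square uniform packing, \code{floor(dx^2/area)}.
#' Used to audit initial conditions of lattice-mode scenarios.
#'
#' @param dx voxel side (nm).
#' @param area molecule area (nm^2), must be > 0.
#' @return Integer capacity.
#' @examples
#' voxelCapacity(50, 100)   # 25
#' voxelCapacity(1000, 100) # 10000 for the whole (1000 nm)^2 lattice
#' @export
voxelCapacity <- function(dx, area) {
  if (!is.numeric(area) || length(area) != 1L || is.na(area) || area <= 0)
    stop("'area' must be a single positive number (point-like species have no capacity bound)")
  if (!is.numeric(dx) || length(dx) != 1L || dx <= 0) stop("'dx' must be > 0")
  as.integer(floor(dx^2 / area))
}

# New distribution array (n x n x 5) with all molecules at rest (d = 0).
# The first collision relaxes the populations toward equilibrium, so at
# omega = 1 the trajectory does not depend on this convention.
.restField <- function(rho, mass) {
  n <- nrow(rho)
  F <- array(0, dim = c(n, n, 5L))
  F[, , 1L] <- rho / mass
  F
}

#' Initial distribution fields of a scenario
#'
#' Builds the per-species D2Q5 population arrays \code{F[i, j, d+1]} from the
#' scenario's initial voxel densities, with all molecules initially at rest.
#'
#' @param scenario a \linkS4class{Scenario}.
#' @return Named list of n x n x 5 arrays.
#' @export
initFields <- function(scenario) {
  out <- lapply(scenario@species, function(s)
    .restField(scenario@densities[[s@name]], s@mass))
  names(out) <- vapply(scenario@species, function(s) s@name, character(1))
  out
}

#' Macroscopic density of a distribution field
#'
#' Recovers the voxel density \eqn{\rho = m \sum_d F_d} from a population
#' array.
#'
#' @param F an n x n x 5 population array.
#' @param mass mass per molecule (g).
#' @return n x n matrix of density (molecules per voxel when \code{mass = 1}).
#' @examples
#' F <- array(5, dim = c(3, 3, 5))
#' fieldDensity(F)[1, 1]  # 25
#' @export
fieldDensity <- function(F, mass = 1) {
  stopifnot(length(dim(F)) == 3L, dim(F)[3L] == 5L)
  mass * (F[, , 1L] + F[, , 2L] + F[, , 3L] + F[, , 4L] + F[, , 5L])
}

#' Recorded density grid of a run
#'
#' Extracts the voxel density matrix of one species at one recorded time from
#' a \linkS4class{DiffusionRun} or \linkS4class{KmcRun}.
#'
#' @param run a run object.
#' @param species species name.
#' @param time recorded time (ms).
#' @return n x n density matrix.
#' @export
voxelDensity <- function(run, species, time) {
  if (!is(run, "DiffusionRun") && !is(run, "KmcRun"))
    stop("'run' must be a DiffusionRun or KmcRun")
  if (!species %in% names(run@densities))
    stop(sprintf("unknown species '%s'", species))
  k <- which(abs(run@times - time) < 1e-9)
  if (length(k) != 1L)
    stop(sprintf("time %g ms was not recorded", time))
  run@densities[[species]][, , k]
}

#' Export recorded densities as long-format CSV
#'
#' Writes (time_ms, species, i, j, rho) rows for every recorded time, using
#' 0-based voxel indices.
#'
#' @param run a \linkS4class{DiffusionRun} or \linkS4class{KmcRun}.
#' @param path output file.
#' @return The path, invisibly.
#' @export
exportDensities <- function(run, path) {
  n <- dim(run@densities[[1L]])[1L]
  idx <- expand.grid(i = seq_len(n) - 1L, j = seq_len(n) - 1L)
  rows <- lapply(names(run@densities), function(sp) {
    do.call(rbind, lapply(seq_along(run@times), function(k)
      data.frame(time_ms = run@times[k], species = sp, i = idx$i, j = idx$j,
                 rho = as.vector(run@densities[[sp]][, , k]))))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
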