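#' Relative distribution error between two density grids
#'
#' Frobenius-norm error of a test grid against a reference grid, as a
#' percentage of the reference molecule count:
#' \deqn{error = 100\,\frac{\|\rho_{ref} - \rho_{test}\|_F}{\sum_{i,j} \rho_{ref}(i,j)}.}
#' The numerator is symmetric in the two grids; only the normalization
#' changes when the arguments are swapped. An error of x\% reads as "x of
#' every 100 reference molecules sit in a different voxel than predicted".
#'
#' @param ref reference density matrix (typically the kMC ensemble mean);
#'   must have a positive total.
#' @param test test density matrix of the same shape.
#' @return Percent error (scalar, >= 0; 0 iff the grids are identical).
#' @examples
#' a <- matrix(0, 5, 5); a[2, 2] <- 100
#' b <- a; b[2, 2] <- 99; b[2, 3] <- 1
#' distributionError(a, b)  # 100 * sqrt(2) / 100 = 1.414...
#' @export
distributionError <- function(ref, test) {
  if (!is.matrix(ref) || !is.matrix(test) || !identical(dim(ref), dim(test)))
    stop("grid shapes differ (two matrices of equal dimensions required)")
  tot <- sum(ref)
  if (tot <= 0) stop("reference grid has zero total")
  100 * sqrt(sum((ref - test)^2)) / tot
}

#' Per-time distribution error between two runs
#'
#' Evaluates \code{\link{distributionError}} for one species at every time
#' recorded in both runs.
#'
#' @param refRun reference run (\linkS4class{KmcRun} or
#'   \linkS4class{DiffusionRun}).
#' @param testRun test run.
#' @param species species name present in both runs.
#' @param times times to compare (default: all shared recorded times > 0).
#' @return data.frame (time, species, error).
#' @export
errorSeries <- function(refRun, testRun, species, times = NULL) {
  if (is.null(times))
    times <- setdiff(intersect(refRun@times, testRun@times), 0)
  err <- vapply(times, function(tt)
    distributionError(voxelDensity(refRun, species, tt),
                      voxelDensity(testRun, species, tt)), numeric(1))
  data.frame(time = times, species = species, error = err)
}

#' Mean squared displacement from origin-labeled densities
#'
#' MSD of a mesoscopic run whose tracer population was split into
#' origin-labeled subspecies (\code{\link{labelOrigins}}): the
#' density-weighted second moment of each subpopulation about its origin
#' voxel center, using minimum-image distances on the periodic box, pooled
#' over origins,
#' \deqn{MSD(t) = \frac{\sum_o \sum_{i,j} \rho_o(i,j,t)\, d^2_{min}(c_{ij}, c_o)}
#'   {\sum_o \sum_{i,j} \rho_o(i,j,t)}.}
#' Displacements are resolved at voxel-center granularity (the displacement
#' from one voxel to another). The estimate is flagged invalid once the rms
#' displacement approaches the half box, where the minimum-image convention
#' truncates the true spread.
#'
#' @param run a \linkS4class{DiffusionRun} of an origin-labeled scenario.
#' @return data.frame (time, msd, valid) with MSD in nm^2; MSD(0) = 0.
#' @export
msdFromDensity <- function(run) {
  sc <- run@scenario
  if (nrow(sc@origins) == 0)
    stop("run's scenario has no origin-labeled tracers (see labelOrigins)")
  geo <- sc@geometry
  n <- geo@n; dx <- geo@dx; L <- geo@L
  # minimum-image squared distance between voxel centers, per origin
  coord <- (seq_len(n) - 1) * dx
  d2 <- function(oi, oj) {
    ddi <- abs(coord - coord[oi + 1L]); ddi <- pmin(ddi, L - ddi)
    ddj <- abs(coord - coord[oj + 1L]); ddj <- pmin(ddj, L - ddj)
    outer(ddi^2, ddj^2, `+`)
  }
  nt <- length(run@times)
  num <- den <- numeric(nt)
  for (r in seq_len(nrow(sc@origins))) {
    sp <- sc@origins$species[r]
    w <- d2(sc@origins$oi[r], sc@origins$oj[r])
    arr <- run@densities[[sp]]
    for (k in seq_len(nt)) {
      num[k] <- num[k] + sum(arr[, , k] * w)
      den[k] <- den[k] + sum(arr[, , k])
    }
  }
  msd <- num / den
  data.frame(time = run@times, msd = msd, valid = sqrt(msd) < L / 4)
}

#' Relative error between two MSD series
#'
#' Pointwise percentage error
#' \eqn{error_{MSD}(t) = 100\,|MSD_{ref}(t) - MSD_{test}(t)| / MSD_{ref}(t)}
#' on the shared time grid; t = 0 is excluded (the reference is zero there).
#'
#' @param ref data.frame with columns \code{time} and \code{msd}
#'   (e.g. from \code{\link{pooledMsd}}).
#' @param test data.frame with columns \code{time} and \code{msd}.
#' @return data.frame (time, error) in percent.
#' @export
msdError <- function(ref, test) {
  times <- setdiff(intersect(ref$time, test$time), 0)
  if (length(times) == 0) stop("no shared positive times")
  r <- ref$msd[match(times, ref$time)]
  s <- test$msd[match(times, test$time)]
  if (any(r <= 0)) stop("reference MSD must be positive for t > 0")
  data.frame(time = times, error = 100 * abs(r - s) / r)
}
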