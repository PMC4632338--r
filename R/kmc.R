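#' Initialize a kinetic Monte Carlo state
#'
#' Builds the single-molecule site lattice from a lattice-mode scenario:
#' each site of side \code{siteSide} nm holds at most one molecule; molecules
#' hop to free von Neumann neighbours at per-direction rate
#' \eqn{D^0 / a^2} (so a free walker's MSD is \eqn{4 D^0 t}).
#'
#' @param scenario a lattice-mode \linkS4class{Scenario}.
#' @return A list with the occupancy \code{grid} (0 = empty, else molecule
#'   index), the molecule table \code{mols} (species, 0-based site, unwrapped
#'   displacement accumulators in sites), per-species hop \code{rates}
#'   (1/ms), site side \code{a} (nm) and clock \code{t} (ms).
#' @export
kmcState <- function(scenario) {
  if (scenario@mode != "lattice")
    stop("kinetic Monte Carlo requires a lattice-mode scenario")
  a <- scenario@siteSide
  nSites <- as.integer(round(scenario@geometry@L / a))
  grid <- matrix(0L, nSites, nSites)
  pl <- scenario@placement
  grid[cbind(pl$si + 1L, pl$sj + 1L)] <- seq_len(nrow(pl))
  rates <- vapply(scenario@species, function(s) s@D0 / a^2, numeric(1))
  names(rates) <- speciesNames(scenario)
  mobile <- vapply(scenario@species, function(s) s@mobile, logical(1))
  names(mobile) <- names(rates)
  list(grid = grid, nSites = nSites, a = a,
       mols = data.frame(species = pl$species, si = pl$si, sj = pl$sj,
                         dxs = 0L, dys = 0L, hops = 0L),
       rates = rates, mobile = mobile, t = 0)
}

#' Enumerate possible hop events
#'
#' One event per (mobile molecule, free neighbouring site) pair, each at the
#' per-direction rate of its species. Fully blocked molecules contribute no
#' events.
#'
#' @param state a kMC state from \code{\link{kmcState}}.
#' @return data.frame (mol, dir, rate) plus attribute \code{"total"}, the
#'   cumulative rate R.
#' @export
enumerateEvents <- function(state) {
  n <- state$nSites
  mols <- state$mols
  out <- vector("list", 4L)
  for (d in 1:4) {
    ti <- (mols$si + .D2Q5_DI[d + 1L]) %% n
    tj <- (mols$sj + .D2Q5_DJ[d + 1L]) %% n
    freeTarget <- state$grid[cbind(ti + 1L, tj + 1L)] == 0L
    ok <- which(freeTarget & state$mobile[mols$species])
    out[[d]] <- data.frame(mol = ok, dir = rep.int(d, length(ok)),
                           rate = unname(state$rates[mols$species[ok]]))
  }
  ev <- do.call(rbind, out)
  structure(ev, total = sum(ev$rate))
}

#' Select and execute one event, advancing the clock
#'
#' An event is chosen with probability proportional to its rate by
#' inverse-cumulative lookup; the molecule hops (periodic wrap, unwrapped
#' displacement accumulated) and the clock advances by an exponential
#' waiting time \eqn{\Delta t = -\ln(u)/R}.
#'
#' @param state a kMC state.
#' @param events event table from \code{\link{enumerateEvents}}.
#' @return The updated state.
#' @export
selectAndAdvance <- function(state, events) {
  R <- attr(events, "total")
  if (is.null(R)) R <- sum(events$rate)
  if (nrow(events) == 0L || R <= 0)
    stop("all molecules are jammed (R = 0): clock advance undefined")
  k <- findInterval(stats::runif(1) * R, cumsum(events$rate),
                    rightmost.closed = TRUE) + 1L
  k <- min(k, nrow(events))
  m <- events$mol[k]; d <- events$dir[k] + 1L
  n <- state$nSites
  state$grid[state$mols$si[m] + 1L, state$mols$sj[m] + 1L] <- 0L
  state$mols$si[m] <- (state$mols$si[m] + .D2Q5_DI[d]) %% n
  state$mols$sj[m] <- (state$mols$sj[m] + .D2Q5_DJ[d]) %% n
  state$mols$dxs[m] <- state$mols$dxs[m] + .D2Q5_DI[d]
  state$mols$dys[m] <- state$mols$dys[m] + .D2Q5_DJ[d]
  state$mols$hops[m] <- state$mols$hops[m] + 1L
  state$grid[state$mols$si[m] + 1L, state$mols$sj[m] + 1L] <- m
  state$t <- state$t - log(stats::runif(1)) / R
  state
}

#' Run the reference kinetic Monte Carlo simulator
#'
#' Plain event-by-event loop (full re-enumeration each event) recording the
#' state at the last event time at or before each requested time
#' ("previous-state" sampling). This is the correctness baseline; use
#' \code{\link{runKmcEnsemble}} for production ensembles.
#'
#' @param scenario a lattice-mode \linkS4class{Scenario}.
#' @param recordTimes increasing positive times (ms).
#' @return List with \code{times} (0 followed by \code{recordTimes}),
#'   \code{densities} (as in \linkS4class{KmcRun}), and \code{msd}
#'   data.frame.
#' @export
runKmc <- function(scenario, recordTimes) {
  stopifnot(all(diff(recordTimes) > 0), all(recordTimes > 0))
  state <- kmcState(scenario)
  n <- scenario@geometry@n
  f <- as.integer(round(scenario@geometry@dx / scenario@siteSide))
  nms <- speciesNames(scenario)
  dens <- lapply(nms, function(x)
    array(0, dim = c(n, n, length(recordTimes) + 1L)))
  names(dens) <- nms
  snap <- function(k) {
    for (sp in nms) {
      sel <- state$mols$species == sp
      dens[[sp]][, , k] <<- dens[[sp]][, , k] +
        tabulate((state$mols$sj[sel] %/% f) * n + (state$mols$si[sel] %/% f) + 1L,
                 nbins = n * n)
    }
  }
  msd <- msdEff <- matrix(0, length(nms), length(recordTimes) + 1L,
                          dimnames = list(nms, NULL))
  snap(1L)
  # `state` holds from state$t until the next event; `nxt` is the
  # already-advanced successor, kept so that one waiting interval spanning
  # several record times snapshots the same state for each of them.
  nxt <- NULL
  for (k in seq_along(recordTimes)) {
    repeat {
      if (is.null(nxt)) nxt <- selectAndAdvance(state, enumerateEvents(state))
      if (nxt$t > recordTimes[k]) break # previous-state sampling
      state <- nxt; nxt <- NULL
    }
    snap(k + 1L)
    for (sp in nms) {
      sel <- state$mols$species == sp
      msd[sp, k + 1L] <- mean(state$mols$dxs[sel]^2 + state$mols$dys[sel]^2) *
        state$a^2
      msdEff[sp, k + 1L] <- mean(state$mols$hops[sel]) * state$a^2
    }
  }
  counts <- as.vector(table(factor(scenario@placement$species, levels = nms)))
  list(times = c(0, recordTimes), densities = dens,
       msd = data.frame(time = rep(c(0, recordTimes), each = length(nms)),
                        species = rep(nms, length(recordTimes) + 1L),
                        msd = as.vector(msd),
                        msdEffective = as.vector(msdEff),
                        n = rep(counts, length(recordTimes) + 1L)))
}

#' Run a kinetic Monte Carlo ensemble (compiled engine)
#'
#' Repeats the scenario's stochastic trajectory \code{reps} times from the
#' same initial placement, records occupancies coarse-grained to the
#' Lattice-Boltzmann voxels at the requested times, averages them over
#' repetitions, and accumulates per-species mean squared displacements from
#' unwrapped site displacements.
#'
#' The compiled inner loop uses uniformization: hop attempts into occupied
#' sites are carried as null events so that the total event rate is constant
#' and the number of events per recording interval is Poisson; this is
#' distributionally identical to the event-by-event exponential-clock
#' procedure of \code{\link{runKmc}} (adding self-loop transitions to a
#' continuous-time Markov chain does not change its law).
#'
#' Two displacement statistics are recorded per species. \code{msd} is the
#' standard net mean squared displacement from unwrapped positions. Under
#' excluded volume the net MSD is reduced by the back-correlation of
#' single-molecule trajectories (a molecule preferentially re-enters the
#' vacancy it just left), a microscopic memory effect that a mesoscopic
#' method cannot see; \code{msdEffective} therefore accumulates the squared
#' displacement of every executed hop (\eqn{a^2 \times} hops), the total
#' "effective" displacement actually performed. For a free walker the two
#' coincide in expectation; \code{msdEffective} is the quantity comparable
#' with the density-based estimator of \code{\link{msdFromDensity}}.
#'
#' @param scenario a lattice-mode \linkS4class{Scenario}.
#' @param reps number of repetitions.
#' @param recordTimes increasing positive times (ms).
#' @return A \linkS4class{KmcRun}.
#' @export
runKmcEnsemble <- function(scenario, reps, recordTimes) {
  if (scenario@mode != "lattice")
    stop("kinetic Monte Carlo requires a lattice-mode scenario")
  stopifnot(reps >= 1, all(recordTimes > 0), all(diff(recordTimes) > 0))
  a <- scenario@siteSide
  nSites <- as.integer(round(scenario@geometry@L / a))
  f <- as.integer(round(scenario@geometry@dx / a))
  nms <- speciesNames(scenario)
  pl <- scenario@placement
  spIdx <- match(pl$species, nms) - 1L
  hopRate <- vapply(scenario@species, function(s) s@D0 / a^2, numeric(1))
  mobile <- vapply(scenario@species, function(s) s@mobile, logical(1))
  res <- kmc_ensemble_cpp(nSites, spIdx, pl$si, pl$sj, hopRate, mobile,
                          recordTimes, f, as.integer(reps))
  n <- scenario@geometry@n
  nt <- length(recordTimes)
  dens <- lapply(seq_along(nms), function(s) {
    arr <- array(0, dim = c(n, n, nt + 1L))
    arr[, , 1L] <- scenario@densities[[nms[s]]]
    arr[, , -1L] <- res$occ[, , s, ]
    arr
  })
  names(dens) <- nms
  counts <- as.vector(table(factor(pl$species, levels = nms)))
  msd <- data.frame(time = rep(c(0, recordTimes), each = length(nms)),
                    species = rep(nms, nt + 1L),
                    msd = c(rep(0, length(nms)), as.vector(res$msd)) * a^2,
                    msdEffective = c(rep(0, length(nms)),
                                     as.vector(res$hops)) * a^2,
                    n = rep(counts, nt + 1L))
  new("KmcRun", times = c(0, recordTimes), densities = dens, msd = msd,
      reps = as.integer(reps), scenario = scenario)
}

#' Pool kMC mean squared displacements over species
#'
#' Molecule-count-weighted combination of per-species MSD series; only
#' meaningful for species with identical size and diffusion coefficient
#' (then every molecule samples the same displacement law and pooling is
#' pure variance reduction).
#'
#' @param run a \linkS4class{KmcRun}.
#' @param species species to pool (default: all).
#' @param estimator \code{"net"} for the standard unwrapped MSD,
#'   \code{"effective"} for the accumulated-hop displacement comparable with
#'   the mesoscopic density-based estimator (see
#'   \code{\link{runKmcEnsemble}}).
#' @return data.frame (time, msd, n).
#' @export
pooledMsd <- function(run, species = NULL, estimator = c("net", "effective")) {
  estimator <- match.arg(estimator)
  m <- run@msd
  if (!is.null(species)) m <- m[m$species %in% species, ]
  col <- if (estimator == "net") m$msd else m$msdEffective
  m$value <- col
  out <- do.call(rbind, lapply(split(m, m$time), function(g)
    data.frame(time = g$time[1], msd = sum(g$value * g$n) / sum(g$n),
               n = sum(g$n))))
  rownames(out) <- NULL
  out[order(out$time), , drop = FALSE]
}
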