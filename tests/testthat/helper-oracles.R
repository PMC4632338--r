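# Shared fixtures and independent oracles, built in code at test time.

# Four-neighbour average with periodic wrap: the finite-difference update at
# the stability limit, written independently of the engine's streaming code.
fdNeighbourAverage <- function(rho) {
  n <- nrow(rho)
  up <- rho[c(2:n, 1), ]; down <- rho[c(n, 1:(n - 1)), ]
  left <- rho[, c(2:n, 1)]; right <- rho[, c(n, 1:(n - 1))]
  (up + down + left + right) / 4
}

# Small disk-mode scenario straight from density matrices (no placement),
# for engine-level tests that need full control of the initial condition.
diskScenario <- function(densities, species, dx = 50, dt = NULL) {
  n <- nrow(densities[[1]])
  if (is.null(dt)) dt <- dx^2 / (4 * species[[1]]@D0) # omega = 1
  names(densities) <- vapply(species, function(s) s@name, character(1))
  new("Scenario", geometry = latticeGeometry(n * dx, dx, dt),
      species = species, densities = densities, mode = "disk",
      siteSide = NA_real_,
      placement = data.frame(species = character(0), si = integer(0),
                             sj = integer(0)),
      origins = data.frame(species = character(0), oi = integer(0),
                           oj = integer(0)),
      placementSpec = list(), seed = 1L, tEnd = 10 * dt, recordEvery = 1L,
      title = "test fixture")
}

# Metropolis-equilibrated hard-disk fluid in a periodic box plus a
# random-insertion estimate of the probability that a disk of radius rTracer
# finds free space: the brute-force oracle for the Scaled Particle Theory
# closed form.
hardDiskInsertionOracle <- function(nDisks, rCrowder, box, rTracer,
                                    sweeps = 400, nInsert = 20000) {
  g <- ceiling(sqrt(nDisks))
  stopifnot(box / g > 2 * rCrowder) # the starting grid must not overlap
  xy <- (expand.grid(x = seq_len(g), y = seq_len(g)) - 0.5) * (box / g)
  xy <- as.matrix(xy[seq_len(nDisks), ])
  minImage <- function(d) d - box * round(d / box)
  noOverlap <- function(p, others, rsum) {
    dx <- minImage(others[, 1] - p[1]); dy <- minImage(others[, 2] - p[2])
    all(dx * dx + dy * dy >= rsum^2)
  }
  step <- rCrowder
  for (s in seq_len(sweeps * nDisks)) {
    k <- sample.int(nDisks, 1)
    cand <- (xy[k, ] + runif(2, -step, step)) %% box
    if (noOverlap(cand, xy[-k, , drop = FALSE], 2 * rCrowder)) xy[k, ] <- cand
  }
  trial <- matrix(runif(2 * nInsert, 0, box), ncol = 2)
  hits <- vapply(seq_len(nInsert), function(i)
    noOverlap(trial[i, ], xy, rCrowder + rTracer), logical(1))
  mean(hits)
}
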