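# Small helper scenarios for the reference simulator.
oneWalker <- function(L = 30, dx = 30, D0 = 100, seed = 1) {
  newScenario("one walker", L = L, dx = dx, dt = 1, mode = "lattice",
              siteSide = 10, seed = seed, speciesSpecs = list(list(
                species = Species("X", area = 100, D0 = D0), count = 1,
                placement = list(type = "random-uniform"))))
}

test_that("event enumeration lists one event per free neighbour at rate D/a^2", {
  st <- kmcState(oneWalker())
  ev <- enumerateEvents(st)
  expect_equal(nrow(ev), 4L)                    # empty lattice: 4 events
  expect_equal(unique(ev$rate), 100 / 100)      # D/a^2 = 1 per ms
  expect_equal(attr(ev, "total"), 4)
  # D = 500, a = 10 gives the 5/ms per-direction rate
  st5 <- kmcState(oneWalker(D0 = 500))
  expect_equal(unique(enumerateEvents(st5)$rate), 5)
})

test_that("fully blocked molecules contribute no events", {
  # center molecule surrounded by four immobile neighbours on a 3x3-site grid
  center <- list(species = Species("X", area = 100, D0 = 100), count = 1,
                 placement = list(type = "fill-voxels",
                                  voxels = list(list(i = 0L, j = 0L, count = 1L))))
  sc <- newScenario("jammed", L = 30, dx = 30, dt = 1, mode = "lattice",
                    siteSide = 10, speciesSpecs = list(center))
  st <- kmcState(sc)
  # move the molecule to the center site and wall in its four neighbours
  st$grid[] <- 0L
  st$mols$si <- 1L; st$mols$sj <- 1L
  st$grid[2, 2] <- 1L
  walls <- rbind(c(1, 2), c(3, 2), c(2, 1), c(2, 3))
  st$grid[walls] <- 99L
  ev <- enumerateEvents(st)
  expect_equal(nrow(ev), 0L)
  expect_error(selectAndAdvance(st, ev), "jammed")
})

test_that("event selection is proportional to rates and the clock is exponential", {
  st0 <- kmcState(oneWalker(seed = 3))
  set.seed(10)
  dirs <- integer(600); dts <- numeric(600)
  for (k in seq_len(600)) {
    st <- st0
    ev <- enumerateEvents(st)
    st1 <- selectAndAdvance(st, ev)
    dirs[k] <- st1$mols$dxs * 10 + st1$mols$dys # encode the step taken
    dts[k] <- st1$t
  }
  # four equal-rate events: uniform over directions (chi-square at 1%)
  expect_gt(chisq.test(table(dirs))$p.value, 0.01)
  # waiting times: exponential with mean 1/R, R = 4 * D/a^2 = 4
  expect_equal(mean(dts), 1 / 4, tolerance = 0.17)
  expect_equal(var(dts), (1 / 4)^2, tolerance = 0.4)
})

test_that("a free walker's long-run position is uniform over sites", {
  sc <- oneWalker(seed = 4)
  st <- kmcState(sc)
  set.seed(11)
  visits <- integer(0)
  for (k in seq_len(2700)) {
    st <- selectAndAdvance(st, enumerateEvents(st))
    if (k %% 10 == 0) # thin to decorrelate (9 sites, ~1 hop/ms)
      visits <- c(visits, st$mols$si * 3 + st$mols$sj + 1)
  }
  expect_gt(chisq.test(tabulate(visits, 9))$p.value, 0.01)
})

test_that("excluded volume holds exactly along a crowded reference trajectory", {
  sc <- newScenario("crowded", L = 60, dx = 30, dt = 1, mode = "lattice",
                    siteSide = 10, seed = 5, speciesSpecs = list(list(
                      species = Species("X", area = 100, D0 = 100), count = 20,
                      placement = list(type = "random-uniform"))))
  st <- kmcState(sc)
  set.seed(12)
  for (k in seq_len(400)) {
    st <- selectAndAdvance(st, enumerateEvents(st))
    occ <- table(st$mols$si * st$nSites + st$mols$sj)
    expect_true(all(occ == 1))                     # one molecule per site
  }
  expect_equal(sort(unique(st$grid[st$grid > 0])), 1:20) # bookkeeping intact
})

test_that("free walker ensembles reproduce MSD = 4 D t and both estimators agree", {
  sc <- oneWalker(L = 200, dx = 100, D0 = 500, seed = 6)
  set.seed(13)
  run <- runKmcEnsemble(sc, reps = 1500, recordTimes = c(10, 20))
  m <- run@msd
  for (tt in c(10, 20)) {
    msd <- m$msd[m$time == tt]
    expect_equal(msd, 4 * 500 * tt, tolerance = 4 / sqrt(1500)) # ~4 SE
    # free walk: net and accumulated-hop displacement coincide in expectation
    expect_equal(m$msdEffective[m$time == tt], msd,
                 tolerance = 3 / sqrt(1500))
  }
})

test_that("compiled ensemble matches the reference simulator in distribution", {
  sc <- newScenario("ab", L = 200, dx = 100, dt = 1, mode = "lattice",
                    siteSide = 10, seed = 7, speciesSpecs = list(list(
                      species = Species("X", area = 100, D0 = 100), count = 30,
                      placement = list(type = "random-uniform"))))
  nRef <- 120; times <- c(1, 2)
  set.seed(14)
  refAcc <- array(0, dim = c(2, 2, length(times) + 1))
  refMsd <- 0
  for (r in seq_len(nRef)) {
    out <- runKmc(sc, recordTimes = times)
    refAcc <- refAcc + out$densities$X
    refMsd <- refMsd + out$msd$msd[out$msd$time == 2]
  }
  refOcc <- refAcc[, , 3] / nRef
  refMsd <- refMsd / nRef
  set.seed(15)
  cpp <- runKmcEnsemble(sc, reps = 1200, recordTimes = times)
  cppOcc <- voxelDensity(cpp, "X", 2)
  cppMsd <- cpp@msd$msd[cpp@msd$time == 2]
  # per-voxel mean occupancy: difference within 4 standard errors
  se <- sqrt(7.5 * (1 / nRef + 1 / 1200))
  expect_lt(max(abs(refOcc - cppOcc)), 4 * se)
  # per-molecule MSD (in sites^2 units ~ 4*rate*t): same law
  seMsd <- (4 * 1 * 2 * 100) * sqrt(1 / (30 * nRef) + 1 / (30 * 1200))
  expect_lt(abs(refMsd - cppMsd), 4 * seMsd)
  # mass conservation per species in the ensemble mean
  expect_equal(sum(cppOcc), 30, tolerance = 1e-9)
})

test_that("ensembles are reproducible under a fixed seed and shift with it", {
  sc <- example3(1000, seed = 8)
  set.seed(16)
  a <- runKmcEnsemble(sc, reps = 5, recordTimes = c(2.5, 5))
  set.seed(16)
  b <- runKmcEnsemble(sc, reps = 5, recordTimes = c(2.5, 5))
  expect_identical(a@densities, b@densities)
  expect_identical(a@msd, b@msd)
  set.seed(17)
  c3 <- runKmcEnsemble(sc, reps = 5, recordTimes = c(2.5, 5))
  expect_false(identical(a@densities, c3@densities))
})

test_that("placement infeasibility and non-lattice scenarios are rejected", {
  expect_error(newScenario("too many", L = 30, dx = 30, dt = 1,
    mode = "lattice", siteSide = 10, speciesSpecs = list(list(
      species = Species("X", area = 100, D0 = 100), count = 10,
      placement = list(type = "random-uniform")))), "infeasible|capacity")
  expect_error(runKmcEnsemble(example4(2), reps = 2, recordTimes = 1),
               "lattice")
})
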