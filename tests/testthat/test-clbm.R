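test_that("crowding correction scales movers by the target voxel probability", {
  # omega = 1 post-collision field over uniform density 10
  Flb <- equilibriumField(matrix(10, 3, 3))
  # P = 1 everywhere recovers the classical populations
  Fc <- crowdingCorrect(Flb, matrix(1, 3, 3))
  expect_equal(Fc[, , 2:5], Flb[, , 2:5])
  expect_equal(Fc[, , 1],
               fieldDensity(Flb) - (Flb[, , 2] + Flb[, , 3] + Flb[, , 4] + Flb[, , 5]))
  # all four neighbours full: every mover returns to rest
  Fc0 <- crowdingCorrect(Flb, matrix(0, 3, 3))
  expect_equal(Fc0[, , 1], matrix(10, 3, 3))
  expect_equal(sum(Fc0[, , 2:5]), 0)
  # one half-blocked neighbour: 2.5 * 0.5 mover, rest picks up the balance
  P <- matrix(1, 3, 3); P[2, 3] <- 0.5
  Fc1 <- crowdingCorrect(Flb, P)
  expect_equal(Fc1[2, 2, 2], 1.25)
  expect_equal(Fc1[2, 2, 1], 10 - (1.25 + 3 * 2.5))
  # movers never exceed their uncorrected value; per-voxel totals close exactly
  expect_true(all(Fc1[, , 2:5] <= Flb[, , 2:5] + 1e-15))
  expect_equal(fieldDensity(Fc1), matrix(10, 3, 3))
  expect_error(crowdingCorrect(Flb, matrix(2, 3, 3)), "0, 1")
})

test_that("full adjacent voxels of different species exchange nothing", {
  n <- 4
  dA <- matrix(0, n, n); dA[2, 2] <- 25
  dB <- matrix(0, n, n); dB[2, 3] <- 25
  sc <- crowdLBM:::.buildScenario("two full voxels", n * 50, 50, 0.625,
    "lattice", 10, 1L, 10, 1L, list(
      list(species = Species("A", area = 100, D0 = 1000), count = 25,
           placement = list(type = "fill-voxels",
                            voxels = list(list(i = 1L, j = 1L, count = 25L)))),
      list(species = Species("B", area = 100, D0 = 1000), count = 25,
           placement = list(type = "fill-voxels",
                            voxels = list(list(i = 1L, j = 2L, count = 25L))))))
  run <- runEngine(sc, "clbm", tEnd = 0.625)
  # A may spread up/down/left (free voxels) but not into B's full voxel
  expect_equal(voxelDensity(run, "A", 0.625)[2, 3], 0)
  expect_equal(voxelDensity(run, "B", 0.625)[2, 2], 0)
})

test_that("voxels surrounded by full voxels are frozen", {
  # all voxels at capacity except one corner: the center voxel, whose four
  # neighbours are all full, can move nothing; voxels next to the hole drain
  grid3 <- expand.grid(i = 0:2, j = 0:2)
  aVox <- grid3[!(grid3$i == 0 & grid3$j == 0), ]
  mk <- function(v) lapply(seq_len(nrow(v)), function(r)
    list(i = v$i[r], j = v$j[r], count = 25L))
  sc <- newScenario("packed but one", L = 150, dx = 50, dt = 0.625,
    mode = "lattice", siteSide = 10, tEnd = 10, speciesSpecs = list(
      list(species = Species("A", area = 100, D0 = 1000), count = 200,
           placement = list(type = "fill-voxels", voxels = mk(aVox)))))
  run <- runEngine(sc, "clbm", tEnd = 0.625)
  d1 <- voxelDensity(run, "A", 0.625)
  expect_equal(d1[2, 2], 25)   # center: all neighbours were full
  expect_gt(d1[1, 1], 0)       # the hole received movers
  expect_equal(sum(d1), 200, tolerance = 1e-9)
})

test_that("zero-size species make the corrected engine identical to the classical one", {
  set.seed(8)
  dens <- list(matrix(runif(64, 0, 10), 8, 8), matrix(runif(64, 0, 10), 8, 8))
  sc <- diskScenario(dens, list(Species("A", radius = 0, area = 0, D0 = 500),
                                Species("B", radius = 0, area = 0, D0 = 600)),
                     dx = 50)
  tEnd <- 100 * sc@geometry@dt
  rc <- runEngine(sc, "clbm", tEnd = tEnd, recordEvery = 100L)
  rl <- runEngine(sc, "lbm", tEnd = tEnd, recordEvery = 100L)
  expect_identical(rc@densities, rl@densities) # bitwise
})

test_that("crowding never widens the spatial spread relative to the classical engine", {
  sc <- labelOrigins(example1(), "A")
  mc <- msdFromDensity(runEngine(sc, "clbm", tEnd = 50))
  ml <- msdFromDensity(runEngine(sc, "lbm", tEnd = 50))
  expect_true(all(mc$msd <= ml$msd + 1e-9))
  expect_lt(mc$msd[mc$time == 30], ml$msd[ml$time == 30]) # strictly slower
})

test_that("corrected steps conserve mass per species over many cycles", {
  sc <- example3(1000, seed = 9)
  run <- runEngine(sc, "clbm", tEnd = 200 * 0.625, recordEvery = 200L)
  expect_equal(sum(voxelDensity(run, "tracer", 125)), 100, tolerance = 1e-9)
  expect_equal(sum(voxelDensity(run, "crowder", 125)), 1000, tolerance = 1e-9)
})

test_that("immobile species stay pinned but still obstruct movers", {
  grid5 <- expand.grid(i = 0:4, j = 0:4)
  wVox <- grid5[!(grid5$i == 2 & grid5$j == 2), ]
  tracerSpec <- list(species = Species("tracer", area = 100, D0 = 1000),
                     count = 10,
                     placement = list(type = "fill-voxels",
                                      voxels = list(list(i = 2L, j = 2L,
                                                         count = 10L))))
  sc <- newScenario("tracer among walls", L = 250, dx = 50, dt = 0.625,
    mode = "lattice", siteSide = 10, tEnd = 10, speciesSpecs = list(
      tracerSpec,
      list(species = Species("wall", area = 100, D0 = 1000, mobile = FALSE),
           count = 15L * nrow(wVox),
           placement = list(type = "fill-voxels",
                            voxels = lapply(seq_len(nrow(wVox)), function(r)
                              list(i = wVox$i[r], j = wVox$j[r], count = 15L))))))
  tf <- 10 * 0.625
  run <- runEngine(labelOrigins(sc, "tracer"), "clbm", tEnd = tf,
                   recordEvery = 10L)
  expect_equal(voxelDensity(run, "wall", tf), sc@densities$wall) # pinned
  tracerSub <- grep("^tracer", names(run@densities), value = TRUE)
  expect_equal(sum(voxelDensity(run, tracerSub, tf)), 10, tolerance = 1e-9)
  # the immobile background narrows the tracer's spread vs an empty lattice
  scFree <- newScenario("free tracer", L = 250, dx = 50, dt = 0.625,
    mode = "lattice", siteSide = 10, tEnd = 10,
    speciesSpecs = list(tracerSpec))
  runFree <- runEngine(labelOrigins(scFree, "tracer"), "clbm", tEnd = tf,
                       recordEvery = 10L)
  mWall <- msdFromDensity(run)
  mFree <- msdFromDensity(runFree)
  expect_lt(mWall$msd[mWall$time == tf], mFree$msd[mFree$time == tf])
})
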