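test_that("example 1 reproduces the packed first column at relaxation one", {
  sc <- example1()
  expect_equal(sum(sc@densities$A), 100)
  expect_equal(sum(sc@densities$B), 900)
  # every first-column voxel sits exactly at capacity
  col1 <- sc@densities$A[, 1] + sc@densities$B[, 1]
  expect_equal(col1, rep(100, 10))
  expect_equal(unname(col1[6]), voxelCapacity(100, 100) * 1) # the A voxel
  expect_equal(sc@densities$A[6, 1], 100)
  expect_true(all((sc@densities$A + sc@densities$B)[, -1] == 0))
  for (s in sc@species)
    expect_equal(computeOmega(s@D0, sc@geometry@dt, sc@geometry@dx), 1)
  # the A voxel row is configurable
  expect_equal(example1(aRow = 2L)@densities$A[3, 1], 100)
})

test_that("example 2 fills regions 3-5 at voxel capacity", {
  sc <- example2()
  expect_equal(vapply(sc@densities, sum, numeric(1)),
               c(A = 1000, B = 1000, C = 1000))
  expect_equal(sum(sc@densities$A > 0), 40)       # 2 columns x 20 rows
  expect_true(all(sc@densities$A[, 5:6] == 25))   # at capacity 25
  expect_true(all(sc@densities$B[, 7:8] == 25))
  expect_true(all(sc@densities$C[, 9:10] == 25))
  omg <- vapply(sc@species, function(s)
    computeOmega(s@D0, sc@geometry@dt, sc@geometry@dx), numeric(1))
  expect_equal(omg[1], 1)
  expect_true(all(omg > 0 & omg <= 1))
})

test_that("example 3 placements respect capacity and the argument catalogue", {
  sc <- example3(4000, seed = 21)
  expect_equal(sum(sc@densities$tracer), 100)
  expect_equal(sum(sc@densities$crowder), 4000)
  cap <- voxelCapacity(50, 100)
  expect_true(all(sc@densities$tracer + sc@densities$crowder <= cap))
  expect_equal(nrow(sc@placement), 4100)
  # one molecule per site
  expect_false(any(duplicated(sc@placement[, c("si", "sj")])))
  sc0 <- example3(0)
  expect_identical(speciesNames(sc0), "tracer")
  expect_error(example3(500), "one of")
})

test_that("disk examples audit the declared area fractions", {
  sc4 <- example4(2, seed = 22)
  crowderArea <- 0
  for (s in sc4@species)
    if (s@name != "tracer")
      crowderArea <- crowderArea + sum(sc4@densities[[s@name]]) * s@area
  expect_equal(crowderArea / 1e6, 0.30, tolerance = 1e-3)
  expect_equal(sum(sc4@densities$tracer), 796)
  # point-like tracer variant
  expect_equal(example4(0)@species[[1]]@area, 0)
  expect_error(example4(3), "one of")
  for (r in c(2, 1.5, 1)) {
    sc5 <- example5(r, seed = 23)
    cr <- sc5@species[[2]]
    expect_equal(sum(sc5@densities$crowder) * cr@area / 1e6, 0.30,
                 tolerance = 1e-3)
    expect_equal(sum(sc5@densities$tracer) * pi * 1.5^2 / 1e6, 0.01,
                 tolerance = 1e-3)
  }
  expect_equal(sum(example5(1)@densities$crowder), 95493)
  expect_error(example5(0.5), "one of")
})

test_that("regeneration with the same seed is bit-identical, different seeds differ", {
  a <- example3(2000, seed = 31)
  b <- example3(2000, seed = 31)
  expect_identical(a@densities, b@densities)
  expect_identical(a@placement, b@placement)
  c4a <- example4(1.5, seed = 31)
  c4b <- example4(1.5, seed = 31)
  expect_identical(c4a@densities, c4b@densities)
  expect_false(identical(a@densities, example3(2000, seed = 32)@densities))
})

test_that("scenario placement does not disturb the caller's RNG stream", {
  set.seed(40); before <- runif(3)
  set.seed(40); invisible(example3(1000, seed = 41)); after <- runif(3)
  expect_identical(before, after)
})

test_that("table parameters round-trip through config serialization unchanged", {
  for (sc in list(example1(), example2(), example3(3000, seed = 51),
                  example4(1.5, seed = 52))) {
    path <- tempfile(fileext = ".yaml")
    writeScenarioConfig(sc, path)
    back <- readScenarioConfig(path)
    expect_identical(back@densities, sc@densities)
    expect_identical(back@placement, sc@placement)
    expect_equal(back@geometry, sc@geometry)
    expect_equal(back@species, sc@species)
    expect_identical(back@placementSpec, sc@placementSpec)
    unlink(path)
  }
})

test_that("origin labeling conserves molecules and records origin voxels", {
  sc <- example3(1000, seed = 61)
  scl <- labelOrigins(sc, "tracer")
  labs <- grep("^tracer\\.o", speciesNames(scl), value = TRUE)
  expect_gt(length(labs), 50)
  expect_equal(sum(vapply(scl@densities[labs], sum, numeric(1))), 100)
  expect_identical(scl@densities$crowder, sc@densities$crowder)
  # each subspecies density sits entirely on its recorded origin voxel
  for (r in sample(nrow(scl@origins), 10)) {
    d <- scl@densities[[scl@origins$species[r]]]
    expect_equal(sum(d > 0), 1)
    expect_gt(d[scl@origins$oi[r] + 1, scl@origins$oj[r] + 1], 0)
  }
  # placement labels follow the molecules (kMC stays runnable)
  expect_equal(sort(unique(scl@placement$species[
    startsWith(scl@placement$species, "tracer")])), sort(labs))
})
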