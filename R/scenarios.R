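# Evaluate expr with a temporary, seeded RNG state; the caller's RNG stream
# is left untouched.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
              rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Core scenario builder. speciesSpecs is a list of
#   list(species = <Species>, count = N, placement = list(type = ..., ...))
# Placement types:
#   fill-voxels:    voxels = list(list(i =, j =, count =)) (0-based voxels),
#                   deterministic row-major fill of sites within each voxel
#   random-uniform: uniform over free sites (lattice) / voxels (disk),
#                   drawn from the scenario seed
.buildScenario <- function(title, L, dx, dt, mode, siteSide, seed, tEnd,
                           recordEvery, speciesSpecs) {
  geo <- latticeGeometry(L, dx, dt)
  n <- geo@n
  nms <- vapply(speciesSpecs, function(x) x$species@name, character(1))
  densities <- rep(list(matrix(0, n, n)), length(nms))
  names(densities) <- nms
  placement <- data.frame(species = character(0), si = integer(0), sj = integer(0))

  .withSeed(seed, {
    if (mode == "lattice") {
      f <- dx / siteSide
      if (abs(f - round(f)) > 1e-9) stop("dx must be a multiple of siteSide")
      f <- as.integer(round(f))
      nSites <- n * f
      free <- matrix(TRUE, nSites, nSites)
      for (spec in speciesSpecs) {
        nm <- spec$species@name
        pl <- spec$placement
        if (pl$type == "fill-voxels") {
          si <- sj <- integer(0)
          for (v in pl$voxels) {
            rows <- v$i * f + seq_len(f) - 1L   # 0-based site rows of voxel
            cols <- v$j * f + seq_len(f) - 1L
            cells <- expand.grid(si = rows, sj = cols)     # row-major fill
            ok <- free[cbind(cells$si + 1L, cells$sj + 1L)]
            cells <- cells[ok, , drop = FALSE]
            if (nrow(cells) < v$count)
              stop(sprintf("voxel (%d,%d) cannot hold %d more '%s' molecules",
                           v$i, v$j, v$count, nm))
            cells <- cells[seq_len(v$count), , drop = FALSE]
            free[cbind(cells$si + 1L, cells$sj + 1L)] <- FALSE
            si <- c(si, cells$si); sj <- c(sj, cells$sj)
          }
        } else if (pl$type == "random-uniform") {
          idx <- which(free)
          if (length(idx) < spec$count)
            stop(sprintf("placement infeasible: %d molecules of '%s', %d free sites",
                         spec$count, nm, length(idx)))
          pick <- if (spec$count > 0) sample(idx, spec$count) else integer(0)
          free[pick] <- FALSE
          si <- (pick - 1L) %% nSites            # 0-based
          sj <- (pick - 1L) %/% nSites
        } else stop("unknown placement type: ", pl$type)
        if (length(si) > 0) {
          placement <- rbind(placement,
                             data.frame(species = nm, si = si, sj = sj))
          vox <- cbind((si %/% f) + 1L, (sj %/% f) + 1L)
          for (r in seq_along(si))
            densities[[nm]][vox[r, 1L], vox[r, 2L]] <-
              densities[[nm]][vox[r, 1L], vox[r, 2L]] + 1
        }
      }
    } else { # disk mode: voxel-resolution placement
      for (spec in speciesSpecs) {
        nm <- spec$species@name
        pl <- spec$placement
        if (pl$type == "fill-voxels") {
          for (v in pl$voxels)
            densities[[nm]][v$i + 1L, v$j + 1L] <-
              densities[[nm]][v$i + 1L, v$j + 1L] + v$count
        } else if (pl$type == "random-uniform") {
          if (spec$count > 0) {
            vox <- sample.int(n * n, spec$count, replace = TRUE)
            tab <- tabulate(vox, nbins = n * n)
            densities[[nm]] <- densities[[nm]] + matrix(tab, n, n)
          }
        } else stop("unknown placement type: ", pl$type)
      }
    }
  })

  specs <- lapply(speciesSpecs, function(x)
    c(list(count = x$count), x$placement))
  names(specs) <- nms
  sc <- new("Scenario", geometry = geo,
            species = lapply(speciesSpecs, `[[`, "species"),
            densities = densities, mode = mode,
            siteSide = if (mode == "lattice") siteSide else NA_real_,
            placement = placement,
            origins = data.frame(species = character(0), oi = integer(0),
                                 oj = integer(0)),
            placementSpec = specs, seed = as.integer(seed),
            tEnd = tEnd, recordEvery = as.integer(recordEvery), title = title)
  validObject(sc)
  sc
}

#' Construct a scenario from species and placement specifications
#'
#' General constructor behind the example catalogue and the config reader.
#' Each element of \code{speciesSpecs} is a list with a \code{species}
#' (\linkS4class{Species}), a \code{count}, and a \code{placement} list of
#' type \code{"fill-voxels"} (with \code{voxels} = list of
#' \code{list(i =, j =, count =)}, 0-based voxel indices, deterministic
#' row-major fill of sites within the voxel) or \code{"random-uniform"}
#' (uniform over free sites in lattice mode, over voxels in disk mode, drawn
#' from \code{seed}). Species are placed in list order.
#'
#' @param title short description.
#' @param L,dx,dt geometry (nm, nm, ms).
#' @param mode \code{"lattice"} or \code{"disk"}.
#' @param siteSide side of a kMC site (nm; lattice mode only).
#' @param seed placement seed.
#' @param tEnd,recordEvery default run schedule.
#' @param speciesSpecs list of per-species specifications (see above).
#' @return A \linkS4class{Scenario}.
#' @examples
#' newScenario("one walker", L = 100, dx = 50, dt = 1.25, mode = "lattice",
#'   siteSide = 10, seed = 1, speciesSpecs = list(list(
#'     species = Species("X", area = 100, D0 = 500), count = 1,
#'     placement = list(type = "random-uniform"))))
#' @export
newScenario <- function(title, L, dx, dt, mode = c("lattice", "disk"),
                        siteSide = NA_real_, seed = 1L, tEnd = 50,
                        recordEvery = 1L, speciesSpecs = list()) {
  .buildScenario(title, L, dx, dt, match.arg(mode), siteSide, seed, tEnd,
                 recordEvery, speciesSpecs)
}

#' Species names of a scenario or run
#'
#' @param x a \linkS4class{Scenario}, \linkS4class{DiffusionRun} or
#'   \linkS4class{KmcRun}.
#' @return Character vector of species names.
#' @export
speciesNames <- function(x) {
  if (is(x, "Scenario")) vapply(x@species, function(s) s@name, character(1))
  else names(x@densities)
}

#' Two-species front on a packed first column (lattice model)
#'
#' (1000 nm)^2 lattice, 100 nm voxels, 5 ms steps, square (10 nm)^2
#' molecules. Every voxel of the first column is filled to capacity (100
#' molecules): one voxel with 100 tracer molecules A, the remaining nine
#' with 900 molecules B; both species have D0 = 500 nm^2/ms, so the
#' relaxation parameter is exactly 1. Diffusion along the column is hindered
#' by B while the row of the A voxel is obstacle-free.
#'
#' @param seed placement seed (the placement is deterministic here; the seed
#'   is recorded for the manifest).
#' @param aRow 0-based row of the voxel holding species A (default 5, the
#'   middle of the column; the vertical/horizontal profile behaviour is
#'   invariant to this choice up to translation under periodic boundaries).
#' @return A \linkS4class{Scenario}.
#' @examples
#' sc <- example1()
#' sum(sc@densities$A); sum(sc@densities$B)  # 100, 900
#' @export
example1 <- function(seed = 1L, aRow = 5L) {
  stopifnot(aRow >= 0L, aRow <= 9L)
  a <- list(species = Species("A", area = 100, D0 = 500), count = 100,
            placement = list(type = "fill-voxels",
                             voxels = list(list(i = aRow, j = 0L, count = 100L))))
  bRows <- setdiff(0:9, aRow)
  b <- list(species = Species("B", area = 100, D0 = 500), count = 900,
            placement = list(type = "fill-voxels",
                             voxels = lapply(bRows, function(r)
                               list(i = r, j = 0L, count = 100L))))
  .buildScenario("example 1: two-species packed first column", 1000, 100, 5,
                 "lattice", 10, seed, 50, 1L, list(a, b))
}

#' Three packed two-column regions (lattice model)
#'
#' (1000 nm)^2 lattice, 50 nm voxels, 0.625 ms steps. The lattice is divided
#' into ten two-column regions of 20 voxels; regions 3, 4 and 5 (taken
#' left-to-right, i.e. 0-based voxel columns 4-5, 6-7, 8-9) are filled at
#' capacity (25 molecules per voxel) with species A, B and C respectively
#' (D0 = 1000, 1050, 1100 nm^2/ms; 1000 molecules each).
#'
#' @param seed recorded placement seed (placement is deterministic).
#' @param firstRegionColumn 0-based leftmost voxel column of region 3
#'   (default 4).
#' @return A \linkS4class{Scenario}.
#' @export
example2 <- function(seed = 1L, firstRegionColumn = 4L) {
  D <- c(A = 1000, B = 1050, C = 1100)
  specs <- lapply(seq_along(D), function(k) {
    cols <- firstRegionColumn + 2L * (k - 1L) + 0:1
    list(species = Species(names(D)[k], area = 100, D0 = unname(D[k])),
         count = 1000,
         placement = list(type = "fill-voxels",
                          voxels = unlist(lapply(cols, function(cc)
                            lapply(0:19, function(r)
                              list(i = r, j = cc, count = 25L))),
                            recursive = FALSE)))
  })
  .buildScenario("example 2: three packed two-column regions", 1000, 50, 0.625,
                 "lattice", 10, seed, 50, 1L, specs)
}

#' Tracer among randomly placed crowders (lattice model)
#'
#' (1000 nm)^2 lattice, 50 nm voxels, 0.625 ms steps. 100 tracer molecules
#' (1\% of the lattice area) and 0 to 4000 crowder molecules (0-40\% of the
#' lattice area), all square (10 nm)^2 molecules with D0 = 1000 nm^2/ms,
#' placed uniformly at random over free sites with the given seed.
#'
#' @param crowders crowder count: 0, 1000, 2000, 3000 or 4000.
#' @param seed placement seed.
#' @return A \linkS4class{Scenario}.
#' @export
example3 <- function(crowders = 1000, seed = 1L) {
  if (!crowders %in% c(0, 1000, 2000, 3000, 4000))
    stop("'crowders' must be one of 0, 1000, 2000, 3000, 4000")
  specs <- list(list(species = Species("tracer", area = 100, D0 = 1000),
                     count = 100,
                     placement = list(type = "random-uniform")))
  if (crowders > 0)
    specs <- c(specs, list(list(
      species = Species("crowder", area = 100, D0 = 1000),
      count = crowders, placement = list(type = "random-uniform"))))
  .buildScenario(sprintf("example 3: tracer with %d crowders", crowders),
                 1000, 50, 0.625, "lattice", 10, seed, 50, 1L, specs)
}

#' Hard-disk tracer in a five-species crowded mixture
#'
#' (1000 nm)^2 lattice, 50 nm voxels, 0.625 ms steps, hard-disk mode. 796
#' tracer molecules of radius 2, 1.5, 1 or 0 nm (D0 = 1000 nm^2/ms) diffuse
#' among four crowder species of radii 1.9, 1.8, 1.6 and 1.5 nm (6172, 9824,
#' 6217 and 11318 molecules; D0 = 1050, 1100, 1200, 1250 nm^2/ms) that
#' together occupy 30\% of the lattice area. All molecules are placed
#' uniformly at random.
#'
#' @param rTracer tracer radius: 2, 1.5, 1 or 0 nm.
#' @param seed placement seed.
#' @return A \linkS4class{Scenario}.
#' @export
example4 <- function(rTracer = 2, seed = 1L) {
  if (!rTracer %in% c(2, 1.5, 1, 0))
    stop("'rTracer' must be one of 2, 1.5, 1, 0")
  tracer <- if (rTracer > 0) Species("tracer", radius = rTracer, D0 = 1000)
            else Species("tracer", radius = 0, area = 0, D0 = 1000)
  crow <- list(c(1.9, 6172, 1050), c(1.8, 9824, 1100),
               c(1.6, 6217, 1200), c(1.5, 11318, 1250))
  specs <- c(list(list(species = tracer, count = 796,
                       placement = list(type = "random-uniform"))),
             lapply(seq_along(crow), function(k)
               list(species = Species(paste0("crowder", k),
                                      radius = crow[[k]][1], D0 = crow[[k]][3]),
                    count = crow[[k]][2],
                    placement = list(type = "random-uniform"))))
  sc <- .buildScenario(sprintf("example 4: hard-disk tracer r = %g nm", rTracer),
                       1000, 50, 0.625, "disk", NA_real_, seed, 50, 1L, specs)
  .auditAreaFraction(sc, exclude = "tracer", declared = 0.30)
  sc
}

#' Crowder-size effect at fixed 30 percent occupancy
#'
#' (1000 nm)^2 lattice, 50 nm voxels, 0.625 ms steps, hard-disk mode. 1414
#' tracer molecules of radius 1.5 nm (1\% of the lattice area) among a single
#' crowder species occupying 30\% of the area with radius 2, 1.5 or 1 nm
#' (23873, 42441 or 95493 molecules; D0 = 1000 nm^2/ms for both species).
#' Smaller crowders at equal total area mean more obstacles and slower
#' tracer diffusion.
#'
#' @param rCrowder crowder radius: 2, 1.5 or 1 nm.
#' @param seed placement seed.
#' @return A \linkS4class{Scenario}.
#' @export
example5 <- function(rCrowder = 2, seed = 1L) {
  counts <- c(`2` = 23873, `1.5` = 42441, `1` = 95493)
  key <- as.character(rCrowder)
  if (!key %in% names(counts)) stop("'rCrowder' must be one of 2, 1.5, 1")
  specs <- list(
    list(species = Species("tracer", radius = 1.5, D0 = 1000), count = 1414,
         placement = list(type = "random-uniform")),
    list(species = Species("crowder", radius = rCrowder, D0 = 1000),
         count = unname(counts[key]),
         placement = list(type = "random-uniform")))
  sc <- .buildScenario(sprintf("example 5: crowder radius %g nm", rCrowder),
                       1000, 50, 0.625, "disk", NA_real_, seed, 50, 1L, specs)
  .auditAreaFraction(sc, exclude = "tracer", declared = 0.30)
  sc
}

# Disk-mode audit: total crowder area fraction matches the declared value
# within 0.1 percentage points, and no voxel starts saturated.
.auditAreaFraction <- function(scenario, exclude, declared) {
  tot <- 0
  for (s in scenario@species)
    if (!s@name %in% exclude)
      tot <- tot + sum(scenario@densities[[s@name]]) * s@area
  frac <- tot / scenario@geometry@L^2
  if (abs(frac - declared) > 1e-3)
    stop(sprintf("crowder area fraction %.4f differs from declared %.2f", frac, declared))
  radii <- vapply(scenario@species, function(s) ifelse(is.na(s@radius), 0, s@radius),
                  numeric(1))
  nms <- vapply(scenario@species, function(s) s@name, character(1))
  S2 <- sptMoments(scenario@densities[nms], radii, scenario@geometry@dx)$S2
  if (any(S2 >= 1)) stop("initial placement saturates a voxel (S2 >= 1)")
  invisible(scenario)
}

#' Split a species into origin-labeled subspecies
#'
#' Replaces each named species by one subspecies per initially occupied
#' voxel (named \code{<species>.o<i>_<j>}, 0-based voxel indices), with
#' identical physical parameters. Because the crowding coupling acts only
#' through total densities, the relabeled scenario has exactly the same
#' dynamics while exposing where each subpopulation started -- the basis of
#' the mean-squared-displacement estimator for mesoscopic runs
#' (\code{\link{msdFromDensity}}).
#'
#' @param scenario a \linkS4class{Scenario}.
#' @param species character vector of species names to label (default:
#'   the species named \code{"tracer"}).
#' @return A new \linkS4class{Scenario} with the \code{origins} slot filled.
#' @export
labelOrigins <- function(scenario, species = "tracer") {
  stopifnot(all(species %in% speciesNames(scenario)))
  newSpecies <- list(); newDens <- list()
  origins <- data.frame(species = character(0), oi = integer(0), oj = integer(0))
  n <- scenario@geometry@n
  placement <- scenario@placement
  for (s in scenario@species) {
    if (!s@name %in% species) {
      newSpecies <- c(newSpecies, list(s))
      newDens[[s@name]] <- scenario@densities[[s@name]]
      next
    }
    dn <- scenario@densities[[s@name]]
    occ <- which(dn > 0, arr.ind = TRUE)
    for (r in seq_len(nrow(occ))) {
      oi <- occ[r, 1L] - 1L; oj <- occ[r, 2L] - 1L
      nm <- sprintf("%s.o%d_%d", s@name, oi, oj)
      sub <- s; sub@name <- nm
      d <- matrix(0, n, n); d[oi + 1L, oj + 1L] <- dn[oi + 1L, oj + 1L]
      newSpecies <- c(newSpecies, list(sub))
      newDens[[nm]] <- d
      origins <- rbind(origins, data.frame(species = nm, oi = oi, oj = oj))
    }
    if (nrow(placement) > 0) {
      sel <- placement$species == s@name
      f <- as.integer(round(scenario@geometry@dx / scenario@siteSide))
      placement$species[sel] <- sprintf("%s.o%d_%d", s@name,
                                        placement$si[sel] %/% f,
                                        placement$sj[sel] %/% f)
    }
  }
  sc <- scenario
  sc@species <- newSpecies
  sc@densities <- newDens
  sc@origins <- origins
  sc@placement <- placement
  sc@placementSpec <- list()  # labeled scenarios are derived, not serialized
  validObject(sc)
  sc
}

#' Write a scenario configuration file
#'
#' Serializes the scenario parameters and placement specification to YAML.
#' Random placements are stored as their seed, so
#' \code{\link{readScenarioConfig}} regenerates the scenario bit-identically.
#'
#' @param scenario a \linkS4class{Scenario} (not origin-labeled).
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeScenarioConfig <- function(scenario, path) {
  if (length(scenario@placementSpec) == 0)
    stop("scenario has no placement specification (derived scenarios cannot be serialized)")
  geo <- scenario@geometry
  species <- lapply(scenario@species, function(s) {
    spec <- scenario@placementSpec[[s@name]]
    entry <- list(name = s@name)
    if (!is.na(s@radius)) entry$radius_nm <- s@radius
    entry$area_nm2 <- s@area
    entry$D0_nm2_per_ms <- s@D0
    entry$mass_g <- s@mass
    entry$mobile <- s@mobile
    entry$count <- spec$count
    entry$placement <- spec[setdiff(names(spec), "count")]
    entry
  })
  cfg <- list(title = scenario@title, mode = scenario@mode,
              lattice = list(L_nm = geo@L, dx_nm = geo@dx, dt_ms = geo@dt),
              site_nm = if (is.na(scenario@siteSide)) NULL else scenario@siteSide,
              run = list(t_end_ms = scenario@tEnd,
                         record_every_steps = scenario@recordEvery,
                         seed = scenario@seed),
              species = species)
  writeLines(yaml::as.yaml(cfg, precision = 15L), path)
  invisible(path)
}

#' Read a scenario configuration file
#'
#' @param path YAML file written by \code{\link{writeScenarioConfig}} (or by
#'   hand in the same schema).
#' @return A \linkS4class{Scenario}.
#' @export
readScenarioConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  specs <- lapply(cfg$species, function(e) {
    sp <- Species(e$name,
                  radius = if (is.null(e$radius_nm)) NA_real_ else e$radius_nm,
                  area = e$area_nm2, D0 = e$D0_nm2_per_ms,
                  mass = if (is.null(e$mass_g)) 1 else e$mass_g,
                  mobile = if (is.null(e$mobile)) TRUE else e$mobile)
    pl <- e$placement
    if (identical(pl$type, "fill-voxels"))
      pl$voxels <- lapply(pl$voxels, function(v)
        list(i = as.integer(v$i), j = as.integer(v$j), count = as.integer(v$count)))
    list(species = sp, count = e$count, placement = pl)
  })
  .buildScenario(cfg$title, cfg$lattice$L_nm, cfg$lattice$dx_nm,
                 cfg$lattice$dt_ms, cfg$mode,
                 if (is.null(cfg$site_nm)) NA_real_ else cfg$site_nm,
                 cfg$run$seed, cfg$run$t_end_ms, cfg$run$record_every_steps,
                 specs)
}
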