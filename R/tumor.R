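#' Tumor cell parameters
#'
#' Defaults describe a breast-adenocarcinoma-like (MCF-7-style) monoculture
#' embedded in a homogeneous gel: linear volume growth up to a division
#' threshold, slightly asymmetric division that conserves volume exactly,
#' Brownian migration, and a small per-step apoptosis probability. The
#' quantitative values are qualitative module defaults, not reproductions of
#' any measured dataset.
#'
#' @param volumeGrowthRate volume added per unit time (um^3 / h).
#' @param divisionDiameter diameter triggering division (um); must exceed
#'   `initialDiameter`.
#' @param divisionVolumeRatioRange interval within (0, 1), symmetric about
#'   0.5, for the daughter volume fraction u ~ Uniform(range).
#' @param migrationSigma Brownian scale (um / sqrt(h)); per-coordinate
#'   increments are Normal(0, sigma^2 dt).
#' @param pApoptosis per-step death probability.
#' @param initialDiameter diameter of newly seeded / daughter reset cells (um).
#' @return A `"TumorCellParams"` list.
#' @export
tumorCellParams <- function(volumeGrowthRate = 60, divisionDiameter = 18,
                            divisionVolumeRatioRange = c(0.45, 0.55),
                            migrationSigma = 0.5, pApoptosis = 2e-4,
                            initialDiameter = 14) {
  stopifnot(volumeGrowthRate >= 0, divisionDiameter > initialDiameter,
            length(divisionVolumeRatioRange) == 2L,
            all(divisionVolumeRatioRange > 0),
            all(divisionVolumeRatioRange < 1),
            abs(sum(divisionVolumeRatioRange) - 1) < 1e-12,
            migrationSigma >= 0, pApoptosis >= 0, pApoptosis <= 1,
            initialDiameter > 0)
  structure(list(volumeGrowthRate = volumeGrowthRate,
                 divisionDiameter = divisionDiameter,
                 ratioRange = divisionVolumeRatioRange,
                 migrationSigma = migrationSigma,
                 pApoptosis = pApoptosis,
                 initialDiameter = initialDiameter),
            class = "TumorCellParams")
}

sphereVolume <- function(d) pi * d^3 / 6
sphereDiameter <- function(v) (6 * v / pi)^(1 / 3)

#' Tumor cell behaviors for the generic engine
#'
#' Growth/division, Brownian migration and apoptosis as engine behaviors.
#' Division conserves volume exactly: the daughter receives fraction
#' u ~ Uniform(ratio range) of the mother volume and is placed one mother
#' radius away in a uniform random direction (queued, visible next
#' iteration); behaviors transfer according to their division flags.
#'
#' @param params a [tumorCellParams()].
#' @return list of [behaviorSpec()] objects.
#' @keywords internal
tumorBehaviors <- function(params) {
  growth <- behaviorSpec("tumor-growth-division", function(sim, ids) {
    pop <- sim$population
    rows <- match(ids, agentIds(pop))
    vol <- agentAttr(pop, "volume")
    vol[rows] <- vol[rows] + params$volumeGrowthRate * sim$params$timeStep
    dividing <- rows[sphereDiameter(vol[rows]) >= params$divisionDiameter]
    diam <- diameters(pop)
    for (row in dividing) {
      u <- runif(1, params$ratioRange[1], params$ratioRange[2])
      vDaughter <- u * vol[row]
      vMother <- vol[row] - vDaughter
      dir <- rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      split <- transferBehaviors(pop@behaviors[[row]], sim$behaviors)
      pos <- positions(pop)[row, ] + dir * diam[row] / 2
      queueNewAgent(sim$ctx, newAgent(
        id = allocateIds(sim), position = pos,
        diameter = sphereDiameter(vDaughter),
        behaviors = split$daughter,
        attrs = list(volume = vDaughter)))
      vol[row] <- vMother
      diam[row] <- sphereDiameter(vMother)
      pop@behaviors[[row]] <- split$mother
    }
    diam[rows] <- sphereDiameter(vol[rows])
    agentAttr(pop, "volume") <- vol
    diameters(pop) <- diam
    sim$population <- pop
    invisible(NULL)
  })
  migration <- behaviorSpec("tumor-migration", function(sim, ids) {
    pop <- sim$population
    rows <- match(ids, agentIds(pop))
    dt <- sim$params$timeStep
    inc <- matrix(rnorm(3 * length(rows), 0,
                        params$migrationSigma * sqrt(dt)), ncol = 3)
    p <- positions(pop)
    p[rows, ] <- p[rows, ] + inc
    positions(pop) <- applyDisplacements(p, matrix(0, nrow(p), 3),
                                         sim$params$bounds,
                                         sim$params$boundaryMode)
    sim$population <- pop
    invisible(NULL)
  })
  apoptosis <- behaviorSpec("tumor-apoptosis", function(sim, ids) {
    dies <- ids[runif(length(ids)) < params$pApoptosis]
    for (id in dies) queueRemoval(sim$ctx, id)
    invisible(NULL)
  })
  list(growth, migration, apoptosis)
}

#' Seed a spheroid of cells uniformly in a ball
#'
#' The ball radius is chosen so the cells occupy a target packing fraction:
#' \eqn{R = (d/2) (n/\phi)^{1/3}}.
#'
#' @param n number of cells.
#' @param cellDiameter initial cell diameter (um).
#' @param packingFraction target cell-volume fraction of the ball.
#' @param center ball center.
#' @return n x 3 matrix of positions.
#' @export
seedSpheroid <- function(n, cellDiameter = 14, packingFraction = 0.6,
                         center = c(0, 0, 0)) {
  R <- (cellDiameter / 2) * (n / packingFraction)^(1 / 3)
  dir <- matrix(rnorm(3 * n), ncol = 3)
  dir <- dir / sqrt(rowSums(dir^2))
  r <- R * runif(n)^(1 / 3)
  sweep(dir * r, 2, center, "+")
}

#' Equivalent-sphere diameter of a cell cloud via its convex hull
#'
#' The 3-D convex hull volume V of all cell centers is mapped to the
#' diameter of the sphere of equal volume, \eqn{d = (6V/\pi)^{1/3}}.
#'
#' @param positions n x 3 matrix of points (n >= 4, non-degenerate).
#' @return Equivalent-sphere diameter.
#' @examples
#' tet <- rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(0,0,1))
#' convexHullDiameter(tet)  # (6 * (1/6) / pi)^(1/3) = (1/pi)^(1/3)
#' @export
convexHullDiameter <- function(positions) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 4L)
    stop("convex hull diameter needs at least 4 points")
  v <- cpp_convex_hull_volume(positions)
  sphereDiameter(v)
}

#' Run the tumor spheroid scenario
#'
#' Cells grow, divide, migrate and die on the generic engine; overlap is
#' resolved by the overdamped mechanics operation. The spheroid diameter is
#' collected from the convex hull of cell centers at a configurable cadence.
#'
#' @param nCells initial cell count (e.g. 2000, 4000 or 8000).
#' @param nDays simulated duration in days.
#' @param timeStep engine time step in hours.
#' @param cellParams a [tumorCellParams()].
#' @param mechParams a [mechanicsParams()], or NULL to disable mechanics.
#' @param cadenceHours hours between diameter measurements.
#' @param seed optional RNG seed.
#' @param domainSide side of the cubic open domain (um), centered at 0.
#' @param extraBehaviors additional behaviors, registered and attached to
#'   every initial cell (e.g. instrumentation).
#' @return list(series = data.frame(iteration, t_hours, nCells,
#'   diameter_um), sim = final simulation object).
#' @export
runSpheroid <- function(nCells = 2000, nDays = 5, timeStep = 1,
                        cellParams = tumorCellParams(),
                        mechParams = mechanicsParams(
                          repulsionStiffness = 4, viscosity = 2,
                          maxDisplacementPerStep = 3),
                        cadenceHours = 24, seed = NULL, domainSide = 2000,
                        extraBehaviors = list()) {
  if (!is.null(seed)) set.seed(seed)
  pos <- seedSpheroid(nCells, cellParams$initialDiameter)
  half <- domainSide / 2
  simPar <- simulationParams(timeStep = timeStep,
                             nIterations = round(nDays * 24 / timeStep),
                             bounds = rbind(rep(-half, 3), rep(half, 3)),
                             boundaryMode = "open")
  extraNames <- vapply(extraBehaviors, `[[`, "", "name")
  pop <- agentPopulation(pos, diameter = cellParams$initialDiameter,
                         behaviors = c("tumor-growth-division",
                                       "tumor-migration", "tumor-apoptosis",
                                       extraNames),
                         attrs = list(
                           volume = rep(sphereVolume(cellParams$initialDiameter),
                                        nCells)))
  # no engine grid: nothing in this scenario queries it (mechanics uses its
  # own internal cell list sized to the current largest diameter)
  sim <- newSimulation(pop, simPar,
                       behaviors = c(tumorBehaviors(cellParams),
                                     extraBehaviors),
                       gridBoxLength = NULL)
  registerCollector(sim, "nCells", nAgents,
                    frequency = max(1L, round(cadenceHours / timeStep)))
  registerCollector(sim, "diameter_um",
                    function(p) convexHullDiameter(positions(p)),
                    frequency = max(1L, round(cadenceHours / timeStep)))
  ops <- list(behaviorOp())
  if (!is.null(mechParams)) ops <- c(ops, list(mechanicsOp(mechParams)))
  runSimulation(sim, ops)
  ts <- timeSeries(sim)
  list(series = data.frame(iteration = ts$iteration,
                           t_hours = ts$iteration * timeStep,
                           nCells = ts$nCells,
                           diameter_um = ts$diameter_um),
       sim = sim)
}

#' Growth curves for several initial populations
#'
#' Convenience wrapper replicating the three-initial-population design
#' (2000, 4000, 8000 cells): one [runSpheroid()] per population size, same
#' parameters.
#'
#' @param nCellsVec initial population sizes.
#' @param ... passed to [runSpheroid()].
#' @param seed base seed; run k uses seed + k - 1.
#' @return Named list of series data.frames.
#' @export
spheroidGrowthCurves <- function(nCellsVec = c(2000, 4000, 8000), seed = 1,
                                 ...) {
  setNames(lapply(seq_along(nCellsVec), function(k)
    runSpheroid(nCells = nCellsVec[k], seed = seed + k - 1, ...)$series),
    paste0("n", nCellsVec))
}
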