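#' Pyramidal cell initial configuration
#'
#' A pyramidal cell starts as a 10 um cell body with one 0.5 um long apical
#' dendrite pointing along +z and three 0.5 um long basal dendrites in the
#' -z hemisphere.
#'
#' @param somaDiameter soma diameter (um).
#' @param initialDendriteLength starting length of each dendrite (um).
#' @param nBasal number of basal dendrites.
#' @param nApical number of apical dendrites.
#' @param apicalDirection unit vector of apical outgrowth.
#' @return A `"PyramidalCellInit"` list.
#' @export
pyramidalCellInit <- function(somaDiameter = 10, initialDendriteLength = 0.5,
                              nBasal = 3L, nApical = 1L,
                              apicalDirection = c(0, 0, 1)) {
  structure(list(somaDiameter = somaDiameter,
                 initialDendriteLength = initialDendriteLength,
                 nBasal = as.integer(nBasal), nApical = as.integer(nApical),
                 apicalDirection = apicalDirection / sqrt(sum(apicalDirection^2))),
            class = "PyramidalCellInit")
}

#' Neurite growth parameters for one dendrite kind
#'
#' @param elongationSpeed length added per iteration (um / step).
#' @param wGradient,wPrevious,wRandom direction weights applied to the
#'   normalized chemical gradient, the previous direction and a uniform
#'   random unit vector (all >= 0, not all zero).
#' @param taper diameter loss per unit grown length (um / um).
#' @param minDiameter diameter floor; reaching it permanently stops growth.
#' @param pBranch per-step bifurcation probability of an active tip.
#' @param branchDiameterRatio daughter diameter as a fraction of the tip
#'   diameter at the branch point, in (0, 1].
#' @param branchAngle full angle between the two daughters (degrees).
#' @param initialDiameter starting dendrite diameter (um).
#' @return A `"NeuriteGrowthParams"` list.
#' @export
neuriteGrowthParams <- function(elongationSpeed = 1, wGradient = 0.2,
                                wPrevious = 2, wRandom = 0.6, taper = 0.005,
                                minDiameter = 0.6, pBranch = 0.01,
                                branchDiameterRatio = 0.9, branchAngle = 45,
                                initialDiameter = 1.5) {
  stopifnot(elongationSpeed > 0, wGradient >= 0, wPrevious >= 0,
            wRandom >= 0, wGradient + wPrevious + wRandom > 0,
            taper >= 0, minDiameter > 0, pBranch >= 0, pBranch <= 1,
            branchDiameterRatio > 0, branchDiameterRatio <= 1,
            initialDiameter > minDiameter)
  structure(list(elongationSpeed = elongationSpeed, wGradient = wGradient,
                 wPrevious = wPrevious, wRandom = wRandom, taper = taper,
                 minDiameter = minDiameter, pBranch = pBranch,
                 branchDiameterRatio = branchDiameterRatio,
                 branchAngle = branchAngle,
                 initialDiameter = initialDiameter),
            class = "NeuriteGrowthParams")
}

#' Default apical/basal growth parameter pair
#'
#' Apical dendrites follow their guidance cue closely and keep direction
#' (straight trunk, sparse branching); basal dendrites are noisier, branch
#' more and taper faster (shorter, more dispersed trees).
#'
#' @return list with elements `apical` and `basal`.
#' @export
pyramidalGrowthParams <- function() {
  list(
    apical = neuriteGrowthParams(elongationSpeed = 1.5, wGradient = 0.8,
                                 wPrevious = 4, wRandom = 0.4,
                                 taper = 0.004, minDiameter = 0.6,
                                 pBranch = 0.006, branchDiameterRatio = 0.9,
                                 branchAngle = 40, initialDiameter = 2),
    basal = neuriteGrowthParams(elongationSpeed = 1, wGradient = 0.15,
                                wPrevious = 2, wRandom = 0.9,
                                taper = 0.006, minDiameter = 0.6,
                                pBranch = 0.012, branchDiameterRatio = 0.9,
                                branchAngle = 50, initialDiameter = 1.5))
}

#' Default guidance cues for pyramidal growth
#'
#' Two static Gaussian growth factors along z: one above the soma plane
#' attracting apical dendrites, one below attracting basal dendrites.
#'
#' @return named list of [GaussianField-class] objects.
#' @export
pyramidalFields <- function() {
  list(apical = gaussianField("apical_cue", amplitude = 1, axis = "z",
                              mean = 300, sigma = 150),
       basal = gaussianField("basal_cue", amplitude = 1, axis = "z",
                             mean = -100, sigma = 100))
}

#' Combine gradient, previous and random direction into a growth direction
#'
#' \eqn{d = \mathrm{normalize}(w_g \hat g + w_p \hat p + w_r \hat u)} with
#' each component normalized before weighting (\eqn{\hat g} is the zero
#' vector when the gradient vanishes). If the weighted sum is (numerically)
#' zero the previous direction is returned unchanged.
#'
#' @param prevDir n x 3 matrix of unit previous directions.
#' @param gradient n x 3 matrix of field gradients (not necessarily unit).
#' @param wGradient,wPrevious,wRandom non-negative weights.
#' @param randomDir optional n x 3 matrix of unit random directions (drawn
#'   internally when NULL).
#' @return n x 3 matrix of unit growth directions.
#' @export
growthDirection <- function(prevDir, gradient, wGradient, wPrevious,
                            wRandom, randomDir = NULL) {
  prevDir <- matrix(prevDir, ncol = 3)
  gradient <- matrix(gradient, ncol = 3)
  n <- nrow(prevDir)
  gn <- sqrt(rowSums(gradient^2))
  ghat <- gradient / ifelse(gn > 0, gn, 1)
  if (is.null(randomDir)) {
    randomDir <- matrix(rnorm(3 * n), ncol = 3)
    randomDir <- randomDir / sqrt(rowSums(randomDir^2))
  }
  d <- wGradient * ghat + wPrevious * prevDir + wRandom * randomDir
  nd <- sqrt(rowSums(d^2))
  degenerate <- nd < 1e-12
  d <- d / ifelse(degenerate, 1, nd)
  if (any(degenerate)) d[degenerate, ] <- prevDir[degenerate, , drop = FALSE]
  d
}

#' Advance a terminal neurite element and taper its diameter
#'
#' The distal point moves by `elongationSpeed * dt` along `direction`; the
#' diameter shrinks by `taper` times the advanced length, floored at
#' `minDiameter`. Hitting the floor permanently deactivates growth.
#'
#' @param tip list with `distal` (3-vector), `diameter`, `growthActive`.
#' @param direction unit 3-vector.
#' @param params a [neuriteGrowthParams()].
#' @param dt time step (iterations are the natural unit; default 1).
#' @return The updated tip list.
#' @export
elongateAndTaper <- function(tip, direction, params, dt = 1) {
  if (!isTRUE(tip$growthActive)) return(tip)
  adv <- params$elongationSpeed * dt
  tip$distal <- tip$distal + adv * as.numeric(direction)
  newDiam <- tip$diameter - params$taper * adv
  if (newDiam <= params$minDiameter) {
    tip$diameter <- params$minDiameter
    tip$growthActive <- FALSE
  } else {
    tip$diameter <- newDiam
  }
  tip
}

#' Two daughter directions symmetric about a mother direction
#'
#' @param dir mother unit direction (3-vector).
#' @param branchAngle full angle between daughters (degrees).
#' @return 2 x 3 matrix of unit daughter directions.
#' @export
branchDirections <- function(dir, branchAngle) {
  dir <- as.numeric(dir)
  # random unit vector orthogonal to dir
  repeat {
    w <- rnorm(3)
    w <- w - sum(w * dir) * dir
    nw <- sqrt(sum(w^2))
    if (nw > 1e-8) { w <- w / nw; break }
  }
  half <- branchAngle / 2 * pi / 180
  rbind(cos(half) * dir + sin(half) * w,
        cos(half) * dir - sin(half) * w)
}

# --- morphology node store -------------------------------------------------
# Nodes are SWC-style rows (nodeId, cellId, type, parentNodeId, x, y, z,
# radius) in a doubling matrix buffer; parents are always recorded before
# children.

newMorphStore <- function() {
  m <- new.env(parent = emptyenv())
  m$mat <- matrix(0, nrow = 4096, ncol = 8)
  m$n <- 0L
  m$nextNode <- 1L
  m
}

morphAdd <- function(m, cellId, type, parent, xyz, radius) {
  k <- length(cellId)
  xyz <- matrix(xyz, ncol = 3)
  while (m$n + k > nrow(m$mat))
    m$mat <- rbind(m$mat, matrix(0, nrow = nrow(m$mat), ncol = 8))
  ids <- m$nextNode + seq_len(k) - 1L
  m$mat[m$n + seq_len(k), ] <- cbind(ids, cellId, type, parent, xyz, radius)
  m$n <- m$n + k
  m$nextNode <- m$nextNode + k
  as.integer(ids)
}

morphNodes <- function(m, cellId = NULL) {
  df <- as.data.frame(m$mat[seq_len(m$n), , drop = FALSE])
  names(df) <- c("index", "cellId", "type", "parent", "x", "y", "z", "radius")
  for (nm in c("index", "cellId", "type", "parent")) df[[nm]] <- as.integer(df[[nm]])
  if (!is.null(cellId)) df <- df[df$cellId %in% cellId, , drop = FALSE]
  df
}

#' Create one pyramidal cell in a simulation
#'
#' Adds one soma agent and four terminal neurite agents (1 apical along the
#' apical direction, 3 basal in the opposite hemisphere), each dendrite
#' 0.5 um long, and records the corresponding morphology nodes (soma node,
#' surface attachment points, initial tips).
#'
#' @param sim a simulation created with [newSimulation()] whose
#'   `sim$user$morph` store exists (see [runPyramidalCells()]).
#' @param center soma center (3-vector).
#' @param cellId integer cell label.
#' @param init a [pyramidalCellInit()].
#' @param params list(apical=, basal=) of [neuriteGrowthParams()].
#' @return Invisibly, the ids of the created agents (soma first).
#' @export
initPyramidalCell <- function(sim, center = c(0, 0, 0), cellId = 1L,
                              init = pyramidalCellInit(),
                              params = pyramidalGrowthParams()) {
  if (is.null(sim$user$morph)) sim$user$morph <- newMorphStore()
  m <- sim$user$morph
  somaR <- init$somaDiameter / 2
  somaNode <- morphAdd(m, cellId, 1L, -1L, center, somaR)

  up <- init$apicalDirection
  dirs <- matrix(up, nrow = init$nApical, ncol = 3, byrow = TRUE)
  kinds <- rep(4L, init$nApical)
  for (b in seq_len(init$nBasal)) {
    repeat {
      v <- rnorm(3)
      v <- v / sqrt(sum(v^2))
      if (sum(v * up) < -1e-3) break  # opposite hemisphere
    }
    dirs <- rbind(dirs, v)
    kinds <- c(kinds, 3L)
  }
  nD <- nrow(dirs)
  attach <- sweep(dirs * somaR, 2, center, "+")
  tipPos <- attach + dirs * init$initialDendriteLength
  attachNodes <- morphAdd(m, rep(cellId, nD), kinds, rep(somaNode, nD),
                          attach,
                          vapply(kinds, function(k)
                            if (k == 4L) params$apical$initialDiameter / 2
                            else params$basal$initialDiameter / 2,
                            numeric(1)))
  tipNodes <- morphAdd(m, rep(cellId, nD), kinds, attachNodes, tipPos,
                       vapply(kinds, function(k)
                         if (k == 4L) params$apical$initialDiameter / 2
                         else params$basal$initialDiameter / 2, numeric(1)))

  ids <- allocateIds(sim, nD + 1L)
  soma <- newAgent(ids[1], center, init$somaDiameter,
                   behaviors = character(0),
                   attrs = list(cellId = cellId, kind = 1L, lastNode = somaNode,
                                dirX = 0, dirY = 0, dirZ = 0,
                                growthActive = FALSE, isTerminal = FALSE))
  adds <- list(soma)
  for (k in seq_len(nD)) {
    diam <- if (kinds[k] == 4L) params$apical$initialDiameter
            else params$basal$initialDiameter
    adds[[k + 1L]] <- newAgent(
      ids[k + 1L], tipPos[k, ], diam, behaviors = "neurite-growth",
      attrs = list(cellId = cellId, kind = kinds[k], lastNode = tipNodes[k],
                   dirX = dirs[k, 1], dirY = dirs[k, 2], dirZ = dirs[k, 3],
                   growthActive = TRUE, isTerminal = TRUE))
  }
  sim$population <- appendAgents(sim$population, adds)
  invisible(ids)
}

#' Neurite growth behavior (direction, elongation, taper, branching)
#'
#' @param params list(apical=, basal=) of [neuriteGrowthParams()].
#' @param fields list(apical=, basal=) of guidance fields.
#' @return A [behaviorSpec()] named `"neurite-growth"`.
#' @export
neuriteGrowthBehavior <- function(params, fields) {
  behaviorSpec("neurite-growth", function(sim, ids) {
    pop <- sim$population
    rows <- match(ids, agentIds(pop))
    active <- rows[agentAttr(pop, "growthActive")[rows] &
                     agentAttr(pop, "isTerminal")[rows]]
    if (!length(active)) return(invisible(NULL))
    m <- sim$user$morph
    kind <- agentAttr(pop, "kind")[active]
    pos <- positions(pop)[active, , drop = FALSE]
    prev <- cbind(agentAttr(pop, "dirX")[active],
                  agentAttr(pop, "dirY")[active],
                  agentAttr(pop, "dirZ")[active])
    diam <- diameters(pop)[active]
    newPos <- pos
    newDiam <- diam
    stillActive <- rep(TRUE, length(active))
    for (kd in c(4L, 3L)) {
      sel <- which(kind == kd)
      if (!length(sel)) next
      pk <- if (kd == 4L) params$apical else params$basal
      fk <- if (kd == 4L) fields$apical else fields$basal
      grad <- fieldGradient(fk, pos[sel, , drop = FALSE])
      d <- growthDirection(prev[sel, , drop = FALSE], grad,
                           pk$wGradient, pk$wPrevious, pk$wRandom)
      adv <- pk$elongationSpeed * sim$params$timeStep
      newPos[sel, ] <- pos[sel, , drop = FALSE] + d * adv
      nd <- diam[sel] - pk$taper * adv
      hitFloor <- nd <= pk$minDiameter
      nd[hitFloor] <- pk$minDiameter
      newDiam[sel] <- nd
      stillActive[sel] <- !hitFloor
      prev[sel, ] <- d
    }
    nodeIds <- morphAdd(m, agentAttr(pop, "cellId")[active], kind,
                        agentAttr(pop, "lastNode")[active], newPos,
                        newDiam / 2)
    p <- positions(pop)
    p[active, ] <- newPos
    positions(pop) <- p
    dm <- diameters(pop)
    dm[active] <- newDiam
    diameters(pop) <- dm
    ln <- agentAttr(pop, "lastNode"); ln[active] <- nodeIds
    agentAttr(pop, "lastNode") <- ln
    dx <- agentAttr(pop, "dirX"); dx[active] <- prev[, 1]
    dy <- agentAttr(pop, "dirY"); dy[active] <- prev[, 2]
    dz <- agentAttr(pop, "dirZ"); dz[active] <- prev[, 3]
    agentAttr(pop, "dirX") <- dx
    agentAttr(pop, "dirY") <- dy
    agentAttr(pop, "dirZ") <- dz
    ga <- agentAttr(pop, "growthActive")
    ga[active] <- stillActive
    agentAttr(pop, "growthActive") <- ga
    for (r in active[!stillActive])
      pop@behaviors[[r]] <- setdiff(pop@behaviors[[r]], "neurite-growth")

    # stochastic bifurcation of still-active tips
    pb <- ifelse(kind == 4L, params$apical$pBranch, params$basal$pBranch)
    u <- runif(length(active))
    branching <- which(stillActive & u < pb)
    it <- agentAttr(pop, "isTerminal")
    for (kidx in branching) {
      r <- active[kidx]
      pk <- if (kind[kidx] == 4L) params$apical else params$basal
      dDaughter <- pk$branchDiameterRatio * newDiam[kidx]
      dirs2 <- branchDirections(prev[kidx, ], pk$branchAngle)
      split <- transferBehaviors(pop@behaviors[[r]], sim$behaviors)
      for (j in 1:2) {
        queueNewAgent(sim$ctx, newAgent(
          id = allocateIds(sim), position = newPos[kidx, ],
          diameter = max(dDaughter, pk$minDiameter),
          behaviors = split$daughter,
          attrs = list(cellId = agentAttr(pop, "cellId")[r],
                       kind = kind[kidx], lastNode = nodeIds[kidx],
                       dirX = dirs2[j, 1], dirY = dirs2[j, 2],
                       dirZ = dirs2[j, 3],
                       growthActive = dDaughter > pk$minDiameter,
                       isTerminal = TRUE)))
      }
      it[r] <- FALSE
      ga[r] <- FALSE
      pop@behaviors[[r]] <- split$mother
      pop@behaviors[[r]] <- setdiff(pop@behaviors[[r]], "neurite-growth")
    }
    agentAttr(pop, "isTerminal") <- it
    agentAttr(pop, "growthActive") <- ga
    sim$population <- pop
    invisible(NULL)
  })
}

#' Run the pyramidal-cell dendritic growth scenario
#'
#' Cells are placed on an x-y lattice (growth is guidance-only; neurite
#' mechanics is disabled) and grown for `nIterations` steps under two static
#' Gaussian cues.
#'
#' @param nCells number of cells.
#' @param nIterations growth iterations.
#' @param params list(apical=, basal=) growth parameters.
#' @param fields list(apical=, basal=) guidance fields.
#' @param init a [pyramidalCellInit()].
#' @param seed optional RNG seed.
#' @param spacing lattice spacing between somata (um).
#' @param extraBehaviors additional behaviors, registered and attached to
#'   every initial agent (e.g. instrumentation).
#' @return list(sim, morph = full node table, cells = cell ids).
#' @export
runPyramidalCells <- function(nCells = 1, nIterations = 250,
                              params = pyramidalGrowthParams(),
                              fields = pyramidalFields(),
                              init = pyramidalCellInit(), seed = NULL,
                              spacing = 100, extraBehaviors = list()) {
  if (!is.null(seed)) set.seed(seed)
  side <- ceiling(sqrt(nCells))
  ext <- max(2000, side * spacing * 2)
  simPar <- simulationParams(timeStep = 1, nIterations = nIterations,
                             bounds = rbind(rep(-ext, 3), rep(ext, 3)),
                             boundaryMode = "open")
  pop <- agentPopulation()
  sim <- newSimulation(pop, simPar,
                       behaviors = c(list(neuriteGrowthBehavior(params, fields)),
                                     extraBehaviors),
                       fields = fields, gridBoxLength = NULL)
  sim$user$morph <- newMorphStore()
  for (k in seq_len(nCells)) {
    cx <- ((k - 1) %% side) * spacing
    cy <- ((k - 1) %/% side) * spacing
    initPyramidalCell(sim, center = c(cx, cy, 0), cellId = k,
                      init = init, params = params)
  }
  extraNames <- vapply(extraBehaviors, `[[`, "", "name")
  if (length(extraNames)) {
    pop <- sim$population
    pop@behaviors <- lapply(pop@behaviors, function(b) c(b, extraNames))
    sim$population <- pop
  }
  refreshGrid(sim)
  runSimulation(sim, list(behaviorOp()), nIterations)
  list(sim = sim, morph = morphNodes(sim$user$morph),
       cells = seq_len(nCells))
}
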