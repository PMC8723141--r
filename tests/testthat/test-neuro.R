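test_that("pyramidal initializer: one apical + three basal dendrites, 0.5 um each, 10 um soma", {
  set.seed(55)
  sim <- newSimulation(agentPopulation(), simulationParams(
    bounds = rbind(rep(-500, 3), rep(500, 3))))
  initPyramidalCell(sim, center = c(0, 0, 0), cellId = 1L)
  pop <- sim$population
  expect_identical(nAgents(pop), 5L)  # soma + 4 tips
  kind <- agentAttr(pop, "kind")
  expect_identical(sum(kind == 1L), 1L)
  expect_identical(sum(kind == 4L), 1L)  # apical
  expect_identical(sum(kind == 3L), 3L)  # basal
  somaRow <- which(kind == 1L)
  expect_equal(diameters(pop)[somaRow], 10)
  # every dendrite tip sits soma radius + 0.5 um from the soma center
  tipRows <- which(kind != 1L)
  d <- sqrt(rowSums(sweep(positions(pop)[tipRows, ], 2,
                          positions(pop)[somaRow, ])^2))
  expect_equal(d, rep(5 + 0.5, 4), tolerance = 1e-12)
  # apical along +z, basal strictly in the lower hemisphere
  apRow <- which(kind == 4L)
  expect_equal(positions(pop)[apRow, ], c(0, 0, 5.5), ignore_attr = TRUE)
  expect_true(all(positions(pop)[kind == 3L, 3] < 0))
  # morphology store: soma node + 4 attachment + 4 tip nodes, each dendrite
  # segment 0.5 um long
  nodes <- agentsim:::morphNodes(sim$user$morph)
  expect_identical(nrow(nodes), 9L)
  att <- nodes[nodes$parent == 1 & nodes$index != 1, ]
  expect_identical(nrow(att), 4L)
  tips <- nodes[nodes$parent %in% att$index, ]
  segLen <- sqrt((tips$x - att$x[match(tips$parent, att$index)])^2 +
                 (tips$y - att$y[match(tips$parent, att$index)])^2 +
                 (tips$z - att$z[match(tips$parent, att$index)])^2)
  expect_equal(segLen, rep(0.5, 4), tolerance = 1e-12)
})

test_that("growth direction combines normalized components; degenerate sums keep direction", {
  prev <- rbind(c(1, 0, 0))
  grad <- rbind(c(0, 2, 0))  # normalized internally to (0,1,0)
  d <- growthDirection(prev, grad, wGradient = 1, wPrevious = 1, wRandom = 0,
                       randomDir = rbind(c(0, 0, 0)))
  expect_equal(as.numeric(d), c(1, 1, 0) / sqrt(2))
  # zero gradient contributes nothing
  d2 <- growthDirection(prev, rbind(c(0, 0, 0)), 5, 1, 0,
                        randomDir = rbind(c(0, 0, 0)))
  expect_equal(as.numeric(d2), c(1, 0, 0))
  # exactly cancelling weights fall back to the previous direction
  d3 <- growthDirection(prev, rbind(c(-1, 0, 0)), 1, 1, 0,
                        randomDir = rbind(c(0, 0, 0)))
  expect_equal(as.numeric(d3), c(1, 0, 0))
  # unit norm always
  set.seed(77)
  d4 <- growthDirection(prev, rbind(rnorm(3)), 0.3, 1.2, 0.5)
  expect_equal(sqrt(sum(d4^2)), 1)
})

test_that("elongateAndTaper advances by speed*dt and floors the diameter permanently", {
  # taper chosen binary-exact so the floor is reached by exact equality
  p <- neuriteGrowthParams(elongationSpeed = 2, taper = 0.125,
                           minDiameter = 0.5, initialDiameter = 1)
  tip <- list(distal = c(0, 0, 0), diameter = 1, growthActive = TRUE)
  tip <- elongateAndTaper(tip, c(0, 0, 1), p, dt = 1)
  expect_equal(tip$distal, c(0, 0, 2))
  expect_equal(tip$diameter, 1 - 0.125 * 2)
  tip <- elongateAndTaper(tip, c(0, 0, 1), p, dt = 1)  # 0.75 - 0.25 = 0.5
  expect_equal(tip$diameter, 0.5)
  expect_false(tip$growthActive)
  frozen <- elongateAndTaper(tip, c(0, 0, 1), p, dt = 1)
  expect_identical(frozen, tip)  # permanently halted
})

test_that("branch directions are unit, symmetric about the mother and at the full angle", {
  set.seed(5)
  dir <- c(0, 0, 1)
  dd <- branchDirections(dir, 40)
  expect_equal(rowSums(dd^2), c(1, 1))
  # angle between daughters = 40 degrees
  expect_equal(acos(sum(dd[1, ] * dd[2, ])) * 180 / pi, 40,
               tolerance = 1e-10)
  # each at 20 degrees from the mother
  expect_equal(acos(dd %*% dir) * 180 / pi, cbind(c(20, 20)),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("deterministic growth: no randomness, no branching -> collinear tree of exact length", {
  params <- pyramidalGrowthParams()
  params$apical$wRandom <- 0; params$apical$wGradient <- 0
  params$apical$pBranch <- 0; params$apical$taper <- 0
  params$basal$wRandom <- 0; params$basal$wGradient <- 0
  params$basal$pBranch <- 0; params$basal$taper <- 0
  n <- 40
  run <- runPyramidalCells(nCells = 1, nIterations = n, params = params,
                           seed = 9)
  mm <- morphometrics(cellMorphology(run, 1))
  expect_identical(mm$nBranchPoints, rep(0L, 4))
  # total length per tree = initial 0.5 + n * speed * dt, exactly
  apLen <- mm$totalLength[mm$kind == 4]
  expect_equal(apLen, 0.5 + n * params$apical$elongationSpeed, tolerance = 1e-9)
  expect_equal(mm$totalLength[mm$kind == 3],
               rep(0.5 + n * params$basal$elongationSpeed, 3),
               tolerance = 1e-9)
  # collinearity: apical nodes lie on the +z ray from the soma surface
  nodes <- cellMorphology(run, 1)
  ap <- nodes[nodes$type == 4, ]
  expect_true(all(abs(ap$x) < 1e-9 & abs(ap$y) < 1e-9))
  expect_equal(max(ap$z), 5 + 0.5 + n * params$apical$elongationSpeed,
               tolerance = 1e-9)
})

test_that("taper floor halts growth permanently during a run", {
  params <- pyramidalGrowthParams()
  # aggressive taper: apical diameter 2 -> floor 0.6 after ceil(1.4/ (taper*speed)) steps
  params$apical$taper <- 0.2; params$apical$pBranch <- 0
  params$apical$wRandom <- 0; params$apical$wGradient <- 0
  params$basal$taper <- 0.2; params$basal$pBranch <- 0
  params$basal$wRandom <- 0; params$basal$wGradient <- 0
  run <- runPyramidalCells(nCells = 1, nIterations = 30, params = params,
                           seed = 3)
  # apical: speed 1.5, loses 0.3 per step from 2.0; floor hit at step 5
  mm <- morphometrics(cellMorphology(run, 1))
  apLen <- mm$totalLength[mm$kind == 4]
  expect_equal(apLen, 0.5 + 5 * 1.5, tolerance = 1e-9)
  # no agent still grows at the end
  expect_false(any(agentAttr(run$sim$population, "growthActive")))
  # tip diameters floored
  kind <- agentAttr(run$sim$population, "kind")
  expect_true(all(abs(diameters(run$sim$population)[kind != 1L] - 0.6) < 1e-9))
})

test_that("branch events: mother stops, two daughters continue, diameters scaled", {
  params <- pyramidalGrowthParams()
  params$apical$pBranch <- 1  # branch every step
  params$basal$pBranch <- 0
  run <- runPyramidalCells(nCells = 1, nIterations = 3, params = params,
                           seed = 13)
  pop <- run$sim$population
  kind <- agentAttr(pop, "kind")
  # apical tips double every iteration: 1 -> 2 -> 4 -> 8 terminals
  expect_identical(sum(kind == 4L & agentAttr(pop, "isTerminal")), 8L)
  mm <- morphometrics(cellMorphology(run, 1))
  expect_gte(mm$nBranchPoints[mm$kind == 4], 3L)
})

test_that("morphometrics of a hand-built binary tree match manual enumeration", {
  # soma(1) -> attachment(2) -> a(3) -> b(4) branch into c(5)/d(6);
  # c -> e(7); d branch into f(8)/g(9); unit-length segments along distinct axes
  nodes <- data.frame(
    index = 1:9,
    type = c(1, 3, 3, 3, 3, 3, 3, 3, 3),
    x = c(0, 0, 0, 0, 1, -1, 2, -1, -1),
    y = c(0, 0, 0, 0, 0, 0, 0, 1, -1),
    z = c(0, 1, 2, 3, 3, 3, 3, 3, 3),
    radius = 1,
    parent = c(-1, 1, 2, 3, 4, 4, 5, 6, 6))
  mm <- morphometrics(nodes)
  expect_identical(nrow(mm), 1L)
  expect_identical(mm$nBranchPoints, 2L)  # nodes 4 and 6 have two children
  # edges counted: 2-3 (1), 3-4 (1), 4-5 (1), 4-6 (1), 5-7 (1), 6-8 (1),
  # 6-9 (1) -> total 7 (the soma->attachment edge is excluded)
  expect_equal(mm$totalLength, 7)
  expect_equal(attr(mm, "meanBranchPoints"), 2)
  # a node with three children is not a bifurcation point
  nodes2 <- rbind(nodes,
                  data.frame(index = 10, type = 3, x = 0, y = 1, z = 3,
                             radius = 1, parent = 4))
  mm2 <- morphometrics(nodes2)
  expect_identical(mm2$nBranchPoints, 1L)  # node 4 now has 3 children
})

test_that("tree validation rejects orphans and cycles, naming the offender", {
  good <- data.frame(index = 1:3, type = c(1, 3, 3), x = 0, y = 0, z = 0:2,
                     radius = 1, parent = c(-1, 1, 2))
  expect_silent(validTree <- agentsim:::validateTree(good))
  orphan <- good; orphan$parent[3] <- 99
  expect_error(agentsim:::validateTree(orphan), "orphan")
  expect_error(agentsim:::validateTree(orphan), "3")
  cyc <- data.frame(index = 1:3, type = c(1, 3, 3), x = 0, y = 0, z = 0:2,
                    radius = 1, parent = c(-1, 3, 2))
  expect_error(agentsim:::validateTree(cyc), "cycle")
  dup <- good; dup$index[3] <- 2
  expect_error(agentsim:::validateTree(dup), "duplicate")
})

test_that("SWC round trip preserves the morphology exactly at 1e-6", {
  run <- runPyramidalCells(nCells = 1, nIterations = 40, seed = 27)
  nodes <- cellMorphology(run, 1)
  lines <- swcLines(nodes)
  back <- readSwc(lines)
  expect_identical(back$index, nodes$index)
  expect_identical(back$parent, nodes$parent)
  expect_identical(back$type, nodes$type)
  expect_equal(back$x, nodes$x, tolerance = 1e-6)
  expect_equal(back$radius, nodes$radius, tolerance = 1e-6)
  # export -> import -> export is byte-identical
  expect_identical(swcLines(back), lines)
  # file round trip with comment header
  path <- tempfile(fileext = ".swc")
  writeSwc(nodes, path)
  expect_identical(swcLines(readSwc(path)), lines)
})

test_that("malformed SWC input raises row-numbered errors", {
  expect_error(readSwc(c("1 1 0 0 0 5 -1", "2 3 0 0")), "row 2")
  expect_error(readSwc(c("1 1 0 0 0 5 -1", "2 3 0 0 1 1 7")),
               "missing parent")
})

test_that("population morphometrics summarise per tree, per cell and across cells", {
  run <- runPyramidalCells(nCells = 2, nIterations = 30, seed = 37)
  pm <- populationMorphometrics(run$morph)
  expect_identical(sort(unique(pm$perTree$cellId)), c(1L, 2L))
  expect_identical(nrow(pm$perTree), 8L)  # 4 trees per cell
  expect_identical(nrow(pm$perCell), 2L)
  expect_true(all(is.finite(pm$population$mean)))
  expect_true(all(is.finite(pm$population$sd)))
  # per-cell mean equals the mean over that cell's trees
  c1 <- pm$perTree[pm$perTree$cellId == 1, ]
  expect_equal(pm$perCell$meanLength[1], mean(c1$totalLength))
})
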