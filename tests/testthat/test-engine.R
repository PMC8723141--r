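test_that("operation frequency: first fire at 0, every f-th, ceil(n/f) total", {
  counter <- new.env()
  counter$fired <- integer(0)
  op <- operationSpec("tick", "standalone", 3L, function(sim)
    counter$fired <- c(counter$fired, sim$iteration))
  sim <- newSimulation(agentPopulation(), simulationParams(nIterations = 10))
  runSimulation(sim, list(op), 10)
  expect_identical(counter$fired, c(0L, 3L, 6L, 9L))
  expect_length(counter$fired, ceiling(10 / 3))

  for (f in c(1L, 2L, 5L, 7L)) for (n in c(0L, 1L, 6L, 13L)) {
    expect_identical(sum(vapply(seq_len(n) - 1L, function(i)
      isDue(list(frequency = f), i), logical(1))), as.integer(ceiling(n / f)))
  }
})

test_that("frequency below 1 is rejected", {
  expect_error(operationSpec("x", "standalone", 0L, function(sim) NULL),
               "frequency")
  expect_error(isDue(list(frequency = 0), 1), "frequency")
})

test_that("op-major scheduling: behavior finishes over all agents before next behavior; ids ascending", {
  trace <- new.env(); trace$log <- character(0)
  bA <- behaviorSpec("A", function(sim, ids)
    trace$log <- c(trace$log, paste0("A:", paste(ids, collapse = ","))))
  bB <- behaviorSpec("B", function(sim, ids)
    trace$log <- c(trace$log, paste0("B:", paste(ids, collapse = ","))))
  pop <- agentPopulation(matrix(0, 3, 3), diameter = 1, id = c(7L, 2L, 5L),
                         behaviors = c("A", "B"))
  sim <- newSimulation(pop, simulationParams(), behaviors = list(bA, bB))
  stepOnce(sim, list(behaviorOp()))
  expect_identical(trace$log, c("A:2,5,7", "B:2,5,7"))
})

test_that("per-agent operations run before standalone operations", {
  trace <- new.env(); trace$log <- character(0)
  pa <- operationSpec("pa", "per-agent", 1L, function(sim)
    trace$log <- c(trace$log, "per-agent"))
  sa <- operationSpec("sa", "standalone", 1L, function(sim)
    trace$log <- c(trace$log, "standalone"))
  sim <- newSimulation(agentPopulation(matrix(0, 1, 3), 1),
                       simulationParams())
  stepOnce(sim, list(sa, pa))  # registration order must not override kind order
  expect_identical(trace$log, c("per-agent", "standalone"))
})

test_that("deferred creation: queued agent invisible now, committed next iteration", {
  creator <- behaviorSpec("creator", function(sim, ids) {
    if (sim$iteration == 0L)
      queueNewAgent(sim$ctx, newAgent(allocateIds(sim), c(1, 1, 1), 1))
    invisible(NULL)
  })
  pop <- agentPopulation(matrix(0, 2, 3), diameter = 1,
                         behaviors = "creator")
  sim <- newSimulation(pop, simulationParams(), behaviors = list(creator),
                       gridBoxLength = 10)
  expect_identical(nAgents(sim$population), 2L)
  stepOnce(sim, list(behaviorOp()))       # iteration 0: creation queued
  expect_identical(nAgents(sim$population), 3L)  # committed at end of 0
  expect_true(3L %in% sim$grid@ids)       # grid rebuilt after commit
})

test_that("deferred removal and add+remove in one iteration", {
  b <- behaviorSpec("reaper", function(sim, ids) {
    if (sim$iteration == 0L) {
      queueRemoval(sim$ctx, 1L)
      id <- allocateIds(sim)
      queueNewAgent(sim$ctx, newAgent(id, c(0, 0, 0), 1))
      queueRemoval(sim$ctx, id)  # never appears
    }
    invisible(NULL)
  })
  pop <- agentPopulation(matrix(0, 2, 3), diameter = 1, behaviors = "reaper")
  sim <- newSimulation(pop, simulationParams(), behaviors = list(b))
  stepOnce(sim, list(behaviorOp()))
  expect_identical(agentIds(sim$population), 2L)
})

test_that("duplicate queued id errors; retired ids can never be reused", {
  pop <- agentPopulation(matrix(0, 2, 3), diameter = 1)
  sim <- newSimulation(pop, simulationParams())
  id <- allocateIds(sim)
  queueNewAgent(sim$ctx, newAgent(id, c(0, 0, 0), 1))
  expect_error(queueNewAgent(sim$ctx, newAgent(id, c(1, 1, 1), 1)),
               "already used")
  expect_error(queueNewAgent(sim$ctx, newAgent(1L, c(1, 1, 1), 1)),
               "already used")  # id 1 is committed
  sim$population <- commitContext(sim$ctx, sim$population)
  queueRemoval(sim$ctx, 2L)
  sim$retiredIds <- c(sim$retiredIds, sim$ctx$removals)
  sim$population <- commitContext(sim$ctx, sim$population)
  expect_error(queueNewAgent(sim$ctx, newAgent(2L, c(0, 0, 0), 1)),
               "already used")  # id 2 is retired
})

test_that("duplicate removal collapses with one warning; unknown removal warns at commit", {
  ctx <- executionContext()
  queueRemoval(ctx, 5L)
  expect_warning(queueRemoval(ctx, 5L), "already queued")
  expect_identical(ctx$removals, 5L)
  pop <- agentPopulation(matrix(0, 1, 3), diameter = 1, id = 5L)
  expect_silent(p2 <- commitContext(ctx, pop))
  expect_identical(nAgents(p2), 0L)
  ctx2 <- executionContext()
  queueRemoval(ctx2, 99L)
  expect_warning(commitContext(ctx2, pop), "unknown agent id")
})

test_that("transferBehaviors honors copy and remove flags, preserving order", {
  b1 <- behaviorSpec("keepBoth", function(sim, ids) NULL,
                     copyOnDivision = TRUE, removeFromMother = FALSE)
  b2 <- behaviorSpec("motherOnly", function(sim, ids) NULL,
                     copyOnDivision = FALSE, removeFromMother = FALSE)
  b3 <- behaviorSpec("daughterOnly", function(sim, ids) NULL,
                     copyOnDivision = TRUE, removeFromMother = TRUE)
  res <- transferBehaviors(list(b1, b2, b3))
  expect_identical(vapply(res$mother, `[[`, "", "name"),
                   c("keepBoth", "motherOnly"))
  expect_identical(vapply(res$daughter, `[[`, "", "name"),
                   c("keepBoth", "daughterOnly"))
  reg <- setNames(list(b1, b2, b3), c("keepBoth", "motherOnly", "daughterOnly"))
  res2 <- transferBehaviors(c("keepBoth", "motherOnly", "daughterOnly"), reg)
  expect_identical(res2$mother, c("keepBoth", "motherOnly"))
  expect_identical(res2$daughter, c("keepBoth", "daughterOnly"))
})

test_that("errors inside operations name the iteration and operation", {
  bad <- operationSpec("explode", "standalone", 1L,
                       function(sim) stop("boom"))
  sim <- newSimulation(agentPopulation(), simulationParams())
  stepOnce(sim, list())
  expect_error(stepOnce(sim, list(bad)), "iteration 1, operation 'explode'")
})

test_that("collectors: collected at iteration 0 and each due iteration; duplicates rejected", {
  pop <- agentPopulation(matrix(0, 4, 3), diameter = 1)
  sim <- newSimulation(pop, simulationParams())
  registerCollector(sim, "n", nAgents, frequency = 2L)
  expect_error(registerCollector(sim, "n", nAgents), "already registered")
  runSimulation(sim, list(), 5)
  ts <- timeSeries(sim)
  expect_identical(ts$iteration, c(0L, 2L, 4L))
  expect_identical(ts$n, rep(4, 3))
})

test_that("identical configuration and seed give identical time series", {
  runIt <- function() {
    set.seed(42)
    b <- behaviorSpec("jiggle", function(sim, ids) {
      pop <- sim$population
      positions(pop) <- positions(pop) + matrix(rnorm(3 * nAgents(pop)),
                                                ncol = 3)
      sim$population <- pop
      invisible(NULL)
    })
    pop <- agentPopulation(matrix(rnorm(30), 10, 3), diameter = 1,
                           behaviors = "jiggle")
    sim <- newSimulation(pop, simulationParams(), behaviors = list(b))
    registerCollector(sim, "mx", function(p) mean(positions(p)))
    runSimulation(sim, list(behaviorOp()), 10)
    timeSeries(sim)
  }
  expect_identical(runIt(), runIt())
})
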