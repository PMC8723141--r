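#' Simulation parameters
#'
#' @param timeStep simulated time per iteration (scenario unit, e.g. hours or
#'   days); must be positive.
#' @param nIterations non-negative integer number of iterations.
#' @param bounds 2 x 3 numeric matrix: row 1 = lower, row 2 = upper bound per
#'   axis; lower must be strictly below upper on each axis.
#' @param boundaryMode `"open"` or `"toroidal"`.
#' @param seed integer RNG seed recorded with the run.
#' @return A validated list of class `"SimulationParams"`.
#' @export
simulationParams <- function(timeStep = 1, nIterations = 0L,
                             bounds = rbind(c(0, 0, 0), c(100, 100, 100)),
                             boundaryMode = c("open", "toroidal"),
                             seed = 1L) {
  boundaryMode <- match.arg(boundaryMode)
  bounds <- as.matrix(bounds)
  if (!isTRUE(timeStep > 0)) stop("timeStep must be > 0")
  if (!isTRUE(nIterations >= 0)) stop("nIterations must be >= 0")
  if (nrow(bounds) != 2L || ncol(bounds) != 3L)
    stop("bounds must be a 2 x 3 matrix (min row, max row)")
  if (any(bounds[1, ] >= bounds[2, ]))
    stop("bounds: min must be < max on each axis")
  structure(list(timeStep = timeStep, nIterations = as.integer(nIterations),
                 bounds = bounds, boundaryMode = boundaryMode,
                 seed = as.integer(seed)),
            class = "SimulationParams")
}

#' Behavior specification
#'
#' A behavior is a named per-agent update rule. Its `run` function receives
#' the simulation object and the ids of the agents that carry the behavior
#' (ascending id order) and updates agent state in place; agent creation and
#' removal must go through the execution context, never directly.
#'
#' @param name unique behavior name.
#' @param run function(sim, ids).
#' @param copyOnDivision should a daughter agent receive this behavior?
#' @param removeFromMother should the mother lose this behavior on division?
#' @return A `"BehaviorSpec"` list.
#' @export
behaviorSpec <- function(name, run, copyOnDivision = TRUE,
                         removeFromMother = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, is.function(run))
  structure(list(name = name, run = run,
                 copyOnDivision = isTRUE(copyOnDivision),
                 removeFromMother = isTRUE(removeFromMother)),
            class = "BehaviorSpec")
}

#' Operation specification
#'
#' Operations drive one iteration. Per-agent operations are applied to every
#' live agent (in ascending id order, vectorized internally); standalone
#' operations run once per due iteration (e.g. a diffusion update). Each
#' operation has an execution frequency: frequency 3 means the operation runs
#' every third iteration, first at iteration 0.
#'
#' @param name operation name (used in error messages).
#' @param kind `"per-agent"` or `"standalone"`.
#' @param frequency positive integer execution frequency.
#' @param procedure function(sim).
#' @return An `"OperationSpec"` list.
#' @export
operationSpec <- function(name, kind = c("per-agent", "standalone"),
                          frequency = 1L, procedure) {
  kind <- match.arg(kind)
  if (!isTRUE(frequency >= 1) || frequency != as.integer(frequency))
    stop("frequency must be a positive integer")
  stopifnot(is.function(procedure))
  structure(list(name = name, kind = kind, frequency = as.integer(frequency),
                 procedure = procedure),
            class = "OperationSpec")
}

#' Is an operation due at a given iteration?
#'
#' An operation with frequency f first fires at iteration 0 and then every
#' f-th iteration, so over n iterations (0 .. n-1) it executes ceiling(n / f)
#' times.
#'
#' @param op an [operationSpec()] (or anything with a `frequency` field).
#' @param iteration non-negative iteration index.
#' @return TRUE iff `iteration %% frequency == 0`.
#' @export
isDue <- function(op, iteration) {
  freq <- if (is.list(op)) op$frequency else op
  if (!isTRUE(freq >= 1)) stop("invalid frequency: must be >= 1")
  iteration %% freq == 0L
}

#' Execution context: deferred agent creation and removal
#'
#' Agents created at iteration i are staged here and become visible to the
#' rest of the simulation only at iteration i + 1; removals likewise take
#' effect at the commit that ends the iteration. Pending agents are invisible
#' to every neighborhood query and per-agent operation of the current
#' iteration because the spatial index is built only from committed agents.
#'
#' @param usedIdCheck function(id) returning TRUE if the id has already been
#'   used in the simulation (committed or retired); defaults to no check.
#' @return A mutable context (environment) with fields `additions`,
#'   `removals`.
#' @export
executionContext <- function(usedIdCheck = function(id) FALSE) {
  ctx <- new.env(parent = emptyenv())
  ctx$additions <- list()
  ctx$removals <- integer(0)
  ctx$usedIdCheck <- usedIdCheck
  class(ctx) <- c("ExecutionContext", "environment")
  ctx
}

#' Describe a new agent for deferred creation
#'
#' @param id unique integer id (allocate with [allocateIds()] inside a
#'   simulation).
#' @param position numeric 3-vector.
#' @param diameter positive diameter.
#' @param behaviors character vector of behavior names.
#' @param attrs named list of scalar attribute values.
#' @return Agent description list for [queueNewAgent()].
#' @export
newAgent <- function(id, position, diameter, behaviors = character(0),
                     attrs = list()) {
  stopifnot(length(position) == 3L, diameter > 0)
  list(id = as.integer(id), position = as.numeric(position),
       diameter = as.numeric(diameter), behaviors = behaviors, attrs = attrs)
}

#' Queue a new agent for creation at the next iteration
#'
#' @param ctx an [executionContext()].
#' @param agent a [newAgent()] description.
#' @return Invisibly, the agent id.
#' @export
queueNewAgent <- function(ctx, agent) {
  pend <- vapply(ctx$additions, function(a) a$id, integer(1))
  if (agent$id %in% pend || isTRUE(ctx$usedIdCheck(agent$id)))
    stop(sprintf("agent id %d already used", agent$id))
  ctx$additions[[length(ctx$additions) + 1L]] <- agent
  invisible(agent$id)
}

#' Queue an agent removal for the next commit
#'
#' Queuing the same id twice warns once and collapses to a single removal
#' (two behaviors may legitimately remove the same agent in one iteration).
#'
#' @param ctx an [executionContext()].
#' @param id agent id to remove.
#' @return Invisibly, NULL.
#' @export
queueRemoval <- function(ctx, id) {
  id <- as.integer(id)
  dup <- id %in% ctx$removals
  if (any(dup)) {
    warning(sprintf("agent id(s) %s already queued for removal",
                    paste(id[dup], collapse = ", ")))
    id <- id[!dup]
  }
  ctx$removals <- c(ctx$removals, id)
  invisible(NULL)
}

#' Commit pending creations and removals
#'
#' Applies all staged additions and removals to the population and empties
#' the context. Removal of an id not present in the (augmented) population is
#' ignored with a warning. An agent queued and removed within the same
#' iteration never appears.
#'
#' @param ctx an [executionContext()].
#' @param population an [AgentPopulation-class].
#' @return The updated population.
#' @export
commitContext <- function(ctx, population) {
  pop <- appendAgents(population, ctx$additions)
  if (length(ctx$removals)) {
    known <- ctx$removals %in% agentIds(pop)
    if (any(!known))
      warning(sprintf("removal of unknown agent id(s) ignored: %s",
                      paste(ctx$removals[!known], collapse = ", ")))
    if (any(known))
      pop <- subsetPopulation(pop, !(agentIds(pop) %in% ctx$removals))
  }
  ctx$additions <- list()
  ctx$removals <- integer(0)
  pop
}

#' Split a behavior list between mother and daughter at a division
#'
#' The daughter receives every behavior flagged `copyOnDivision`; the mother
#' keeps every behavior not flagged `removeFromMother`. Order is preserved.
#'
#' @param behaviors list of [behaviorSpec()] objects (or character names
#'   resolved against `registry`).
#' @param registry optional named list of behavior specs, required when
#'   `behaviors` is a character vector.
#' @return list(mother = ..., daughter = ...) in the same representation as
#'   the input.
#' @export
transferBehaviors <- function(behaviors, registry = NULL) {
  if (is.character(behaviors)) {
    specs <- lapply(behaviors, function(nm) registry[[nm]])
    if (any(vapply(specs, is.null, logical(1))))
      stop("behavior name not found in registry")
    res <- transferBehaviors(specs)
    return(list(mother = vapply(res$mother, `[[`, "", "name"),
                daughter = vapply(res$daughter, `[[`, "", "name")))
  }
  copy <- vapply(behaviors, function(b) b$copyOnDivision, logical(1))
  rem <- vapply(behaviors, function(b) b$removeFromMother, logical(1))
  list(mother = behaviors[!rem], daughter = behaviors[copy])
}

#' Create a simulation object
#'
#' The simulation object is a mutable container (an environment) holding the
#' committed population, the execution context, the behavior registry, scalar
#' fields, the spatial index and collected time series. All randomness flows
#' through R's global RNG; callers seed it once per run so that a full run is
#' a pure function of (configuration, seed).
#'
#' @param population initial [AgentPopulation-class].
#' @param params a [simulationParams()].
#' @param behaviors list of [behaviorSpec()] in registration order.
#' @param fields named list of scalar fields.
#' @param gridBoxLength box length for the uniform-grid index, `NA` for
#'   auto-sizing from the largest agent, or `NULL` for no index.
#' @return A `"Simulation"` environment.
#' @export
newSimulation <- function(population, params, behaviors = list(),
                          fields = list(), gridBoxLength = NULL) {
  sim <- new.env(parent = emptyenv())
  sim$population <- population
  sim$params <- params
  sim$iteration <- 0L
  sim$maxId <- if (nAgents(population)) max(agentIds(population)) else 0L
  sim$retiredIds <- integer(0)
  sim$ctx <- executionContext(usedIdCheck = function(id)
    id %in% agentIds(sim$population) || id %in% sim$retiredIds)
  sim$behaviors <- setNames(behaviors,
                            vapply(behaviors, `[[`, "", "name"))
  sim$fields <- fields
  sim$gridBoxLength <- gridBoxLength
  sim$grid <- NULL
  sim$collectors <- list()
  sim$series <- list()
  sim$user <- new.env(parent = emptyenv())
  class(sim) <- c("Simulation", "environment")
  refreshGrid(sim)
  sim
}

#' Allocate fresh agent ids
#'
#' @param sim a simulation object.
#' @param n how many ids.
#' @return Integer vector of n new ids, never used before in this simulation.
#' @export
allocateIds <- function(sim, n = 1L) {
  ids <- sim$maxId + seq_len(n)
  sim$maxId <- sim$maxId + as.integer(n)
  as.integer(ids)
}

#' Rebuild the simulation's spatial index from the committed population
#' @param sim a simulation object.
#' @return Invisibly, the simulation.
#' @export
refreshGrid <- function(sim) {
  if (is.null(sim$gridBoxLength)) {
    sim$grid <- NULL
  } else {
    bl <- sim$gridBoxLength
    sim$grid <- buildGrid(sim$population,
                          boxLength = if (is.na(bl)) NULL else bl,
                          bounds = sim$params$bounds,
                          mode = sim$params$boundaryMode)
  }
  invisible(sim)
}

#' Standard per-agent operation that executes all registered behaviors
#'
#' Behaviors run in registration order; each behavior is applied to its
#' carriers in ascending id order (op-major scheduling: a behavior finishes
#' over the whole population before the next behavior starts).
#'
#' @param frequency execution frequency.
#' @return An [operationSpec()].
#' @export
behaviorOp <- function(frequency = 1L) {
  operationSpec("execute-behaviors", "per-agent", frequency, function(sim) {
    for (spec in sim$behaviors) {
      carriers <- vapply(sim$population@behaviors, function(b)
        spec$name %in% b, logical(1))
      ids <- agentIds(sim$population)[carriers]
      if (length(ids)) {
        res <- tryCatch(spec$run(sim, ids), error = function(e)
          stop(sprintf("behavior '%s' failed (first agent id %d): %s",
                       spec$name, ids[1], conditionMessage(e)), call. = FALSE))
      }
    }
    invisible(NULL)
  })
}

#' Advance the simulation by one iteration
#'
#' Every due per-agent operation runs (registration order, agents in
#' ascending id order), then every due standalone operation, then the
#' execution context is committed and the spatial index rebuilt. Errors
#' raised inside an operation abort the iteration with the operation name in
#' the message.
#'
#' @param sim a simulation object.
#' @param ops list of [operationSpec()] objects in registration order.
#' @return Invisibly, the simulation.
#' @export
stepOnce <- function(sim, ops) {
  runOp <- function(op) {
    tryCatch(op$procedure(sim), error = function(e)
      stop(sprintf("iteration %d, operation '%s': %s", sim$iteration,
                   op$name, conditionMessage(e)), call. = FALSE))
  }
  for (op in ops)
    if (op$kind == "per-agent" && isDue(op, sim$iteration)) runOp(op)
  for (op in ops)
    if (op$kind == "standalone" && isDue(op, sim$iteration)) runOp(op)
  sim$retiredIds <- c(sim$retiredIds, sim$ctx$removals)
  sim$population <- commitContext(sim$ctx, sim$population)
  sim$iteration <- sim$iteration + 1L
  refreshGrid(sim)
  invisible(sim)
}

#' Register a time-series collector
#'
#' @param sim a simulation object.
#' @param name unique column name.
#' @param reducer function(population) -> single number.
#' @param frequency evaluation frequency (collected at iteration 0 and every
#'   `frequency`-th iteration thereafter).
#' @return Invisibly, the simulation.
#' @export
registerCollector <- function(sim, name, reducer, frequency = 1L) {
  if (name %in% names(sim$collectors))
    stop(sprintf("collector '%s' already registered", name))
  sim$collectors[[name]] <- list(reducer = reducer,
                                 frequency = as.integer(frequency))
  invisible(sim)
}

collectNow <- function(sim) {
  due <- Filter(function(nm) isDue(sim$collectors[[nm]], sim$iteration),
                names(sim$collectors))
  if (!length(due)) return(invisible(sim))
  row <- c(list(iteration = sim$iteration),
           setNames(lapply(due, function(nm) {
             tryCatch(sim$collectors[[nm]]$reducer(sim$population),
                      error = function(e)
                        stop(sprintf("collector '%s' failed: %s", nm,
                                     conditionMessage(e)), call. = FALSE))
           }), due))
  sim$series[[length(sim$series) + 1L]] <- row
  invisible(sim)
}

#' Run a simulation for a fixed number of iterations
#'
#' Collectors are evaluated at iteration 0 (initial state) and after each due
#' iteration. Identical (configuration, seed) pairs give bit-identical time
#' series.
#'
#' @param sim a simulation object.
#' @param ops list of [operationSpec()] objects.
#' @param nIterations number of iterations (defaults to the value in
#'   `sim$params`).
#' @return Invisibly, the simulation (time series via [timeSeries()]).
#' @export
runSimulation <- function(sim, ops, nIterations = sim$params$nIterations) {
  collectNow(sim)
  it <- 0L
  while (it < nIterations) {
    stepOnce(sim, ops)
    it <- it + 1L
    collectNow(sim)
  }
  invisible(sim)
}

#' Collected time series of a simulation
#'
#' @param sim a simulation object after [runSimulation()].
#' @return data.frame keyed by iteration (one row per collected iteration).
#' @export
timeSeries <- function(sim) {
  if (!length(sim$series))
    return(data.frame(iteration = integer(0)))
  cols <- unique(unlist(lapply(sim$series, names)))
  out <- lapply(cols, function(nm)
    vapply(sim$series, function(row)
      if (is.null(row[[nm]])) NA_real_ else as.numeric(row[[nm]]), numeric(1)))
  df <- as.data.frame(setNames(out, cols))
  df$iteration <- as.integer(df$iteration)
  df
}
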