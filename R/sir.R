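#' Parameters of the SIR ordinary-differential-equation model
#'
#' Classic compartmental model
#' \deqn{dS/dt = -\beta S I / N, \quad dI/dt = \beta S I / N - \gamma I,
#'   \quad dR/dt = \gamma I}
#' parameterized by the basic reproduction number and the recovery duration:
#' \eqn{R_0 = \beta/\gamma} and \eqn{\gamma = 1/T_R}.
#'
#' @param R0 basic reproduction number (> 0).
#' @param TR mean recovery duration (days, > 0).
#' @param N total population size.
#' @param I0 initially infected count.
#' @return A `"SirOdeParams"` list with derived `beta` and `gamma`.
#' @examples
#' measles <- sirOdeParams(R0 = 12.9, TR = 8, N = 2010, I0 = 10)
#' measles$beta / measles$gamma  # == R0
#' @export
sirOdeParams <- function(R0, TR, N, I0) {
  stopifnot(R0 > 0, TR > 0, N >= 1, I0 >= 0, I0 <= N)
  gamma <- 1 / TR
  structure(list(R0 = R0, TR = TR, N = N, I0 = I0,
                 beta = R0 * gamma, gamma = gamma),
            class = "SirOdeParams")
}

#' Solve the SIR ODE system with classic RK4
#'
#' @param params a [sirOdeParams()].
#' @param horizon final time (days).
#' @param dt solver step (days); the default is small enough that halving it
#'   changes even a steep measles-like trajectory by well under 0.1% of N
#'   (and it is binary-exact, so integer days appear exactly in the output
#'   time grid).
#' @return data.frame with columns `t`, `S`, `I`, `R` (counts); the invariant
#'   S + I + R = N holds at every time point to rounding error.
#' @export
sirOdeSolve <- function(params, horizon, dt = 0.25) {
  deriv <- function(t, y, p) {
    inf <- p$beta * y[1] * y[2] / p$N
    rec <- p$gamma * y[2]
    list(c(-inf, inf - rec, rec))
  }
  times <- seq(0, horizon, by = dt)
  out <- deSolve::ode(y = c(S = params$N - params$I0, I = params$I0, R = 0),
                      times = times, func = deriv, parms = params,
                      method = "rk4")
  if (any(!is.finite(out))) stop("non-finite state in SIR ODE solution")
  df <- as.data.frame(out)
  names(df)[1] <- "t"
  df
}

#' Final attack fraction of an SIR epidemic (final-size relation)
#'
#' Solves the fixed-point equation \eqn{z = 1 - \exp(-R_0 z)} for the
#' positive root by bisection to 1e-12; below threshold (\eqn{R_0 \le 1})
#' the attack fraction is 0.
#'
#' @param R0 basic reproduction number (> 0).
#' @return Attack fraction in [0, 1).
#' @examples
#' analyticFinalSize(2)    # ~0.7968
#' analyticFinalSize(0.9)  # 0
#' @export
analyticFinalSize <- function(R0) {
  stopifnot(R0 > 0)
  if (R0 <= 1) return(0)
  f <- function(z) z - (1 - exp(-R0 * z))
  lo <- 1e-9
  hi <- 1
  # f(lo) > 0 only below threshold; bracket from a point past the unstable 0 root
  lo <- 1 - 1 / R0  # f < 0 here for R0 > 1
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) <= 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-13) break
  }
  (lo + hi) / 2
}

#' Count S/I/R states
#'
#' @param x an [AgentPopulation-class] with a `state` attribute, or a vector
#'   of states (integer codes 0/1/2 or characters "S"/"I"/"R").
#' @return Named integer vector `c(S=, I=, R=)`; the sum equals the
#'   population size.
#' @export
countStates <- function(x) {
  st <- if (is(x, "AgentPopulation")) agentAttr(x, "state") else x
  if (is.character(st)) st <- match(st, c("S", "I", "R")) - 1L
  c(S = sum(st == 0L), I = sum(st == 1L), R = sum(st == 2L))
}

#' Parameters of the spatial SIR agent-based model
#'
#' Persons are point-like agents moving randomly in a toroidal cube of side
#' `boxSide`. Per iteration (one day), a susceptible with at least one
#' infected agent within `infectionRadius` draws a single
#' Bernoulli(`pInfection`) regardless of how many infected neighbors it has;
#' an infected agent recovers with `pRecovery` (set to \eqn{\gamma} per day);
#' every agent then moves by a uniform random unit vector times a step length
#' uniform on [0, `maxStep`], wrapped toroidally.
#'
#' @param nTotal total number of persons N.
#' @param nInfected initially infected count.
#' @param infectionRadius contact radius (length units).
#' @param pInfection per-step infection probability given an infected
#'   neighbor.
#' @param pRecovery per-step recovery probability (\eqn{= \gamma \cdot} 1 day).
#' @param maxStep maximum movement distance per step.
#' @param boxSide toroidal domain side length L.
#' @return A `"SirAbmParams"` list.
#' @export
sirAbmParams <- function(nTotal, nInfected, infectionRadius, pInfection,
                         pRecovery, maxStep, boxSide) {
  stopifnot(nTotal >= 1, nInfected >= 0, nInfected <= nTotal,
            infectionRadius > 0, pInfection >= 0, pInfection <= 1,
            pRecovery >= 0, pRecovery <= 1, maxStep >= 0, boxSide > 0,
            infectionRadius <= boxSide)
  structure(list(nTotal = as.integer(nTotal),
                 nInfected = as.integer(nInfected),
                 infectionRadius = infectionRadius,
                 pInfection = pInfection, pRecovery = pRecovery,
                 maxStep = maxStep, boxSide = boxSide),
            class = "SirAbmParams")
}

initSirPositions <- function(params) {
  n <- params$nTotal
  matrix(runif(3 * n, 0, params$boxSide), ncol = 3,
         dimnames = list(NULL, c("x", "y", "z")))
}

sirSeries <- function(counts, timeStep = 1) {
  data.frame(iteration = seq_len(nrow(counts)) - 1L,
             t = (seq_len(nrow(counts)) - 1L) * timeStep,
             S = counts[, 1], I = counts[, 2], R = counts[, 3])
}

#' SIR behaviors for the generic engine (reference path)
#'
#' Builds the infection, recovery, movement and state-commit pieces as
#' engine behaviors/operations operating through the uniform-grid index.
#' State transitions computed during iteration i are applied together at the
#' end of the iteration, so a person infected at i can neither transmit nor
#' recover before i + 1 (matching the vectorized core).
#'
#' @param params a [sirAbmParams()].
#' @return list(behaviors = ..., standaloneOps = ...).
#' @keywords internal
sirBehaviors <- function(params) {
  infection <- behaviorSpec("sir-infection", function(sim, ids) {
    pop <- sim$population
    st <- agentAttr(pop, "state")
    sus <- which(st == 0L)
    if (!length(sus) || !any(st == 1L)) return(invisible(NULL))
    nxt <- sim$user$nextState
    for (row in sus) {
      nb <- neighborsWithin(sim$grid, agentIds(pop)[row],
                            params$infectionRadius)
      infNb <- nb[st[match(nb, agentIds(pop))] == 1L]
      if (length(infNb) && runif(1) < params$pInfection)
        nxt[row] <- 1L
    }
    sim$user$nextState <- nxt
    invisible(NULL)
  })
  recovery <- behaviorSpec("sir-recovery", function(sim, ids) {
    st <- agentAttr(sim$population, "state")
    inf <- which(st == 1L)
    if (!length(inf)) return(invisible(NULL))
    rec <- inf[runif(length(inf)) < params$pRecovery]
    sim$user$nextState[rec] <- 2L
    invisible(NULL)
  })
  movement <- behaviorSpec("sir-movement", function(sim, ids) {
    pop <- sim$population
    n <- nAgents(pop)
    dir <- matrix(rnorm(3 * n), ncol = 3)
    dir <- dir / sqrt(rowSums(dir^2))
    step <- runif(n, 0, params$maxStep)
    positions(pop) <- applyDisplacements(positions(pop), dir * step,
                                         sim$params$bounds, "toroidal")
    sim$population <- pop
    invisible(NULL)
  })
  commitStates <- operationSpec("sir-commit-states", "standalone", 1L,
    function(sim) {
      pop <- sim$population
      agentAttr(pop, "state") <- sim$user$nextState
      sim$population <- pop
      invisible(NULL)
    })
  list(behaviors = list(infection, recovery, movement),
       standaloneOps = list(commitStates))
}

#' Run the spatial SIR agent-based model
#'
#' @param params a [sirAbmParams()].
#' @param nIterations number of days to simulate.
#' @param seed optional integer seed (`set.seed` when given; otherwise the
#'   current RNG stream is used).
#' @param engine `"fast"` (vectorized core) or `"reference"` (generic engine
#'   with behaviors and the uniform-grid index; intended for small
#'   populations and instrumentation). Both implement the same model.
#' @param earlyStop stop iterating once no infected agents remain (the
#'   remaining time series rows are constant); fast engine only.
#' @param extraBehaviors additional [behaviorSpec()] objects appended to the
#'   reference engine's registry and attached to every initial agent (e.g.
#'   instrumentation).
#' @return list with `series` (data.frame iteration, t, S, I, R),
#'   `attackFraction` (1 - S_final / N), `finalState`, `params`.
#' @examples
#' p <- sirAbmParams(nTotal = 200, nInfected = 5, infectionRadius = 3,
#'                   pInfection = 0.8, pRecovery = 0.125, maxStep = 10,
#'                   boxSide = 20)
#' run <- runSirAbm(p, nIterations = 60, seed = 1)
#' head(run$series)
#' @export
runSirAbm <- function(params, nIterations, seed = NULL,
                      engine = c("fast", "reference"), earlyStop = TRUE,
                      extraBehaviors = list()) {
  engine <- match.arg(engine)
  if (!is.null(seed)) set.seed(seed)
  state0 <- c(rep(1L, params$nInfected),
              rep(0L, params$nTotal - params$nInfected))
  pos0 <- initSirPositions(params)
  if (engine == "fast") {
    res <- cpp_sir_run(pos0, state0, params$pInfection, params$pRecovery,
                       params$infectionRadius, params$maxStep,
                       params$boxSide, as.integer(nIterations),
                       isTRUE(earlyStop))
    series <- sirSeries(res$counts)
    finalState <- res$state
  } else {
    L <- params$boxSide
    simPar <- simulationParams(timeStep = 1, nIterations = nIterations,
                               bounds = rbind(c(0, 0, 0), c(L, L, L)),
                               boundaryMode = "toroidal")
    extraNames <- vapply(extraBehaviors, `[[`, "", "name")
    pop <- agentPopulation(pos0, diameter = 1e-6,
                           behaviors = c("sir-infection", "sir-recovery",
                                         "sir-movement", extraNames),
                           attrs = list(state = state0))
    pieces <- sirBehaviors(params)
    sim <- newSimulation(pop, simPar,
                         behaviors = c(pieces$behaviors, extraBehaviors),
                         gridBoxLength = max(params$infectionRadius,
                                             params$boxSide / 50))
    sim$user$nextState <- agentAttr(pop, "state")
    registerCollector(sim, "S", function(p) countStates(p)[["S"]])
    registerCollector(sim, "I", function(p) countStates(p)[["I"]])
    registerCollector(sim, "R", function(p) countStates(p)[["R"]])
    ops <- c(list(behaviorOp()), pieces$standaloneOps)
    runSimulation(sim, ops, nIterations)
    ts <- timeSeries(sim)
    series <- data.frame(iteration = ts$iteration, t = as.numeric(ts$iteration),
                         S = as.integer(ts$S), I = as.integer(ts$I),
                         R = as.integer(ts$R))
    finalState <- agentAttr(sim$population, "state")
    attr(series, "sim") <- sim
  }
  list(series = series,
       attackFraction = 1 - series$S[nrow(series)] / params$nTotal,
       finalState = finalState, params = params)
}

#' Mean SIR trajectory over several seeds
#'
#' @param params a [sirAbmParams()].
#' @param nIterations days per run.
#' @param seeds integer vector of seeds (one run each).
#' @param engine passed to [runSirAbm()].
#' @return list(mean = data.frame(t, S, I, R), runs = list of per-seed
#'   series, attackFractions = numeric vector).
#' @export
sirAbmEnsemble <- function(params, nIterations, seeds, engine = "fast") {
  runs <- lapply(seeds, function(s)
    runSirAbm(params, nIterations, seed = s, engine = engine))
  arr <- vapply(runs, function(r) as.matrix(r$series[, c("S", "I", "R")]),
                matrix(0, nIterations + 1L, 3))
  m <- apply(arr, c(1, 2), mean)
  list(mean = data.frame(t = 0:nIterations, S = m[, 1], I = m[, 2],
                         R = m[, 3]),
       runs = lapply(runs, `[[`, "series"),
       attackFractions = vapply(runs, `[[`, 0, "attackFraction"))
}

#' Squared-error objective between ABM ensemble mean and the ODE solution
#'
#' Sum over integer days of the squared differences of the S, I and R
#' curves, normalized by N^2 (the per-compartment fractions).
#'
#' @param abmMean data.frame from [sirAbmEnsemble()]`$mean`.
#' @param ode data.frame from [sirOdeSolve()].
#' @param N population size.
#' @return Non-negative scalar.
#' @export
sirObjectiveScore <- function(abmMean, ode, N) {
  days <- abmMean$t
  odeAt <- ode[match(days, ode$t), ]
  sum(((abmMean$S - odeAt$S)^2 + (abmMean$I - odeAt$I)^2 +
         (abmMean$R - odeAt$R)^2) / N^2)
}

#' Calibrate the spatial SIR model against its ODE counterpart
#'
#' Particle swarm optimization over (infection radius, infection
#' probability, maximum step length): each candidate runs the agent-based
#' model for `nSeeds` seeds and scores the ensemble mean against the RK4 ODE
#' solution with [sirObjectiveScore()]. The recovery probability is fixed at
#' \eqn{\gamma \cdot} 1 day and is not calibrated. One particle is
#' warm-started at the well-mixed mean-field guess
#' \eqn{p_{inf} = \beta / (q N)} with
#' \eqn{q = 1 - \exp(-\tfrac{4}{3}\pi r^3 / L^3)}.
#'
#' @param odeParams a [sirOdeParams()].
#' @param boxSide toroidal domain side L.
#' @param horizon days simulated/compared per candidate.
#' @param nSeeds seeds averaged per candidate.
#' @param swarmSize,nIterations PSO settings.
#' @param bounds list with `lower` and `upper` 3-vectors for
#'   (radius, pInfection, maxStep).
#' @param seed RNG seed for the whole calibration (candidate runs use seeds
#'   derived from it).
#' @return list with `params` (calibrated [sirAbmParams()]), `pso` (the
#'   optimizer result), `ode` (the reference trajectory).
#' @export
calibrateSirAbm <- function(odeParams, boxSide = 30, horizon = 90,
                            nSeeds = 3, swarmSize = 30, nIterations = 100,
                            bounds = list(lower = c(0.8, 0.05, 1),
                                          upper = c(5, 1, 25)),
                            seed = 1) {
  ode <- sirOdeSolve(odeParams, horizon)
  seedBase <- (seed * 1000L) %% .Machine$integer.max
  makeParams <- function(par)
    sirAbmParams(nTotal = odeParams$N, nInfected = odeParams$I0,
                 infectionRadius = par[1], pInfection = par[2],
                 pRecovery = odeParams$gamma, maxStep = par[3],
                 boxSide = boxSide)
  objective <- function(par) {
    ens <- sirAbmEnsemble(makeParams(par), horizon,
                          seeds = seedBase + seq_len(nSeeds))
    sirObjectiveScore(ens$mean, ode, odeParams$N)
  }
  r0 <- mean(c(bounds$lower[1], bounds$upper[1]))
  q0 <- 1 - exp(-(4 / 3) * pi * r0^3 / boxSide^3)
  warm <- c(r0, min(1, odeParams$beta / (q0 * odeParams$N)), boxSide / 2)
  pso <- calibratePso(objective, bounds$lower, bounds$upper,
                      swarmSize = swarmSize, nIterations = nIterations,
                      seed = seed, init = rbind(warm))
  list(params = makeParams(pso$par), pso = pso, ode = ode)
}

#' Fit the infection probability for a second disease on a calibrated
#' contact structure
#'
#' The contact geometry (infection radius) and mobility (maximum step) are
#' properties of the simulated population, not of the pathogen, so they are
#' reused from a calibrated scenario; only the per-contact infection
#' probability is re-fitted (1-D particle swarm) against the new disease's
#' ODE trajectory. A plain rescaling of the infection probability by the
#' ratio of transmission rates is not accurate enough because the
#' at-least-one-infected-neighbor contact law saturates with local
#' prevalence.
#'
#' @param odeParams a [sirOdeParams()] for the new disease.
#' @param radius,maxStep,boxSide calibrated contact structure.
#' @param horizon days per candidate run.
#' @param nSeeds seeds averaged per candidate.
#' @param swarmSize,nIterations 1-D PSO settings.
#' @param seed RNG seed.
#' @return list(params, pso, ode) as in [calibrateSirAbm()].
#' @export
calibrateSirPInfection <- function(odeParams, radius, maxStep, boxSide = 30,
                                   horizon = 250, nSeeds = 3, swarmSize = 10,
                                   nIterations = 30, seed = 1) {
  ode <- sirOdeSolve(odeParams, horizon)
  seedBase <- (seed * 2000L) %% .Machine$integer.max
  makeParams <- function(p)
    sirAbmParams(nTotal = odeParams$N, nInfected = odeParams$I0,
                 infectionRadius = radius, pInfection = p,
                 pRecovery = odeParams$gamma, maxStep = maxStep,
                 boxSide = boxSide)
  objective <- function(par) {
    ens <- sirAbmEnsemble(makeParams(par[1]), horizon,
                          seeds = seedBase + seq_len(nSeeds))
    sirObjectiveScore(ens$mean, ode, odeParams$N)
  }
  q <- 1 - exp(-(4 / 3) * pi * radius^3 / boxSide^3)
  warm <- min(1, odeParams$beta / (q * odeParams$N))
  pso <- calibratePso(objective, 1e-4, 1, swarmSize = swarmSize,
                      nIterations = nIterations, seed = seed,
                      init = rbind(warm))
  list(params = makeParams(pso$par[1]), pso = pso, ode = ode)
}

#' Built-in disease presets for the SIR scenario
#'
#' Literature values: measles R0 = 12.9, TR = 8 days; seasonal influenza
#' R0 = 1.3, TR = 4.1 days. Population sizes are desk-scale defaults.
#'
#' @param disease `"measles"` or `"influenza"`.
#' @return A [sirOdeParams()].
#' @export
diseasePreset <- function(disease = c("measles", "influenza")) {
  disease <- match.arg(disease)
  switch(disease,
         measles = sirOdeParams(R0 = 12.9, TR = 8, N = 2010, I0 = 10),
         influenza = sirOdeParams(R0 = 1.3, TR = 4.1, N = 2020, I0 = 20))
}
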