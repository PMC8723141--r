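---
title: "Methods: the agentsim simulation engine and its demonstration models"
author: "Package Author"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the agentsim simulation engine and its demonstration models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agentsim)
```

# Overview

`agentsim` is a modular agent-based simulation engine for desk-scale
biological models, plus three validated demonstration models built on it:

* a **spatial SIR epidemic** on a toroidal domain, compared against the
  Kermack--McKendrick ODE system and calibrated by particle swarm
  optimization;
* a **tumor spheroid** with linear volume growth, volume-conserving
  division, Brownian migration, apoptosis and overdamped contact
  mechanics, measured through the convex hull of the cell cloud;
* **pyramidal-cell dendritic growth** guided by static Gaussian cues,
  with tapering, stochastic bifurcation, morphometrics and SWC I/O.

This vignette documents the numerical methods and the scheduling
contracts; the README shows end-to-end usage.

# The engine

## Agents, behaviors, operations

An [`AgentPopulation`](../help/AgentPopulation-class) is a
column-oriented store of agents: unique integer ids (never reused),
positions, diameters, an ordered list of attached *behavior* names per
agent, and named per-agent attribute vectors. A *behavior*
(`behaviorSpec()`) is a named update rule; a simulation holds a registry
of behaviors, and each agent lists which ones it carries.

Iterations are driven by *operations* (`operationSpec()`). The standard
`behaviorOp()` executes every registered behavior over its carriers;
scenario-level updates (e.g. committing epidemic state transitions, a
mechanical relaxation pass) are further operations. Scheduling is
**op-major**: within one iteration every due per-agent operation runs
first (in registration order, agents in ascending id order), then every
due standalone operation, then the iteration's structural changes are
committed. Each operation has an execution *frequency* `f`: it fires at
iteration 0 and every `f`-th iteration thereafter, i.e.
`ceiling(n / f)` times over `n` iterations.

```{r frequency}
op <- operationSpec("demo", "standalone", 3L, function(sim) NULL)
which(vapply(0:9, function(i) isDue(op, i), logical(1))) - 1L
```

## Deferred lifecycle

Agent creation and removal go through an execution context
(`executionContext()`): agents queued at iteration `i` (via
`queueNewAgent()`) become visible at `i + 1`, and removals take effect at
the commit that ends the iteration. Because the spatial index is rebuilt
from the *committed* population only, a queued agent can never appear in
any neighbor query of the iteration that created it. Ids are allocated
centrally (`allocateIds()`) and never reused, including ids of removed
agents.

## Determinism

All randomness flows through R's global RNG; every runner accepts a
`seed` so a run is a pure function of (configuration, seed).

# Space: the uniform-grid index

`buildGrid()` divides the domain into uniform boxes. The requested box
length is rounded so that an integer number of boxes tiles each axis
(every effective edge is at least the requested length), which makes the
27-box stencil of `neighborsWithin()` complete for any query radius up
to the requested box length; larger radii are rejected. Open boundaries
drop out-of-domain boxes; toroidal boundaries wrap them (with
de-duplication when fewer than three boxes tile an axis). The number of
distinct boxes scanned is reported as the `boxesVisited` attribute, and
`bruteForceNeighbors()` provides the quadratic oracle used throughout
the tests.

```{r grid}
pts <- rbind(c(50, 50, 50), matrix(runif(300, 0, 100), ncol = 3))
g <- buildGrid(pts, boxLength = 10,
               bounds = rbind(c(0, 0, 0), c(100, 100, 100)))
attr(neighborsWithin(g, 1L, 10), "boxesVisited")
```

# Extracellular fields

`gaussianField()` is a static axis-aligned Gaussian profile with
closed-form value and gradient. `diffusionGrid()` advances a substance
on a regular lattice with the explicit FTCS 7-point scheme and zero-flux
boundaries, `c' = c + dt (D lap(c) - mu c)`; the scheme is stable for
`D dt / dx^2 <= 1/6` (larger steps raise an error stating the admissible
`dt`) and, with zero decay, conserves total mass to rounding error.
Values at arbitrary points are trilinearly interpolated (exact for
linear profiles); gradients use central differences of the interpolant.

# Mechanics

Contacting spheres interact through a linear spring on the overlap,
`F = (k - k_adh) * delta`, summed over pairs found with an internal cell
list, and integrated with overdamped dynamics
`dp = clamp(F / zeta * dt)`. The update is synchronous (all forces from
the pre-step configuration) and the per-step displacement clamp bounds
the step regardless of stiffness. `pairwiseForce()` isolates the contact
law; antisymmetry holds to rounding error.

# The three models

## Spatial SIR vs the ODE

Persons are point agents moving randomly in a toroidal cube. Per
one-day iteration, a susceptible with at least one infected agent within
the infection radius draws a single Bernoulli(`pInfection`); infected
agents recover with probability `gamma * 1 day`; then everyone moves.
State transitions commit at the end of the iteration, so infections
cannot cascade within a day. Two implementations exist: a vectorized
C++ core (`engine = "fast"`) and a reference path on the generic engine
(`engine = "reference"`); both implement the same model and are compared
distributionally in the tests.

The ODE counterpart `sirOdeSolve()` integrates the Kermack--McKendrick
system with RK4; `analyticFinalSize()` solves the final-size relation
`z = 1 - exp(-R0 z)` by bisection. `calibrateSirAbm()` fits (infection
radius, infection probability, maximum step) with particle swarm
optimization against the ODE trajectory; `calibrateSirPInfection()`
refits only the infection probability for a second pathogen on the same
contact structure, since radius and mobility are properties of the
population, not of the disease.

```{r finalsize}
analyticFinalSize(2)
analyticFinalSize(1.3)
```

## Tumor spheroid

Cells grow linearly in volume, divide above a diameter threshold
(division conserves volume exactly; the daughter receives a uniform
fraction from a symmetric interval and is queued for the next
iteration), migrate as Brownian particles and die with a small per-step
probability; overlap relaxes through the mechanics operation. The
spheroid diameter is the equivalent-sphere diameter of the convex hull
of all cell centers, `d = (6 V / pi)^(1/3)`, computed by an incremental
3-D hull in C++ and validated against a facet-enumeration oracle.

## Pyramidal-cell growth

Each cell starts as a soma with one apical and three basal dendrites of
0.5 um. Terminal tips are agents; per iteration a tip advances by its
elongation speed along a direction blending the guidance-cue gradient,
its previous direction and noise, tapers its diameter (reaching the
floor permanently stops growth), and bifurcates with a small
probability into two daughters at the branch angle. Every advance
appends an SWC-style node (parents always precede children).
`morphometrics()` reports branch points (nodes with exactly two
children) and tree lengths; `writeSwc()` / `readSwc()` round-trip the
morphology byte-identically.

# Reproducing the validation

The full property suite lives in `tests/testthat/` (run
`testthat::test_dir("tests/testthat", package = "agentsim",
load_package = "installed")`), and `scripts/acceptance.R` reruns the
headline quantities end to end:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Both derive every random stream from the given seed.
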