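#' Mechanical interaction parameters
#'
#' Pairwise contact law between spherical agents: a linear spring on the
#' overlap \eqn{\delta = (r_a + r_b) - |p_a - p_b|} (zero force without
#' contact), with an optional linear adhesion term, integrated with
#' overdamped first-order dynamics \eqn{\Delta p = F/\zeta \, dt} and a
#' per-step displacement clamp that guarantees stability regardless of
#' stiffness. The contact law is isolated behind [pairwiseForce()] so a
#' different law can be substituted.
#'
#' @param repulsionStiffness spring constant k (force / length), > 0.
#' @param viscosity damping \eqn{\zeta} (force time / length), > 0.
#' @param maxDisplacementPerStep displacement clamp (length), > 0.
#' @param adhesionCoefficient linear adhesion (force / length), default 0.
#' @return A `"MechanicsParams"` list.
#' @export
mechanicsParams <- function(repulsionStiffness = 2, viscosity = 1,
                            maxDisplacementPerStep = 3,
                            adhesionCoefficient = 0) {
  stopifnot(repulsionStiffness > 0, viscosity > 0,
            maxDisplacementPerStep > 0, adhesionCoefficient >= 0)
  structure(list(k = repulsionStiffness, zeta = viscosity,
                 maxDisp = maxDisplacementPerStep,
                 adhesion = adhesionCoefficient),
            class = "MechanicsParams")
}

#' Pairwise contact force between two spheres
#'
#' Force on sphere `a` exerted by sphere `b`: magnitude
#' \eqn{(k - k_{adh}) \delta} along the center line from b to a for positive
#' overlap \eqn{\delta}, zero otherwise. Antisymmetric by construction.
#' Coincident centers get a deterministic (seeded) random direction with a
#' warning.
#'
#' @param posA,posB center positions (3-vectors).
#' @param radiusA,radiusB sphere radii.
#' @param params a [mechanicsParams()].
#' @return Numeric force 3-vector on `a`.
#' @examples
#' p <- mechanicsParams(repulsionStiffness = 2)
#' pairwiseForce(c(0, 0, 0), c(8, 0, 0), 5, 5, p)  # overlap 2, |F| = 4
#' @export
pairwiseForce <- function(posA, posB, radiusA, radiusB, params) {
  e <- as.numeric(posA) - as.numeric(posB)
  d <- sqrt(sum(e^2))
  delta <- (radiusA + radiusB) - d
  if (delta <= 0) return(c(0, 0, 0))
  if (d < 1e-12) {
    warning("coincident sphere centers: using a random separation direction")
    e <- rnorm(3)
    d <- sqrt(sum(e^2))
  }
  (params$k - params$adhesion) * delta * e / d
}

#' Overdamped displacements for a population of spheres
#'
#' Sums contact forces from the pre-step configuration for all agents
#' (synchronous update), then converts to clamped displacements
#' \eqn{\Delta p = \mathrm{clamp}(F/\zeta \, dt)}. Neighbor candidates come
#' from an internal cell list whose cell edge is at least the largest
#' diameter, so no contacting pair is missed.
#'
#' @param positions n x 3 matrix of centers.
#' @param radii numeric vector of sphere radii.
#' @param params a [mechanicsParams()].
#' @param dt time step.
#' @return n x 3 matrix of displacements.
#' @export
mechanicalDisplacements <- function(positions, radii, params, dt) {
  positions <- as.matrix(positions)
  res <- cpp_mech_displacements(positions, as.numeric(radii), params$k,
                                params$adhesion, params$zeta, dt,
                                params$maxDisp)
  if (res$n_coincident > 0)
    warning(sprintf("%d coincident sphere pair(s): random separation direction used",
                    res$n_coincident))
  res$disp
}

#' Apply displacements with boundary handling
#'
#' @param positions n x 3 matrix.
#' @param displacements n x 3 matrix (one row per agent).
#' @param bounds 2 x 3 domain bounds.
#' @param mode `"open"` (clamp to bounds) or `"toroidal"` (wrap).
#' @return Updated n x 3 position matrix.
#' @export
applyDisplacements <- function(positions, displacements, bounds,
                               mode = c("open", "toroidal")) {
  mode <- match.arg(mode)
  positions <- as.matrix(positions)
  if (!identical(dim(positions), dim(as.matrix(displacements))))
    stop("positions and displacements must have identical dimensions")
  out <- positions + displacements
  for (j in 1:3) {
    lo <- bounds[1, j]; hi <- bounds[2, j]
    if (mode == "toroidal") {
      out[, j] <- lo + (out[, j] - lo) %% (hi - lo)
    } else {
      out[, j] <- pmin(pmax(out[, j], lo), hi)
    }
  }
  out
}

#' Per-agent operation running one mechanical relaxation pass
#'
#' @param params a [mechanicsParams()].
#' @param frequency execution frequency.
#' @return An [operationSpec()] usable with [stepOnce()].
#' @export
mechanicsOp <- function(params, frequency = 1L) {
  operationSpec("mechanical-relaxation", "per-agent", frequency,
                function(sim) {
    pop <- sim$population
    if (nAgents(pop) < 2L) return(invisible(NULL))
    disp <- mechanicalDisplacements(positions(pop), diameters(pop) / 2,
                                    params, sim$params$timeStep)
    positions(pop) <- applyDisplacements(positions(pop), disp,
                                         sim$params$bounds,
                                         sim$params$boundaryMode)
    sim$population <- pop
    invisible(NULL)
  })
}
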