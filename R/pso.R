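#' Global-best particle swarm optimization
#'
#' Standard global-best PSO with constriction-style coefficients. Velocity
#' update per particle:
#' \deqn{v \leftarrow w v + c_1 r_1 (p_{best} - x) + c_2 r_2 (g_{best} - x)}
#' with componentwise uniform \eqn{r_1, r_2}; positions are clamped to the
#' box bounds. Deterministic given the RNG seed. A particle whose objective
#' evaluates non-finite is reset uniformly into the bounds (counted in the
#' result).
#'
#' @param objective function(parameter vector) -> finite score (minimized).
#' @param lower,upper numeric vectors of box bounds (finite, same length).
#' @param swarmSize number of particles.
#' @param nIterations number of velocity/position updates.
#' @param w inertia weight.
#' @param c1,c2 cognitive / social acceleration coefficients.
#' @param seed optional integer seed (`set.seed` is called when given).
#' @param init optional matrix of initial particle positions (one row per
#'   particle; remaining particles are drawn uniformly in the bounds).
#' @return list with `par` (best-ever position), `value` (its score),
#'   `history` (best score after each iteration), `nResets`.
#' @examples
#' sphere <- function(x) sum(x^2)
#' fit <- calibratePso(sphere, rep(-5, 3), rep(5, 3), swarmSize = 30,
#'                     nIterations = 200, seed = 1)
#' fit$value < 1e-6
#' @export
calibratePso <- function(objective, lower, upper, swarmSize = 30,
                         nIterations = 100, w = 0.7298, c1 = 1.49618,
                         c2 = 1.49618, seed = NULL, init = NULL) {
  stopifnot(length(lower) == length(upper), all(is.finite(lower)),
            all(is.finite(upper)), all(upper > lower))
  if (!is.null(seed)) set.seed(seed)
  d <- length(lower)
  span <- upper - lower
  x <- matrix(runif(swarmSize * d), swarmSize, d) %*% diag(span, d) +
    matrix(lower, swarmSize, d, byrow = TRUE)
  if (!is.null(init)) {
    init <- matrix(init, ncol = d)
    k <- min(nrow(init), swarmSize)
    x[seq_len(k), ] <- pmin(pmax(init[seq_len(k), , drop = FALSE],
                                 matrix(lower, k, d, byrow = TRUE)),
                            matrix(upper, k, d, byrow = TRUE))
  }
  v <- matrix(runif(swarmSize * d, -1, 1), swarmSize, d) %*% diag(span, d) * 0.1
  evalSafe <- function(p) {
    val <- objective(p)
    if (!is.finite(val)) NA_real_ else val
  }
  nResets <- 0L
  fx <- numeric(swarmSize)
  for (i in seq_len(swarmSize)) {
    fx[i] <- evalSafe(x[i, ])
    if (is.na(fx[i])) {
      nResets <- nResets + 1L
      x[i, ] <- lower + runif(d) * span
      fx[i] <- evalSafe(x[i, ])
      if (is.na(fx[i])) fx[i] <- Inf
    }
  }
  pbest <- x
  fpbest <- fx
  g <- which.min(fpbest)
  gbest <- pbest[g, ]
  fgbest <- fpbest[g]
  history <- numeric(nIterations)
  for (it in seq_len(nIterations)) {
    for (i in seq_len(swarmSize)) {
      r1 <- runif(d); r2 <- runif(d)
      v[i, ] <- w * v[i, ] + c1 * r1 * (pbest[i, ] - x[i, ]) +
        c2 * r2 * (gbest - x[i, ])
      x[i, ] <- pmin(pmax(x[i, ] + v[i, ], lower), upper)
      fi <- evalSafe(x[i, ])
      if (is.na(fi)) {
        nResets <- nResets + 1L
        x[i, ] <- lower + runif(d) * span
        v[i, ] <- 0
        fi <- evalSafe(x[i, ])
        if (is.na(fi)) fi <- Inf
      }
      if (fi < fpbest[i]) {
        fpbest[i] <- fi
        pbest[i, ] <- x[i, ]
        if (fi < fgbest) {
          fgbest <- fi
          gbest <- x[i, ]
        }
      }
    }
    history[it] <- fgbest
  }
  list(par = gbest, value = fgbest, history = history, nResets = nResets)
}
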