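# Independent reference implementations used as test oracles. These are
# deliberately naive (quadratic / quartic) and share no code with the
# package internals they validate.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# O(n^4) convex hull volume by facet enumeration: a point triple is a hull
# facet iff every other point lies on one side of its plane. Requires the
# points to be in general position (no 4 coplanar hull points), which holds
# almost surely for the random sets used in the tests.
oracleHullVolume <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  stopifnot(n >= 4)
  g <- colMeans(pts)
  scale <- max(abs(sweep(pts, 2, g)))
  tol <- 1e-10 * max(scale^2, 1)
  vol <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- pts[i, ]; b <- pts[j, ]; cc <- pts[k, ]
    nrm <- cross3(b - a, cc - a)
    if (sqrt(sum(nrm^2)) < tol) next
    s <- as.numeric(pts %*% nrm) - sum(nrm * a)
    if (all(s <= tol) || all(s >= -tol)) {
      # orient the facet normal away from the centroid
      if (sum(nrm * (g - a)) > 0) { tmp <- b; b <- cc; cc <- tmp }
      vol <- vol + det(rbind(a - g, b - g, cc - g)) / 6
    }
  }
  vol
}

# brute-force neighbor oracle is provided by the package itself
# (bruteForceNeighbors); used directly since it is a one-liner over
# pairwise distances and is itself unit-tested against hand cases.

# random point cloud helpers
randomCloud <- function(n, lo, hi) {
  matrix(runif(3 * n, lo, hi), ncol = 3)
}

clusteredCloud <- function(n, lo, hi, nClusters = 5, spread = NULL) {
  if (is.null(spread)) spread <- (hi - lo) / 20
  centers <- matrix(runif(3 * nClusters, lo, hi), ncol = 3)
  pick <- sample(nClusters, n, replace = TRUE)
  pts <- centers[pick, , drop = FALSE] + matrix(rnorm(3 * n, 0, spread),
                                                ncol = 3)
  pmin(pmax(pts, lo), hi)
}

# behavior that records, every iteration, whether any id queued in the
# execution context is visible in the committed population or in a
# fixed-radius neighbor list built from it
visibilityAuditBehavior <- function(radius = 5) {
  behaviorSpec("visibility-audit", function(sim, ids) {
    queued <- vapply(sim$ctx$additions, function(a) a$id, integer(1))
    log <- sim$user$visibilityLog
    if (is.null(log)) log <- list()
    committed <- agentIds(sim$population)
    leakedPop <- any(queued %in% committed)
    leakedNb <- FALSE
    if (length(queued) && nAgents(sim$population) >= 1) {
      # box length capped from below by the domain size so the box count
      # stays small even over very large scenario domains
      ext <- sim$params$bounds[2, ] - sim$params$bounds[1, ]
      grid <- buildGrid(sim$population,
                        boxLength = max(radius, max(ext) / 8),
                        bounds = sim$params$bounds,
                        mode = sim$params$boundaryMode)
      nbs <- unlist(lapply(committed, function(id)
        neighborsWithin(grid, id, radius)), use.names = FALSE)
      leakedNb <- any(queued %in% nbs)
    }
    log[[length(log) + 1L]] <- list(iteration = sim$iteration,
                                    queued = queued,
                                    visibleNow = leakedPop || leakedNb,
                                    committed = committed)
    sim$user$visibilityLog <- log
    invisible(NULL)
  }, copyOnDivision = FALSE)
}

# checks a visibility log: every queued id must be absent at its queueing
# iteration and present in the committed population at the next audited
# iteration (if any)
auditDeferredVisibility <- function(log) {
  sawQueued <- FALSE
  for (k in seq_along(log)) {
    entry <- log[[k]]
    if (entry$visibleNow) return(list(ok = FALSE, sawQueued = TRUE,
                                      why = "queued id visible same iteration"))
    if (length(entry$queued)) {
      sawQueued <- TRUE
      if (k < length(log)) {
        nxt <- log[[k + 1L]]
        if (!all(entry$queued %in% nxt$committed))
          return(list(ok = FALSE, sawQueued = TRUE,
                      why = "queued id missing at next iteration"))
      }
    }
  }
  list(ok = TRUE, sawQueued = sawQueued, why = "")
}
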