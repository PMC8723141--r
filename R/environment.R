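#' Uniform-grid spatial index
#'
#' The simulation space is divided into uniform boxes; each agent is assigned
#' to the box containing its center. A fixed-radius neighborhood query scans
#' the query agent's box and its surrounding boxes (27 boxes in total for an
#' interior agent; fewer at open boundaries, wrapped in toroidal mode).
#' The requested box length is rounded so that an integer number of boxes
#' tiles each axis; every effective box edge is at least the requested
#' length, so the 27-box scan is complete for any query radius up to the
#' requested box length.
#'
#' @slot boxLength requested box edge length (auto-size: largest diameter).
#' @slot effLength effective box edge per axis (>= boxLength when > 1 box).
#' @slot origin lower bounds per axis.
#' @slot extent domain extent per axis.
#' @slot dims box counts per axis.
#' @slot boxContents list mapping linear box index to agent row indices.
#' @slot ids agent ids in row order.
#' @slot positions agent positions in row order.
#' @slot mode `"open"` or `"toroidal"`.
#' @export
setClass("UniformGridEnvironment",
  representation(
    boxLength = "numeric", effLength = "numeric", origin = "numeric",
    extent = "numeric", dims = "integer", boxContents = "list",
    ids = "integer", positions = "matrix", mode = "character"))

setMethod("show", "UniformGridEnvironment", function(object) {
  cat(sprintf("UniformGridEnvironment: %d agents, %s boxes (box length %.4g, %s)\n",
              length(object@ids), paste(object@dims, collapse = " x "),
              object@boxLength, object@mode))
  invisible(NULL)
})

linearBoxIndex <- function(bx, dims) {
  (bx[, 1] * dims[2] + bx[, 2]) * dims[3] + bx[, 3] + 1L
}

#' Build a uniform-grid spatial index
#'
#' @param agents an [AgentPopulation-class], or an n x 3 position matrix.
#' @param boxLength box edge length; `NULL` auto-sizes to the largest agent
#'   diameter (error for an empty population or a bare position matrix).
#' @param bounds 2 x 3 matrix of domain bounds (min row, max row).
#' @param mode `"open"` or `"toroidal"` (positions must be pre-wrapped).
#' @param diameter diameters used for auto-sizing when `agents` is a matrix.
#' @return A [UniformGridEnvironment-class].
#' @examples
#' pop <- agentPopulation(matrix(runif(60, 0, 50), ncol = 3),
#'                        diameter = c(10, 12, 8))
#' grid <- buildGrid(pop, bounds = rbind(c(0, 0, 0), c(50, 50, 50)))
#' grid@boxLength  # 12: largest diameter
#' @export
buildGrid <- function(agents, boxLength = NULL,
                      bounds = rbind(c(0, 0, 0), c(100, 100, 100)),
                      mode = c("open", "toroidal"), diameter = NULL) {
  mode <- match.arg(mode)
  if (is(agents, "AgentPopulation")) {
    pos <- positions(agents)
    ids <- agentIds(agents)
    diameter <- diameters(agents)
  } else {
    pos <- as.matrix(agents)
    ids <- seq_len(nrow(pos))
  }
  if (is.null(boxLength)) {
    if (!length(diameter) || nrow(pos) == 0L)
      stop("auto box size undefined: no agents (pass an explicit boxLength)")
    boxLength <- max(diameter)
  }
  if (!isTRUE(boxLength > 0)) stop("boxLength must be > 0")
  origin <- as.numeric(bounds[1, ])
  extent <- as.numeric(bounds[2, ] - bounds[1, ])
  dims <- pmax(1L, as.integer(floor(extent / boxLength)))
  effLength <- extent / dims
  nb <- prod(dims)
  boxContents <- rep(list(integer(0)), nb)
  if (nrow(pos) > 0) {
    bx <- sapply(1:3, function(j)
      pmin(pmax(floor((pos[, j] - origin[j]) / effLength[j]), 0), dims[j] - 1L))
    if (nrow(pos) == 1L) bx <- matrix(bx, nrow = 1)
    lin <- linearBoxIndex(bx, dims)
    boxContents[seq_len(nb)] <- split(seq_len(nrow(pos)),
                                      factor(lin, levels = seq_len(nb)))
  }
  new("UniformGridEnvironment", boxLength = boxLength, effLength = effLength,
      origin = origin, extent = extent, dims = dims,
      boxContents = boxContents, ids = as.integer(ids), positions = pos,
      mode = mode)
}

torDelta <- function(d, L) {
  d <- abs(d)
  pmin(d, L - d)
}

#' Pairwise distance respecting the boundary mode
#'
#' @param a n x 3 matrix (or 3-vector) of positions.
#' @param b 3-vector.
#' @param mode `"open"` or `"toroidal"`.
#' @param extent domain extent per axis (toroidal mode).
#' @return Numeric vector of distances.
#' @export
boundaryDistance <- function(a, b, mode = "open", extent = NULL) {
  a <- matrix(a, ncol = 3)
  d <- sweep(a, 2, as.numeric(b))
  if (mode == "toroidal") {
    for (j in 1:3) d[, j] <- torDelta(d[, j], extent[j])
  }
  sqrt(rowSums(d * d))
}

#' Fixed-radius neighborhood query on the uniform grid
#'
#' Returns the ids of all agents (excluding the query agent) whose centers
#' lie within `radius` of the query position, inclusive of the boundary
#' (distance exactly `radius` counts). The query must not exceed the grid's
#' box length, otherwise the 27-box scan would be incomplete. The number of
#' distinct boxes scanned is attached as attribute `"boxesVisited"`.
#'
#' @param grid a [UniformGridEnvironment-class].
#' @param query an agent id present in the grid, or a numeric 3-vector.
#' @param radius query radius; must satisfy `radius <= grid@boxLength`.
#' @return Integer vector of neighbor ids (ascending), with attribute
#'   `boxesVisited`.
#' @export
neighborsWithin <- function(grid, query, radius) {
  if (radius > grid@boxLength + 1e-12)
    stop(sprintf(paste0("invalid radius %g: must be <= box length %g, ",
                        "otherwise the 27-box scan is incomplete"),
                 radius, grid@boxLength))
  if (length(query) == 1L) {
    row <- match(as.integer(query), grid@ids)
    if (is.na(row)) stop(sprintf("agent id %s not in grid", query))
    qpos <- grid@positions[row, ]
    qid <- grid@ids[row]
  } else {
    stopifnot(length(query) == 3L)
    qpos <- as.numeric(query)
    qid <- NA_integer_
  }
  dims <- grid@dims
  qb <- pmin(pmax(floor((qpos - grid@origin) / grid@effLength), 0), dims - 1L)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  cand <- sweep(offsets, 2, qb, "+")
  if (grid@mode == "toroidal") {
    for (j in 1:3) cand[, j] <- cand[, j] %% dims[j]
  } else {
    keep <- cand[, 1] >= 0 & cand[, 1] < dims[1] &
            cand[, 2] >= 0 & cand[, 2] < dims[2] &
            cand[, 3] >= 0 & cand[, 3] < dims[3]
    cand <- cand[keep, , drop = FALSE]
  }
  lin <- unique(linearBoxIndex(cand, dims))
  rows <- unlist(grid@boxContents[lin], use.names = FALSE)
  out <- integer(0)
  if (length(rows)) {
    d <- boundaryDistance(grid@positions[rows, , drop = FALSE], qpos,
                          grid@mode, grid@extent)
    hit <- grid@ids[rows[d <= radius + 1e-12]]
    out <- sort(hit[is.na(qid) | hit != qid])
  }
  attr(out, "boxesVisited") <- length(lin)
  out
}

#' Brute-force fixed-radius neighbor search (quadratic oracle)
#'
#' Direct pairwise-distance reference used to validate the uniform grid; in
#' toroidal mode the per-axis distance is `min(|d|, L - |d|)`.
#'
#' @param agents an [AgentPopulation-class] or an n x 3 position matrix.
#' @param query an agent id (population input) / row index (matrix input), or
#'   a numeric 3-vector.
#' @param radius query radius (inclusive).
#' @param mode `"open"` or `"toroidal"`.
#' @param bounds 2 x 3 domain bounds (needed in toroidal mode).
#' @return Integer vector of neighbor ids (ascending).
#' @export
bruteForceNeighbors <- function(agents, query, radius, mode = "open",
                                bounds = NULL) {
  if (is(agents, "AgentPopulation")) {
    pos <- positions(agents); ids <- agentIds(agents)
  } else {
    pos <- as.matrix(agents); ids <- seq_len(nrow(pos))
  }
  extent <- if (!is.null(bounds)) as.numeric(bounds[2, ] - bounds[1, ])
  if (length(query) == 1L) {
    row <- match(as.integer(query), ids)
    qpos <- pos[row, ]; qid <- ids[row]
  } else {
    qpos <- as.numeric(query); qid <- NA_integer_
  }
  d <- boundaryDistance(pos, qpos, mode, extent)
  hit <- ids[d <= radius + 1e-12]
  sort(hit[is.na(qid) | hit != qid])
}

#' Box occupancy histogram of a grid (diagnostics)
#'
#' @param grid a [UniformGridEnvironment-class].
#' @return data.frame with columns `occupancy` and `nBoxes`.
#' @export
gridOccupancy <- function(grid) {
  occ <- lengths(grid@boxContents)
  tab <- table(occ)
  data.frame(occupancy = as.integer(names(tab)),
             nBoxes = as.integer(tab))
}
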