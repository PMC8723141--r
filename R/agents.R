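#' Agent population container
#'
#' Column-oriented store for a set of agents: stable integer ids, 3-D
#' positions, diameters, an ordered list of attached behavior names per agent,
#' and arbitrary named per-agent attribute vectors for scenario state.
#' Ids are unique within a simulation and are never reused, even after an
#' agent is removed.
#'
#' @slot id integer vector of unique agent ids (kept in ascending order).
#' @slot position numeric matrix, one row per agent, columns x, y, z.
#' @slot diameter positive numeric vector (length units).
#' @slot alive logical vector; agents in a committed population are alive.
#' @slot behaviors list of character vectors: the ordered behavior names
#'   attached to each agent (resolved against a behavior registry at run time).
#' @slot attrs named list of vectors, each of length `nAgents`.
#' @export
setClass("AgentPopulation",
  representation(
    id = "integer",
    position = "matrix",
    diameter = "numeric",
    alive = "logical",
    behaviors = "list",
    attrs = "list"
  ),
  prototype(
    id = integer(0),
    position = matrix(numeric(0), ncol = 3,
                      dimnames = list(NULL, c("x", "y", "z"))),
    diameter = numeric(0),
    alive = logical(0),
    behaviors = list(),
    attrs = list()
  )
)

setValidity("AgentPopulation", function(object) {
  n <- length(object@id)
  msgs <- character(0)
  if (anyDuplicated(object@id)) msgs <- c(msgs, "agent ids must be unique")
  if (nrow(object@position) != n || ncol(object@position) != 3L)
    msgs <- c(msgs, "position must be an n x 3 matrix")
  if (length(object@diameter) != n || any(object@diameter <= 0))
    msgs <- c(msgs, "diameter must be positive for every agent")
  if (length(object@alive) != n) msgs <- c(msgs, "alive must have length n")
  if (length(object@behaviors) != n)
    msgs <- c(msgs, "behaviors must have one entry per agent")
  bad <- vapply(object@attrs, function(a) length(a) != n, logical(1))
  if (any(bad))
    msgs <- c(msgs, sprintf("attrs not of length n: %s",
                            paste(names(object@attrs)[bad], collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct an agent population
#'
#' @param position n x 3 numeric matrix (or NULL for an empty population).
#' @param diameter numeric vector of positive diameters, recycled to n rows.
#' @param id integer ids; defaults to `seq_len(n)`.
#' @param behaviors list of character vectors (behavior names per agent), a
#'   single character vector applied to all agents, or NULL.
#' @param attrs named list of per-agent attribute vectors.
#' @return An [AgentPopulation-class] object with agents sorted by id.
#' @examples
#' pop <- agentPopulation(matrix(rnorm(30), ncol = 3), diameter = 10)
#' nAgents(pop)
#' @export
agentPopulation <- function(position = NULL, diameter = 1, id = NULL,
                            behaviors = NULL, attrs = list()) {
  if (is.null(position)) {
    position <- matrix(numeric(0), ncol = 3)
  }
  position <- as.matrix(position)
  if (ncol(position) != 3L) stop("position must have 3 columns")
  n <- nrow(position)
  colnames(position) <- c("x", "y", "z")
  if (is.null(id)) id <- seq_len(n)
  id <- as.integer(id)
  diameter <- rep_len(as.numeric(diameter), n)
  if (is.null(behaviors)) {
    behaviors <- rep(list(character(0)), n)
  } else if (is.character(behaviors)) {
    behaviors <- rep(list(behaviors), n)
  }
  attrs <- lapply(attrs, function(a) rep_len(a, n))
  ord <- order(id)
  new("AgentPopulation",
      id = id[ord],
      position = position[ord, , drop = FALSE],
      diameter = diameter[ord],
      alive = rep(TRUE, n),
      behaviors = behaviors[ord],
      attrs = lapply(attrs, function(a) a[ord]))
}

#' @rdname nAgents
#' @export
setMethod("nAgents", "AgentPopulation", function(x) length(x@id))

#' @rdname agentIds
#' @export
setMethod("agentIds", "AgentPopulation", function(x) x@id)

#' @rdname positions
#' @export
setMethod("positions", "AgentPopulation", function(x) x@position)

#' @rdname positions
#' @export
setMethod("positions<-", "AgentPopulation", function(x, value) {
  stopifnot(is.matrix(value), nrow(value) == nAgents(x), ncol(value) == 3L)
  x@position <- value
  x
})

#' @rdname diameters
#' @export
setMethod("diameters", "AgentPopulation", function(x) x@diameter)

#' @rdname diameters
#' @export
setMethod("diameters<-", "AgentPopulation", function(x, value) {
  stopifnot(length(value) == nAgents(x), all(value > 0))
  x@diameter <- as.numeric(value)
  x
})

#' @rdname agentAttr
#' @export
setMethod("agentAttr", "AgentPopulation", function(x, name) x@attrs[[name]])

#' @rdname agentAttr
#' @export
setMethod("agentAttr<-", "AgentPopulation", function(x, name, value) {
  stopifnot(length(value) == nAgents(x))
  x@attrs[[name]] <- value
  x
})

setMethod("show", "AgentPopulation", function(object) {
  cat("AgentPopulation with", nAgents(object), "agents\n")
  if (nAgents(object) > 0) {
    cat("  diameter range:", paste(signif(range(object@diameter), 4),
                                   collapse = " .. "), "\n")
    if (length(object@attrs))
      cat("  attrs:", paste(names(object@attrs), collapse = ", "), "\n")
  }
  invisible(NULL)
})

#' Subset an agent population by row index
#'
#' @param pop an [AgentPopulation-class].
#' @param idx integer or logical row index.
#' @return The subset population (id order preserved).
#' @keywords internal
subsetPopulation <- function(pop, idx) {
  new("AgentPopulation",
      id = pop@id[idx],
      position = pop@position[idx, , drop = FALSE],
      diameter = pop@diameter[idx],
      alive = pop@alive[idx],
      behaviors = pop@behaviors[idx],
      attrs = lapply(pop@attrs, function(a) a[idx]))
}

#' Append agents to a population
#'
#' New agents must carry ids larger than any existing id (ids are never
#' reused); attribute columns are unioned, missing entries filled with NA.
#'
#' @param pop an [AgentPopulation-class].
#' @param additions list of agent description lists as produced by
#'   [newAgent()].
#' @return The enlarged population.
#' @keywords internal
appendAgents <- function(pop, additions) {
  if (!length(additions)) return(pop)
  ids <- vapply(additions, function(a) a$id, integer(1))
  posNew <- do.call(rbind, lapply(additions, function(a) a$position))
  colnames(posNew) <- c("x", "y", "z")
  diamNew <- vapply(additions, function(a) a$diameter, numeric(1))
  behNew <- lapply(additions, function(a) a$behaviors)
  attrNames <- union(names(pop@attrs),
                     unique(unlist(lapply(additions, function(a) names(a$attrs)))))
  n0 <- nAgents(pop)
  n1 <- length(additions)
  attrs <- setNames(lapply(attrNames, function(nm) {
    old <- if (nm %in% names(pop@attrs)) pop@attrs[[nm]] else rep(NA, n0)
    addVals <- lapply(additions, function(a)
      if (nm %in% names(a$attrs)) a$attrs[[nm]] else NA)
    c(old, unlist(addVals))
  }), attrNames)
  out <- new("AgentPopulation",
             id = c(pop@id, ids),
             position = rbind(pop@position, posNew),
             diameter = c(pop@diameter, diamNew),
             alive = c(pop@alive, rep(TRUE, n1)),
             behaviors = c(pop@behaviors, behNew),
             attrs = attrs)
  if (is.unsorted(out@id)) {
    ord <- order(out@id)
    out <- subsetPopulation(out, ord)
  }
  out
}
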