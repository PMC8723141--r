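#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats runif rnorm setNames
#' @importFrom utils head write.csv read.csv
NULL

#' Number of agents in a population
#'
#' @param x an [AgentPopulation-class] object.
#' @return Integer scalar.
#' @export
setGeneric("nAgents", function(x) standardGeneric("nAgents"))

#' Agent identifiers
#'
#' @param x an [AgentPopulation-class] object.
#' @return Integer vector of unique, never-reused agent ids (ascending).
#' @export
setGeneric("agentIds", function(x) standardGeneric("agentIds"))

#' Agent positions
#'
#' @param x an [AgentPopulation-class] object.
#' @return Numeric matrix with one row per agent and columns x, y, z.
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname positions
#' @param value replacement matrix, same shape as `positions(x)`.
#' @export
setGeneric("positions<-", function(x, value) standardGeneric("positions<-"))

#' Agent diameters
#'
#' @param x an [AgentPopulation-class] object.
#' @return Numeric vector of diameters (length units), all positive.
#' @export
setGeneric("diameters", function(x) standardGeneric("diameters"))

#' @rdname diameters
#' @param value replacement numeric vector.
#' @export
setGeneric("diameters<-", function(x, value) standardGeneric("diameters<-"))

#' Extra per-agent attribute columns
#'
#' Scenario models attach their own per-agent state (epidemic state, cell
#' volume, neurite topology) as named attribute vectors.
#'
#' @param x an [AgentPopulation-class] object.
#' @param name attribute name.
#' @return The attribute vector (length `nAgents(x)`).
#' @export
setGeneric("agentAttr", function(x, name) standardGeneric("agentAttr"))

#' @rdname agentAttr
#' @param value replacement vector of length `nAgents(x)`.
#' @export
setGeneric("agentAttr<-", function(x, name, value) standardGeneric("agentAttr<-"))

#' Scalar field value at one or more points
#'
#' @param field a [GaussianField-class] or [DiffusionGrid-class].
#' @param points numeric 3-vector or an n x 3 matrix of query points.
#' @return Numeric vector of concentrations, one per query point. Points
#'   outside the field's domain are clamped to the boundary value (a note is
#'   logged once per call).
#' @export
setGeneric("fieldValue", function(field, points) standardGeneric("fieldValue"))

#' Scalar field gradient at one or more points
#'
#' @inheritParams fieldValue
#' @return An n x 3 matrix of gradient vectors (concentration / length).
#' @export
setGeneric("fieldGradient", function(field, points) standardGeneric("fieldGradient"))

#' Total substance mass on a diffusion grid
#'
#' @param field a [DiffusionGrid-class].
#' @return Sum of voxel concentrations times voxel volume.
#' @export
setGeneric("totalMass", function(field) standardGeneric("totalMass"))
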