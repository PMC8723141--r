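#' Static Gaussian guidance cue
#'
#' A time-invariant extracellular substance whose concentration follows a
#' Gaussian profile along one axis:
#' \eqn{c(p) = A \exp(-(p_{axis} - m)^2 / (2\sigma^2))}. Used e.g. as an
#' artificial growth factor guiding dendrite outgrowth; because the profile
#' never changes, it needs no diffusion solver and no stability constraint.
#'
#' @slot substanceName substance label.
#' @slot amplitude peak concentration A.
#' @slot axis `"x"`, `"y"` or `"z"`.
#' @slot mean profile center m (length units).
#' @slot sigma profile width, > 0.
#' @export
setClass("GaussianField",
  representation(substanceName = "character", amplitude = "numeric",
                 axis = "character", mean = "numeric", sigma = "numeric"))

setValidity("GaussianField", function(object) {
  if (!object@axis %in% c("x", "y", "z")) return("axis must be x, y or z")
  if (object@sigma <= 0) return("sigma must be > 0")
  TRUE
})

#' @rdname GaussianField-class
#' @param substanceName substance label.
#' @param amplitude peak concentration.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param mean profile center.
#' @param sigma profile width (> 0).
#' @return A [GaussianField-class].
#' @examples
#' cue <- gaussianField("apical_cue", amplitude = 1, axis = "z",
#'                      mean = 0, sigma = 1)
#' fieldValue(cue, c(0, 0, 1))  # exp(-0.5)
#' @export
gaussianField <- function(substanceName, amplitude, axis = "z", mean = 0,
                          sigma = 1) {
  new("GaussianField", substanceName = substanceName,
      amplitude = as.numeric(amplitude), axis = axis,
      mean = as.numeric(mean), sigma = as.numeric(sigma))
}

setMethod("show", "GaussianField", function(object) {
  cat(sprintf("GaussianField '%s': A=%g along %s, mean=%g, sigma=%g\n",
              object@substanceName, object@amplitude, object@axis,
              object@mean, object@sigma))
  invisible(NULL)
})

#' Explicit diffusion grid
#'
#' Extracellular substance on a regular 3-D lattice, advanced with a
#' forward-time centered-space (FTCS) 7-point scheme with zero-flux (closed)
#' boundaries and optional first-order decay:
#' \eqn{c' = c + dt (D \nabla^2 c - \mu c)}. With \eqn{\mu = 0} and closed
#' boundaries the scheme conserves total mass to rounding error.
#'
#' @slot substanceName substance label.
#' @slot conc 3-D array of concentrations (all dims >= 3).
#' @slot spacing lattice spacing \eqn{\Delta x}.
#' @slot diffusionCoefficient D (length^2 / time).
#' @slot decayRate \eqn{\mu} (1 / time).
#' @slot origin lower corner of the lattice (voxel centers at
#'   origin + (i - 1/2) spacing).
#' @export
setClass("DiffusionGrid",
  representation(substanceName = "character", conc = "array",
                 spacing = "numeric", diffusionCoefficient = "numeric",
                 decayRate = "numeric", origin = "numeric"))

setValidity("DiffusionGrid", function(object) {
  if (length(dim(object@conc)) != 3L) return("conc must be a 3-D array")
  if (any(dim(object@conc) < 3L)) return("lattice dims must be >= 3 per axis")
  if (object@spacing <= 0) return("spacing must be > 0")
  if (object@diffusionCoefficient < 0) return("D must be >= 0")
  if (object@decayRate < 0) return("decay rate must be >= 0")
  TRUE
})

#' @rdname DiffusionGrid-class
#' @param substanceName substance label.
#' @param dims integer 3-vector of lattice sizes (>= 3 each).
#' @param spacing lattice spacing.
#' @param diffusionCoefficient diffusion coefficient D.
#' @param decayRate first-order decay rate.
#' @param origin lower corner of the lattice.
#' @param conc optional initial concentration array (defaults to zeros).
#' @return A [DiffusionGrid-class].
#' @export
diffusionGrid <- function(substanceName, dims = c(10, 10, 10), spacing = 1,
                          diffusionCoefficient = 1, decayRate = 0,
                          origin = c(0, 0, 0), conc = NULL) {
  if (is.null(conc)) conc <- array(0, dim = dims)
  new("DiffusionGrid", substanceName = substanceName, conc = conc,
      spacing = as.numeric(spacing),
      diffusionCoefficient = as.numeric(diffusionCoefficient),
      decayRate = as.numeric(decayRate), origin = as.numeric(origin))
}

setMethod("show", "DiffusionGrid", function(object) {
  cat(sprintf("DiffusionGrid '%s': %s voxels, dx=%g, D=%g, mu=%g, mass=%g\n",
              object@substanceName, paste(dim(object@conc), collapse = " x "),
              object@spacing, object@diffusionCoefficient, object@decayRate,
              totalMass(object)))
  invisible(NULL)
})

axisIndex <- function(axis) match(axis, c("x", "y", "z"))

#' @rdname fieldValue
setMethod("fieldValue", "GaussianField", function(field, points) {
  points <- matrix(points, ncol = 3)
  u <- points[, axisIndex(field@axis)] - field@mean
  field@amplitude * exp(-u^2 / (2 * field@sigma^2))
})

#' @rdname fieldGradient
setMethod("fieldGradient", "GaussianField", function(field, points) {
  points <- matrix(points, ncol = 3)
  g <- matrix(0, nrow = nrow(points), ncol = 3,
              dimnames = list(NULL, c("x", "y", "z")))
  j <- axisIndex(field@axis)
  u <- points[, j] - field@mean
  g[, j] <- field@amplitude * exp(-u^2 / (2 * field@sigma^2)) *
    (-u / field@sigma^2)
  g
})

# fractional voxel-center coordinates, clamped into the lattice (points
# outside the bounds take the boundary value; noted once per call)
gridFrac <- function(field, points) {
  dims <- dim(field@conc)
  frac <- matrix(0, nrow(points), 3)
  clamped <- FALSE
  for (j in 1:3) {
    f <- (points[, j] - field@origin[j]) / field@spacing - 0.5
    if (any(f < 0 | f > dims[j] - 1)) clamped <- TRUE
    frac[, j] <- pmin(pmax(f, 0), dims[j] - 1)
  }
  if (clamped)
    message(sprintf("field '%s': query outside bounds clamped to boundary",
                    field@substanceName))
  frac
}

trilinear <- function(conc, frac) {
  i0 <- pmin(floor(frac[, 1]) + 1L, dim(conc)[1] - 1L)
  j0 <- pmin(floor(frac[, 2]) + 1L, dim(conc)[2] - 1L)
  k0 <- pmin(floor(frac[, 3]) + 1L, dim(conc)[3] - 1L)
  tx <- frac[, 1] - (i0 - 1L); ty <- frac[, 2] - (j0 - 1L)
  tz <- frac[, 3] - (k0 - 1L)
  v <- 0
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di) tx else 1 - tx) * (if (dj) ty else 1 - ty) *
         (if (dk) tz else 1 - tz)
    v <- v + w * conc[cbind(i0 + di, j0 + dj, k0 + dk)]
  }
  v
}

#' @rdname fieldValue
setMethod("fieldValue", "DiffusionGrid", function(field, points) {
  points <- matrix(points, ncol = 3)
  frac <- gridFrac(field, points)
  trilinear(field@conc, frac)
})

#' @rdname fieldGradient
setMethod("fieldGradient", "DiffusionGrid", function(field, points) {
  points <- matrix(points, ncol = 3)
  g <- matrix(0, nrow(points), 3, dimnames = list(NULL, c("x", "y", "z")))
  h <- field@spacing
  # the +/- h probes legitimately cross the boundary for near-edge points,
  # where the clamped difference degrades to one-sided; no message for that
  for (j in 1:3) {
    pp <- points; pp[, j] <- pp[, j] + h
    pm <- points; pm[, j] <- pm[, j] - h
    g[, j] <- suppressMessages(
      fieldValue(field, pp) - fieldValue(field, pm)) / (2 * h)
  }
  g
})

shiftReflect <- function(a, axis, by) {
  d <- dim(a)
  idx <- seq_len(d[axis]) + by
  idx[idx < 1L] <- 1L
  idx[idx > d[axis]] <- d[axis]
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

#' Advance a diffusion grid by one explicit time step
#'
#' FTCS 7-point Laplacian with zero-flux boundaries. The scheme is stable for
#' \eqn{D\,dt/\Delta x^2 \le 1/6}; larger steps raise an error that states
#' the admissible dt.
#'
#' @param field a [DiffusionGrid-class].
#' @param dt time step.
#' @return The advanced grid.
#' @export
diffusionStep <- function(field, dt) {
  D <- field@diffusionCoefficient
  h <- field@spacing
  lim <- h^2 / (6 * max(D, .Machine$double.xmin))
  if (D > 0 && dt > lim)
    stop(sprintf("unstable diffusion step: D*dt/dx^2 = %.4g > 1/6 (dt must be <= %.4g)",
                 D * dt / h^2, lim))
  c0 <- field@conc
  lap <- (shiftReflect(c0, 1L, 1L) + shiftReflect(c0, 1L, -1L) +
          shiftReflect(c0, 2L, 1L) + shiftReflect(c0, 2L, -1L) +
          shiftReflect(c0, 3L, 1L) + shiftReflect(c0, 3L, -1L) - 6 * c0) / h^2
  field@conc <- c0 + dt * (D * lap - field@decayRate * c0)
  field
}

#' Deposit substance into the voxel containing a point
#'
#' Voxels are half-open, so a point on a voxel boundary targets exactly one
#' voxel; total mass increases by exactly `amount`.
#'
#' @param field a [DiffusionGrid-class].
#' @param point numeric 3-vector.
#' @param amount non-negative mass to add.
#' @return The updated grid.
#' @export
deposit <- function(field, point, amount) {
  if (amount < 0) stop("deposit amount must be >= 0")
  dims <- dim(field@conc)
  idx <- integer(3)
  for (j in 1:3) {
    i <- floor((point[j] - field@origin[j]) / field@spacing) + 1L
    idx[j] <- min(max(i, 1L), dims[j])
  }
  field@conc[idx[1], idx[2], idx[3]] <-
    field@conc[idx[1], idx[2], idx[3]] + amount / field@spacing^3
  field
}

#' @rdname totalMass
setMethod("totalMass", "DiffusionGrid", function(field)
  sum(field@conc) * field@spacing^3)

#' Export a diffusion grid snapshot as (x, y, z, value) rows
#'
#' @param field a [DiffusionGrid-class].
#' @param path optional CSV path; when NULL the data.frame is returned only.
#' @return data.frame with voxel-center coordinates and concentrations.
#' @export
gridSnapshot <- function(field, path = NULL) {
  dims <- dim(field@conc)
  ctr <- lapply(1:3, function(j)
    field@origin[j] + (seq_len(dims[j]) - 0.5) * field@spacing)
  df <- expand.grid(x = ctr[[1]], y = ctr[[2]], z = ctr[[3]])
  df$value <- as.vector(field@conc)
  if (!is.null(path)) exportCsv(df, path)
  df
}
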