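#' Evaluate the P-surface nodal field
#'
#' Computes \eqn{f = \cos(u/s) + \cos(v/s) + \cos(w/s)} where
#' \eqn{u = 2\pi x / L} maps cell coordinates (mm, centred on the cell) to the
#' canonical \eqn{[-\pi, \pi]} domain, and likewise for \eqn{v, w}. For the
#' default \code{L = 2*pi} the argument reduces to \eqn{x/s}. The surface is
#' the level set \eqn{f = k}; the internal (material) phase is \eqn{f > k}.
#'
#' @param x,y,z coordinates in mm (vectors, recycled to common length).
#' @param params a \code{\link{pcellParams}} object.
#' @return Numeric vector of field values in \eqn{[-3, 3]}.
#' @examples
#' p <- pcellParams()
#' evalField(0, 0, 0, p)        # 3
#' evalField(pi, pi, pi, p)     # -3
#' @export
evalField <- function(x, y, z, params) {
  stopifnot(inherits(params, "pcell_params"))
  if (!all(is.finite(x), is.finite(y), is.finite(z))) {
    stop("coordinates must be finite")
  }
  a <- (2 * pi / params$L) / params$s
  cos(a * x) + cos(a * y) + cos(a * z)
}

#' Sample the nodal field on a regular grid
#'
#' Node-centred sampling of the P-surface field on an N x N x N grid spanning
#' \eqn{[-L/2, L/2]^3} inclusive of the endpoints, so the spacing is
#' \eqn{L/(N-1)} per axis.
#'
#' @param params a \code{\link{pcellParams}} object.
#' @return A \code{pcell_field}: list with \code{values} (N^3 array),
#'   \code{axis} (node coordinates), \code{spacing}, \code{origin},
#'   \code{params}.
#' @export
sampleField <- function(params) {
  stopifnot(inherits(params, "pcell_params"))
  N <- params$N
  axis <- seq(-params$L / 2, params$L / 2, length.out = N)
  a <- (2 * pi / params$L) / params$s
  cs <- cos(a * axis)
  # separable: f(i,j,k) = cs[i] + cs[j] + cs[k]
  values <- outer(outer(cs, cs, `+`), cs, `+`)
  newField(values, axis, params,
           fun = function(x, y, z) evalField(x, y, z, params))
}

newField <- function(values, axis, params, fun = NULL) {
  structure(
    list(
      values = values,
      axis = axis,
      spacing = axis[2] - axis[1],
      origin = axis[1],
      params = params,
      fun = fun
    ),
    class = "pcell_field"
  )
}

#' @export
print.pcell_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "Sampled field: %d x %d x %d nodes, spacing %.4g mm, range [%.4g, %.4g]\n",
    d[1], d[2], d[3], x$spacing, min(x$values), max(x$values)))
  invisible(x)
}

# central-difference gradient of a 3D array along one axis (one-sided at the
# ends); the divisor is broadcast along `axis`, not recycled columnwise
axisGradient <- function(values, spacing, axis) {
  n <- dim(values)[axis]
  idx_p <- pmin(seq_len(n) + 1L, n)
  idx_m <- pmax(seq_len(n) - 1L, 1L)
  sel <- function(idx) {
    args <- rep(list(quote(expr = )), 3)
    args[[axis]] <- idx
    do.call(`[`, c(list(values), args, list(drop = FALSE)))
  }
  sweep(sel(idx_p) - sel(idx_m), axis, spacing * (idx_p - idx_m), "/")
}

#' Build a scalar field from an arbitrary function
#'
#' Samples \code{fun(x, y, z)} on the same node-centred grid layout used by
#' \code{\link{sampleField}}. Used for the analytic phantom fields that serve
#' as oracles for the geometric estimators.
#'
#' @param fun vectorised function of three coordinate vectors.
#' @param L cube side (mm).
#' @param N grid points per axis.
#' @param params optional \code{pcell_params} carried along (for phantoms a
#'   placeholder with matching \code{L}, \code{N} is built).
#' @return A \code{pcell_field}.
#' @export
fieldFromFunction <- function(fun, L, N, params = NULL) {
  if (is.null(params)) params <- pcellParams(k = 0, s = 1, L = L, N = N)
  axis <- seq(-L / 2, L / 2, length.out = N)
  g <- expand.grid(x = axis, y = axis, z = axis)
  values <- array(fun(g$x, g$y, g$z), dim = c(N, N, N))
  newField(values, axis, params, fun = fun)
}
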