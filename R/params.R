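#' P-cell parameters
#'
#' Bundle the analytical parameters of the Schwarz Primitive nodal surface
#' \eqn{\cos(u/s) + \cos(v/s) + \cos(w/s) = k} (with \eqn{(u,v,w)} the cell
#' coordinates rescaled to the canonical \eqn{[-\pi,\pi]^3} domain) together
#' with the cubic cell side \code{L} and the sampling resolution \code{N}.
#'
#' The level offset \code{k} selects which level surface of the implicit
#' field is extracted; the scale parameter \code{s} acts as a uniform scaling
#' of the surface about the cell barycentre before truncation by the cube.
#' The cell keeps a single connected surface with one open duct per cube face
#' only for \code{k} in (-1, 1) at \code{s = 1} and \code{s} in [0.75, 1.5]
#' at \code{k = 0}; values outside those ranges are permitted for exploration
#' but flagged in \code{$valid_k} / \code{$valid_s}.
#'
#' @param k level-set offset (dimensionless).
#' @param s scale parameter (dimensionless, > 0).
#' @param L cubic cell side length in mm (default \code{2*pi}).
#' @param N number of grid points per axis (>= 3, default 100).
#' @return An object of class \code{pcell_params}.
#' @examples
#' p <- pcellParams(k = 0, s = 1)
#' p$valid_k
#' @export
pcellParams <- function(k = 0, s = 1, L = 2 * pi, N = 100L) {
  stopifnot(is.numeric(k), length(k) == 1, is.finite(k))
  stopifnot(is.numeric(s), length(s) == 1, is.finite(s))
  stopifnot(is.numeric(L), length(L) == 1, is.finite(L))
  stopifnot(is.numeric(N), length(N) == 1, is.finite(N))
  N <- as.integer(N)
  if (N < 3L) stop("N must be at least 3")
  if (L <= 0) stop("L must be positive")
  if (s <= 0) stop("s must be positive")
  structure(
    list(
      k = k, s = s, L = L, N = N,
      valid_k = (k > -1 && k < 1),
      valid_s = (s >= 0.75 && s <= 1.5)
    ),
    class = "pcell_params"
  )
}

#' @export
print.pcell_params <- function(x, ...) {
  cat(sprintf("P-cell parameters: k = %g, s = %g, L = %g mm, N = %d\n",
              x$k, x$s, x$L, x$N))
  flag <- function(ok) if (ok) "in range" else "OUT OF RANGE"
  cat(sprintf("  k %s of ]-1, 1[ (at s = 1); s %s of [0.75, 1.5] (at k = 0)\n",
              flag(x$valid_k), flag(x$valid_s)))
  invisible(x)
}

#' Uniformly scale a P-cell
#'
#' Multiply the cell side \code{L} by \code{factor}, leaving the analytical
#' parameters untouched. All dimensionless cell properties (volume fraction,
#' \eqn{S/L^2}, \eqn{p_s/L}, ...) are invariant under this operation, while
#' dimensional ones (pore radius, surface area) scale with the factor.
#'
#' @param params a \code{\link{pcellParams}} object.
#' @param factor positive scale factor.
#' @return A rescaled \code{pcell_params} object.
#' @export
scaleParams <- function(params, factor) {
  stopifnot(inherits(params, "pcell_params"))
  if (!is.numeric(factor) || length(factor) != 1 || !is.finite(factor) ||
      factor <= 0) {
    stop("scale factor must be a positive finite number")
  }
  pcellParams(k = params$k, s = params$s, L = params$L * factor, N = params$N)
}
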