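# distance to the {f = k} surface on a cell-centred voxel grid: positive
# inside the internal phase {f > k}, zero outside. Within ~1.5 voxels of
# the interface the first-order estimate (f - k)/|grad f| is used (error
# O(d^2 * curvature), which keeps sub-voxel shells accurate); further in,
# the exact Euclidean distance transform corrected by the depth of the
# nearest outside voxel beyond the interface takes over.
voxelDistanceField <- function(values, spacing, k) {
  mask <- values > k
  ed <- .cpp_edt3d(!mask, dim(values))
  D <- sqrt(ed$dist2) * spacing
  gnorm <- pmax(sqrt(axisGradient(values, spacing, 1)^2 +
                     axisGradient(values, spacing, 2)^2 +
                     axisGradient(values, spacing, 3)^2), 1e-12)
  d_near <- (values - k) / gnorm
  rho <- (k - values[ed$feature]) / gnorm[ed$feature]
  rho <- pmax(pmin(rho, spacing), 0)
  d_edt <- pmax(D - array(rho, dim(values)), 0)
  d <- ifelse(d_near < 1.5 * spacing, pmin(d_near, d_edt), d_edt)
  d <- pmax(d, 0)
  d[!mask] <- 0
  list(d = d, mask = mask)
}

#' Solidify a P-surface into a shell of thickness t
#'
#' Builds the solid shell \eqn{\{x : f(x) > k \;\mathrm{and}\;
#' \mathrm{dist}(x, \{f = k\}) \le t\}} by an inward offset of the surface
#' realised on a Euclidean distance field over a cell-centred voxel grid
#' (offsetting the distance field avoids the self-intersections that
#' vertex-normal offsetting produces at saddle points). Besides the voxel
#' occupancy, the smooth outer surface, the inner offset surface (level
#' \eqn{t} of the distance field) and a watertight triangulated boundary of
#' the voxel solid (used for volume checks) are returned.
#'
#' @param field a \code{pcell_field} (its generating function is re-sampled
#'   at the voxel centres).
#' @param k isovalue (defaults to the field's parameter).
#' @param t shell thickness in mm (\code{0 <= t < p_s}).
#' @param M voxels per edge (default 100, i.e. voxel size L/100).
#' @return A \code{pcell_solid}: occupancy array (M^3), \code{voxel_size},
#'   \code{material_volume} (mm^3), \code{porosity}, thickness, the shell
#'   meshes (\code{outer_mesh}, \code{inner_mesh}, \code{boundary_mesh}) and
#'   the generating parameters.
#' @examples
#' fld <- sampleField(pcellParams(N = 40))
#' sol <- solidify(fld, t = 0.4, M = 40)
#' porosity(sol)
#' @export
solidify <- function(field, k = NULL, t, M = 100L) {
  stopifnot(inherits(field, "pcell_field"))
  if (is.null(k)) k <- field$params$k
  if (!is.numeric(t) || length(t) != 1 || !is.finite(t) || t < 0) {
    stop("thickness t must be a non-negative finite number")
  }
  L <- field$params$L
  M <- as.integer(M)
  hv <- L / M
  centers <- seq(-L / 2 + hv / 2, L / 2 - hv / 2, length.out = M)
  if (!is.null(field$fun)) {
    g <- expand.grid(x = centers, y = centers, z = centers)
    vals <- array(field$fun(g$x, g$y, g$z), dim = c(M, M, M))
  } else {
    pts <- as.matrix(expand.grid(x = centers, y = centers, z = centers))
    vals <- array(trilinear(field$values, field, pts), dim = c(M, M, M))
  }
  df <- voxelDistanceField(vals, hv, k)
  p_s_est <- max(df$d)
  # p_s_est under-resolves the true pore radius by up to about one voxel
  if (t > 0 && t >= p_s_est + hv) {
    stop(sprintf(
      "shell closes the pore: t = %g mm >= pore radius %.4g mm", t, p_s_est))
  }
  if (t > 0 && t < 2 * hv) {
    warning(sprintf(
      "thickness %g mm under-resolved at voxel size %g mm", t, hv))
  }
  occ <- df$mask & df$d <= t & t > 0
  material_volume <- sum(occ) * hv^3
  outer_mesh <- extractIsosurface(field, k, normals = "none")
  inner_mesh <- NULL
  if (t > 0 && any(df$d > t)) {
    dfield <- newField(df$d, centers,
                       pcellParams(field$params$k, field$params$s, L, M))
    inner_mesh <- extractIsosurface(dfield, t, normals = "none")
  }
  structure(
    list(occupancy = occ, voxel_size = hv, M = M, L = L, t = t, k = k,
         material_volume = material_volume,
         porosity = 1 - material_volume / L^3,
         pore_radius = p_s_est,
         outer_mesh = outer_mesh, inner_mesh = inner_mesh,
         boundary_mesh = voxelBoundaryMesh(occ, hv, -L / 2),
         params = field$params),
    class = "pcell_solid"
  )
}

#' @export
print.pcell_solid <- function(x, ...) {
  cat(sprintf(
    "Voxel solid: %d^3 grid, voxel %.4g mm, t = %g mm, porosity %.4f\n",
    x$M, x$voxel_size, x$t, x$porosity))
  invisible(x)
}

#' Porosity of a voxel solid
#'
#' \eqn{P = 1 - V_{P\mathrm{-cell}} / L^3}, the void fraction of the
#' solidified cell.
#'
#' @param solid a \code{pcell_solid}.
#' @param L cell side; defaults to the solid's own.
#' @return Porosity in [0, 1].
#' @export
porosity <- function(solid, L = NULL) {
  stopifnot(inherits(solid, "pcell_solid"))
  if (is.null(L)) L <- solid$L
  1 - solid$material_volume / L^3
}

# watertight triangle mesh of the voxel solid boundary: two triangles per
# exposed voxel face, outward winding, vertices on the (M+1)^3 node lattice
voxelBoundaryMesh <- function(occ, hv, origin) {
  M <- dim(occ)[1]
  Mn <- M + 1L
  nid <- function(i, j, k) i + Mn * (j - 1L) + Mn * Mn * (k - 1L)
  tris <- list()
  shift_void <- function(axis, dir) {
    # TRUE where neighbour (axis, dir) of an occupied voxel is void/outside
    idx <- rep(list(quote(expr = )), 3)
    out <- array(TRUE, dim(occ))
    if (dir > 0) {
      src <- rep(list(quote(expr = )), 3)
      src[[axis]] <- 2:M
      dst <- rep(list(quote(expr = )), 3)
      dst[[axis]] <- 1:(M - 1)
      out_part <- !do.call(`[`, c(list(occ), src, list(drop = FALSE)))
      out <- do.call(`[<-`, c(list(out), dst, list(out_part)))
      edge <- rep(list(quote(expr = )), 3)
      edge[[axis]] <- M
      out <- do.call(`[<-`, c(list(out), edge, list(TRUE)))
    } else {
      src <- rep(list(quote(expr = )), 3)
      src[[axis]] <- 1:(M - 1)
      dst <- rep(list(quote(expr = )), 3)
      dst[[axis]] <- 2:M
      out_part <- !do.call(`[`, c(list(occ), src, list(drop = FALSE)))
      out <- do.call(`[<-`, c(list(out), dst, list(out_part)))
      edge <- rep(list(quote(expr = )), 3)
      edge[[axis]] <- 1L
      out <- do.call(`[<-`, c(list(out), edge, list(TRUE)))
    }
    out
  }
  # node offsets of the 4 corners of each voxel face, ordered so the two
  # triangles wind outward (right-hand rule towards the void neighbour)
  face_corners <- list(
    `1+` = rbind(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1), c(1, 0, 1)),
    `1-` = rbind(c(0, 0, 0), c(0, 0, 1), c(0, 1, 1), c(0, 1, 0)),
    `2+` = rbind(c(0, 1, 0), c(0, 1, 1), c(1, 1, 1), c(1, 1, 0)),
    `2-` = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 1), c(0, 0, 1)),
    `3+` = rbind(c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)),
    `3-` = rbind(c(0, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, 0, 0))
  )
  all_faces <- list()
  for (axis in 1:3) {
    for (dir in c(1, -1)) {
      exposed <- occ & shift_void(axis, dir)
      if (!any(exposed)) next
      idx <- which(exposed, arr.ind = TRUE)
      key <- paste0(axis, if (dir > 0) "+" else "-")
      fc <- face_corners[[key]]
      corner_ids <- sapply(1:4, function(q) {
        nid(idx[, 1] + fc[q, 1], idx[, 2] + fc[q, 2], idx[, 3] + fc[q, 3])
      })
      if (is.null(dim(corner_ids))) corner_ids <- matrix(corner_ids, 1)
      all_faces[[length(all_faces) + 1L]] <-
        rbind(corner_ids[, c(1, 2, 3), drop = FALSE],
              corner_ids[, c(1, 3, 4), drop = FALSE])
    }
  }
  if (length(all_faces) == 0) {
    return(structure(list(vertices = matrix(numeric(0), 0, 3),
                          faces = matrix(integer(0), 0, 3), normals = NULL,
                          L = (dim(occ)[1]) * hv, iso = NA_real_,
                          params = NULL),
                     class = "pcell_mesh"))
  }
  f <- do.call(rbind, all_faces)
  used <- sort(unique(as.vector(f)))
  remap <- integer(max(used))
  remap[used] <- seq_along(used)
  # node lattice coordinates from linear ids
  u0 <- used - 1L
  i <- u0 %% Mn
  j <- (u0 %/% Mn) %% Mn
  kk <- u0 %/% (Mn * Mn)
  verts <- cbind(origin + i * hv, origin + j * hv, origin + kk * hv)
  structure(
    list(vertices = verts, faces = matrix(remap[f], ncol = 3), normals = NULL,
         L = M * hv, iso = NA_real_, params = NULL),
    class = "pcell_mesh"
  )
}

#' Shell thickness for a target porosity (thin-shell relation)
#'
#' Inverts the thin-shell porosity relation \eqn{P = 1 - (S/L^2)(t/L)}:
#' \eqn{t = (1 - P) L / (S/L^2)}. The relation is the first-order limit of
#' the exact voxel porosity for thin shells.
#'
#' @param P_target target porosity in (0, 1).
#' @param surface_ratio the cell's \eqn{S/L^2}.
#' @param L cell side (mm).
#' @param p_s optional pore radius (mm); when given, a thickness at or above
#'   it raises an infeasibility error reporting the reachable porosity range.
#' @param f_v optional volume fraction used to report the minimum reachable
#'   porosity (\eqn{1 - f_v}) in the infeasibility message.
#' @return Thickness t in mm.
#' @examples
#' thicknessForPorosity(0.9, 2.3451, 2 * pi)  # ~ 0.268 mm
#' @export
thicknessForPorosity <- function(P_target, surface_ratio, L, p_s = NULL,
                                 f_v = NULL) {
  if (!is.numeric(P_target) || P_target <= 0 || P_target >= 1) {
    stop("P_target must lie strictly between 0 and 1")
  }
  if (!is.numeric(surface_ratio) || surface_ratio <= 0) {
    stop("surface_ratio must be positive")
  }
  t <- (1 - P_target) * L / surface_ratio
  if (!is.null(p_s) && t >= p_s) {
    pmin_msg <- if (!is.null(f_v)) {
      sprintf("; minimum achievable porosity is about %.3f (= 1 - f_v)",
              1 - f_v)
    } else {
      sprintf("; porosities below about %.3f are unreachable",
              1 - surface_ratio * p_s / L)
    }
    stop(sprintf(
      "infeasible: required thickness %.4g mm >= pore radius %.4g mm%s",
      t, p_s, pmin_msg))
  }
  t
}

#' Design a solid P-cell from target requirements
#'
#' Implements the design workflow: (1) choose the analytical parameters
#' (k, s) by inverse interpolation of a property sweep table so the
#' dimensionless target (volume fraction) is met; (2) choose the cell side L
#' so a dimensional target (pore radius) is met; (3) choose the thickness t
#' from a target porosity through the thin-shell relation.
#'
#' @param f_v target volume fraction (dimensionless), optional.
#' @param p_s_target target pore radius in mm, optional (sets L).
#' @param P_target target porosity in (0, 1), optional (sets t).
#' @param L cell side in mm; may not be combined with \code{p_s_target}.
#' @param table precomputed sweep table from \code{\link{propertyTable}}
#'   covering the k-sweep at s = 1 and the s-sweep at k = 0; computed at
#'   resolution \code{N} when missing.
#' @param N grid resolution used when computing the sweep table.
#' @return A \code{solid_cell_spec}: list with \code{params}, \code{t},
#'   \code{P_predicted}, \code{candidates} and an achieved-vs-requested
#'   \code{report} data.frame.
#' @export
designCell <- function(f_v = NULL, p_s_target = NULL, P_target = NULL,
                       L = NULL, table = NULL, N = 50L) {
  if (is.null(f_v)) {
    stop("a dimensionless target (f_v) is required to pick (k, s)")
  }
  if (!is.null(p_s_target) && !is.null(L)) {
    stop("conflicting targets: pore radius p_s_target and cell side L both fix the cell size")
  }
  if (is.null(table)) {
    table <- propertyTable(k = seq(-0.9, 0.9, by = 0.1), s = 1, N = N)
    table <- rbind(table,
                   propertyTable(k = 0, s = seq(0.75, 1.5, by = 0.05), N = N))
  }
  tab <- table[is.na(table$error) | table$error == "", , drop = FALSE]
  candidates <- list()
  kfam <- tab[tab$s == 1, , drop = FALSE]
  kfam <- kfam[!duplicated(kfam$k), , drop = FALSE]
  kfam <- kfam[order(kfam$k), , drop = FALSE]
  if (nrow(kfam) >= 2 && f_v >= min(kfam$f_v) && f_v <= max(kfam$f_v)) {
    k_hat <- stats::approx(kfam$f_v, kfam$k, xout = f_v)$y
    candidates[[length(candidates) + 1L]] <- list(
      k = k_hat, s = 1,
      p_s_over_L = stats::approx(kfam$k, kfam$p_s_over_L, xout = k_hat)$y,
      surface_ratio = stats::approx(kfam$k, kfam$surface_ratio,
                                    xout = k_hat)$y)
  }
  sfam <- tab[tab$k == 0, , drop = FALSE]
  sfam <- sfam[!duplicated(sfam$s), , drop = FALSE]
  sfam <- sfam[order(sfam$s), , drop = FALSE]
  if (nrow(sfam) >= 2 && f_v >= min(sfam$f_v) && f_v <= max(sfam$f_v)) {
    s_hat <- stats::approx(sfam$f_v, sfam$s, xout = f_v)$y
    candidates[[length(candidates) + 1L]] <- list(
      k = 0, s = s_hat,
      p_s_over_L = stats::approx(sfam$s, sfam$p_s_over_L, xout = s_hat)$y,
      surface_ratio = stats::approx(sfam$s, sfam$surface_ratio,
                                    xout = s_hat)$y)
  }
  if (length(candidates) == 0) {
    stop(sprintf(
      "unreachable target: f_v = %.3g outside the achievable interval [%.3g, %.3g]",
      f_v, min(tab$f_v, na.rm = TRUE), max(tab$f_v, na.rm = TRUE)))
  }
  # prefer the candidate closest to the standard cell
  dist_std <- vapply(candidates,
                     function(cd) abs(cd$k) + abs(cd$s - 1), numeric(1))
  chosen <- candidates[[which.min(dist_std)]]
  if (!is.null(p_s_target)) {
    L_final <- p_s_target / chosen$p_s_over_L
  } else if (!is.null(L)) {
    L_final <- L
  } else {
    L_final <- 2 * pi
  }
  t <- NA_real_
  P_pred <- NA_real_
  if (!is.null(P_target)) {
    p_s_mm <- chosen$p_s_over_L * L_final
    t <- thicknessForPorosity(P_target, chosen$surface_ratio, L_final,
                              p_s = p_s_mm, f_v = f_v)
    P_pred <- 1 - chosen$surface_ratio * t / L_final
  }
  params <- pcellParams(k = chosen$k, s = chosen$s, L = L_final)
  report <- data.frame(
    quantity = c("f_v", "p_s", "porosity"),
    requested = c(f_v,
                  if (is.null(p_s_target)) NA_real_ else p_s_target,
                  if (is.null(P_target)) NA_real_ else P_target),
    achieved = c(f_v, chosen$p_s_over_L * L_final, P_pred)
  )
  structure(
    list(params = params, t = t, P_predicted = P_pred,
         surface_ratio = chosen$surface_ratio,
         p_s_over_L = chosen$p_s_over_L,
         candidates = candidates, report = report),
    class = "solid_cell_spec"
  )
}

#' @export
print.solid_cell_spec <- function(x, ...) {
  cat(sprintf("Solid cell spec: k = %.3g, s = %.3g, L = %.4g mm, t = %s mm\n",
              x$params$k, x$params$s, x$params$L,
              if (is.na(x$t)) "unset" else sprintf("%.4g", x$t)))
  print(x$report)
  invisible(x)
}
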