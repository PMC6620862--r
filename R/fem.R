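#' Material constants
#'
#' Linear-elastic isotropic material. Defaults are the Ti-6Al-4V constants
#' used for titanium bone scaffolds: E_s = 110 GPa, G_s = 40 GPa, nu = 0.3.
#' The solver uses (E_s, nu); G_s is the reference for normalising apparent
#' shear moduli.
#'
#' @param E_s elastic modulus in GPa.
#' @param G_s shear modulus in GPa (normalisation reference).
#' @param nu_s Poisson ratio, in [0, 0.5).
#' @return A \code{pcell_material}.
#' @export
pcellMaterial <- function(E_s = 110, G_s = 40, nu_s = 0.3) {
  stopifnot(E_s > 0, G_s > 0, nu_s >= 0, nu_s < 0.5)
  structure(list(E_s = E_s, G_s = G_s, nu_s = nu_s),
            class = "pcell_material")
}

#' A fully dense voxel cube
#'
#' Homogeneous occupancy, used for patch tests and as the dense limit of the
#' stiffness-porosity relations.
#'
#' @param L cube side (mm).
#' @param M voxels per edge.
#' @return A \code{pcell_solid}.
#' @export
fullSolid <- function(L, M) {
  occ <- array(TRUE, c(M, M, M))
  hv <- L / M
  structure(
    list(occupancy = occ, voxel_size = hv, M = as.integer(M), L = L,
         t = NA_real_, k = NA_real_,
         material_volume = L^3, porosity = 0, pore_radius = NA_real_,
         outer_mesh = NULL, inner_mesh = NULL,
         boundary_mesh = NULL, params = NULL),
    class = "pcell_solid"
  )
}

# keep only components of the voxel solid that connect the two constraint
# face layers along `axis`; returns filtered occupancy and the removed count
percolatingOccupancy <- function(occ, axis) {
  lab <- .cpp_voxel_components(occ, dim(occ))
  M <- dim(occ)[axis]
  sel_layer <- function(pos) {
    args <- rep(list(quote(expr = )), 3)
    args[[axis]] <- pos
    do.call(`[`, c(list(lab), args))
  }
  lo <- unique(as.vector(sel_layer(1L)))
  hi <- unique(as.vector(sel_layer(M)))
  keep_ids <- setdiff(intersect(lo, hi), 0L)
  if (length(keep_ids) == 0) {
    stop("structure does not connect the loading faces")
  }
  keep <- array(lab %in% keep_ids, dim(occ)) & occ
  n_all <- length(setdiff(unique(as.vector(lab)), 0L))
  list(occ = keep, n_removed = n_all - length(keep_ids),
       removed_volume = sum(occ) - sum(keep))
}

# assemble constraint masks and run the matrix-free solver
runFem <- function(occ, M, hv, material, fixed_idx_list, uval_list,
                   tol = 1e-8, maxit = 50000) {
  Mn <- M + 1L
  ndof <- 3L * Mn^3
  fixed <- logical(ndof)
  uval <- numeric(ndof)
  for (q in seq_along(fixed_idx_list)) {
    ii <- fixed_idx_list[[q]]
    fixed[ii] <- TRUE
    uval[ii] <- uval_list[[q]]
  }
  E_mpa <- material$E_s * 1000
  .cpp_fem_solve(occ, M, hv, E_mpa, material$nu_s, fixed, uval,
                 tol = tol, maxit = maxit)
}

# DOF ids (1-based) of component `comp` (1=x,2=y,3=z) at lattice nodes where
# index along `axis` equals `layer` (0-based node layer)
faceDofs <- function(M, axis, layer, comp) {
  Mn <- M + 1L
  idx <- 0:M
  grids <- list(idx, idx, idx)
  grids[[axis]] <- layer
  g <- expand.grid(i = grids[[1]], j = grids[[2]], k = grids[[3]])
  node <- g$i + Mn * (g$j + Mn * g$k)
  3L * node + comp # 1-based: comp in 1:3 -> dof = 3*node + comp
}

#' Apparent elastic modulus under uniaxial compression
#'
#' Prescribes a uniform displacement corresponding to the applied strain
#' \code{eps_A} (default 0.1\%) on the top (+y) node layer in the y
#' direction while the bottom layer is fully constrained (the default
#' \code{support = "clamped"}) or constrained only normally with symmetry
#' planes (\code{support = "rolling"}, which reproduces the uniform-strain
#' patch solution exactly on a homogeneous cube). Floating material
#' components that do not connect the two faces are removed first.
#'
#' The apparent modulus is \eqn{E = (F_R / A) / \epsilon_A} with \eqn{F_R}
#' the total reaction force on the loaded face and \eqn{A = L^2}.
#'
#' @param solid a \code{pcell_solid}.
#' @param material a \code{\link{pcellMaterial}}.
#' @param eps_A applied compressive strain (dimensionless).
#' @param support \code{"clamped"} or \code{"rolling"}.
#' @param tol relative residual for the conjugate-gradient solve.
#' @param maxit iteration cap.
#' @return A \code{pcell_elasticity}: displacements, nodal forces, reaction
#'   \code{F_R} (N), \code{E_app} and \code{E_over_Es}, solver diagnostics.
#' @export
femCompression <- function(solid, material = pcellMaterial(),
                           eps_A = 0.001, support = c("clamped", "rolling"),
                           tol = 1e-8, maxit = 50000) {
  stopifnot(inherits(solid, "pcell_solid"))
  support <- match.arg(support)
  M <- solid$M
  hv <- solid$voxel_size
  L <- solid$L
  perc <- percolatingOccupancy(solid$occupancy, axis = 2L)
  if (perc$n_removed > 0) {
    message(sprintf("removed %d floating component(s), %.4g mm^3",
                    perc$n_removed, perc$removed_volume * hv^3))
  }
  u_top <- -eps_A * L
  if (support == "clamped") {
    fixed <- list(faceDofs(M, 2, 0L, 1), faceDofs(M, 2, 0L, 2),
                  faceDofs(M, 2, 0L, 3), faceDofs(M, 2, M, 2))
    uval <- list(0, 0, 0, u_top)
  } else {
    fixed <- list(faceDofs(M, 2, 0L, 2), faceDofs(M, 2, M, 2),
                  faceDofs(M, 1, 0L, 1), faceDofs(M, 3, 0L, 3))
    uval <- list(0, u_top, 0, 0)
  }
  sol <- runFem(perc$occ, M, hv, material, fixed, uval, tol, maxit)
  top <- faceDofs(M, 2, M, 2)
  F_R <- -sum(sol$f[top]) # reaction opposing the imposed compression
  A <- L^2
  E_app_gpa <- (F_R / A) / eps_A / 1000
  structure(
    list(mode = "compression", u = sol$u, f = sol$f,
         F_R = F_R, A = A, eps_A = eps_A,
         E_app = E_app_gpa, E_over_Es = E_app_gpa / material$E_s,
         iterations = sol$iterations, relres = sol$relres,
         n_elements = sol$n_elements,
         n_removed_components = perc$n_removed,
         occupancy = perc$occ, M = M, voxel_size = hv, L = L,
         material = material, support = support),
    class = "pcell_elasticity"
  )
}

#' Apparent shear modulus
#'
#' Prescribes a uniform y displacement on the +x node layer (equivalent
#' shear strain \code{eps_A}), fully constrains the -x layer, and constrains
#' the +y and -y layers in the x direction. The apparent shear modulus is
#' \eqn{G = (F_R / A) / \epsilon_A} from the y reaction on the driven face;
#' with these clamped conditions it is an apparent (not pure) shear modulus.
#'
#' @inheritParams femCompression
#' @return A \code{pcell_elasticity} with \code{G_app} and
#'   \code{G_over_Gs}.
#' @export
femShear <- function(solid, material = pcellMaterial(), eps_A = 0.001,
                     tol = 1e-8, maxit = 50000) {
  stopifnot(inherits(solid, "pcell_solid"))
  M <- solid$M
  hv <- solid$voxel_size
  L <- solid$L
  perc <- percolatingOccupancy(solid$occupancy, axis = 1L)
  if (perc$n_removed > 0) {
    message(sprintf("removed %d floating component(s), %.4g mm^3",
                    perc$n_removed, perc$removed_volume * hv^3))
  }
  u_drive <- eps_A * L
  fixed <- list(
    faceDofs(M, 1, 0L, 1), faceDofs(M, 1, 0L, 2), faceDofs(M, 1, 0L, 3),
    faceDofs(M, 1, M, 2),
    faceDofs(M, 2, 0L, 1), faceDofs(M, 2, M, 1)
  )
  uval <- list(0, 0, 0, u_drive, 0, 0)
  sol <- runFem(perc$occ, M, hv, material, fixed, uval, tol, maxit)
  drive <- faceDofs(M, 1, M, 2)
  F_R <- sum(sol$f[drive])
  A <- L^2
  G_app_gpa <- (F_R / A) / eps_A / 1000
  structure(
    list(mode = "shear", u = sol$u, f = sol$f,
         F_R = F_R, A = A, eps_A = eps_A,
         G_app = G_app_gpa, G_over_Gs = G_app_gpa / material$G_s,
         iterations = sol$iterations, relres = sol$relres,
         n_elements = sol$n_elements,
         n_removed_components = perc$n_removed,
         occupancy = perc$occ, M = M, voxel_size = hv, L = L,
         material = material),
    class = "pcell_elasticity"
  )
}

#' @export
print.pcell_elasticity <- function(x, ...) {
  if (x$mode == "compression") {
    cat(sprintf(
      "Compression: E = %.4g GPa (E/E_s = %.4f), F_R = %.4g N, %d CG iters\n",
      x$E_app, x$E_over_Es, x$F_R, x$iterations))
  } else {
    cat(sprintf(
      "Shear: G = %.4g GPa (G/G_s = %.4f), F_R = %.4g N, %d CG iters\n",
      x$G_app, x$G_over_Gs, x$F_R, x$iterations))
  }
  invisible(x)
}

#' Per-element von Mises stress field
#'
#' Element-centroid stresses of a converged solution, in MPa.
#'
#' @param solution a \code{pcell_elasticity}.
#' @return data.frame with element linear index, the six Voigt stress
#'   components (xx, yy, zz, yz, xz, xy) and \code{von_mises}, all MPa.
#' @export
vonMisesField <- function(solution) {
  stopifnot(inherits(solution, "pcell_elasticity"))
  st <- .cpp_fem_stress(solution$occupancy, solution$M, solution$voxel_size,
                        solution$material$E_s * 1000,
                        solution$material$nu_s, solution$u)
  out <- as.data.frame(st$stress)
  names(out) <- c("s_xx", "s_yy", "s_zz", "s_yz", "s_xz", "s_xy")
  out$von_mises <- st$von_mises
  out$element <- st$element
  out
}

#' Stiffness-porosity table over a family of solid cells
#'
#' Solidifies and solves each (k, s, t) specification and tabulates porosity
#' against normalised compressive and shear moduli. Per-row failures are
#' recorded and the sweep continues.
#'
#' @param specs data.frame with columns \code{k}, \code{s}, \code{t} and
#'   optionally \code{family} (a label such as "k" or "s").
#' @param material a \code{\link{pcellMaterial}}.
#' @param L cell side (mm), default 5 as for the production stiffness runs.
#' @param M voxels per edge.
#' @param N field sampling resolution for solidification.
#' @param modes which loadings to run.
#' @param tol CG relative residual.
#' @return data.frame (k, s, t, family, P, E_over_Es, G_over_Gs, F_R_compression, error).
#' @export
stiffnessPorosityCurve <- function(specs, material = pcellMaterial(),
                                   L = 5, M = 50L, N = 60L,
                                   modes = c("compression", "shear"),
                                   tol = 1e-8) {
  stopifnot(is.data.frame(specs), all(c("k", "s", "t") %in% names(specs)))
  if (is.null(specs$family)) specs$family <- NA_character_
  rows <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    rows[[i]] <- tryCatch({
      fld <- sampleField(pcellParams(specs$k[i], specs$s[i], L = L, N = N))
      sol <- solidify(fld, t = specs$t[i], M = M)
      P <- porosity(sol)
      e_over <- NA_real_
      g_over <- NA_real_
      fr <- NA_real_
      if ("compression" %in% modes) {
        ce <- femCompression(sol, material, tol = tol)
        e_over <- ce$E_over_Es
        fr <- ce$F_R
      }
      if ("shear" %in% modes) {
        sh <- femShear(sol, material, tol = tol)
        g_over <- sh$G_over_Gs
      }
      data.frame(k = specs$k[i], s = specs$s[i], t = specs$t[i],
                 family = specs$family[i], P = P,
                 E_over_Es = e_over, G_over_Gs = g_over,
                 F_R_compression = fr, error = NA_character_)
    }, error = function(e) {
      data.frame(k = specs$k[i], s = specs$s[i], t = specs$t[i],
                 family = specs$family[i], P = NA_real_,
                 E_over_Es = NA_real_, G_over_Gs = NA_real_,
                 F_R_compression = NA_real_,
                 error = conditionMessage(e))
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
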