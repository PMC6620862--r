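#' Extract the tessellated P-surface from a sampled field
#'
#' Triangulates the level set \eqn{\{f = k\}} of a sampled scalar field,
#' clipped to the cubic cell, by marching tetrahedra on the Kuhn 6-tetrahedron
#' decomposition of each grid cell with linear interpolation along edges.
#' Interpolated vertices are shared exactly between adjacent triangles, so the
#' mesh is watertight up to the cube boundary. Triangle winding is consistent:
#' geometric normals point away from the internal phase \eqn{\{f > k\}}.
#'
#' If the isovalue coincides with a sampled node value to within 1e-12 it is
#' perturbed by 1e-9 (deterministically) to avoid degenerate intersections.
#' Zero-area triangles are removed and unreferenced vertices dropped.
#'
#' @param field a \code{pcell_field} from \code{\link{sampleField}} or
#'   \code{\link{fieldFromFunction}}.
#' @param k isovalue; defaults to the \code{k} stored in the field parameters.
#' @param normals how to compute vertex normals: \code{"gradient"}
#'   (interpolated finite-difference field gradient, oriented along
#'   \eqn{-\nabla f}, i.e. away from the internal phase) or \code{"none"}.
#' @return A \code{pcell_mesh}: list with \code{vertices} (V x 3 mm),
#'   \code{faces} (F x 3, 1-based), \code{normals} (V x 3 unit vectors or
#'   NULL), \code{L}, \code{iso}, and the generating parameters.
#' @examples
#' fld <- sampleField(pcellParams(N = 40))
#' m <- extractIsosurface(fld)
#' nrow(m$faces)
#' @export
extractIsosurface <- function(field, k = NULL,
                              normals = c("gradient", "none")) {
  stopifnot(inherits(field, "pcell_field"))
  normals <- match.arg(normals)
  if (is.null(k)) k <- field$params$k
  rng <- range(field$values)
  if (k < rng[1] || k > rng[2]) {
    stop(sprintf("isovalue %g outside the sampled field range [%g, %g]",
                 k, rng[1], rng[2]))
  }
  if (k == rng[1] || k == rng[2]) {
    warning("isovalue touches the field range; empty level set")
    return(emptyMesh(field, k))
  }
  # deterministic perturbation of degenerate isovalues
  scale <- max(abs(rng))
  if (min(abs(field$values - k)) < 1e-12 * max(1, scale)) {
    k_use <- k + 1e-9 * max(1, scale)
  } else {
    k_use <- k
  }
  raw <- .cpp_march_tets(as.numeric(field$values), dim(field$values),
                         rep(field$origin, 3), field$spacing, k_use)
  if (nrow(raw$vertices) == 0) {
    warning("empty level set")
    return(emptyMesh(field, k))
  }
  m <- structure(
    list(vertices = raw$vertices, faces = raw$faces, normals = NULL,
         L = field$params$L, iso = k, params = field$params),
    class = "pcell_mesh"
  )
  m <- cleanupMesh(m)
  if (normals == "gradient") m$normals <- gradientNormals(field, m$vertices)
  m
}

emptyMesh <- function(field, k) {
  structure(
    list(vertices = matrix(numeric(0), 0, 3),
         faces = matrix(integer(0), 0, 3), normals = NULL,
         L = field$params$L, iso = k, params = field$params),
    class = "pcell_mesh"
  )
}

#' @export
print.pcell_mesh <- function(x, ...) {
  cat(sprintf("Triangle mesh: %d vertices, %d faces (L = %g mm, iso = %g)\n",
              nrow(x$vertices), nrow(x$faces), x$L, x$iso))
  invisible(x)
}

# merge geometrically coincident vertices (tolerance 1e-9 L), then drop the
# faces that collapse to an edge or point; the sliver's neighbours become
# adjacent, so the surface topology is preserved
cleanupMesh <- function(mesh, tol = NULL) {
  if (nrow(mesh$faces) == 0) return(mesh)
  if (is.null(tol)) tol <- 1e-7 * mesh$L
  v <- mesh$vertices
  f <- mesh$faces
  # two rounding grids offset by half a tolerance so coincident vertices
  # straddling one grid boundary are caught by the other
  for (off in c(0, 0.5)) {
    key <- paste(round(v[, 1] / tol + off), round(v[, 2] / tol + off),
                 round(v[, 3] / tol + off))
    first <- !duplicated(key)
    vmap <- match(key, key[first])
    f <- matrix(vmap[f], ncol = 3)
    v <- v[first, , drop = FALSE]
    if (!is.null(mesh$normals)) {
      mesh$normals <- mesh$normals[first, , drop = FALSE]
    }
  }
  degen <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
  f <- f[!degen, , drop = FALSE]
  # coincident face pairs (zero-volume flaps left by collapsed slivers)
  # cancel in pairs; an odd multiplicity keeps one representative
  fkey <- paste(pmin(f[, 1], pmin(f[, 2], f[, 3])),
                f[, 1] + f[, 2] + f[, 3],
                pmax(f[, 1], pmax(f[, 2], f[, 3])))
  mult <- table(fkey)[fkey]
  keep_face <- mult == 1 | (mult %% 2 == 1 & !duplicated(fkey))
  f <- f[keep_face, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(v))
  remap[used] <- seq_along(used)
  mesh$vertices <- v[used, , drop = FALSE]
  mesh$faces <- matrix(remap[f], ncol = 3)
  if (!is.null(mesh$normals)) {
    mesh$normals <- mesh$normals[used, , drop = FALSE]
  }
  mesh
}

triangleAreas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  u <- vertices[faces[, 2], , drop = FALSE] - a
  w <- vertices[faces[, 3], , drop = FALSE] - a
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total mesh area
#'
#' @param mesh a \code{pcell_mesh}.
#' @return Sum of triangle areas in mm^2.
#' @export
meshArea <- function(mesh) {
  stopifnot(inherits(mesh, "pcell_mesh"))
  if (nrow(mesh$faces) == 0) return(0)
  sum(triangleAreas(mesh$vertices, mesh$faces))
}

# per-vertex normals from the trilinearly interpolated central-difference
# gradient of the field, oriented along -grad f (away from {f > k})
gradientNormals <- function(field, vertices) {
  v <- field$values
  N <- dim(v)
  h <- field$spacing
  gx <- axisGradient(v, h, 1)
  gy <- axisGradient(v, h, 2)
  gz <- axisGradient(v, h, 3)
  g <- cbind(trilinear(gx, field, vertices),
             trilinear(gy, field, vertices),
             trilinear(gz, field, vertices))
  nrm <- sqrt(rowSums(g^2))
  nrm[nrm == 0] <- 1
  -g / nrm
}

# vectorised trilinear interpolation of a node array at arbitrary points
trilinear <- function(arr, field, pts) {
  N <- dim(arr)
  h <- field$spacing
  t <- (pts - field$origin) / h
  i0 <- pmin(pmax(floor(t), 0), N[col(t)] - 2)
  w <- t - i0
  i0 <- i0 + 1L # 1-based lower corner
  ix <- i0[, 1]; iy <- i0[, 2]; iz <- i0[, 3]
  wx <- w[, 1]; wy <- w[, 2]; wz <- w[, 3]
  at <- function(dx, dy, dz) {
    arr[cbind(ix + dx, iy + dy, iz + dz)]
  }
  (1 - wx) * ((1 - wy) * ((1 - wz) * at(0, 0, 0) + wz * at(0, 0, 1)) +
              wy * ((1 - wz) * at(0, 1, 0) + wz * at(0, 1, 1))) +
    wx * ((1 - wy) * ((1 - wz) * at(1, 0, 0) + wz * at(1, 0, 1)) +
          wy * ((1 - wz) * at(1, 1, 0) + wz * at(1, 1, 1)))
}

# boundary edge table: edges appearing in exactly one face
meshEdges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(1, 3)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  list(edges = e, key = key, count = table(key))
}

#' Boundary loops of a clipped surface mesh
#'
#' Identifies boundary edges (edges used by exactly one triangle) and chains
#' them into closed loops. For a P-cell mesh clipped to the cube each loop is
#' the rim of one lateral opening and lies on a cube face.
#'
#' @param mesh a \code{pcell_mesh}.
#' @return List with \code{loops} (list of vertex-index cycles),
#'   \code{n_nonmanifold} (edges shared by > 2 faces), and \code{regular}
#'   (TRUE when every boundary vertex has exactly two boundary edges).
#' @export
boundaryLoops <- function(mesh) {
  stopifnot(inherits(mesh, "pcell_mesh"))
  if (nrow(mesh$faces) == 0) {
    return(list(loops = list(), n_nonmanifold = 0L, regular = TRUE))
  }
  ed <- meshEdges(mesh$faces)
  cnt <- ed$count
  n_nonmanifold <- sum(cnt > 2)
  bkeys <- names(cnt)[cnt == 1]
  if (length(bkeys) == 0) {
    return(list(loops = list(),
                n_nonmanifold = as.integer(n_nonmanifold), regular = TRUE))
  }
  bm <- do.call(rbind, strsplit(bkeys, " ", fixed = TRUE))
  be <- cbind(as.integer(bm[, 1]), as.integer(bm[, 2]))
  # adjacency over boundary vertices
  adj <- split(c(be[, 2], be[, 1]), c(be[, 1], be[, 2]))
  deg <- lengths(adj)
  regular <- all(deg == 2)
  visited_edge <- new.env(hash = TRUE)
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  loops <- list()
  for (r in seq_len(nrow(be))) {
    a0 <- be[r, 1]; b0 <- be[r, 2]
    if (!is.null(visited_edge[[ekey(a0, b0)]])) next
    loop <- c(a0)
    prev <- a0
    cur <- b0
    visited_edge[[ekey(a0, b0)]] <- TRUE
    ok <- TRUE
    for (step in seq_len(2L * nrow(be) + 2L)) {
      if (cur == a0) break
      loop <- c(loop, cur)
      nb <- adj[[as.character(cur)]]
      nxt <- NULL
      for (cand in nb) {
        if (cand != prev && is.null(visited_edge[[ekey(cur, cand)]])) {
          nxt <- cand
          break
        }
      }
      if (is.null(nxt)) {
        # fall back: allow returning to start
        if (a0 %in% nb && is.null(visited_edge[[ekey(cur, a0)]])) {
          nxt <- a0
        } else {
          ok <- FALSE
          break
        }
      }
      visited_edge[[ekey(cur, nxt)]] <- TRUE
      prev <- cur
      cur <- nxt
    }
    if (ok) loops[[length(loops) + 1L]] <- loop
  }
  list(loops = loops, n_nonmanifold = as.integer(n_nonmanifold),
       regular = regular)
}

#' Check P-cell integrity
#'
#' A P-cell tessellation is considered intact when its surface forms a single
#' connected component whose boundary consists of exactly six closed loops,
#' one per cube face — i.e. the cell keeps one open duct through each lateral
#' face and the surface is not fragmented. Loops that wrap around a cube edge
#' (vertices on more than one face plane) or faces without a loop of their
#' own fail the check, as do non-manifold edges.
#'
#' @param mesh a \code{pcell_mesh} clipped to the cube \eqn{[-L/2, L/2]^3}.
#' @param tol tolerance for assigning boundary vertices to cube face planes,
#'   default \code{1e-6 * L}.
#' @return An \code{integrity_report}: list with \code{n_components},
#'   \code{n_boundary_loops}, \code{loops_per_face} (named length-6 vector),
#'   \code{n_nonmanifold} and \code{passes}.
#' @examples
#' fld <- sampleField(pcellParams(N = 40))
#' checkIntegrity(extractIsosurface(fld))$passes
#' @export
checkIntegrity <- function(mesh, tol = NULL) {
  stopifnot(inherits(mesh, "pcell_mesh"))
  if (nrow(mesh$faces) == 0) stop("cannot check integrity of an empty mesh")
  if (is.null(tol)) tol <- 1e-6 * mesh$L
  comp <- .cpp_mesh_components(mesh$faces, nrow(mesh$vertices))
  n_components <- length(unique(comp))
  bl <- boundaryLoops(mesh)
  half <- mesh$L / 2
  face_names <- c("x-", "x+", "y-", "y+", "z-", "z+")
  loops_per_face <- stats::setNames(integer(6), face_names)
  spanning <- 0L
  for (loop in bl$loops) {
    pv <- mesh$vertices[loop, , drop = FALSE]
    assigned <- FALSE
    for (ax in 1:3) {
      for (side in c(-1, 1)) {
        if (all(abs(pv[, ax] - side * half) < tol)) {
          fi <- (ax - 1L) * 2L + if (side < 0) 1L else 2L
          loops_per_face[fi] <- loops_per_face[fi] + 1L
          assigned <- TRUE
        }
      }
    }
    if (!assigned) spanning <- spanning + 1L
  }
  passes <- n_components == 1L &&
    length(bl$loops) == 6L &&
    spanning == 0L &&
    all(loops_per_face == 1L) &&
    bl$n_nonmanifold == 0L &&
    bl$regular
  structure(
    list(n_components = n_components,
         n_boundary_loops = length(bl$loops),
         loops_per_face = loops_per_face,
         n_spanning_loops = spanning,
         n_nonmanifold = bl$n_nonmanifold,
         passes = passes),
    class = "integrity_report"
  )
}

#' @export
print.integrity_report <- function(x, ...) {
  cat(sprintf("Integrity: %s (%d component(s), %d boundary loop(s))\n",
              if (x$passes) "PASS" else "FAIL",
              x$n_components, x$n_boundary_loops))
  cat("  loops per face:",
      paste(names(x$loops_per_face), x$loops_per_face, sep = "="), "\n")
  invisible(x)
}
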