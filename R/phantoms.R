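#' Analytic phantom surfaces and fields with closed-form oracles
#'
#' Builds simple geometries whose area, volume and principal curvatures are
#' known in closed form. They serve as oracles for the geometric estimators:
#' the curvature phantoms (\code{sphere}, \code{cylinder}, \code{plane},
#' \code{saddle}) are returned as triangle meshes with analytic vertex
#' normals, while \code{sphere-void} is returned as a sampled implicit field
#' whose internal phase is a centred spherical pore (its inscribed-sphere
#' radius is exactly the sphere radius).
#'
#' Normal convention for the mesh phantoms: normals point away from the
#' material, i.e. for \code{sphere} and \code{cylinder} towards the axis /
#' centre (the surfaces are read as pore walls). With the package sign
#' convention this gives principal curvatures \eqn{+1/r} for the sphere and
#' \eqn{(+1/r, 0)} for the cylinder; \code{flip_normals = TRUE} negates
#' both.
#'
#' @param kind one of \code{"sphere"}, \code{"cylinder"}, \code{"plane"},
#'   \code{"saddle"}, \code{"sphere-void"}.
#' @param r radius (mm) for sphere/cylinder/sphere-void.
#' @param L cube or patch side (mm).
#' @param height cylinder height (mm).
#' @param n tessellation density (subdivision level for the sphere, grid
#'   points per axis otherwise).
#' @param flip_normals flip the mesh normals (material on the other side).
#' @return List with \code{kind}, \code{mesh} (or NULL), \code{field} (or
#'   NULL) and \code{oracle} (list with \code{area}, \code{volume},
#'   \code{k1}, \code{k2} where defined).
#' @examples
#' ph <- makePhantom("sphere", r = 1, n = 3)
#' abs(meshArea(ph$mesh) - ph$oracle$area) / ph$oracle$area
#' @export
makePhantom <- function(kind = c("sphere", "cylinder", "plane", "saddle",
                                 "sphere-void"),
                        r = 1, L = 4, height = 2, n = 4,
                        flip_normals = FALSE) {
  kind <- match.arg(kind)
  if (r <= 0 || L <= 0 || height <= 0) stop("phantom sizes must be positive")
  out <- switch(kind,
    "sphere" = {
      m <- icosphereMesh(r, level = n)
      # normals towards the centre: pore-wall convention
      m$normals <- -m$vertices / sqrt(rowSums(m$vertices^2))
      list(mesh = m, field = NULL,
           oracle = list(area = 4 * pi * r^2, volume = 4 / 3 * pi * r^3,
                         k1 = 1 / r, k2 = 1 / r))
    },
    "cylinder" = {
      m <- cylinderMesh(r, height, n = max(n * 16, 32))
      m$normals <- {
        nr <- -cbind(m$vertices[, 1], m$vertices[, 2], 0)
        nr / sqrt(rowSums(nr^2))
      }
      list(mesh = m, field = NULL,
           oracle = list(area = 2 * pi * r * height,
                         volume = pi * r^2 * height,
                         k1 = 1 / r, k2 = 0))
    },
    "plane" = {
      m <- gridSurfaceMesh(function(x, y) 0 * x, L, n = max(n * 8, 16))
      m$normals <- matrix(rep(c(0, 0, 1), each = nrow(m$vertices)), ncol = 3)
      list(mesh = m, field = NULL,
           oracle = list(area = L^2, volume = NA_real_, k1 = 0, k2 = 0))
    },
    "saddle" = {
      m <- gridSurfaceMesh(function(x, y) (x^2 - y^2) / 2, L,
                           n = max(n * 8, 16))
      g <- m$vertices
      nr <- cbind(-g[, 1], g[, 2], 1)
      m$normals <- nr / sqrt(rowSums(nr^2))
      # principal curvatures at the origin only
      list(mesh = m, field = NULL,
           oracle = list(area = NA_real_, volume = NA_real_, k1 = 1, k2 = -1))
    },
    "sphere-void" = {
      if (2 * r >= L) stop("sphere-void must fit inside the cube")
      fld <- fieldFromFunction(
        function(x, y, z) r - sqrt(x^2 + y^2 + z^2),
        L = L, N = max(n * 16, 48))
      list(mesh = NULL, field = fld,
           oracle = list(area = 4 * pi * r^2, volume = 4 / 3 * pi * r^3,
                         k1 = 1 / r, k2 = 1 / r))
    })
  if (flip_normals && !is.null(out$mesh) && !is.null(out$mesh$normals)) {
    out$mesh$normals <- -out$mesh$normals
  }
  c(list(kind = kind), out)
}

# icosahedron subdivided `level` times, vertices projected onto the sphere
icosphereMesh <- function(r, level = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lv in seq_len(level)) {
    edge_mid <- new.env(hash = TRUE)
    nv <- nrow(v)
    newf <- matrix(0L, nrow(f) * 4, 3)
    vlist <- list(v)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- edge_mid[[key]]
      if (!is.null(id)) return(id)
      m <- (vlist[[1]][a, ] + vlist[[1]][b, ]) / 2
      m <- m / sqrt(sum(m^2))
      vlist[[1]] <<- rbind(vlist[[1]], m)
      id <- nrow(vlist[[1]])
      edge_mid[[key]] <- id
      id
    }
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[4 * i - 3, ] <- c(a, ab, ca)
      newf[4 * i - 2, ] <- c(b, bc, ab)
      newf[4 * i - 1, ] <- c(cc, ca, bc)
      newf[4 * i, ] <- c(ab, bc, ca)
    }
    v <- vlist[[1]]
    f <- newf
  }
  structure(list(vertices = v * r, faces = f, normals = NULL,
                 L = 2 * r, iso = NA_real_, params = NULL),
            class = "pcell_mesh")
}

# open tube of radius r, height h, axis z, nc around, nh along
cylinderMesh <- function(r, h, n = 64) {
  nc <- n
  nh <- max(8L, round(n * h / (2 * pi * r)))
  theta <- seq(0, 2 * pi, length.out = nc + 1)[-(nc + 1)]
  zs <- seq(-h / 2, h / 2, length.out = nh)
  vid <- function(i, j) (j - 1L) * nc + i # i around, j along
  verts <- cbind(r * cos(rep(theta, nh)), r * sin(rep(theta, nh)),
                 rep(zs, each = nc))
  faces <- matrix(0L, 2 * nc * (nh - 1), 3)
  row <- 0L
  for (j in seq_len(nh - 1)) {
    for (i in seq_len(nc)) {
      i2 <- if (i == nc) 1L else i + 1L
      faces[row + 1L, ] <- c(vid(i, j), vid(i2, j), vid(i2, j + 1))
      faces[row + 2L, ] <- c(vid(i, j), vid(i2, j + 1), vid(i, j + 1))
      row <- row + 2L
    }
  }
  structure(list(vertices = verts, faces = faces, normals = NULL,
                 L = h, iso = NA_real_, params = NULL),
            class = "pcell_mesh")
}

# graph surface z = fun(x, y) over [-L/2, L/2]^2 on an n x n grid
gridSurfaceMesh <- function(fun, L, n = 32) {
  ax <- seq(-L / 2, L / 2, length.out = n)
  g <- expand.grid(x = ax, y = ax)
  verts <- cbind(g$x, g$y, fun(g$x, g$y))
  vid <- function(i, j) (j - 1L) * n + i
  faces <- matrix(0L, 2 * (n - 1)^2, 3)
  row <- 0L
  for (j in seq_len(n - 1)) {
    for (i in seq_len(n - 1)) {
      faces[row + 1L, ] <- c(vid(i, j), vid(i + 1, j), vid(i + 1, j + 1))
      faces[row + 2L, ] <- c(vid(i, j), vid(i + 1, j + 1), vid(i, j + 1))
      row <- row + 2L
    }
  }
  structure(list(vertices = verts, faces = faces, normals = NULL,
                 L = L, iso = NA_real_, params = NULL),
            class = "pcell_mesh")
}
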