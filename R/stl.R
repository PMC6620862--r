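#' Write a triangle mesh as STL
#'
#' Writes either the 50-byte-per-triangle little-endian binary dialect
#' (80-byte header, uint32 triangle count, 12 float32 + uint16 per triangle)
#' or the ASCII dialect. Facet normals are the geometric triangle normals.
#'
#' @param mesh a \code{pcell_mesh}.
#' @param path output file path.
#' @param dialect \code{"binary"} (default) or \code{"ascii"}.
#' @param name solid name written in the header.
#' @return The path, invisibly.
#' @export
writeSTL <- function(mesh, path, dialect = c("binary", "ascii"),
                     name = "pcell") {
  stopifnot(inherits(mesh, "pcell_mesh"))
  dialect <- match.arg(dialect)
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  u <- b - a
  w <- cc - a
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  nl <- sqrt(rowSums(n^2))
  nl[nl == 0] <- 1
  n <- n / nl
  nf <- nrow(f)
  if (dialect == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", substr(name, 1, 79)))[1:80]
    writeBin(header, con)
    writeBin(as.integer(nf), con, size = 4, endian = "little")
    if (nf > 0) {
      dat <- cbind(n, a, b, cc) # 12 floats per triangle
      fl <- writeBin(as.numeric(t(dat)), raw(), size = 4, endian = "little")
      flm <- matrix(fl, nrow = 48)
      attr_bytes <- matrix(as.raw(0), nrow = 2, ncol = nf)
      writeBin(as.vector(rbind(flm, attr_bytes)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("solid %s", name), con)
    if (nf > 0) {
      fmt <- paste0(
        "facet normal %.9e %.9e %.9e\n outer loop\n",
        "  vertex %.9e %.9e %.9e\n  vertex %.9e %.9e %.9e\n",
        "  vertex %.9e %.9e %.9e\n endloop\nendfacet")
      txt <- sprintf(fmt, n[, 1], n[, 2], n[, 3],
                     a[, 1], a[, 2], a[, 3],
                     b[, 1], b[, 2], b[, 3],
                     cc[, 1], cc[, 2], cc[, 3])
      writeLines(txt, con)
    }
    writeLines(sprintf("endsolid %s", name), con)
  }
  invisible(path)
}

#' Read an STL file
#'
#' Auto-detects the binary/ASCII dialect. Triangles are read as independent
#' facets; vertices repeated across facets are merged exactly.
#'
#' @param path STL file path.
#' @param L cell side attached to the resulting mesh (for downstream
#'   property functions); defaults to the bounding-box extent.
#' @return A \code{pcell_mesh}.
#' @export
readSTL <- function(path, L = NULL) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  head <- readBin(con, "raw", n = min(84, sz))
  is_binary <- FALSE
  if (sz >= 84) {
    nf_guess <- readBin(head[81:84], "integer", size = 4, endian = "little")
    if (84 + 50 * as.numeric(nf_guess) == sz) is_binary <- TRUE
  }
  close(con)
  if (is_binary) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80)
    nf <- readBin(con, "integer", size = 4, endian = "little")
    body <- readBin(con, "raw", n = 50 * nf)
    bm <- matrix(body, nrow = 50)
    fl <- readBin(as.vector(bm[1:48, , drop = FALSE]), "numeric",
                  n = 12 * nf, size = 4, endian = "little")
    dat <- matrix(fl, ncol = 12, byrow = TRUE)
    tri <- dat[, 4:12, drop = FALSE]
  } else {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", txt, value = TRUE)
    parts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p) {
      as.numeric(p[2:4])
    }))
    nf <- nrow(parts) / 3
    tri <- cbind(parts[seq(1, 3 * nf, by = 3), , drop = FALSE],
                 parts[seq(2, 3 * nf, by = 3), , drop = FALSE],
                 parts[seq(3, 3 * nf, by = 3), , drop = FALSE])
  }
  verts_all <- rbind(tri[, 1:3, drop = FALSE], tri[, 4:6, drop = FALSE],
                     tri[, 7:9, drop = FALSE])
  key <- paste(verts_all[, 1], verts_all[, 2], verts_all[, 3])
  uid <- !duplicated(key)
  verts <- verts_all[uid, , drop = FALSE]
  vmap <- match(key, key[uid])
  nf <- nrow(tri)
  faces <- cbind(vmap[seq_len(nf)], vmap[nf + seq_len(nf)],
                 vmap[2 * nf + seq_len(nf)])
  if (is.null(L)) L <- max(apply(verts, 2, function(x) diff(range(x))))
  structure(
    list(vertices = verts, faces = faces, normals = NULL,
         L = L, iso = NA_real_, params = NULL),
    class = "pcell_mesh"
  )
}
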