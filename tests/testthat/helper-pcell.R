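# lazily computed shared fixtures; helpers persist across test files in one
# test_dir() run, so heavyweight meshes are built once
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

std_field <- function(N = 60) {
  fixture(paste0("field", N), sampleField(pcellParams(N = N)))
}

std_mesh <- function(N = 60) {
  fixture(paste0("mesh", N), extractIsosurface(std_field(N)))
}

# handmade pcell_solid with a given occupancy array (for porosity identities)
manual_solid <- function(occ, L) {
  M <- dim(occ)[1]
  hv <- L / M
  structure(
    list(occupancy = occ, voxel_size = hv, M = M, L = L, t = NA_real_,
         k = NA_real_, material_volume = sum(occ) * hv^3,
         porosity = 1 - sum(occ) * hv^3 / L^3, pore_radius = NA_real_,
         outer_mesh = NULL, inner_mesh = NULL, boundary_mesh = NULL,
         params = NULL),
    class = "pcell_solid"
  )
}

# fake curvature table for classification unit cases
fake_curvature <- function(k1, k2, fit_ok = TRUE) {
  out <- data.frame(k1 = k1, k2 = k2, G = k1 * k2, H = (k1 + k2) / 2,
                    R = sqrt(k1^2 + k2^2),
                    fit_ok = rep_len(fit_ok, length(k1)))
  class(out) <- c("pcell_curvature", "data.frame")
  out
}
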