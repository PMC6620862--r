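#' Reproduce the characterization sweeps as CSV tables
#'
#' Runs the deterministic parameter sweeps behind the package's cell
#' characterization — global properties along the k sweep (s = 1) and the s
#' sweep (k = 0), a combined (k, s) grid, curvature-region statistics, and
#' porosity versus thickness — and writes one CSV per table plus a manifest
#' with the generating parameters and package version. Output is sorted by
#' parameter tuples, so reruns produce byte-identical files.
#'
#' Stiffness-porosity tables are optional because the voxel FEM sweeps
#' dominate the runtime; enable them with \code{fem = TRUE}.
#'
#' @param outdir output directory (created if missing).
#' @param N grid resolution for property sweeps.
#' @param region_N resolution for the curvature-region sweep.
#' @param thicknesses shell thicknesses (mm) for the porosity table.
#' @param M voxel resolution for solidification.
#' @param fem also run the stiffness-porosity sweep (slow).
#' @param fem_M,fem_N voxel and field resolution for the FEM sweep.
#' @return Invisibly, the named list of written file paths.
#' @export
reproduceFigures <- function(outdir, N = 100L, region_N = 80L,
                             thicknesses = c(0.2, 0.4, 0.6), M = 100L,
                             fem = FALSE, fem_M = 50L, fem_N = 60L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  kseq <- seq(-0.9, 0.9, by = 0.1)
  sseq <- seq(0.75, 1.5, by = 0.05)

  paths$global_k_sweep <- file.path(outdir, "global_k_sweep.csv")
  tk <- propertyTable(k = kseq, s = 1, N = N)
  writePropertyCSV(tk, paths$global_k_sweep)

  paths$global_s_sweep <- file.path(outdir, "global_s_sweep.csv")
  ts <- propertyTable(k = 0, s = sseq, N = N)
  writePropertyCSV(ts, paths$global_s_sweep)

  paths$global_ks_grid <- file.path(outdir, "global_ks_grid.csv")
  tg <- propertyTable(k = c(-0.5, -0.25, 0, 0.25, 0.5),
                      s = c(0.85, 1, 1.15), N = N)
  writePropertyCSV(tg, paths$global_ks_grid)

  paths$curvature_regions <- file.path(outdir, "curvature_regions.csv")
  combos <- expand.grid(k = c(-0.7, -0.5, -0.3, 0.3, 0.5, 0.7),
                        s = c(0.85, 1, 1.15))
  combos <- combos[order(combos$s, combos$k), ]
  reg_rows <- lapply(seq_len(nrow(combos)), function(i) {
    p <- pcellParams(combos$k[i], combos$s[i], N = region_N)
    tryCatch(curvatureAnalysis(p)$stats, error = function(e) {
      data.frame(k = p$k, s = p$s, n_regions = NA_integer_,
                 label = NA_character_, R_mean_L = NA_real_,
                 A_r_pct = NA_real_)
    })
  })
  writePropertyCSV(do.call(rbind, reg_rows), paths$curvature_regions)

  paths$porosity_thickness <- file.path(outdir, "porosity_thickness.csv")
  pt_rows <- list()
  for (t in sort(thicknesses)) {
    for (kk in seq(-0.75, 0.75, by = 0.25)) {
      fld <- sampleField(pcellParams(kk, 1, N = N))
      pt_rows[[length(pt_rows) + 1L]] <- porosityRow(fld, kk, 1, t, M)
    }
    for (ss in seq(0.8, 1.4, by = 0.1)) {
      fld <- sampleField(pcellParams(0, ss, N = N))
      pt_rows[[length(pt_rows) + 1L]] <- porosityRow(fld, 0, ss, t, M)
    }
  }
  writePropertyCSV(do.call(rbind, pt_rows), paths$porosity_thickness)

  if (fem) {
    paths$stiffness_porosity <- file.path(outdir, "stiffness_porosity.csv")
    specs <- rbind(
      data.frame(k = c(-0.5, -0.25, 0, 0.25, 0.5), s = 1, family = "k"),
      data.frame(k = 0, s = c(0.85, 1, 1.15, 1.3), family = "s"))
    specs <- do.call(rbind, lapply(c(0.3, 0.4, 0.5), function(t) {
      cbind(specs, t = t)
    }))
    tab <- stiffnessPorosityCurve(specs, L = 5, M = fem_M, N = fem_N)
    writePropertyCSV(tab, paths$stiffness_porosity)
  }

  paths$manifest <- file.path(outdir, "manifest.csv")
  manifest <- data.frame(
    key = c("package", "version", "N", "region_N", "M",
            "thicknesses", "fem"),
    value = c("pcellkit",
              as.character(utils::packageVersion("pcellkit")),
              N, region_N, M, paste(sort(thicknesses), collapse = ";"),
              fem))
  utils::write.csv(manifest, paths$manifest, row.names = FALSE, quote = FALSE)
  invisible(paths)
}

porosityRow <- function(fld, k, s, t, M) {
  tryCatch({
    sol <- suppressWarnings(solidify(fld, t = t, M = M))
    data.frame(k = k, s = s, t = t, P = porosity(sol),
               P_thin_shell = 1 - surfaceRatio(sol$outer_mesh) * t / sol$L,
               error = NA_character_)
  }, error = function(e) {
    data.frame(k = k, s = s, t = t, P = NA_real_, P_thin_shell = NA_real_,
               error = conditionMessage(e))
  })
}
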