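# Output writers: CSV profiles, legacy-VTK structured fields, JSON
# summaries. All writers are deterministic (no timestamps), so re-running
# an experiment with the same configuration reproduces every artifact
# bit-identically.

#' Write a scalar field as a legacy VTK structured-points file
#'
#' Voxel fields are written as 3D `STRUCTURED_POINTS`; axisymmetric and
#' slab fields as degenerate 2D/1D grids (r or x vs depth z). ASCII legacy
#' format, readable by ParaView and VisIt.
#'
#' @param values numeric array on the phantom grid
#' @param phantom the phantom
#' @param path output file path
#' @param name data array name
#' @return the path, invisibly
#' @export
write_vtk <- function(values, phantom, path, name = "field") {
  h <- phantom$spacing
  dims <- switch(phantom$grid_kind,
    slab_1d = c(1L, 1L, phantom$dims[["nz"]]),
    axisymmetric_2d = c(phantom$dims[["nr"]], 1L, phantom$dims[["nz"]]),
    voxel_3d = unname(phantom$dims))
  v <- as.vector(values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               paste0("tnirsim ", name),
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", dims[1], dims[2], dims[3]),
               sprintf("ORIGIN %g %g %g", h / 2, h / 2, h / 2),
               sprintf("SPACING %g %g %g", h, h, h),
               sprintf("POINT_DATA %d", length(v)),
               sprintf("SCALARS %s double 1", name),
               "LOOKUP_TABLE default"), con)
  writeLines(format(v, digits = 10, trim = TRUE, scientific = TRUE), con)
  invisible(path)
}

write_profile_csv <- function(profile, path) {
  write.csv(profile, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# djb2-style rolling hash of a serialized R object, for artifact
# provenance (not cryptographic). Kept below 2^31 so the arithmetic is
# exact in doubles.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  hash <- 5381
  for (b in bytes) hash <- (hash * 33 + b) %% 2147483647
  sprintf("%08x", hash)
}

#' Read an experiment configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [experiment_config()]:
#' `wavelengths`, `modes`, `chromophores`, `seed`, `out_dir`,
#' `irradiance_mW_cm2`, `aperture_cm2`, `source_kind`, and a `phantom`
#' block with `thicknesses_mm` (scalp_skull, csf, gray_matter),
#' `spacing_mm`, `lateral_extent_mm`, `depth_mm`, `grid_kind`. Unset keys
#' fall back to the defaults.
#'
#' @param path YAML file path
#' @return an `experiment_config` object
#' @export
config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  ph <- y$phantom
  layers <- if (!is.null(ph$thicknesses_mm)) {
    t_mm <- ph$thicknesses_mm
    default_layers(scalp_skull = t_mm[[1]] / 1e3, csf = t_mm[[2]] / 1e3,
                   gray_matter = t_mm[[3]] / 1e3)
  } else default_layers()
  src <- source_spec(
    kind = y$source_kind %||% "point",
    irradiance = (y$irradiance_mW_cm2 %||% 500) * 10, # mW/cm2 -> W/m2
    aperture_area = (y$aperture_cm2 %||% 1) * 1e-4)
  experiment_config(
    wavelengths = unlist(y$wavelengths) %||% c(630, 700, 810),
    modes = unlist(y$modes) %||% "whole_tissue",
    chromophores = unlist(y$chromophores) %||% CHROMOPHORES,
    source = src,
    layers = layers,
    grid_kind = ph$grid_kind %||% "axisymmetric_2d",
    spacing = (ph$spacing_mm %||% 0.5) / 1e3,
    lateral_extent = (ph$lateral_extent_mm %||% 60) / 1e3,
    depth = (ph$depth_mm %||% 60) / 1e3,
    seed = y$seed %||% 1,
    out_dir = y$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
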