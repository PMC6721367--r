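#' Layer specification for a head phantom
#'
#' @param tissue tissue label, one of `scalp_skull`, `csf`, `gray_matter`,
#'   `white_matter`
#' @param thickness layer thickness in meters; `NA` marks the innermost
#'   layer as filling the remainder of the domain
#' @return a `layer_spec` object
#' @export
layer_spec <- function(tissue, thickness = NA_real_) {
  tissue <- match.arg(tissue, TISSUES)
  if (!is.na(thickness) && thickness <= 0)
    stop("layer '", tissue, "' must have positive thickness", call. = FALSE)
  structure(list(tissue = tissue, thickness = thickness),
            class = "layer_spec")
}

#' Default four-layer head stack
#'
#' Combined scalp and skull (13 mm), cerebrospinal fluid (7 mm), gray matter
#' (4 mm) and white matter filling the remainder. The cumulative outer
#' thickness places the gray-matter interface 20 mm below the scalp surface.
#' Thicknesses are assumptions of the synthetic phantom, not anatomical
#' measurements; all are overridable.
#'
#' @param scalp_skull,csf,gray_matter layer thicknesses in meters
#' @return list of [layer_spec()] objects
#' @export
default_layers <- function(scalp_skull = 0.013, csf = 0.007,
                           gray_matter = 0.004) {
  list(layer_spec("scalp_skull", scalp_skull),
       layer_spec("csf", csf),
       layer_spec("gray_matter", gray_matter),
       layer_spec("white_matter", NA_real_))
}

#' Build a discretized layered head phantom
#'
#' Generates a structured-grid stand-in for an anatomical head mesh: a stack
#' of horizontal tissue layers discretized on a 1D slab, an axisymmetric
#' (r, z) grid, or a 3D voxel grid. Depth `z` increases into the head from
#' the surface at `z = 0`; each cell is labeled with the tissue whose layer
#' contains its center. Cells deeper than the last finite layer are labeled
#' with the innermost remainder layer (white matter for the default stack).
#'
#' @param layers list of [layer_spec()] objects, outermost first (default:
#'   [default_layers()])
#' @param grid_kind `"slab_1d"`, `"axisymmetric_2d"` or `"voxel_3d"`
#' @param spacing cell edge length, m; must resolve the thinnest finite
#'   layer with at least two cells
#' @param lateral_extent lateral half-width (axisymmetric radius) or full
#'   width (voxel), m; ignored for slabs
#' @param depth total domain depth, m; defaults to the summed finite layer
#'   thicknesses, or 60 mm when a remainder layer is present
#' @return a `nir_phantom` object
#' @export
#' @examples
#' ph <- build_phantom(spacing = 1e-3)
#' ph$layer_interfaces  # 0.013 0.020 0.024
build_phantom <- function(layers = default_layers(),
                          grid_kind = c("axisymmetric_2d", "slab_1d",
                                        "voxel_3d"),
                          spacing = 5e-4,
                          lateral_extent = 0.06,
                          depth = NULL) {
  grid_kind <- match.arg(grid_kind)
  if (spacing <= 0) stop("spacing must be positive", call. = FALSE)
  stopifnot(length(layers) >= 1L,
            all(vapply(layers, inherits, logical(1), "layer_spec")))
  thick <- vapply(layers, function(l) l$thickness, numeric(1))
  tiss <- vapply(layers, function(l) l$tissue, character(1))
  if (anyNA(thick[-length(thick)]))
    stop("only the innermost layer may have unspecified thickness",
         call. = FALSE)
  finite <- thick[!is.na(thick)]
  if (length(finite)) {
    thinnest <- which.min(finite)
    if (spacing > min(finite) / 2)
      stop("spacing ", spacing, " m is too coarse to resolve layer '",
           tiss[!is.na(thick)][thinnest], "' (", min(finite), " m thick)",
           call. = FALSE)
  }
  if (is.null(depth))
    depth <- if (anyNA(thick)) max(0.06, sum(finite)) else sum(finite)
  if (depth < sum(finite))
    stop("domain depth is smaller than the summed layer thicknesses",
         call. = FALSE)
  if (grid_kind != "slab_1d" && lateral_extent <= 0)
    stop("lateral_extent must be positive", call. = FALSE)

  nz <- max(1L, round(depth / spacing))
  z_centers <- (seq_len(nz) - 0.5) * spacing
  # tissue of the layer containing each depth
  breaks <- cumsum(ifelse(is.na(thick), Inf, thick))
  layer_of <- findInterval(z_centers, c(0, breaks[-length(breaks)]))
  fill <- if (anyNA(thick)) tiss[length(tiss)] else "white_matter"
  col_tissue <- ifelse(layer_of > length(tiss), fill, tiss[layer_of])
  interfaces <- breaks[is.finite(breaks) & breaks < depth]

  dims <- switch(grid_kind,
    slab_1d = c(nz = nz),
    axisymmetric_2d = c(nr = max(1L, round(lateral_extent / spacing)),
                        nz = nz),
    voxel_3d = {
      n_lat <- max(1L, round(lateral_extent / spacing))
      c(nx = n_lat, ny = n_lat, nz = nz)
    })
  tissue <- switch(grid_kind,
    slab_1d = col_tissue,
    axisymmetric_2d = matrix(rep(col_tissue, each = dims[["nr"]]),
                             nrow = dims[["nr"]]),
    voxel_3d = array(rep(col_tissue, each = dims[["nx"]] * dims[["ny"]]),
                     dim = dims))

  structure(list(grid_kind = grid_kind, spacing = spacing, dims = dims,
                 depth = nz * spacing, lateral_extent = lateral_extent,
                 z_centers = z_centers, tissue = tissue,
                 layer_interfaces = unname(interfaces),
                 layers = layers),
            class = "nir_phantom")
}

#' @export
print.nir_phantom <- function(x, ...) {
  cat(sprintf("<nir_phantom> %s grid, spacing %.3g mm, %s cells\n",
              x$grid_kind, x$spacing * 1e3,
              paste(x$dims, collapse = " x ")))
  cat("  layer interfaces at",
      paste(sprintf("%.1f", x$layer_interfaces * 1e3), collapse = ", "),
      "mm depth\n")
  invisible(x)
}

n_cells <- function(phantom) prod(phantom$dims)

# depth of each cell center, flattened in array order
cell_depths <- function(phantom) {
  switch(phantom$grid_kind,
    slab_1d = phantom$z_centers,
    axisymmetric_2d = rep(phantom$z_centers, each = phantom$dims[["nr"]]),
    voxel_3d = rep(phantom$z_centers,
                   each = phantom$dims[["nx"]] * phantom$dims[["ny"]]))
}

# cell volumes, flattened; slab volumes are per unit cross-section (1 m2)
cell_volumes <- function(phantom) {
  h <- phantom$spacing
  switch(phantom$grid_kind,
    slab_1d = rep(h, phantom$dims[["nz"]]),
    axisymmetric_2d = {
      nr <- phantom$dims[["nr"]]
      r <- (seq_len(nr) - 0.5) * h
      rep(2 * pi * r * h^2, times = phantom$dims[["nz"]])
    },
    voxel_3d = rep(h^3, n_cells(phantom)))
}

#' Assign per-cell optical (and derived) properties
#'
#' Maps the whole-tissue optical table at the requested wavelength onto every
#' cell of a phantom and derives the diffusion coefficient
#' `D = 1/(3(mu_a + mu_s'))`. `overrides` replaces individual per-tissue
#' values, e.g. to run a single chromophore's absorption in the brain layers
#' while keeping scattering unchanged. The result is a pure function of
#' `(phantom, wavelength, overrides)`.
#'
#' @param phantom a [build_phantom()] result
#' @param wavelength_nm wavelength in nm; must be tabulated unless
#'   `overrides` supplies `mu_a` and `mu_s_prime` for every tissue present
#' @param overrides named list: `overrides[[tissue]]` is a list with any of
#'   `mu_a`, `mu_s_prime` (1/m)
#' @param g anisotropy factor carried for Monte Carlo use
#' @return a `nir_properties` object with per-cell vectors `mu_a`,
#'   `mu_s_prime`, `D` (flattened in array order) and the per-tissue table
#' @export
assign_properties <- function(phantom, wavelength_nm, overrides = NULL,
                              g = DEFAULT_G) {
  stopifnot(inherits(phantom, "nir_phantom"))
  present <- unique(as.vector(phantom$tissue))
  opt <- nir_tables()$optical
  per_tissue <- lapply(setNames(present, present), function(ts) {
    row <- opt[opt$tissue == ts & opt$wavelength_nm == wavelength_nm, ]
    ov <- overrides[[ts]]
    mu_a <- if (!is.null(ov$mu_a)) ov$mu_a
            else if (nrow(row) == 1L) row$mu_a_per_m
            else stop("no tabulated mu_a for ", ts, " at ", wavelength_nm,
                      " nm and no override supplied", call. = FALSE)
    mu_s <- if (!is.null(ov$mu_s_prime)) ov$mu_s_prime
            else if (nrow(row) == 1L) row$mu_s_prime_per_m
            else stop("no tabulated mu_s_prime for ", ts, " at ",
                      wavelength_nm, " nm and no override supplied",
                      call. = FALSE)
    list(mu_a = mu_a, mu_s_prime = mu_s,
         D = diffusion_coefficient(mu_a, mu_s))
  })
  lab <- as.vector(phantom$tissue)
  take <- function(field) vapply(per_tissue, `[[`, numeric(1), field)[lab]
  structure(list(mu_a = unname(take("mu_a")),
                 mu_s_prime = unname(take("mu_s_prime")),
                 D = unname(take("D")),
                 per_tissue = per_tissue,
                 wavelength_nm = wavelength_nm, g = g,
                 refractive_index = DEFAULT_REFRACTIVE_INDEX),
            class = "nir_properties")
}
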