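#' Light source specification
#'
#' A surface source on the scalp at the stimulation site. The nominal
#' protocol is an irradiance of 500 mW/cm2 (5000 W/m2) delivered through a
#' 1 cm2 aperture, i.e. 0.5 W of total power. `point` sources inject the
#' full power on the beam axis; `disc` sources spread it uniformly over the
#' aperture.
#'
#' @param kind `"point"` or `"disc"`
#' @param irradiance source irradiance, W/m2
#' @param aperture_area aperture area, m2
#' @return a `source_spec` object with `total_power = irradiance *
#'   aperture_area` (W)
#' @export
#' @examples
#' source_spec() # 0.5 W point source
source_spec <- function(kind = c("point", "disc"),
                        irradiance = 5000, aperture_area = 1e-4) {
  kind <- match.arg(kind)
  if (irradiance < 0 || aperture_area <= 0)
    stop("irradiance must be >= 0 and aperture_area > 0", call. = FALSE)
  structure(list(kind = kind, irradiance = irradiance,
                 aperture_area = aperture_area,
                 total_power = irradiance * aperture_area),
            class = "source_spec")
}

# Source density on the grid. The collimated surface beam is replaced by
# an isotropic source one transport mean free path (1 / mu_s' of the entry
# tissue) below the entry point; to keep the discrete solution convergent
# under grid refinement the point is regularized with a fixed-width
# Gaussian kernel (sigma in meters, independent of the spacing) truncated
# at three sigma and normalized on the grid. Disc sources spread the
# kernel uniformly over the aperture radius. `depth` overrides the
# placement (used e.g. to emulate an interior point source in a
# homogeneous medium). Returns the unnormalized per-cell weight density.
source_density <- function(phantom, properties, source, depth = NULL,
                           sigma = 5e-4) {
  h <- phantom$spacing
  entry_tissue <- as.vector(phantom$tissue)[1]
  if (is.null(depth)) {
    musp <- properties$per_tissue[[entry_tissue]]$mu_s_prime
    if (musp <= 0)
      stop("cannot place the source: entry tissue has no scattering",
           call. = FALSE)
    depth <- 1 / musp
  }
  if (depth > phantom$depth)
    stop("source depth lies outside the phantom", call. = FALSE)
  zc <- phantom$z_centers
  kern <- function(d2) {
    w <- exp(-d2 / (2 * sigma^2))
    w[d2 > (3 * sigma)^2] <- 0
    w
  }
  wz <- kern((zc - depth)^2)
  if (all(wz == 0)) wz[which.min(abs(zc - depth))] <- 1
  w <- switch(phantom$grid_kind,
    slab_1d = wz,
    axisymmetric_2d = {
      nr <- phantom$dims[["nr"]]
      r <- (seq_len(nr) - 0.5) * h
      wr <- if (source$kind == "disc") {
        radius <- sqrt(source$aperture_area / pi)
        as.numeric(r <= max(radius, h))
      } else kern(r^2)
      if (all(wr == 0)) wr[1] <- 1
      as.vector(outer(wr, wz))
    },
    voxel_3d = {
      nx <- phantom$dims[["nx"]]; ny <- phantom$dims[["ny"]]
      wx <- kern(((seq_len(nx) - 0.5) * h - (nx / 2) * h)^2)
      wy <- kern(((seq_len(ny) - 0.5) * h - (ny / 2) * h)^2)
      if (all(wx == 0)) wx[as.integer(ceiling(nx / 2))] <- 1
      if (all(wy == 0)) wy[as.integer(ceiling(ny / 2))] <- 1
      as.vector(outer(outer(wx, wy), wz))
    })
  list(weight = w, depth = depth)
}

#' Solve the steady-state photon diffusion equation
#'
#' Discretizes `-div(D grad phi) + mu_a phi = Q0` with a finite-volume
#' scheme on the phantom grid and a partial-current (Robin) boundary
#' `phi + 2 A D dphi/dn = 0` on all outer surfaces (index-matched, `A = 1`;
#' surface reflection is not modeled). The collimated surface beam is
#' regularized as an isotropic source one transport mean free path below
#' the entry point. The scheme is locally conservative, so absorbed power
#' plus boundary escape equals injected power to solver precision.
#'
#' For `slab_1d` phantoms the source is a planar beam and all extensive
#' quantities (power, absorption) are per unit surface area.
#'
#' @param phantom a [build_phantom()] result
#' @param properties an [assign_properties()] result on the same phantom
#' @param source a [source_spec()]
#' @param source_depth optional source depth override, m
#' @param source_sigma regularization width of the source kernel, m
#' @return a `nir_fluence` object: `values` (fluence rate, W/m2, shaped like
#'   the grid), energy `balance`, and provenance fields
#' @export
solve_diffusion <- function(phantom, properties, source = source_spec(),
                            source_depth = NULL, source_sigma = 5e-4) {
  stopifnot(inherits(phantom, "nir_phantom"),
            inherits(properties, "nir_properties"),
            inherits(source, "source_spec"))
  if (length(properties$mu_a) != n_cells(phantom))
    stop("properties do not cover every cell of the phantom",
         call. = FALSE)
  # partial-current closure on every outer boundary: J_out = phi / (2A)
  A_coef <- 1
  robin <- list(surface = list(c1 = 1 / (2 * A_coef), u_inf = 0),
                bottom = list(c1 = 1 / (2 * A_coef), u_inf = 0),
                lateral = list(c1 = 1 / (2 * A_coef), u_inf = 0))
  op <- fv_operator(phantom, properties$D, properties$mu_a, robin)
  src <- source_density(phantom, properties, source, source_depth,
                        source_sigma)
  injected <- if (phantom$grid_kind == "slab_1d") source$irradiance
              else source$total_power
  wv <- src$weight * op$vol
  rhs <- injected * wv / sum(wv) + op$b_bc
  phi <- fv_solve(op, rhs)
  resid <- sqrt(sum((as.numeric(op$A %*% phi) - rhs)^2)) /
    max(sqrt(sum(rhs^2)), .Machine$double.xmin)
  if (!all(is.finite(phi)))
    stop("diffusion solve failed: non-finite fluence", call. = FALSE)
  if (resid > 1e-8)
    stop("diffusion solve did not converge: relative residual ", resid,
         call. = FALSE)
  absorbed <- sum(properties$mu_a * phi * op$vol)
  escaped <- fv_boundary_outflow(op, phi)
  structure(list(values = array(phi, dim = phantom$dims),
                 phantom = phantom, properties = properties,
                 source = source, source_depth = src$depth,
                 wavelength_nm = properties$wavelength_nm,
                 balance = list(injected = injected, absorbed = absorbed,
                                escaped = escaped, residual = resid)),
            class = "nir_fluence")
}

#' @export
print.nir_fluence <- function(x, ...) {
  cat(sprintf(
    "<nir_fluence> %g nm, %s grid; injected %.3g W, absorbed %.3g W, escaped %.3g W\n",
    x$wavelength_nm, x$phantom$grid_kind, x$balance$injected,
    x$balance$absorbed, x$balance$escaped))
  invisible(x)
}

# On-axis (through-source) column of a field, as cell-center values.
axis_column <- function(values, phantom) {
  switch(phantom$grid_kind,
    slab_1d = as.vector(values),
    axisymmetric_2d = as.matrix(values)[1, ],
    voxel_3d = {
      nx <- phantom$dims[["nx"]]; ny <- phantom$dims[["ny"]]
      values[as.integer(ceiling(nx / 2)), as.integer(ceiling(ny / 2)), ]
    })
}

#' Extract a cutline profile through the source
#'
#' Samples a scalar field along the depth axis through the source entry
#' point at uniform steps, by linear interpolation of cell-center values,
#' and labels every sample with the tissue of its layer. Only depth-axis
#' cutlines are supported on the structured phantoms; the direction vector
#' must point into the head.
#'
#' @param field a `nir_fluence` or `nir_temperature` object, or a numeric
#'   array on the phantom grid (then `phantom` must be given)
#' @param direction cutline direction; must be the inward surface normal
#'   `c(0, 0, 1)` (up to scale)
#' @param step sampling step, m (default: grid spacing)
#' @param phantom phantom, required when `field` is a bare array
#' @return a data frame of class `nir_cutline` with columns `depth_m`,
#'   `tissue`, `value`
#' @export
extract_cutline <- function(field, direction = c(0, 0, 1), step = NULL,
                            phantom = NULL) {
  if (inherits(field, c("nir_fluence", "nir_temperature"))) {
    phantom <- field$phantom
    values <- field$values
  } else {
    if (is.null(phantom))
      stop("phantom must be supplied for bare arrays", call. = FALSE)
    values <- field
  }
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0)
    stop("degenerate cutline direction vector", call. = FALSE)
  direction <- direction / nrm
  if (abs(direction[length(direction)] - 1) > 1e-12 ||
      any(abs(direction[-length(direction)]) > 1e-12))
    stop("only depth-axis cutlines are supported on structured phantoms",
         call. = FALSE)
  if (is.null(step)) step <- phantom$spacing
  if (step <= 0) stop("step must be positive", call. = FALSE)
  col <- axis_column(values, phantom)
  zc <- phantom$z_centers
  depths <- seq(zc[1], zc[length(zc)], by = step)
  vals <- if (length(zc) == 1L) rep(col, length(depths))
          else approx(zc, col, xout = depths)$y
  col_tissue <- axis_column(array(as.vector(phantom$tissue),
                                  dim = phantom$dims), phantom)
  lab <- col_tissue[pmin(length(zc), pmax(1L, round(depths / phantom$spacing + 0.5)))]
  structure(data.frame(depth_m = depths, tissue = lab, value = vals,
                       stringsAsFactors = FALSE),
            class = c("nir_cutline", "data.frame"))
}

#' Fluence-fraction profile along the source axis
#'
#' Normalizes the on-axis fluence cutline by its value at the source entry
#' cell (the surface cell on the beam axis), giving the dimensionless
#' fraction of the entering fluence rate that survives to each depth.
#'
#' @param field a solved `nir_fluence`
#' @param step sampling step, m
#' @return a data frame of class `nir_profile` with columns `depth_m`,
#'   `tissue`, `fluence_W_per_m2`, `fraction`, `log_fluence`
#' @export
fluence_fraction_profile <- function(field, step = NULL) {
  stopifnot(inherits(field, "nir_fluence"))
  if (length(field$phantom$layer_interfaces) < 1L &&
      length(unique(as.vector(field$phantom$tissue))) < 2L)
    warning("fraction profile on a single-layer phantom")
  cut <- extract_cutline(field, step = step)
  ref <- cut$value[1]
  if (!is.finite(ref) || ref <= 0)
    stop("entry-cell fluence is not positive; cannot normalize",
         call. = FALSE)
  structure(data.frame(depth_m = cut$depth_m, tissue = cut$tissue,
                       fluence_W_per_m2 = cut$value,
                       fraction = cut$value / ref,
                       log_fluence = log(pmax(cut$value,
                                              .Machine$double.xmin)),
                       stringsAsFactors = FALSE),
            class = c("nir_profile", "data.frame"))
}

#' Fluence fraction at a given depth
#'
#' @param field a solved `nir_fluence`
#' @param depth depth from the surface, m (e.g. the gray-matter interface)
#' @return the on-axis fluence at `depth` divided by the entry-cell fluence
#' @export
fluence_fraction_at <- function(field, depth) {
  prof <- fluence_fraction_profile(field)
  if (depth < min(prof$depth_m) || depth > max(prof$depth_m))
    stop("depth lies outside the phantom", call. = FALSE)
  approx(prof$depth_m, prof$fraction, xout = depth)$y
}

#' Single-chromophore attenuation run
#'
#' Re-solves the diffusion equation with the gray- and white-matter
#' absorption replaced by one chromophore's contribution, keeping the
#' reduced scattering of the brain layers and the full (absorption and
#' scattering) properties of the scalp-skull and CSF layers unchanged.
#' This isolates the fluence attenuation attributable to that chromophore
#' at fixed tissue scattering.
#'
#' @param phantom a [build_phantom()] result
#' @param wavelength_nm one of the tabulated wavelengths
#' @param chromophore one of `water`, `fat`, `oxyhemoglobin`,
#'   `deoxyhemoglobin`, `oxidized_cco`, `reduced_cco`
#' @param source a [source_spec()]
#' @return a `nir_fluence` with attribute `chromophore`
#' @export
per_chromophore_run <- function(phantom, wavelength_nm, chromophore,
                                source = source_spec()) {
  chromophore <- match.arg(chromophore, CHROMOPHORES)
  overrides <- list(
    gray_matter = list(
      mu_a = nir_lookup("gray_matter", wavelength_nm, chromophore)),
    white_matter = list(
      mu_a = nir_lookup("white_matter", wavelength_nm, chromophore)))
  props <- assign_properties(phantom, wavelength_nm, overrides)
  field <- solve_diffusion(phantom, props, source)
  attr(field, "chromophore") <- chromophore
  field
}
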