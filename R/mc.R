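#' Monte Carlo transport configuration
#'
#' @param n_photons number of photon packets to launch
#' @param seed integer seed; identical seeds give bit-identical results
#' @param roulette_threshold weight below which Russian roulette is played
#' @param roulette_survival survival probability of the roulette (surviving
#'   packets have their weight boosted by its inverse, keeping the estimate
#'   unbiased)
#' @param g Henyey-Greenstein anisotropy factor
#' @param max_steps safety cap on scattering events per packet
#' @return an `mc_config` object
#' @export
mc_config <- function(n_photons = 1e5, seed = 1,
                      roulette_threshold = 1e-4, roulette_survival = 0.1,
                      g = DEFAULT_G, max_steps = 1e6) {
  if (n_photons < 1) stop("n_photons must be at least 1", call. = FALSE)
  if (roulette_survival <= 0 || roulette_survival >= 1)
    stop("roulette survival probability must lie in (0, 1)", call. = FALSE)
  structure(list(n_photons = n_photons, seed = seed,
                 roulette_threshold = roulette_threshold,
                 roulette_survival = roulette_survival, g = g,
                 max_steps = max_steps),
            class = "mc_config")
}

#' Voxel Monte Carlo photon transport
#'
#' Independent stochastic oracle for the diffusion solver: weighted photon
#' packets with implicit capture, Henyey-Greenstein scattering at the
#' configured anisotropy, and Russian roulette. The per-tissue scattering
#' coefficient is recovered from the reduced one as
#' `mu_s = mu_s' / (1 - g)`. Fluence is estimated from the absorbed-energy
#' tally, `phi = E_dep / (mu_a V)`, and is undefined (`NA`) in
#' non-absorbing voxels.
#'
#' @param phantom a `voxel_3d` [build_phantom()] result
#' @param properties an [assign_properties()] result on the same phantom
#' @param source a [source_spec()]; the packet weight is normalized so that
#'   fluence is reported for its total power
#' @param config an [mc_config()]
#' @param source_kind `"pencil"` (collimated beam entering at the surface,
#'   the default) or `"isotropic"` (point emitter at `source_position`)
#' @param source_position length-3 position in meters; defaults to the
#'   lateral center of the surface
#' @return a `nir_mc` object with the `fluence` array (W/m2), the
#'   `absorbed`, `reflected` and `transmitted` weight fractions, and the
#'   configuration used
#' @export
run_mc <- function(phantom, properties, source = source_spec(),
                   config = mc_config(), source_kind = c("pencil",
                                                         "isotropic"),
                   source_position = NULL) {
  stopifnot(inherits(phantom, "nir_phantom"),
            inherits(properties, "nir_properties"),
            inherits(config, "mc_config"))
  source_kind <- match.arg(source_kind)
  if (phantom$grid_kind != "voxel_3d")
    stop("Monte Carlo transport requires a voxel_3d phantom",
         call. = FALSE)
  g <- config$g
  if (g >= 1) stop("anisotropy g must be < 1 to recover mu_s",
                   call. = FALSE)
  mu_s <- properties$mu_s_prime / (1 - g)
  h <- phantom$spacing
  if (is.null(source_position)) {
    nx <- phantom$dims[["nx"]]; ny <- phantom$dims[["ny"]]
    source_position <- c((nx / 2) * h, (ny / 2) * h, 0)
  }
  raw <- .cpp_mc_transport(as.integer(phantom$dims), h,
                           as.numeric(properties$mu_a), as.numeric(mu_s),
                           g, as.numeric(source_position),
                           if (source_kind == "isotropic") 1L else 0L,
                           config$n_photons, config$seed,
                           config$roulette_threshold,
                           config$roulette_survival, config$max_steps)
  vol <- h^3
  P <- source$total_power
  mu_a <- as.numeric(properties$mu_a)
  phi <- raw$absorb * P / (config$n_photons * mu_a * vol)
  phi[mu_a == 0] <- NA_real_
  structure(list(fluence = array(phi, dim = phantom$dims),
                 absorbed_fraction = raw$absorbed,
                 reflected_fraction = raw$reflected,
                 transmitted_fraction = raw$transmitted,
                 phantom = phantom, source = source, config = config,
                 source_kind = source_kind,
                 source_position = source_position),
            class = "nir_mc")
}

#' @export
print.nir_mc <- function(x, ...) {
  cat(sprintf(
    "<nir_mc> %s photons (seed %s): absorbed %.4f, reflected %.4f, transmitted %.4f\n",
    format(x$config$n_photons, big.mark = ","), x$config$seed,
    x$absorbed_fraction, x$reflected_fraction, x$transmitted_fraction))
  invisible(x)
}

#' Sample Henyey-Greenstein deflection cosines
#'
#' Direct access to the scattering-angle sampler used by [run_mc()], for
#' validation (the empirical mean cosine estimates `g`).
#'
#' @param n number of samples
#' @param g anisotropy factor
#' @param seed integer seed
#' @return numeric vector of sampled cosines
#' @export
sample_hg <- function(n, g, seed = 1) {
  .cpp_sample_hg(n, g, seed)
}

#' Radial shell average of a voxel field
#'
#' Averages a per-voxel field over spherical shells around a center point;
#' used to compare Monte Carlo fluence against the point-source diffusion
#' Green's function.
#'
#' @param values voxel array (e.g. `nir_mc$fluence`)
#' @param phantom the voxel phantom
#' @param center length-3 center, m
#' @param r_max maximum radius, m
#' @param dr shell width, m (default: grid spacing)
#' @return data frame with columns `r_m` (shell mid-radius) and `value`
#' @export
radial_profile <- function(values, phantom, center, r_max, dr = NULL) {
  stopifnot(phantom$grid_kind == "voxel_3d")
  h <- phantom$spacing
  if (is.null(dr)) dr <- h
  nx <- phantom$dims[["nx"]]; ny <- phantom$dims[["ny"]]
  nz <- phantom$dims[["nz"]]
  cx <- (seq_len(nx) - 0.5) * h - center[1]
  cy <- (seq_len(ny) - 0.5) * h - center[2]
  cz <- (seq_len(nz) - 0.5) * h - center[3]
  r <- sqrt(outer(outer(cx^2, cy^2, `+`), cz^2, `+`))
  bin <- findInterval(r, seq(0, r_max, by = dr),
                      rightmost.closed = FALSE)
  keep <- r <= r_max & is.finite(values)
  means <- tapply(values[keep], bin[keep], mean)
  mids <- (as.integer(names(means)) - 0.5) * dr
  data.frame(r_m = mids, value = as.numeric(means))
}

#' Compare Monte Carlo and diffusion fluence by depth
#'
#' Bins both fields along depth within a lateral radius of the beam axis
#' and reports the relative difference per bin, the quantitative check on
#' where the diffusion approximation degrades (notably the low-scattering
#' CSF layer).
#'
#' @param mc a `nir_mc` result
#' @param diffusion a `nir_fluence` solved on the same phantom
#' @param lateral_radius radius around the axis to average over, m
#' @return data frame of class `nir_mc_compare` with columns `depth_m`,
#'   `tissue`, `phi_mc`, `phi_diffusion`, `rel_diff`
#' @export
mc_compare <- function(mc, diffusion, lateral_radius = 2e-3) {
  stopifnot(inherits(mc, "nir_mc"), inherits(diffusion, "nir_fluence"))
  phantom <- mc$phantom
  if (!identical(phantom$dims, diffusion$phantom$dims))
    stop("Monte Carlo and diffusion fields live on different grids",
         call. = FALSE)
  h <- phantom$spacing
  nx <- phantom$dims[["nx"]]; ny <- phantom$dims[["ny"]]
  cx <- (seq_len(nx) - 0.5) * h - mc$source_position[1]
  cy <- (seq_len(ny) - 0.5) * h - mc$source_position[2]
  lat <- sqrt(outer(cx^2, cy^2, `+`)) <= lateral_radius
  col_tissue <- axis_column(array(as.vector(phantom$tissue),
                                  dim = phantom$dims), phantom)
  out <- lapply(seq_len(phantom$dims[["nz"]]), function(k) {
    fm <- mc$fluence[, , k][lat]
    fd <- diffusion$values[, , k][lat]
    ok <- is.finite(fm)
    pm <- mean(fm[ok]); pd <- mean(fd[ok])
    data.frame(depth_m = phantom$z_centers[k], tissue = col_tissue[k],
               phi_mc = pm, phi_diffusion = pd,
               rel_diff = (pd - pm) / pm, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out), class = c("nir_mc_compare", "data.frame"))
}
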