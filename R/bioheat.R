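#' Convective surface boundary
#'
#' Heat loss at the scalp surface by convection to ambient air:
#' `-K dT/dn = h (T - T_ambient)`.
#'
#' @param h convective coefficient, W/m2.degC (default 4)
#' @param T_ambient ambient air temperature, degC (default 25)
#' @return a `surface_boundary` object
#' @export
surface_boundary <- function(h = 4, T_ambient = 25) {
  if (h < 0) stop("convective coefficient h must be >= 0", call. = FALSE)
  structure(list(h = h, T_ambient = T_ambient), class = "surface_boundary")
}

# Printed tissue density for CSF (0) and brain (0.08 kg/m3) are physically
# impossible (presumed typos); these literature values replace them unless
# `as_printed = TRUE`. Specific heats are not tabulated at all; standard
# literature values are used. Steady-state solutions do not depend on
# rho * c, only transients do.
THERMAL_DEFAULTS <- list(
  density = c(scalp = 1100, skull = 1990, csf = 1007, brain = 1040),
  specific_heat = c(scalp = 3391, skull = 1313, csf = 4096, brain = 3630))

#' Assign per-cell thermal and perfusion properties
#'
#' Maps the tabulated thermal conductivity, density, metabolic heat and
#' blood-perfusion parameters onto the phantom cells. The combined
#' scalp-skull layer takes thickness-weighted means of the separate scalp
#' and skull rows (`scalp_fraction` of the layer is scalp); gray and white
#' matter take the brain row; CSF is unperfused. The perfusion heat-sink
#' coefficient is `s = rho_b * omega_b * c_b` (W/m3.degC).
#'
#' @param phantom a [build_phantom()] result
#' @param scalp_fraction scalp share of the combined scalp-skull layer
#'   thickness (default 5 mm of 13 mm)
#' @param blood_specific_heat blood specific heat, J/kg.degC; the tabulated
#'   3600 by default (a 3664 variant appears in some sources)
#' @param as_printed use the tabulated densities verbatim, including the
#'   impossible CSF and brain values (transients then degrade; a warning is
#'   emitted)
#' @param overrides named list `overrides[[tissue]]` with any of
#'   `conductivity`, `density`, `specific_heat`, `metabolic_heat`,
#'   `perfusion_rate`
#' @param arterial_temperature arterial blood temperature, degC
#' @return a `nir_thermal` object with per-cell vectors `K`, `rho_c`,
#'   `Q_met`, `s` and scalars `T_a`, `c_b`, `rho_b`
#' @export
assign_thermal <- function(phantom, scalp_fraction = 5 / 13,
                           blood_specific_heat = 3600,
                           as_printed = FALSE, overrides = NULL,
                           arterial_temperature = 37) {
  stopifnot(inherits(phantom, "nir_phantom"))
  if (scalp_fraction < 0 || scalp_fraction > 1)
    stop("scalp_fraction must lie in [0, 1]", call. = FALSE)
  tbl <- nir_tables()
  th <- tbl$thermal; pf <- tbl$perfusion
  row_of <- function(df, ts) df[df$tissue == ts, , drop = FALSE]
  base <- lapply(setNames(c("scalp", "skull", "csf", "brain"),
                          c("scalp", "skull", "csf", "brain")),
                 function(ts) {
    t_r <- row_of(th, ts); p_r <- row_of(pf, ts)
    dens <- if (as_printed) t_r$density_kg_per_m3
            else THERMAL_DEFAULTS$density[[ts]]
    list(conductivity = t_r$conductivity_W_per_m_C,
         density = dens,
         specific_heat = THERMAL_DEFAULTS$specific_heat[[ts]],
         metabolic_heat = t_r$metabolic_heat_W_per_m3,
         perfusion_rate = p_r$blood_perfusion_per_s,
         rho_b = p_r$blood_density_kg_per_m3)
  })
  if (as_printed && any(vapply(base, `[[`, numeric(1), "density") <= 1))
    warning("as-printed densities include non-physical values; ",
            "transient solutions will be meaningless", call. = FALSE)
  wmean <- function(field)
    scalp_fraction * base$scalp[[field]] +
      (1 - scalp_fraction) * base$skull[[field]]
  per_tissue <- list(
    scalp_skull = lapply(setNames(names(base$scalp), names(base$scalp)),
                         wmean),
    csf = base$csf, gray_matter = base$brain, white_matter = base$brain)
  for (ts in names(overrides)) {
    if (!ts %in% names(per_tissue))
      stop("unknown tissue in thermal overrides: ", ts, call. = FALSE)
    for (f in names(overrides[[ts]]))
      per_tissue[[ts]][[f]] <- overrides[[ts]][[f]]
  }
  lab <- as.vector(phantom$tissue)
  take <- function(field)
    unname(vapply(per_tissue, `[[`, numeric(1), field)[lab])
  rho_b <- per_tissue$gray_matter$rho_b
  structure(list(K = take("conductivity"),
                 rho_c = take("density") * take("specific_heat"),
                 Q_met = take("metabolic_heat"),
                 s = rho_b * blood_specific_heat * take("perfusion_rate"),
                 T_a = arterial_temperature,
                 c_b = blood_specific_heat, rho_b = rho_b,
                 per_tissue = per_tissue),
            class = "nir_thermal")
}

#' Optical heat source
#'
#' The volumetric heat deposited by light, `Qr = mu_a * phi` (W/m3), the
#' pointwise product of the absorption map and the fluence-rate field.
#' `tissues` optionally restricts the load to the named layers (the study
#' protocol takes the power absorbed by the brain layers as the heat
#' source), zeroing it elsewhere.
#'
#' @param mu_a_map per-cell absorption coefficients, 1/m (e.g.
#'   `properties$mu_a`)
#' @param fluence a solved `nir_fluence`, or a per-cell numeric vector
#' @param tissues optional character vector of tissue labels to keep;
#'   requires `phantom` (taken from `fluence` when available)
#' @param phantom phantom, needed only when `fluence` is a bare vector and
#'   `tissues` is given
#' @return per-cell heat source, W/m3
#' @export
heat_source <- function(mu_a_map, fluence, tissues = NULL,
                        phantom = NULL) {
  if (inherits(fluence, "nir_fluence")) {
    phantom <- fluence$phantom
    phi <- as.vector(fluence$values)
  } else phi <- as.numeric(fluence)
  if (length(mu_a_map) != length(phi))
    stop("absorption map and fluence field have mismatched shapes",
         call. = FALSE)
  q <- mu_a_map * phi
  if (!is.null(tissues)) {
    if (is.null(phantom))
      stop("phantom required to restrict the heat source by tissue",
           call. = FALSE)
    q[!(as.vector(phantom$tissue) %in% tissues)] <- 0
  }
  q
}

bioheat_operator <- function(phantom, thermal, boundary) {
  robin <- list(surface = list(c1 = boundary$h, u_inf = boundary$T_ambient))
  fv_operator(phantom, thermal$K, thermal$s, robin)
}

#' Solve the steady-state Pennes bioheat equation
#'
#' Discrete solution of `-div(K grad T) + rho_b w_b c_b (T - T_a) = Q_met +
#' Qr` with convective loss `-K dT/dn = h (T - T_ambient)` at the scalp
#' surface and insulated lateral and bottom boundaries. Solved twice, with
#' and without the optical load `Qr`, so that the temperature rise
#' `dT = T - baseline` is defined against the self-consistent no-source
#' steady state (surface convection cools the scalp below 37 degC even
#' without light).
#'
#' @param phantom a [build_phantom()] result
#' @param thermal an [assign_thermal()] result
#' @param Qr per-cell optical heat source, W/m3 (from [heat_source()]);
#'   `NULL` for no optical load
#' @param boundary a [surface_boundary()]
#' @return a `nir_temperature` object with arrays `values` and `baseline`
#'   (degC)
#' @export
solve_steady_bioheat <- function(phantom, thermal, Qr = NULL,
                                 boundary = surface_boundary()) {
  stopifnot(inherits(phantom, "nir_phantom"),
            inherits(thermal, "nir_thermal"))
  n <- n_cells(phantom)
  if (is.null(Qr)) Qr <- numeric(n)
  if (length(Qr) != n)
    stop("heat source does not cover every cell", call. = FALSE)
  op <- bioheat_operator(phantom, thermal, boundary)
  if (all(thermal$s == 0) && all(op$bflux$g == 0) && all(thermal$K == 0))
    stop("singular bioheat system: no perfusion, conduction or surface ",
         "exchange", call. = FALSE)
  b0 <- (thermal$Q_met + thermal$s * thermal$T_a) * op$vol + op$b_bc
  sol <- Matrix::solve(op$A, cbind(b0 + Qr * op$vol, b0))
  sol <- as.matrix(sol)
  if (!all(is.finite(sol)))
    stop("bioheat solve failed: singular or ill-posed system",
         call. = FALSE)
  structure(list(values = array(sol[, 1], dim = phantom$dims),
                 baseline = array(sol[, 2], dim = phantom$dims),
                 phantom = phantom, thermal = thermal,
                 boundary = boundary, Qr = Qr),
            class = "nir_temperature")
}

#' @export
print.nir_temperature <- function(x, ...) {
  dT <- as.vector(x$values) - as.vector(x$baseline)
  cat(sprintf(
    "<nir_temperature> %s grid; T in [%.3f, %.3f] degC, max rise %.4g degC\n",
    x$phantom$grid_kind, min(x$values), max(x$values), max(dT)))
  invisible(x)
}

#' Solve the transient Pennes bioheat equation
#'
#' Backward-Euler (unconditionally stable implicit) time stepping of the
#' bioheat equation from an initial state, with the same spatial operator
#' and boundaries as [solve_steady_bioheat()]. The system matrix is
#' factorized once and reused across steps.
#'
#' @inheritParams solve_steady_bioheat
#' @param t_end final time, s
#' @param dt time step, s
#' @param T_init initial temperature per cell, degC; defaults to the
#'   no-source steady state
#' @param save_every store the state every this many steps (default: final
#'   state only)
#' @return a `nir_transient` object with `times`, a `states` matrix (one
#'   column per saved time) and the `final` state
#' @export
solve_transient_bioheat <- function(phantom, thermal, Qr = NULL,
                                    boundary = surface_boundary(),
                                    t_end, dt, T_init = NULL,
                                    save_every = NULL) {
  if (dt <= 0 || t_end <= 0)
    stop("dt and t_end must be positive", call. = FALSE)
  n <- n_cells(phantom)
  if (is.null(Qr)) Qr <- numeric(n)
  op <- bioheat_operator(phantom, thermal, boundary)
  if (is.null(T_init)) {
    base <- solve_steady_bioheat(phantom, thermal, NULL, boundary)
    T_init <- as.vector(base$baseline)
  }
  nsteps <- max(1L, ceiling(t_end / dt))
  if (is.null(save_every)) save_every <- nsteps
  m <- thermal$rho_c * op$vol / dt
  lhs <- op$A + Matrix::Diagonal(n, m)
  fac <- Matrix::Cholesky(Matrix::forceSymmetric(lhs))
  b <- (thermal$Q_met + thermal$s * thermal$T_a + Qr) * op$vol + op$b_bc
  Tn <- T_init
  keep <- seq(save_every, nsteps, by = save_every)
  states <- matrix(NA_real_, n, length(keep))
  k <- 0L
  for (step in seq_len(nsteps)) {
    Tn <- as.numeric(Matrix::solve(fac, b + m * Tn))
    if (step %in% keep) {
      k <- k + 1L
      states[, k] <- Tn
    }
  }
  structure(list(times = keep * dt, states = states,
                 final = array(Tn, dim = phantom$dims),
                 phantom = phantom, dt = dt),
            class = "nir_transient")
}

#' Per-tissue temperature-rise summary
#'
#' Volume-weighted per-tissue maxima, means and averages of a solved
#' temperature field and of its rise above the no-source baseline, plus the
#' on-axis cutline and the surface maximum rise.
#'
#' @param field a `nir_temperature`
#' @param phantom phantom (default: taken from the field)
#' @return a list with elements `per_tissue` (data frame: tissue, max_dT_C,
#'   mean_dT_C, volume_avg_T_C), `surface_max_dT_C`, and `cutline`
#'   (depth_m, tissue, T_C, dT_C)
#' @export
temperature_rise_summary <- function(field, phantom = field$phantom) {
  stopifnot(inherits(field, "nir_temperature"))
  Tv <- as.vector(field$values)
  dT <- Tv - as.vector(field$baseline)
  vol <- cell_volumes(phantom)
  lab <- as.vector(phantom$tissue)
  per <- do.call(rbind, lapply(unique(lab), function(ts) {
    i <- lab == ts
    data.frame(tissue = ts,
               max_dT_C = max(dT[i]),
               mean_dT_C = sum(dT[i] * vol[i]) / sum(vol[i]),
               volume_avg_T_C = sum(Tv[i] * vol[i]) / sum(vol[i]),
               stringsAsFactors = FALSE)
  }))
  surf <- switch(phantom$grid_kind,
    slab_1d = 1L,
    axisymmetric_2d = seq_len(phantom$dims[["nr"]]),
    voxel_3d = seq_len(phantom$dims[["nx"]] * phantom$dims[["ny"]]))
  cutT <- extract_cutline(field$values, phantom = phantom)
  cutB <- extract_cutline(field$baseline, phantom = phantom)
  cut <- data.frame(depth_m = cutT$depth_m, tissue = cutT$tissue,
                    T_C = cutT$value, dT_C = cutT$value - cutB$value,
                    stringsAsFactors = FALSE)
  list(per_tissue = per, surface_max_dT_C = max(dT[surf]), cutline = cut)
}
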