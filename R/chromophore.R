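#' Reduced scattering coefficient
#'
#' `mu_s' = mu_s (1 - g)`, the isotropic-equivalent scattering rate of a
#' forward-peaked scatterer with anisotropy factor `g` (mean cosine of the
#' single-scattering deflection angle).
#'
#' @param mu_s scattering coefficient, 1/m
#' @param g anisotropy factor in `[0, 1]`
#' @return reduced scattering coefficient, 1/m
#' @export
#' @examples
#' reduced_scattering(6781.82, 0.89) # ~746, gray matter at 810 nm
reduced_scattering <- function(mu_s, g) {
  if (any(mu_s < 0)) stop("mu_s must be non-negative", call. = FALSE)
  if (any(g < 0) || any(g > 1))
    stop("anisotropy factor g must lie in [0, 1]", call. = FALSE)
  mu_s * (1 - g)
}

#' Diffusion coefficient of the P1 approximation
#'
#' `D = 1 / (3 (mu_a + mu_s'))`, in meters. Governs fluence spreading in the
#' diffusion equation.
#'
#' @param mu_a absorption coefficient, 1/m
#' @param mu_s_prime reduced scattering coefficient, 1/m
#' @return diffusion coefficient, m
#' @export
diffusion_coefficient <- function(mu_a, mu_s_prime) {
  if (any(mu_a < 0) || any(mu_s_prime < 0))
    stop("optical coefficients must be non-negative", call. = FALSE)
  total <- mu_a + mu_s_prime
  if (any(total <= 0))
    stop("degenerate medium: mu_a + mu_s_prime must be positive",
         call. = FALSE)
  1 / (3 * total)
}

#' Effective attenuation coefficient
#'
#' `mu_eff = sqrt(mu_a / D) = sqrt(3 mu_a (mu_a + mu_s'))`, the asymptotic
#' exponential decay rate of fluence with depth in a homogeneous medium.
#'
#' @inheritParams diffusion_coefficient
#' @return effective attenuation coefficient, 1/m
#' @export
effective_attenuation <- function(mu_a, mu_s_prime) {
  if (any(mu_a < 0) || any(mu_s_prime < 0))
    stop("optical coefficients must be non-negative", call. = FALSE)
  sqrt(3 * mu_a * (mu_a + mu_s_prime))
}

#' Chromophore contribution to tissue absorption
#'
#' Describes one chromophore's concentration in a tissue and the product rule
#' that converts it to an absorption coefficient contribution:
#' \describe{
#'   \item{volume_fraction}{`mu_a = fraction * specific_absorption` where
#'     `specific_absorption` is the pure-substance absorption coefficient
#'     (1/m); used for water (0.75 volume fraction in brain tissue).}
#'   \item{mass_fraction_x_density}{`mu_a = mass_fraction * tissue_density *
#'     specific_absorption` with `specific_absorption` in 1/m per kg/m3; used
#'     for lipid (dry-weight fraction times tissue density).}
#'   \item{blood_volume_fraction_with_SO2}{`mu_a = bvf * (SO2 * mu_a_HbO2 +
#'     (1 - SO2) * mu_a_Hb)` where the two coefficients are whole-blood
#'     values (1/m); used for hemoglobin at a mixed arterio-venous oxygen
#'     saturation.}
#'   \item{molar_concentration}{`mu_a = concentration_mM * specific_absorption`
#'     with `specific_absorption` in 1/m per mM; used for the oxidized and
#'     reduced states of cytochrome c oxidase.}
#' }
#'
#' @param name chromophore label
#' @param kind descriptor kind, one of the four listed above
#' @param ... descriptor parameters, see Details: `fraction` and
#'   `specific_absorption`; or `mass_fraction`, `density`,
#'   `specific_absorption`; or `blood_volume_fraction`, `so2`, `mu_a_oxy`,
#'   `mu_a_deoxy`; or `concentration_mM`, `specific_absorption`
#' @return an object of class `chromophore_contribution` with the computed
#'   `mu_a_contribution` (1/m)
#' @export
#' @examples
#' chromophore_contribution("water", "volume_fraction",
#'                          fraction = 0.75, specific_absorption = 2.213)
chromophore_contribution <- function(name,
                                     kind = c("volume_fraction",
                                              "mass_fraction_x_density",
                                              "blood_volume_fraction_with_SO2",
                                              "molar_concentration"),
                                     ...) {
  kind <- match.arg(kind)
  p <- list(...)
  need <- function(nms) {
    missing <- setdiff(nms, names(p))
    if (length(missing))
      stop("descriptor kind '", kind, "' requires parameter(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  chk_frac <- function(x, what) {
    if (x < 0 || x > 1)
      stop(what, " must lie in [0, 1]", call. = FALSE)
  }
  chk_nonneg <- function(x, what) {
    if (x < 0) stop(what, " must be non-negative", call. = FALSE)
  }
  mu <- switch(kind,
    volume_fraction = {
      need(c("fraction", "specific_absorption"))
      chk_frac(p$fraction, "volume fraction")
      chk_nonneg(p$specific_absorption, "specific absorption")
      p$fraction * p$specific_absorption
    },
    mass_fraction_x_density = {
      need(c("mass_fraction", "density", "specific_absorption"))
      chk_frac(p$mass_fraction, "mass fraction")
      chk_nonneg(p$density, "density")
      chk_nonneg(p$specific_absorption, "specific absorption")
      p$mass_fraction * p$density * p$specific_absorption
    },
    blood_volume_fraction_with_SO2 = {
      need(c("blood_volume_fraction", "so2", "mu_a_oxy", "mu_a_deoxy"))
      chk_frac(p$blood_volume_fraction, "blood volume fraction")
      chk_frac(p$so2, "oxygen saturation")
      chk_nonneg(p$mu_a_oxy, "oxyhemoglobin absorption")
      chk_nonneg(p$mu_a_deoxy, "deoxyhemoglobin absorption")
      p$blood_volume_fraction *
        (p$so2 * p$mu_a_oxy + (1 - p$so2) * p$mu_a_deoxy)
    },
    molar_concentration = {
      need(c("concentration_mM", "specific_absorption"))
      chk_nonneg(p$concentration_mM, "molar concentration")
      chk_nonneg(p$specific_absorption, "specific absorption")
      p$concentration_mM * p$specific_absorption
    })
  structure(list(name = name, kind = kind, params = p,
                 mu_a_contribution = mu),
            class = "chromophore_contribution")
}

#' Absorption contribution of a chromophore
#'
#' @param contribution a [chromophore_contribution()] object
#' @return its absorption coefficient contribution, 1/m
#' @export
chromophore_mu_a <- function(contribution) {
  if (!inherits(contribution, "chromophore_contribution"))
    stop("expected a chromophore_contribution object", call. = FALSE)
  contribution$mu_a_contribution
}

#' Compose whole-tissue absorption from chromophore contributions
#'
#' The tissue absorption coefficient is the sum of the contributions of each
#' chromophore of interest. Accepts `chromophore_contribution` objects or
#' bare non-negative numbers.
#'
#' @param contributions list of contributions (possibly empty)
#' @return total absorption coefficient, 1/m
#' @export
#' @examples
#' compose_tissue_mu_a(list(0.26, 0.04, 14.06, 73, 35.64, 4.25)) # 127.25
compose_tissue_mu_a <- function(contributions) {
  if (length(contributions) == 0L) return(0)
  vals <- vapply(contributions, function(x) {
    if (inherits(x, "chromophore_contribution")) x$mu_a_contribution
    else as.numeric(x)
  }, numeric(1))
  if (any(vals < 0))
    stop("chromophore contributions must be non-negative", call. = FALSE)
  sum(vals)
}

#' @export
print.chromophore_contribution <- function(x, ...) {
  cat(sprintf("<chromophore contribution> %s (%s): mu_a = %.4g 1/m\n",
              x$name, x$kind, x$mu_a_contribution))
  invisible(x)
}
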