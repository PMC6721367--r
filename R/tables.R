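#' Packaged tissue parameter tables
#'
#' Loads the packaged reference tables used throughout the model: whole-tissue
#' optical properties per layer and wavelength, thermal and blood-perfusion
#' parameters per tissue, chromophore-specific absorption coefficients for
#' gray and white matter, and the whole-tissue (all chromophores lumped)
#' absorption coefficients. All values are stored in SI units (1/m, W/m.degC,
#' kg/m3, J/kg.degC, W/m3) exactly as tabulated; no unit conversion is applied
#' on ingestion.
#'
#' @return A named list of data frames:
#' \describe{
#'   \item{optical}{tissue, wavelength_nm, mu_a_per_m, mu_s_prime_per_m}
#'   \item{thermal}{tissue (scalp, skull, csf, brain), conductivity, density,
#'     metabolic heat}
#'   \item{perfusion}{tissue, blood specific heat, perfusion rate, blood
#'     density, metabolic heat}
#'   \item{chromophore}{chromophore, tissue, wavelength_nm, mu_a_per_m}
#'   \item{whole_tissue}{tissue, wavelength_nm, mu_a_per_m}
#' }
#' @export
#' @examples
#' tbl <- nir_tables()
#' subset(tbl$optical, tissue == "gray_matter" & wavelength_nm == 810)
nir_tables <- function() {
  if (!is.null(.table_cache$tables)) return(.table_cache$tables)
  files <- c(optical = "optical_properties.csv",
             thermal = "thermal_properties.csv",
             perfusion = "perfusion_properties.csv",
             chromophore = "chromophore_absorption.csv",
             whole_tissue = "whole_tissue_absorption.csv")
  tables <- lapply(files, function(f) {
    path <- system.file("extdata", f, package = "tnirsim", mustWork = TRUE)
    read.csv(path, stringsAsFactors = FALSE)
  })
  validate_tables(tables)
  .table_cache$tables <- tables
  tables
}

.table_cache <- new.env(parent = emptyenv())

# Integrity check on the packaged fixtures: required rows present, physical
# ranges respected. A failure here means a corrupted installation.
validate_tables <- function(tables) {
  opt <- tables$optical
  if (!all(TISSUES %in% opt$tissue) ||
      !all(c(630, 700, 810) %in% opt$wavelength_nm) ||
      nrow(opt) != 12L)
    stop("optical property table is corrupted: expected 12 rows covering ",
         "four tissues at 630/700/810 nm", call. = FALSE)
  if (any(opt$mu_a_per_m < 0) || any(opt$mu_s_prime_per_m < 0))
    stop("optical property table is corrupted: negative coefficients",
         call. = FALSE)
  chr <- tables$chromophore
  if (nrow(chr) != 36L || !all(CHROMOPHORES %in% chr$chromophore) ||
      any(chr$mu_a_per_m < 0))
    stop("chromophore absorption table is corrupted", call. = FALSE)
  for (nm in c("scalp", "skull", "csf", "brain")) {
    if (!nm %in% tables$thermal$tissue || !nm %in% tables$perfusion$tissue)
      stop("thermal/perfusion tables are corrupted: missing tissue ", nm,
           call. = FALSE)
  }
  invisible(tables)
}

#' Look up a packaged parameter value
#'
#' Convenience accessor over [nir_tables()]. `quantity` selects the table and
#' column: `"mu_a"` and `"mu_s_prime"` read the whole-tissue optical table,
#' `"whole_tissue_mu_a"` the lumped absorption table, and a chromophore name
#' (e.g. `"deoxyhemoglobin"`) its per-tissue contribution.
#'
#' @param tissue tissue label (`scalp_skull`, `csf`, `gray_matter`,
#'   `white_matter`)
#' @param wavelength_nm wavelength in nanometers (630, 700 or 810)
#' @param quantity quantity name, see Details
#' @return a single numeric value in 1/m
#' @export
#' @examples
#' nir_lookup("gray_matter", 810, "whole_tissue_mu_a")
#' nir_lookup("csf", 700, "mu_s_prime")
nir_lookup <- function(tissue, wavelength_nm, quantity) {
  tbl <- nir_tables()
  tissue <- match.arg(tissue, TISSUES)
  pick <- function(df, col) {
    row <- df[df$tissue == tissue & df$wavelength_nm == wavelength_nm, ]
    if (nrow(row) != 1L)
      stop("no tabulated value for ", tissue, " at ", wavelength_nm, " nm",
           call. = FALSE)
    row[[col]]
  }
  if (quantity == "mu_a") return(pick(tbl$optical, "mu_a_per_m"))
  if (quantity == "mu_s_prime") return(pick(tbl$optical, "mu_s_prime_per_m"))
  if (quantity == "whole_tissue_mu_a")
    return(pick(tbl$whole_tissue, "mu_a_per_m"))
  if (quantity %in% CHROMOPHORES) {
    df <- tbl$chromophore
    row <- df[df$chromophore == quantity & df$tissue == tissue &
                df$wavelength_nm == wavelength_nm, ]
    if (nrow(row) != 1L)
      stop("no ", quantity, " contribution tabulated for ", tissue, " at ",
           wavelength_nm, " nm", call. = FALSE)
    return(row$mu_a_per_m)
  }
  stop("unknown quantity: ", quantity, call. = FALSE)
}
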