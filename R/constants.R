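#' Physical constants and model coefficients
#'
#' All internal physics is carried out in CGS units (cm, g, s) at airway-lumen
#' ("body") conditions. The defaults ship as a human-readable YAML file under
#' `inst/extdata/constants.yaml` so that every results file can echo the exact
#' constants a run used. `default_constants()` reads that file (cached per
#' session); `read_constants()` reads any user-supplied override file with the
#' same structure.
#'
#' The constants file holds four groups:
#' \describe{
#'   \item{gas}{temperature (K), dynamic air viscosity (g/(cm s)), particle
#'     mean free path (µm) and gravitational acceleration (cm/s²) at body
#'     conditions, plus the Boltzmann constant in erg/K.}
#'   \item{inhalability}{coefficients `a`, `b` of the rat inhalability curve
#'     `IF(d) = 1 - 1/(1 + exp(a - b log(d)))` (aerodynamic diameter in µm).}
#'   \item{extrathoracic}{per species/route coefficients `a`, `b` of the
#'     empirical head-filtration efficiency `1 - exp(-a (d_ae^2 Q)^b)` with
#'     `d_ae` in µm and `Q` in cm³/s, and the extrathoracic dead-space volume
#'     (cm³) per species.}
#'   \item{lung}{total alveolar (expanding) volume per species (cm³) used to
#'     apportion the tidal air among alveolated airways.}
#' }
#'
#' @param path Path to a YAML constants file.
#' @return A nested list of constants.
#' @examples
#' cst <- default_constants()
#' cst$gas$temperature_K
#' @export
default_constants <- function() {
  if (is.null(.respdose_env$constants)) {
    path <- system.file("extdata", "constants.yaml", package = "respdose")
    if (path == "") { # not installed yet (e.g. pkgload); fall back to source
      path <- file.path("inst", "extdata", "constants.yaml")
    }
    .respdose_env$constants <- read_constants(path)
  }
  .respdose_env$constants
}

.respdose_env <- new.env(parent = emptyenv())

#' @rdname default_constants
#' @export
read_constants <- function(path) {
  if (!file.exists(path)) {
    stop("constants file not found: ", path, call. = FALSE)
  }
  cst <- yaml::read_yaml(path)
  needed <- c("gas", "inhalability", "extrathoracic", "lung")
  missing <- setdiff(needed, names(cst))
  if (length(missing)) {
    stop("constants file lacks section(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cst
}

#' Gas conditions at airway-lumen temperature
#'
#' Bundles the physical state of the carrier gas used by the transport
#' coefficient functions. Defaults are body conditions (310 K).
#'
#' @param temperature_K Absolute temperature in K.
#' @param viscosity Dynamic viscosity of air in g/(cm s).
#' @param mean_free_path_um Mean free path of air molecules in µm.
#' @param gravity Gravitational acceleration in cm/s².
#' @return An object of class `gas_conditions`.
#' @examples
#' gas_conditions()
#' @export
gas_conditions <- function(temperature_K = NULL, viscosity = NULL,
                           mean_free_path_um = NULL, gravity = NULL) {
  g <- default_constants()$gas
  x <- list(
    temperature_K     = temperature_K %||% g$temperature_K,
    viscosity         = viscosity %||% g$viscosity_g_cm_s,
    mean_free_path_um = mean_free_path_um %||% g$mean_free_path_um,
    gravity           = gravity %||% g$gravity_cm_s2,
    boltzmann         = g$boltzmann_erg_K
  )
  vals <- unlist(x)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("gas conditions must be finite and positive", call. = FALSE)
  }
  structure(x, class = "gas_conditions")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gas_conditions <- function(x, ...) {
  cat("Gas conditions (CGS):\n")
  cat(sprintf("  T = %g K, mu = %g g/(cm s), lambda = %g um, g = %g cm/s2\n",
              x$temperature_K, x$viscosity, x$mean_free_path_um, x$gravity))
  invisible(x)
}
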