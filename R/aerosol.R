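#' Exposure-atmosphere aerosol specification
#'
#' Describes a lognormal dust aerosol by its mass median aerodynamic diameter
#' (MMAD), geometric standard deviation (GSD), particle density and airborne
#' mass concentration.
#'
#' @param mmad Mass median aerodynamic diameter, µm (> 0).
#' @param gsd Geometric standard deviation, dimensionless (>= 1). `gsd = 1`
#'   denotes a monodisperse aerosol.
#' @param density Particle density, g/cm³ (> 0).
#' @param concentration Airborne mass concentration, mg/m³ (>= 0).
#' @return An object of class `aerosol_spec`.
#' @examples
#' aerosol_spec(mmad = 2.74, gsd = 2.8, concentration = 5212)
#' @export
aerosol_spec <- function(mmad, gsd, density = 1, concentration = 0) {
  vals <- c(mmad = mmad, gsd = gsd, density = density,
            concentration = concentration)
  if (any(!is.finite(vals))) {
    stop("aerosol_spec fields must be finite numbers", call. = FALSE)
  }
  if (mmad <= 0) stop("mmad must be > 0", call. = FALSE)
  if (gsd < 1) stop("gsd must be >= 1", call. = FALSE)
  if (density <= 0) stop("density must be > 0", call. = FALSE)
  if (concentration < 0) stop("concentration must be >= 0", call. = FALSE)
  structure(list(mmad = mmad, gsd = gsd, density = density,
                 concentration = concentration),
            class = "aerosol_spec")
}

#' @export
print.aerosol_spec <- function(x, ...) {
  cat(sprintf("Aerosol: MMAD %g um, GSD %g, density %g g/cm3, %g mg/m3\n",
              x$mmad, x$gsd, x$density, x$concentration))
  invisible(x)
}

#' Discretize a lognormal aerosol mass distribution into size bins
#'
#' Splits the lognormal mass distribution defined by MMAD and GSD into
#' geometrically spaced aerodynamic-diameter bins spanning
#' `mmad * gsd^(-span_sigmas)` to `mmad * gsd^(+span_sigmas)`. Each bin carries
#' the lognormal mass fraction falling between its edges, renormalized so the
#' fractions sum to exactly 1, and is represented by the geometric midpoint of
#' its edges. A GSD of 1 collapses to a single bin at the MMAD carrying all
#' mass.
#'
#' @param spec An [aerosol_spec()].
#' @param n_bins Number of bins (>= 1). Default 1000.
#' @param span_sigmas Half-width of the diameter range in units of `log(gsd)`
#'   (> 0). Default 4.
#' @return A data.frame with columns `d_ae` (µm) and `mass_fraction`.
#' @examples
#' b <- discretize_lognormal(aerosol_spec(2.74, 2.8))
#' sum(b$mass_fraction)
#' @export
discretize_lognormal <- function(spec, n_bins = 1000, span_sigmas = 4) {
  stopifnot(inherits(spec, "aerosol_spec"))
  if (!is.finite(n_bins) || n_bins < 1) stop("n_bins must be >= 1", call. = FALSE)
  if (!is.finite(span_sigmas) || span_sigmas <= 0) {
    stop("span_sigmas must be > 0", call. = FALSE)
  }
  n_bins <- as.integer(n_bins)
  if (spec$gsd == 1) {
    return(data.frame(d_ae = spec$mmad, mass_fraction = 1))
  }
  lsg <- log(spec$gsd)
  edges <- exp(seq(log(spec$mmad) - span_sigmas * lsg,
                   log(spec$mmad) + span_sigmas * lsg,
                   length.out = n_bins + 1L))
  cdf <- stats::pnorm(log(edges / spec$mmad) / lsg)
  w <- diff(cdf)
  w <- w / sum(w)
  data.frame(d_ae = sqrt(edges[-1L] * edges[-(n_bins + 1L)]),
             mass_fraction = w)
}

#' Cunningham slip correction factor
#'
#' `C(d) = 1 + (lambda/d) * (2.514 + 0.800 * exp(-0.55 * d/lambda))`, always
#' >= 1 and monotonically decreasing in particle diameter; approaches 1 in the
#' continuum limit.
#'
#' @param d Particle diameter, µm (> 0). Vectorized.
#' @param gas A [gas_conditions()] object.
#' @return Dimensionless slip correction factor(s).
#' @examples
#' slip_correction(1, gas_conditions(mean_free_path_um = 0.0665))
#' @export
slip_correction <- function(d, gas = gas_conditions()) {
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop("particle diameter must be finite and > 0", call. = FALSE)
  }
  lam <- gas$mean_free_path_um
  1 + (lam / d) * (2.514 + 0.800 * exp(-0.55 * d / lam))
}

#' Terminal settling velocity of an aerodynamic-diameter particle
#'
#' Stokes settling velocity under the aerodynamic-diameter convention
#' (unit density 1 g/cm³):
#' `v_ts = rho0 * d_ae^2 * g * C(d_ae) / (18 * mu)`.
#'
#' @param d_ae Aerodynamic diameter, µm (> 0). Vectorized.
#' @inheritParams slip_correction
#' @return Settling velocity in cm/s.
#' @examples
#' settling_velocity(1)
#' @export
settling_velocity <- function(d_ae, gas = gas_conditions()) {
  if (any(!is.finite(d_ae)) || any(d_ae <= 0)) {
    stop("aerodynamic diameter must be finite and > 0", call. = FALSE)
  }
  d_cm <- d_ae * 1e-4
  1 * d_cm^2 * gas$gravity * slip_correction(d_ae, gas) / (18 * gas$viscosity)
}

#' Brownian diffusion coefficient (Stokes–Einstein)
#'
#' `D = k_B * T * C(d) / (3 * pi * mu * d)`, strictly decreasing in particle
#' diameter.
#'
#' @param d Particle diameter, µm (> 0). Vectorized.
#' @inheritParams slip_correction
#' @return Diffusion coefficient in cm²/s.
#' @examples
#' diffusion_coefficient(1)
#' @export
diffusion_coefficient <- function(d, gas = gas_conditions()) {
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop("particle diameter must be finite and > 0", call. = FALSE)
  }
  d_cm <- d * 1e-4
  gas$boltzmann * gas$temperature_K * slip_correction(d, gas) /
    (3 * pi * gas$viscosity * d_cm)
}

#' Convert aerodynamic to physical diameter
#'
#' `d_physical = d_ae / sqrt(rho / rho0)` with `rho0 = 1` g/cm³. With unit
#' particle density the two coincide.
#'
#' @param d_ae Aerodynamic diameter, µm.
#' @param density Particle density, g/cm³.
#' @return Physical diameter, µm.
#' @export
aerodynamic_to_physical <- function(d_ae, density) {
  if (density <= 0) stop("density must be > 0", call. = FALSE)
  d_ae / sqrt(density)
}

#' Species-specific inhalability of an aerosol
#'
#' Inhalability is the fraction of airborne particles that enters the
#' respiratory tract at all. For humans it is 1 for particles up to 10 µm
#' aerodynamic diameter (all aerosols considered here). For rats it decreases
#' with particle size; the curve used is logistic in `log(d_ae)`,
#' `IF(d) = 1 - 1/(1 + exp(a - b log d))`, with coefficients frozen in the
#' constants file (see [default_constants()]), and approaches 1 as `d_ae -> 0`.
#'
#' `inhalable_fraction()` returns the mass-weighted mean inhalability of a
#' discretized aerosol; `inhalability_curve()` evaluates the per-diameter
#' curve.
#'
#' @param spec An [aerosol_spec()].
#' @param species `"rat"` or `"human"`.
#' @param bins Size bins from [discretize_lognormal()]; computed from `spec`
#'   when omitted.
#' @param constants Constants list, see [default_constants()].
#' @return Mass-weighted inhalable fraction in (0, 1].
#' @examples
#' inhalable_fraction(aerosol_spec(2.74, 2.8), "rat")
#' inhalable_fraction(aerosol_spec(2.74, 2.8), "human")
#' @export
inhalable_fraction <- function(spec, species, bins = NULL,
                               constants = default_constants()) {
  species <- match.arg(species, c("rat", "human"))
  stopifnot(inherits(spec, "aerosol_spec"))
  if (is.null(bins)) bins <- discretize_lognormal(spec)
  if (abs(sum(bins$mass_fraction) - 1) > 1e-9) {
    stop("bins must be normalized", call. = FALSE)
  }
  iff <- inhalability_curve(bins$d_ae, species, constants)
  sum(bins$mass_fraction * iff)
}

#' @rdname inhalable_fraction
#' @param d_ae Aerodynamic diameter(s), µm.
#' @export
inhalability_curve <- function(d_ae, species, constants = default_constants()) {
  species <- match.arg(species, c("rat", "human"))
  if (any(!is.finite(d_ae)) || any(d_ae <= 0)) {
    stop("aerodynamic diameter must be finite and > 0", call. = FALSE)
  }
  if (species == "human") {
    # human inhalability only declines above ~10 um MMAD; unity here
    rep(1, length(d_ae))
  } else {
    cf <- constants$inhalability$rat
    1 - 1 / (1 + exp(cf$a - cf$b * log(d_ae)))
  }
}

#' Calibrate the rat inhalability curve
#'
#' Solves for the logistic coefficients `(a, b)` such that two reference
#' aerosols attain prescribed mass-weighted inhalable fractions. Used once to
#' produce the coefficients frozen in the shipped constants file; exported for
#' transparency and re-derivation.
#'
#' @param targets A data.frame with columns `mmad`, `gsd`, `fraction`.
#' @param n_bins Bins used for the mass weighting.
#' @return Named list with elements `a` and `b`.
#' @export
calibrate_inhalability <- function(targets, n_bins = 1000) {
  stopifnot(nrow(targets) == 2)
  binsets <- lapply(seq_len(2), function(i)
    discretize_lognormal(aerosol_spec(targets$mmad[i], targets$gsd[i]), n_bins))
  obj <- function(p) {
    got <- vapply(binsets, function(b) {
      iff <- 1 - 1 / (1 + exp(p[1] - p[2] * log(b$d_ae)))
      sum(b$mass_fraction * iff)
    }, numeric(1))
    sum((got - targets$fraction)^2)
  }
  fit <- stats::optim(c(3, 2), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  if (fit$value > 1e-10) {
    warning("inhalability calibration residual ", format(fit$value))
  }
  list(a = fit$par[1], b = fit$par[2])
}
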