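#' Breathing physiology of an exposure scenario
#'
#' @param tidal_volume_ml Tidal volume, mL/breath (> 0).
#' @param frequency_bpm Breathing frequency, breaths/min (> 0).
#' @param route Breathing route: `"nasal"`, `"oral"` or `"nose-only"`.
#' @param inspiratory_fraction Fraction of the breath period spent inhaling.
#' @param pause_fraction Fraction of the breath period spent in the
#'   end-inspiratory pause. The expiratory fraction is the remainder; all three
#'   must sum to 1 with both stated fractions in \\[0, 1\\]. The default
#'   square-wave cycle is half inspiration, half expiration, no pause.
#' @return An object of class `ventilation_pattern`.
#' @examples
#' ventilation_pattern(625, 12, "nasal")
#' @export
ventilation_pattern <- function(tidal_volume_ml, frequency_bpm, route,
                                inspiratory_fraction = 0.5,
                                pause_fraction = 0) {
  route <- match.arg(route, c("nasal", "oral", "nose-only"))
  if (!is.finite(tidal_volume_ml) || tidal_volume_ml <= 0) {
    stop("tidal_volume_ml must be > 0", call. = FALSE)
  }
  if (!is.finite(frequency_bpm) || frequency_bpm <= 0) {
    stop("frequency_bpm must be > 0", call. = FALSE)
  }
  expf <- 1 - inspiratory_fraction - pause_fraction
  if (inspiratory_fraction <= 0 || inspiratory_fraction > 1 ||
      pause_fraction < 0 || pause_fraction > 1 || expf <= 0) {
    stop("breath-phase fractions must lie in [0, 1] and sum to 1 with a ",
         "positive inspiratory and expiratory phase", call. = FALSE)
  }
  structure(list(tidal_volume_ml = tidal_volume_ml,
                 frequency_bpm = frequency_bpm, route = route,
                 inspiratory_fraction = inspiratory_fraction,
                 pause_fraction = pause_fraction,
                 expiratory_fraction = expf),
            class = "ventilation_pattern")
}

#' Full exposure scenario
#'
#' Binds an aerosol, a breathing pattern, an airway tree and an exposure
#' duration into one runnable scenario (one exposure condition).
#'
#' @param aerosol An [aerosol_spec()].
#' @param ventilation A [ventilation_pattern()].
#' @param tree An [airway_tree()].
#' @param duration_h Exposure duration in hours (> 0).
#' @param inhalability_on Apply the species inhalability correction? Standard
#'   practice: on for rats (micron aerosols are not fully inhalable by rats),
#'   off for humans.
#' @param gas A [gas_conditions()] object.
#' @param label Free-text scenario label used in reports.
#' @return An object of class `exposure_scenario`.
#' @export
exposure_scenario <- function(aerosol, ventilation, tree, duration_h = 4,
                              inhalability_on = tree$species == "rat",
                              gas = gas_conditions(), label = NULL) {
  stopifnot(inherits(aerosol, "aerosol_spec"),
            inherits(ventilation, "ventilation_pattern"),
            inherits(tree, "airway_tree"))
  if (!is.finite(duration_h) || duration_h <= 0) {
    stop("duration_h must be > 0", call. = FALSE)
  }
  if (is.null(label)) {
    label <- sprintf("%s_%s_%gmgm3", tree$species, ventilation$route,
                     aerosol$concentration)
  }
  structure(list(aerosol = aerosol, ventilation = ventilation, tree = tree,
                 duration_h = duration_h, inhalability_on = inhalability_on,
                 gas = gas, label = label),
            class = "exposure_scenario")
}

#' @export
print.exposure_scenario <- function(x, ...) {
  cat(sprintf("Exposure scenario '%s':\n", x$label))
  print(x$aerosol)
  cat(sprintf("  %s breathing, V_T %g mL at %g/min, %g h, inhalability %s\n",
              x$ventilation$route, x$ventilation$tidal_volume_ml,
              x$ventilation$frequency_bpm, x$duration_h,
              if (x$inhalability_on) "on" else "off"))
  invisible(x)
}

#' The five standard acute limit-test scenarios
#'
#' Returns the five exposure conditions of the acute 4-h study design: three
#' rat nose-only exposures (5212 mg/m³ at MMAD 2.74 µm / GSD 2.8;
#' 2000 and 1084 mg/m³ at MMAD 2.01 µm / GSD 3.0) with rat resting physiology
#' (tidal volume 2.12614 mL scaled to 300 g body weight, 166 breaths/min) and
#' inhalability correction on, plus human nasal and oral breathing at
#' 5212 mg/m³ (625 mL, 12 breaths/min, inhalability correction off). Particle
#' density 1 g/cm³ and 4-h duration throughout.
#'
#' @param rat_tree Airway tree used for the rat scenarios. Defaults to the
#'   synthetic monopodial surrogate with `seed`.
#' @param human_tree Airway tree used for the human scenarios. Defaults to
#'   [builtin_human_tree()].
#' @param seed Seed for the default rat surrogate tree.
#' @return List of five [exposure_scenario()] objects.
#' @export
scenario_fixtures <- function(rat_tree = NULL, human_tree = NULL, seed = 1L) {
  if (is.null(rat_tree)) {
    rat_tree <- generate_monopodial_tree(tree_gen_params(seed = seed))
  }
  if (is.null(human_tree)) human_tree <- builtin_human_tree()
  rat_vent <- ventilation_pattern(2.12614, 166, "nose-only")
  hum_vent_nasal <- ventilation_pattern(625, 12, "nasal")
  hum_vent_oral <- ventilation_pattern(625, 12, "oral")
  list(
    rat_5212 = exposure_scenario(
      aerosol_spec(2.74, 2.8, 1.0, 5212), rat_vent, rat_tree,
      inhalability_on = TRUE, label = "rat_nose-only_5212mgm3"),
    rat_2000 = exposure_scenario(
      aerosol_spec(2.01, 3.0, 1.0, 2000), rat_vent, rat_tree,
      inhalability_on = TRUE, label = "rat_nose-only_2000mgm3"),
    rat_1084 = exposure_scenario(
      aerosol_spec(2.01, 3.0, 1.0, 1084), rat_vent, rat_tree,
      inhalability_on = TRUE, label = "rat_nose-only_1084mgm3"),
    human_nasal = exposure_scenario(
      aerosol_spec(2.74, 2.8, 1.0, 5212), hum_vent_nasal, human_tree,
      inhalability_on = FALSE, label = "human_nasal_5212mgm3"),
    human_oral = exposure_scenario(
      aerosol_spec(2.74, 2.8, 1.0, 5212), hum_vent_oral, human_tree,
      inhalability_on = FALSE, label = "human_oral_5212mgm3")
  )
}

#' Read and write scenario configuration files
#'
#' Scenario files are YAML (or JSON) with fields mirroring the exposure-table
#' column names: `species`, `route`, `tidal_volume_ml`, `frequency_bpm`,
#' `concentration_mg_m3`, `mmad_um`, `gsd`, `density_g_cm3`,
#' `inhalability`, `duration_h`, and optionally `label`,
#' `inspiratory_fraction`, `pause_fraction`. The airway tree is supplied
#' separately (it has its own file format).
#'
#' @param path Scenario file (`.yaml`/`.yml` or `.json`).
#' @param tree An `airway_tree` to bind into the scenario.
#' @param gas Gas conditions.
#' @return An [exposure_scenario()].
#' @export
read_scenario <- function(path, tree, gas = gas_conditions()) {
  if (!file.exists(path)) stop("scenario file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  need <- c("species", "route", "tidal_volume_ml", "frequency_bpm",
            "concentration_mg_m3", "mmad_um", "gsd")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    stop("scenario file lacks field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!identical(cfg$species, tree$species)) {
    stop(sprintf("scenario species '%s' does not match tree species '%s'",
                 cfg$species, tree$species), call. = FALSE)
  }
  exposure_scenario(
    aerosol_spec(cfg$mmad_um, cfg$gsd, cfg$density_g_cm3 %||% 1,
                 cfg$concentration_mg_m3),
    ventilation_pattern(cfg$tidal_volume_ml, cfg$frequency_bpm, cfg$route,
                        cfg$inspiratory_fraction %||% 0.5,
                        cfg$pause_fraction %||% 0),
    tree,
    duration_h = cfg$duration_h %||% 4,
    inhalability_on = cfg$inhalability %||% (cfg$species == "rat"),
    gas = gas,
    label = cfg$label %||% NULL)
}

#' @rdname read_scenario
#' @param scenario An `exposure_scenario` to serialize (without its tree).
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  cfg <- list(
    label = scenario$label,
    species = scenario$tree$species,
    route = scenario$ventilation$route,
    tidal_volume_ml = scenario$ventilation$tidal_volume_ml,
    frequency_bpm = scenario$ventilation$frequency_bpm,
    inspiratory_fraction = scenario$ventilation$inspiratory_fraction,
    pause_fraction = scenario$ventilation$pause_fraction,
    concentration_mg_m3 = scenario$aerosol$concentration,
    mmad_um = scenario$aerosol$mmad,
    gsd = scenario$aerosol$gsd,
    density_g_cm3 = scenario$aerosol$density,
    inhalability = scenario$inhalability_on,
    duration_h = scenario$duration_h)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}
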