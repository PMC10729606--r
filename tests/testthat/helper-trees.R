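# Small airway trees built in code for engine and obstruction tests.

# Symmetric dichotomous toy lung: n_tb conducting + n_pul pulmonary
# generations, one row per generation, alveolar volume split equally across
# pulmonary generations.
small_symmetric_tree <- function(n_tb = 4, n_pul = 2, alveolar_volume = 300,
                                 species = "human") {
  n <- n_tb + n_pul
  gen <- seq_len(n)
  d0 <- if (species == "human") 0.5 else 0.25
  diameter <- d0 * 0.72^(gen - 1)
  len <- diameter * 2.5
  region <- c(rep("TB", n_tb), rep("PUL", n_pul))
  mult <- 2^(gen - 1)
  lum <- pi / 4 * diameter^2 * len
  alv <- ifelse(region == "PUL", alveolar_volume / n_pul / mult, 0)
  distal <- numeric(n)
  for (g in rev(gen)) {
    distal[g] <- lum[g] + alv[g] + if (g < n) 2 * distal[g + 1] else 0
  }
  airway_tree(
    data.frame(id = gen, parent_id = c(NA, gen[-n]), generation = gen,
               region = region, length_cm = len, diameter_cm = diameter,
               branching_angle_deg = c(0, rep(35, n - 1)),
               gravity_angle_deg = c(0, 30, rep(50, n - 2)),
               multiplicity = mult, lobe = NA_character_,
               distal_volume_cm3 = distal),
    species = species, representation = "symmetric",
    provenance = "test fixture")
}

# Three-airway single path (one airway per generation, multiplicity 1),
# used by the hand-unrolled serial-filtration oracle.
toy_path_tree <- function() {
  len <- c(2.3, 0.8, 0.5)
  dia <- c(0.26, 0.15, 0.08)
  lum <- pi / 4 * dia^2 * len
  alv <- c(0, 0, 6)
  distal <- c(lum[1] + lum[2] + lum[3] + 6, lum[2] + lum[3] + 6, lum[3] + 6)
  airway_tree(
    data.frame(id = 1:3, parent_id = c(NA, 1, 2), generation = 1:3,
               region = c("TB", "TB", "PUL"), length_cm = len,
               diameter_cm = dia, branching_angle_deg = c(0, 40, 60),
               gravity_angle_deg = c(10, 45, 60), multiplicity = 1,
               lobe = NA_character_, distal_volume_cm3 = distal),
    species = "rat", representation = "asymmetric",
    provenance = "test fixture")
}

human_reference_scenario <- function(route) {
  exposure_scenario(aerosol_spec(2.74, 2.8, 1.0, 5212),
                    ventilation_pattern(625, 12, route),
                    builtin_human_tree(),
                    inhalability_on = FALSE,
                    label = paste0("human_", route))
}
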