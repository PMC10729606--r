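test_that("airway flows: tracheal value, halving, and conservation", {
  tr <- builtin_human_tree()
  q <- airway_flows(tr, ventilation_pattern(625, 12, "nasal"))
  expect_equal(q[[1]], 250) # 625 mL / (0.5 * 5 s)
  # symmetric tree: every child flow is half the parent's
  expect_equal(q[-1] / q[-24], rep(0.5, 23), tolerance = 1e-12,
               ignore_attr = TRUE)
  # multiplicity-weighted conservation to the leaves
  a <- tr$airways
  expect_equal(sum(q[a$generation == 24] * a$multiplicity[a$generation == 24]),
               q[[1]], tolerance = 1e-9)
  # asymmetric tree conserves flow at every branch
  rt <- generate_monopodial_tree(tree_gen_params(seed = 2,
                                                 termination_diameter_cm = 0.05))
  qr <- airway_flows(rt, ventilation_pattern(2.12614, 166, "nose-only"))
  ar <- rt$airways
  pidx <- match(ar$parent_id, ar$id)
  kid_sums <- tapply(qr, pidx, sum)
  inner <- as.integer(names(kid_sums))
  expect_equal(as.numeric(kid_sums), unname(qr[inner]), tolerance = 1e-9)
})

test_that("single-airway efficiencies obey their limiting behavior", {
  aw <- list(diameter_cm = 0.3, length_cm = 1, branching_angle_deg = 35,
             gravity_angle_deg = 50)
  straight <- modifyList(aw, list(branching_angle_deg = 0))
  vertical <- modifyList(aw, list(gravity_angle_deg = 0))
  b <- function(d) list(d_ae = d)
  expect_equal(efficiency_impaction(straight, 100, b(5)), 0)
  expect_equal(efficiency_sedimentation(vertical, 100, b(5)), 0)
  # impaction monotone in particle size and flow
  expect_gt(efficiency_impaction(aw, 100, b(4)),
            efficiency_impaction(aw, 100, b(1)))
  expect_gt(efficiency_impaction(aw, 200, b(4)),
            efficiency_impaction(aw, 100, b(4)))
  expect_lt(efficiency_impaction(aw, 100, b(0.001)), 1e-4)
  # sedimentation grows with residence length
  long <- modifyList(aw, list(length_cm = 2))
  expect_gt(efficiency_sedimentation(long, 100, b(5)),
            efficiency_sedimentation(aw, 100, b(5)))
  # diffusion: monotone in diffusivity, saturates for tiny particles at
  # long residence
  expect_gt(efficiency_diffusion(aw, 100, b(0.01)),
            efficiency_diffusion(aw, 100, b(1)))
  slow <- list(diameter_cm = 0.01, length_cm = 50, branching_angle_deg = 0,
               gravity_angle_deg = 0)
  expect_equal(efficiency_diffusion(slow, 1e-4, b(0.001)), 1, tolerance = 1e-3)
  for (f in list(efficiency_impaction, efficiency_sedimentation,
                 efficiency_diffusion)) {
    v <- f(aw, 150, b(3))
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
})

test_that("extrathoracic model reproduces the calibrated head fractions", {
  b <- discretize_lognormal(aerosol_spec(2.74, 2.8))
  eta_n <- extrathoracic_deposition("nasal", "human", 250, b$d_ae)
  expect_equal(sum(b$mass_fraction * eta_n), 0.513, tolerance = 1e-6)
  eta_o <- extrathoracic_deposition("oral", "human", 250, b$d_ae)
  expect_equal(sum(b$mass_fraction * eta_o), 0.143, tolerance = 1e-6)
  # fine-particle limit and monotonicity in the impaction parameter
  expect_lt(extrathoracic_deposition("nasal", "human", 250, 0.001), 1e-3)
  expect_true(all(diff(extrathoracic_deposition("nasal", "human", 250,
                                                c(1, 2, 5, 10))) > 0))
  expect_error(extrathoracic_deposition("nasal", "rat", 10, 2), "no extrathoracic")
})

test_that("serial filtration matches a hand-unrolled oracle on a toy path", {
  tree <- toy_path_tree()
  vent <- ventilation_pattern(1.5, 100, "nose-only")
  spec <- aerosol_spec(3, 1.8, 1, 1000)
  sc <- exposure_scenario(spec, vent, tree, duration_h = 4,
                          inhalability_on = TRUE, label = "toy")
  res <- run_deposition(sc, n_bins = 2, span_sigmas = 2)

  # ---- independent hand-unrolled computation -------------------------------
  cst <- default_constants()
  gas <- gas_conditions()
  bins <- discretize_lognormal(spec, 2, 2)
  iff <- inhalability_curve(bins$d_ae, "rat")
  w <- bins$mass_fraction * iff
  if_mass <- sum(w)
  w <- w / if_mass

  a <- tree$airways
  lum <- pi / 4 * a$diameter_cm^2 * a$length_cm
  alv_d <- c(6, 6, 6) # distal alveolar volume per airway
  v_t <- 1.5
  t_breath <- 60 / 100
  t_insp <- t_exp <- t_breath / 2
  q <- v_t / t_insp * c(1, 1, 1)
  u <- q / (pi / 4 * a$diameter_cm^2)
  v_et <- cst$extrathoracic$dead_space_cm3$rat

  rsum <- c(v_et / 6, v_et / 6 + lum[1] / 6, v_et / 6 + lum[1] / 6 + lum[2] / 6)
  fresh <- pmax(0, alv_d * (v_t / 6 - rsum))
  ratio <- c(fresh[1] / v_t, fresh[2] / fresh[1], fresh[3] / fresh[2])
  passed <- c(fresh[2] / fresh[1], fresh[3] / fresh[2], 0)

  transit_in <- c(0, a$length_cm[1] / u[1],
                  a$length_cm[1] / u[1] + a$length_cm[2] / u[2])
  rt <- transit_in * 2
  frac1 <- pmin(1, rsum * 6 / v_t)
  frac2 <- pmin(1, (rsum + lum / alv_d) * 6 / v_t)
  frac2[3] <- 1 # leaf holds the earliest air
  t1 <- pmax(0, t_breath * frac1 - rt)
  t2 <- pmax(t1, t_breath * pmax(frac2, frac1) - rt)

  alv_own <- c(0, 0, 6)
  w_alv <- alv_own / (alv_own + lum)
  d_alv <- cst$lung$alveolus_diameter_cm$rat
  inv_d <- (1 - w_alv) / a$diameter_cm + w_alv / d_alv
  inv_r2 <- (1 - w_alv) / (a$diameter_cm / 2)^2 + w_alv / (d_alv / 2)^2

  dep_hand <- matrix(0, 3, 2)
  head_hand <- exh_hand <- 0
  for (k in 1:2) {
    d <- bins$d_ae[k]
    eta_et <- extrathoracic_deposition("nose-only", "rat", q[1], d)
    eta <- numeric(3)
    for (j in 1:3) {
      aw <- as.list(a[j, ])
      ei <- efficiency_impaction(aw, q[j], list(d_ae = d), gas)
      es <- efficiency_sedimentation(aw, q[j], list(d_ae = d), gas)
      ed <- efficiency_diffusion(aw, q[j], list(d_ae = d), gas)
      eta[j] <- 1 - (1 - ei) * (1 - es) * (1 - ed)
    }
    k_res <- (4 / pi) * settling_velocity(d, gas) *
      sin(a$gravity_angle_deg * pi / 180) * inv_d +
      5.78 * diffusion_coefficient(d, gas) * inv_r2
    surv <- ifelse(k_res * (t2 - t1) < 1e-10, exp(-k_res * (t1 + t2) / 2),
                   (exp(-k_res * t1) - exp(-k_res * t2)) / (k_res * (t2 - t1)))

    enter1 <- (1 - eta_et) * ratio[1]
    after1 <- enter1 * (1 - eta[1])
    enter2 <- after1 * ratio[2]
    after2 <- enter2 * (1 - eta[2])
    enter3 <- after2 * ratio[3]
    after3 <- enter3 * (1 - eta[3])
    park <- c(after1 * (1 - passed[1]), after2 * (1 - passed[2]), after3)
    rel <- park * surv
    up3 <- rel[3]
    out3 <- up3 * (1 - eta[3]) # equal phases: expiratory efficiency = eta
    up2 <- rel[2] + out3
    out2 <- up2 * (1 - eta[2])
    up1 <- rel[1] + out2
    out1 <- up1 * (1 - eta[1])
    dep_hand[, k] <- c(enter1, enter2, enter3) * eta +
      park * (1 - surv) +
      c(up1, up2, up3) * eta
    head_hand <- head_hand + w[k] * eta_et
    exh_hand <- exh_hand + w[k] * (out1 + (1 - eta_et) * (1 - ratio[1]))
  }
  frac_hand <- as.numeric(dep_hand %*% w)

  expect_equal(res$per_airway$fraction, frac_hand, tolerance = 1e-12)
  expect_equal(res$regional$fraction[1], head_hand, tolerance = 1e-12)
  expect_equal(res$regional$fraction[4], exh_hand, tolerance = 1e-12)
  expect_equal(res$inhalable_fraction, if_mass, tolerance = 1e-12)
  mass_hand <- 1000 * 1.5 * 100 * 60 * 4 * 1e-3 * if_mass
  expect_equal(res$total_inhaled_mass_ug, mass_hand, tolerance = 1e-12)
})

test_that("mass balance holds to 1e-9 for every scenario", {
  trees <- list(small_symmetric_tree(), builtin_human_tree(), toy_path_tree())
  vents <- list(ventilation_pattern(200, 15, "oral"),
                ventilation_pattern(625, 12, "nasal"),
                ventilation_pattern(1.5, 100, "nose-only"))
  for (i in seq_along(trees)) {
    sc <- exposure_scenario(aerosol_spec(2.74, 2.8, 1, 5212), vents[[i]],
                            trees[[i]],
                            inhalability_on = trees[[i]]$species == "rat",
                            label = "mb")
    res <- run_deposition(sc, n_bins = 200)
    total <- sum(res$regional$fraction)
    expect_equal(total, 1, tolerance = 1e-9)
    expect_true(all(res$regional$fraction >= 0))
    expect_true(all(res$per_airway$fraction >= 0))
  }
})

test_that("fractions are concentration-invariant, masses linear in C and t", {
  tr <- small_symmetric_tree()
  mk <- function(conc, dur = 4) {
    exposure_scenario(aerosol_spec(2.74, 2.8, 1, conc),
                      ventilation_pattern(200, 15, "oral"), tr,
                      duration_h = dur, inhalability_on = FALSE, label = "lin")
  }
  r1 <- run_deposition(mk(500), n_bins = 100)
  r2 <- run_deposition(mk(1000), n_bins = 100)
  r10 <- run_deposition(mk(5000), n_bins = 100)
  expect_equal(r1$per_airway$fraction, r2$per_airway$fraction, tolerance = 1e-12)
  expect_equal(r1$per_airway$fraction, r10$per_airway$fraction, tolerance = 1e-12)
  expect_equal(r2$per_airway$mass_per_airway_ug,
               2 * r1$per_airway$mass_per_airway_ug, tolerance = 1e-12)
  expect_equal(r10$per_airway$mass_per_airway_ug,
               10 * r1$per_airway$mass_per_airway_ug, tolerance = 1e-12)
  rlong <- run_deposition(mk(500, dur = 8), n_bins = 100)
  expect_equal(rlong$per_airway$mass_per_airway_ug,
               2 * r1$per_airway$mass_per_airway_ug, tolerance = 1e-12)
  # zero concentration: fractions unchanged, masses zero
  r0 <- run_deposition(mk(0), n_bins = 100)
  expect_equal(r0$per_airway$fraction, r1$per_airway$fraction, tolerance = 1e-12)
  expect_true(all(r0$per_airway$mass_per_airway_ug == 0))
})

test_that("symmetric and expanded representations give identical results", {
  sym <- small_symmetric_tree()
  ex <- expand_symmetric(sym, nrow(sym$airways))
  mk <- function(tr) {
    exposure_scenario(aerosol_spec(3, 2, 1, 1000),
                      ventilation_pattern(200, 15, "oral"), tr,
                      inhalability_on = FALSE, label = "sym")
  }
  rs <- run_deposition(mk(sym), n_bins = 50)
  re <- run_deposition(mk(ex), n_bins = 50)
  expect_equal(rs$regional$fraction, re$regional$fraction, tolerance = 1e-12)
  # all airways of a generation receive the same per-airway fraction,
  # equal to the symmetric per-single value
  for (g in seq_len(nrow(sym$airways))) {
    per <- re$per_airway$fraction_per_airway[re$per_airway$generation == g]
    expect_equal(diff(range(per)), 0, tolerance = 1e-15)
    expect_equal(per[1],
                 rs$per_airway$fraction_per_airway[rs$per_airway$generation == g],
                 tolerance = 1e-12)
  }
})

test_that("human deep lung: terminal alveolar generations stay clean", {
  res <- run_deposition(human_reference_scenario("nasal"), n_bins = 300)
  pg <- res$per_generation
  expect_equal(sum(pg$fraction[pg$generation >= 22]), 0, tolerance = 1e-12)
  expect_gt(sum(pg$fraction[pg$generation %in% 18:21]), 0.01)
})

test_that("bin refinement leaves totals unchanged below 0.1 points", {
  sc <- human_reference_scenario("nasal")
  t100 <- sum(run_deposition(sc, n_bins = 100)$regional$fraction[1:3])
  t1000 <- sum(run_deposition(sc, n_bins = 1000)$regional$fraction[1:3])
  t10000 <- sum(run_deposition(sc, n_bins = 10000)$regional$fraction[1:3])
  expect_lt(abs(t1000 - t100), 1e-3)
  expect_lt(abs(t10000 - t1000), 1e-3)
})

test_that("invalid trees and geometry are refused", {
  tr <- small_symmetric_tree()
  tr$airways$diameter_cm[2] <- -1
  sc <- exposure_scenario(aerosol_spec(1, 2, 1, 10),
                          ventilation_pattern(200, 15, "oral"),
                          small_symmetric_tree(), inhalability_on = FALSE)
  sc$tree <- tr
  expect_error(run_deposition(sc), "invalid airway tree")
  # zero distal volume at a branch
  tr2 <- small_symmetric_tree()
  tr2$airways$distal_volume_cm3[-1] <- 0
  expect_error(airway_flows(tr2, ventilation_pattern(200, 15, "oral")),
               "distal volume")
})
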