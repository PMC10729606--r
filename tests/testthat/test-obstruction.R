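test_that("coalesced sphere diameter follows the cube-root law", {
  # 1 ug at unit density: V = 1e-6 cm3, d = (6e-6/pi)^(1/3)
  expect_equal(coalesced_sphere_diameter(1, 1), 0.0124070098, tolerance = 1e-8)
  expect_equal(coalesced_sphere_diameter(0, 1), 0)
  expect_equal(coalesced_sphere_diameter(8, 1),
               2 * coalesced_sphere_diameter(1, 1), tolerance = 1e-12)
  # halved density doubles the volume
  expect_equal(coalesced_sphere_diameter(1, 0.5),
               coalesced_sphere_diameter(2, 1), tolerance = 1e-12)
  expect_error(coalesced_sphere_diameter(1, 0), "density")
  expect_error(coalesced_sphere_diameter(-1, 1), "mass")
})

make_result_with_masses <- function(tree, masses_ug) {
  sc <- exposure_scenario(aerosol_spec(3, 2, 1, 1000),
                          ventilation_pattern(200, 15, "oral"), tree,
                          inhalability_on = FALSE, label = "hand")
  res <- run_deposition(sc, n_bins = 20)
  res$per_airway$mass_per_airway_ug <- masses_ug
  res
}

test_that("an airway exactly filled by its deposit has ratio one", {
  tr <- small_symmetric_tree()
  d <- tr$airways$diameter_cm
  fill_mass <- pi / 6 * d^3 * 1e6 # ug at unit density
  res <- make_result_with_masses(tr, fill_mass)
  prof <- obstruction_ratios(res, tr, density = 1)
  expect_equal(prof$per_airway$ratio, rep(1, nrow(prof$per_airway)),
               tolerance = 1e-12)
})

test_that("binning matches a brute-force classification on hand-set masses", {
  tr <- expand_symmetric(small_symmetric_tree(n_tb = 3, n_pul = 1), 4)
  d <- tr$airways$diameter_cm
  # choose masses giving ratios 0, .05, .12, .3, .45, .5, .55, .8, 1.0, 2.0
  target <- c(0, 0.05, 0.12, 0.3, 0.45, 0.5, 0.55, 0.8, 1.0, 2.0,
              rep(0.07, nrow(tr$airways) - 10))
  masses <- pi / 6 * (target * d)^3 * 1e6
  res <- make_result_with_masses(tr, masses)
  prof <- bin_ratios(obstruction_ratios(res, tr), "human")
  h <- prof$histogram[prof$histogram$region == "all", ]
  # manual: edges 0,.1,.2,.3,.4,.5,Inf, right-open
  manual <- table(cut(target, c(0, 0.1, 0.2, 0.3, 0.4, 0.5, Inf),
                      right = FALSE))
  expect_equal(h$count, as.integer(manual))
  expect_equal(sum(h$count), nrow(tr$airways))
  expect_equal(sum(h$percent), 100, tolerance = 1e-6)
  # rat quartile scheme on the same ratios
  pr <- bin_ratios(obstruction_ratios(res, tr), "rat")
  hr <- pr$histogram[pr$histogram$region == "all", ]
  manual_rat <- table(cut(target, c(0, 0.25, 0.5, 0.75, 1, Inf),
                          right = FALSE))
  expect_equal(hr$count, as.integer(manual_rat))
})

test_that("TB and PUL percentages each sum to 100 and counts partition", {
  tr <- small_symmetric_tree()
  sc <- exposure_scenario(aerosol_spec(3, 2, 1, 1000),
                          ventilation_pattern(200, 15, "oral"), tr,
                          inhalability_on = FALSE, label = "p")
  res <- run_deposition(sc, n_bins = 50)
  prof <- bin_ratios(obstruction_ratios(res, tr), "human")
  h <- prof$histogram
  for (reg in c("all", "TB", "PUL")) {
    expect_equal(sum(h$percent[h$region == reg]), 100, tolerance = 1e-6)
  }
  expect_equal(sum(h$count[h$region == "TB"]) + sum(h$count[h$region == "PUL"]),
               sum(h$count[h$region == "all"]))
  expect_equal(sum(h$count[h$region == "all"]),
               sum(tr$airways$multiplicity))
  # all-zero ratios all land in the lowest bin
  res0 <- res
  res0$per_airway$mass_per_airway_ug <- 0
  p0 <- bin_ratios(obstruction_ratios(res0, tr), "human")
  h0 <- p0$histogram[p0$histogram$region == "all", ]
  expect_equal(h0$percent[1], 100, tolerance = 1e-9)
})

test_that("ratios are invariant to the tree representation", {
  sym <- small_symmetric_tree()
  ex <- expand_symmetric(sym, nrow(sym$airways))
  mk <- function(tr) {
    run_deposition(exposure_scenario(aerosol_spec(3, 2, 1, 1000),
                                     ventilation_pattern(200, 15, "oral"), tr,
                                     inhalability_on = FALSE, label = "r"),
                   n_bins = 50)
  }
  ps <- bin_ratios(obstruction_ratios(mk(sym), sym), "human")
  pe <- bin_ratios(obstruction_ratios(mk(ex), ex), "human")
  expect_equal(ps$histogram$count, pe$histogram$count)
  for (g in unique(ps$per_airway$generation)) {
    rs <- ps$per_airway$ratio[ps$per_airway$generation == g]
    re <- unique(round(pe$per_airway$ratio[pe$per_airway$generation == g], 12))
    expect_equal(re, round(rs, 12))
  }
})

test_that("ratios follow the cube-root law in concentration and duration", {
  tr <- small_symmetric_tree()
  mk <- function(conc, dur) {
    run_deposition(exposure_scenario(aerosol_spec(2.74, 2.8, 1, conc),
                                     ventilation_pattern(200, 15, "oral"), tr,
                                     duration_h = dur, inhalability_on = FALSE,
                                     label = "c"),
                   n_bins = 50)
  }
  base <- obstruction_ratios(mk(1000, 4), tr)$per_airway$ratio
  for (case in list(c(2000, 4), c(5212, 4), c(1000, 8), c(2000, 8),
                    c(5212, 2))) {
    scale <- (case[1] * case[2] / (1000 * 4))^(1 / 3)
    got <- obstruction_ratios(mk(case[1], case[2]), tr)$per_airway$ratio
    expect_equal(got, base * scale, tolerance = 1e-9)
  }
})

test_that("profile comparison flags monotone growth across concentrations", {
  tr <- small_symmetric_tree()
  profs <- lapply(c(1000, 3000, 9000), function(conc) {
    res <- run_deposition(
      exposure_scenario(aerosol_spec(2.74, 2.8, 1, conc),
                        ventilation_pattern(200, 15, "oral"), tr,
                        inhalability_on = FALSE,
                        label = sprintf("c%d", conc)),
      n_bins = 50)
    bin_ratios(obstruction_ratios(res, tr), "rat")
  })
  cmp <- compare_profiles(profs)
  expect_true(all(cmp$monotonicity$non_decreasing))
  # identical profiles differ nowhere
  cmp0 <- compare_profiles(list(profs[[1]], profs[[1]]), c("a", "b"))
  ca <- cmp0$table[cmp0$table$profile == "a", ]
  cb <- cmp0$table[cmp0$table$profile == "b", ]
  expect_equal(ca$count, cb$count)
  expect_true(all(!cmp0$monotonicity$strictly_increasing |
                    cmp0$monotonicity$non_decreasing))
  # inconsistent bin edges are refused
  ph <- bin_ratios(profs[[1]], "human")
  expect_error(compare_profiles(list(profs[[2]], ph)), "inconsistent")
})

test_that("mismatched airway ids are caught", {
  tr <- small_symmetric_tree()
  sc <- exposure_scenario(aerosol_spec(3, 2, 1, 1000),
                          ventilation_pattern(200, 15, "oral"), tr,
                          inhalability_on = FALSE, label = "m")
  res <- run_deposition(sc, n_bins = 20)
  other <- toy_path_tree()
  expect_error(obstruction_ratios(res, other), "different airway ids")
})
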