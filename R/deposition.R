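#' Mean inspiratory flow through every airway
#'
#' The root (tracheal) flow is `tidal_volume / (inspiratory_fraction * breath
#' period)`. At every branch point the flow splits across the children in
#' proportion to their distal volumes, so flow is conserved at each branch.
#' Values are per single airway (a symmetric generation row reports the flow
#' through one of its `multiplicity` airways).
#'
#' @param tree An [airway_tree()].
#' @param ventilation A [ventilation_pattern()].
#' @return Numeric vector of mean inspiratory flows (cm³/s) named by airway id,
#'   in the tree's row order.
#' @examples
#' q <- airway_flows(builtin_human_tree(), ventilation_pattern(625, 12, "nasal"))
#' q[[1]] # tracheal flow, cm3/s
#' @export
airway_flows <- function(tree, ventilation) {
  stopifnot(inherits(tree, "airway_tree"),
            inherits(ventilation, "ventilation_pattern"))
  a <- tree$airways
  ord <- order(a$generation)
  a <- a[ord, ]
  pidx <- match(a$parent_id, a$id)
  t_breath <- 60 / ventilation$frequency_bpm
  q_root <- ventilation$tidal_volume_ml /
    (ventilation$inspiratory_fraction * t_breath)
  q <- numeric(nrow(a))
  root <- which(is.na(pidx))
  q[root] <- q_root
  # denominator per parent: sum over child rows of multiplicity-weighted
  # distal volume, normalized to one parent airway
  wd <- a$multiplicity * a$distal_volume_cm3
  den <- rowsum(wd[-root], pidx[-root])
  den_full <- numeric(nrow(a))
  den_full[as.integer(rownames(den))] <- den[, 1]
  if (any(den_full[unique(pidx[-root])] <= 0)) {
    stop("zero distal volume at a branch point: flow split undefined",
         call. = FALSE)
  }
  for (g in sort(unique(a$generation))[-1]) {
    idx <- which(a$generation == g)
    p <- pidx[idx]
    q[idx] <- q[p] * a$multiplicity[p] * a$distal_volume_cm3[idx] / den_full[p]
  }
  out <- q[order(ord)]
  names(out) <- tree$airways$id
  out
}

# ---- single-airway deposition efficiency formulas (vectorized internals) ----

eta_impaction_calc <- function(stk, theta_rad) {
  x <- pmin(theta_rad * stk, 1)
  phi <- acos(x)
  pmax(0, 1 - (2 / pi) * phi + (1 / pi) * sin(2 * phi))
}

eta_sedimentation_calc <- function(v_ts, length_cm, diameter_cm, u, sin_gamma) {
  1 - exp(-(4 / pi) * v_ts * length_cm * sin_gamma / (diameter_cm * u))
}

eta_diffusion_calc <- function(x) {
  pmin(1, pmax(0, 1 - 0.819 * exp(-14.63 * x) - 0.0976 * exp(-89.22 * x) -
                 0.0325 * exp(-228 * x) - 0.0509 * exp(-125.9 * x^(2 / 3))))
}

#' Single-airway deposition efficiencies
#'
#' Analytic per-airway efficiencies for the three mechanical deposition
#' mechanisms during transit of one airway, as used by the serial-filtration
#' engine:
#' \describe{
#'   \item{impaction}{arccos-form probability in the turning parameter
#'     `theta * Stk`, with Stokes number
#'     `Stk = rho0 d_ae^2 C(d_ae) U / (18 mu d_airway)` and `theta` the
#'     branching angle; zero for a straight continuation, increasing in
#'     particle size and flow.}
#'   \item{sedimentation}{`1 - exp(-(4/pi) v_ts L sin(gravity_angle) /
#'     (d_airway U))`; zero for a vertical airway, approaching 1 as the
#'     residence time `L/U` grows.}
#'   \item{diffusion}{Ingham-type exponential series in the dimensionless
#'     parameter `x = D L / (4 U R^2)`; increasing in `x` with limit 1.}
#' }
#'
#' @param airway One airway: a list or single data.frame row with
#'   `diameter_cm`, `length_cm`, `branching_angle_deg`, `gravity_angle_deg`.
#' @param flow Mean flow through the single airway, cm³/s (> 0).
#' @param bin A size bin (list or row with `d_ae` in µm), e.g. one row of
#'   [discretize_lognormal()].
#' @param gas A [gas_conditions()] object.
#' @return Deposition efficiency in \\[0, 1\\].
#' @export
efficiency_impaction <- function(airway, flow, bin, gas = gas_conditions()) {
  check_eff_inputs(airway, flow, bin)
  u <- flow / (pi / 4 * airway$diameter_cm^2)
  d_cm <- bin$d_ae * 1e-4
  stk <- d_cm^2 * slip_correction(bin$d_ae, gas) * u /
    (18 * gas$viscosity * airway$diameter_cm)
  eta_impaction_calc(stk, airway$branching_angle_deg * pi / 180)
}

#' @rdname efficiency_impaction
#' @export
efficiency_sedimentation <- function(airway, flow, bin, gas = gas_conditions()) {
  check_eff_inputs(airway, flow, bin)
  u <- flow / (pi / 4 * airway$diameter_cm^2)
  eta_sedimentation_calc(settling_velocity(bin$d_ae, gas), airway$length_cm,
                         airway$diameter_cm, u,
                         sin(airway$gravity_angle_deg * pi / 180))
}

#' @rdname efficiency_impaction
#' @export
efficiency_diffusion <- function(airway, flow, bin, gas = gas_conditions()) {
  check_eff_inputs(airway, flow, bin)
  u <- flow / (pi / 4 * airway$diameter_cm^2)
  r <- airway$diameter_cm / 2
  x <- diffusion_coefficient(bin$d_ae, gas) * airway$length_cm / (4 * u * r^2)
  eta_diffusion_calc(x)
}

check_eff_inputs <- function(airway, flow, bin) {
  if (!all(c("diameter_cm", "length_cm") %in% names(airway))) {
    stop("airway must carry diameter_cm and length_cm", call. = FALSE)
  }
  if (!is.finite(flow) || flow <= 0) stop("flow must be > 0", call. = FALSE)
  if (any(!is.finite(bin$d_ae)) || any(bin$d_ae <= 0)) {
    stop("bin d_ae must be > 0", call. = FALSE)
  }
  invisible(TRUE)
}

#' Empirical extrathoracic (head) deposition efficiency
#'
#' The head region (nose or mouth through the larynx) is modeled empirically,
#' not airway-by-airway: the inspiratory filtration efficiency follows the
#' impaction-parameter correlation `1 - exp(-a (d_ae^2 Q)^b)` with `d_ae` in
#' µm and `Q` the mean inspiratory flow in cm³/s. Coefficients per
#' species/route ship in the constants file; they are calibrated once so the
#' reference human scenarios (2.74 µm MMAD, GSD 2.8, 625 mL at 12/min)
#' reproduce head deposition of 51.3% (nasal) and 14.3% (oral) of inhaled
#' mass, and the rat nose-only route 34.5% of the inhalable mass.
#'
#' @param route `"nasal"`, `"oral"` or `"nose-only"`.
#' @param species `"rat"` or `"human"`.
#' @param flow Mean inspiratory flow, cm³/s.
#' @param d_ae Aerodynamic diameter(s), µm. Vectorized.
#' @param constants Constants list, see [default_constants()].
#' @return Deposition efficiency(ies) in \\[0, 1\\], as a fraction of the mass
#'   entering the head.
#' @export
extrathoracic_deposition <- function(route, species, flow, d_ae,
                                     constants = default_constants()) {
  species <- match.arg(species, c("rat", "human"))
  route <- match.arg(route, c("nasal", "oral", "nose-only"))
  key <- paste(species, route, sep = "_")
  cf <- constants$extrathoracic[[key]]
  if (is.null(cf)) {
    stop(sprintf("no extrathoracic model for species '%s' with route '%s'",
                 species, route), call. = FALSE)
  }
  if (!is.finite(flow) || flow <= 0) stop("flow must be > 0", call. = FALSE)
  if (any(!is.finite(d_ae)) || any(d_ae <= 0)) {
    stop("d_ae must be > 0", call. = FALSE)
  }
  1 - exp(-cf$a * (d_ae^2 * flow)^cf$b)
}

#' Calibrate an extrathoracic coefficient to a target head fraction
#'
#' Solves for the `a` coefficient (at fixed exponent `b`) of the head
#' filtration model so that a given aerosol at a given inspiratory flow
#' attains a prescribed mass-weighted head deposition fraction. Used once to
#' produce the coefficients frozen in the shipped constants file.
#'
#' @param target Mass-weighted head deposition fraction to reproduce.
#' @param bins Discretized aerosol bins (with optional `weight` column taking
#'   precedence over `mass_fraction`).
#' @param flow Mean inspiratory flow, cm³/s.
#' @param b Fixed exponent of the impaction-parameter correlation.
#' @return The calibrated `a` coefficient.
#' @export
calibrate_extrathoracic <- function(target, bins, flow, b = 1) {
  w <- bins$weight %||% bins$mass_fraction
  w <- w / sum(w)
  f <- function(la) {
    sum(w * (1 - exp(-exp(la) * (bins$d_ae^2 * flow)^b))) - target
  }
  la <- stats::uniroot(f, c(-40, 5), tol = 1e-14)$root
  exp(la)
}

# ---- the serial-filtration engine ----

#' Run whole-lung deposition for an exposure scenario
#'
#' Serial-filtration deposition over one tidal breath, aggregated over a
#' discretized lognormal aerosol and scaled to the exposure duration.
#' Per size bin the engine:
#' \enumerate{
#'   \item applies the species inhalability correction (rat scenarios);
#'   \item filters the inhaled air through the empirical head model;
#'   \item tracks the fresh-aerosol tidal front into the lung: the tidal air
#'     is apportioned over the alveolar (expanding) volumes, and air bound for
#'     an airway first displaces the particle-free dead-space gas of the
#'     airways proximal to it, so deep airways beyond the front receive no
#'     aerosol at all;
#'   \item deposits during inspiratory transit with per-airway combined
#'     efficiency `1 - (1-eta_I)(1-eta_S)(1-eta_D)`;
#'   \item lets the air parked in the deepest reached airways deposit by
#'     sedimentation and diffusion over its residence time (parcels arrive
#'     uniformly over inspiration and leave last-in-first-out over
#'     expiration, extended by any end-inspiratory pause; the exponential
#'     survival is averaged exactly over the parcel residence times);
#'   \item filters the exiting air leaves-to-root with expiratory-flow
#'     efficiencies (branching and gravity angles unchanged).
#' }
#' Mass is conserved exactly: head + TB + PUL + exhaled = 1 for every bin.
#' Deposition fractions are independent of the exposure concentration;
#' deposited masses scale linearly with concentration and duration. Deposition
#' never alters downstream flow (no two-way particle-flow coupling), and no
#' clearance acts during the acute exposure, so deposited mass accumulates
#' breath by breath.
#'
#' @param scenario An [exposure_scenario()].
#' @param n_bins Number of aerosol size bins (default 1000).
#' @param span_sigmas Diameter span of the discretization, see
#'   [discretize_lognormal()].
#' @param chunk_size Number of bins processed per vectorized block (memory /
#'   speed trade-off; no effect on results).
#' @param constants Constants list, see [default_constants()].
#' @return An object of class `deposition_result` with elements
#'   `per_airway` (data.frame: id, generation, region, lobe, multiplicity,
#'   fraction of inhaled mass deposited in all airways of the row,
#'   `fraction_per_airway` and `mass_per_airway_ug` for one airway),
#'   `per_generation`, `regional` (head/TB/PUL/exhaled fractions of inhaled
#'   mass), `inhalable_fraction`, `total_inhaled_mass_ug`, `exhaled_fraction`,
#'   plus the scenario label and bin count.
#' @examples
#' \donttest{
#' sc <- scenario_fixtures()[["human_nasal"]]
#' res <- run_deposition(sc)
#' res$regional
#' }
#' @export
run_deposition <- function(scenario, n_bins = 1000, span_sigmas = 4,
                           chunk_size = 256, constants = default_constants()) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  tree <- scenario$tree
  viol <- validate_tree(tree)
  if (length(viol)) {
    stop("invalid airway tree: ", paste(viol, collapse = "; "), call. = FALSE)
  }
  vent <- scenario$ventilation
  gas <- scenario$gas
  species <- tree$species

  bins <- discretize_lognormal(scenario$aerosol, n_bins, span_sigmas)
  nb <- nrow(bins)
  iff <- if (scenario$inhalability_on) {
    inhalability_curve(bins$d_ae, species, constants)
  } else {
    rep(1, nb)
  }
  w <- bins$mass_fraction * iff
  if_mass <- sum(w)
  w <- w / if_mass

  # geometry in topological (generation) order
  a <- tree$airways
  ord <- order(a$generation)
  a <- a[ord, ]
  n <- nrow(a)
  pidx <- match(a$parent_id, a$id)
  levels_ <- split(seq_len(n), a$generation)
  root <- which(is.na(pidx))

  q <- airway_flows(tree, vent)[ord]
  t_breath <- 60 / vent$frequency_bpm
  t_insp <- vent$inspiratory_fraction * t_breath
  t_exp <- vent$expiratory_fraction * t_breath
  t_pause <- vent$pause_fraction * t_breath
  v_t <- vent$tidal_volume_ml

  area <- pi / 4 * a$diameter_cm^2
  u_insp <- q / area
  u_exp <- u_insp * (t_insp / t_exp)
  sin_g <- sin(a$gravity_angle_deg * pi / 180)
  theta <- a$branching_angle_deg * pi / 180
  r_aw <- a$diameter_cm / 2
  lumen <- area * a$length_cm
  m <- a$multiplicity

  # per-single-airway distal alveolar volume and own alveolar volume
  child_rows <- split(seq_len(n)[-root], pidx[-root])
  kids_of <- vector("list", n)
  kids_of[as.integer(names(child_rows))] <- child_rows
  alv_distal <- numeric(n)
  alv_own <- numeric(n)
  for (g in rev(seq_along(levels_))) {
    for (j in levels_[[g]]) {
      kid_sum <- 0
      for (c_ in kids_of[[j]]) {
        kid_sum <- kid_sum + m[c_] / m[j] * alv_distal[c_]
      }
      own <- a$distal_volume_cm3[j] - lumen[j] -
        sum(m[kids_of[[j]]] / m[j] * a$distal_volume_cm3[kids_of[[j]]])
      alv_own[j] <- max(0, own)
      alv_distal[j] <- alv_own[j] + kid_sum
    }
  }
  d_r <- alv_distal[root] # total alveolar (expanding) volume
  if (d_r <= 0) {
    stop("tree has no alveolar volume: distal volumes do not exceed lumen",
         call. = FALSE)
  }
  v_et <- constants$extrathoracic$dead_space_cm3[[species]]
  # fresh-aerosol air volume entering each single airway over one breath
  rsum <- numeric(n)
  rsum[root] <- v_et / d_r
  fresh <- numeric(n)
  fresh[root] <- max(0, alv_distal[root] * (v_t / d_r - rsum[root]))
  for (g in seq_along(levels_)[-1]) {
    idx <- levels_[[g]]
    p <- pidx[idx]
    rsum[idx] <- rsum[p] + ifelse(alv_distal[p] > 0, lumen[p] / alv_distal[p], Inf)
    fresh[idx] <- pmax(0, alv_distal[idx] * (v_t / d_r - rsum[idx]))
  }
  childf <- numeric(n) # multiplicity-weighted fresh air claimed by children
  cf <- rowsum((m * fresh)[-root], pidx[-root])
  childf[as.integer(rownames(cf))] <- cf[, 1]
  ratio <- numeric(n) # share of parent's onward air carried into this row
  ratio[root] <- fresh[root] / v_t
  nz <- setdiff(which(fresh > 0), root)
  ratio[nz] <- (m[nz] * fresh[nz]) / (m[pidx[nz]] * fresh[pidx[nz]])
  passed <- ifelse(fresh > 0, pmin(1, childf / (m * fresh)), 0)

  # Residence-time window of the air parked in each airway at end-inspiration.
  # Air is stacked last-in-first-out along each path: the parcel parked at a
  # plane with proximal dead space DS entered the mouth at breath fraction
  # tau = 1 - DS/V_T and leaves after (1-tau)*(t_insp+t_exp) plus the pause.
  # Parked air in airway j spans the window between its own entry plane and
  # its children's; leaves hold the earliest air of the breath.
  # The mouth-to-mouth window includes the transit through the airways on the
  # way in and out; transit deposition is accounted separately per airway, so
  # the in-place residence excludes the round-trip transit time.
  t_tot <- t_insp + t_exp
  frac1 <- pmin(1, rsum * d_r / v_t)
  frac2 <- pmin(1, (rsum + ifelse(alv_distal > 0, lumen / alv_distal, Inf)) *
                  d_r / v_t)
  is_leaf <- lengths(kids_of) == 0
  frac2[is_leaf] <- 1
  transit_in <- numeric(n) # transit time from the trachea to the entry plane
  for (g in seq_along(levels_)[-1]) {
    idx <- levels_[[g]]
    p <- pidx[idx]
    transit_in[idx] <- transit_in[p] + a$length_cm[p] / u_insp[p]
  }
  round_trip <- transit_in * (1 + t_exp / t_insp)
  t1 <- pmax(0, t_pause + t_tot * frac1 - round_trip)
  t2 <- pmax(t1, t_pause + t_tot * pmax(frac2, frac1) - round_trip)

  # volume-weighted deposition-rate geometry of the parked air
  d_alv <- constants$lung$alveolus_diameter_cm[[species]]
  w_alv <- ifelse(alv_own + lumen > 0, alv_own / (alv_own + lumen), 0)
  inv_d_eff <- (1 - w_alv) / a$diameter_cm + w_alv / d_alv
  inv_r2_eff <- (1 - w_alv) / r_aw^2 + w_alv / (d_alv / 2)^2

  et_key_flow <- q[root] # head model sees the tracheal (= total) flow
  dep <- numeric(n)
  dep_phase <- matrix(0, n, 3, dimnames = list(NULL, c("insp", "res", "exp")))
  head_frac <- 0
  exhaled_frac <- 0

  for (lo in seq(1, nb, by = chunk_size)) {
    sel <- lo:min(lo + chunk_size - 1, nb)
    db <- bins$d_ae[sel]
    wb <- w[sel]
    cb <- slip_correction(db, gas)
    vb <- settling_velocity(db, gas)
    difb <- diffusion_coefficient(db, gas)
    eta_et <- extrathoracic_deposition(vent$route, species, et_key_flow, db,
                                       constants)
    d_cm2c <- (db * 1e-4)^2 * cb

    stk <- outer(u_insp / (18 * gas$viscosity * a$diameter_cm), d_cm2c)
    eta_i <- eta_impaction_calc(stk, theta)
    eta_s <- 1 - exp(-(4 / pi) * outer(a$length_cm * sin_g / (a$diameter_cm * u_insp), vb))
    eta_d <- eta_diffusion_calc(outer(a$length_cm / (4 * u_insp * r_aw^2), difb))
    eta <- 1 - (1 - eta_i) * (1 - eta_s) * (1 - eta_d)

    stk_e <- outer(u_exp / (18 * gas$viscosity * a$diameter_cm), d_cm2c)
    eta_ie <- eta_impaction_calc(stk_e, theta)
    eta_se <- 1 - exp(-(4 / pi) * outer(a$length_cm * sin_g / (a$diameter_cm * u_exp), vb))
    eta_de <- eta_diffusion_calc(outer(a$length_cm / (4 * u_exp * r_aw^2), difb))
    eta_e <- 1 - (1 - eta_ie) * (1 - eta_se) * (1 - eta_de)

    # exponential survival averaged exactly over the parked-air residence
    # window [t1, t2]: (exp(-k t1) - exp(-k t2)) / (k (t2 - t1)).
    # Parked air splits between the airway lumen and its own alveoli; the
    # alveolus-stored share settles and diffuses over the alveolus scale.
    k_res <- outer((4 / pi) * sin_g * inv_d_eff, vb) +
      5.78 * outer(inv_r2_eff, difb)
    kdt <- k_res * (t2 - t1)
    surv <- ifelse(kdt < 1e-10,
                   exp(-k_res * (t1 + t2) / 2),
                   (exp(-k_res * t1) - exp(-k_res * t2)) / kdt)
    eta_r <- 1 - surv

    nbq <- length(sel)
    enter <- matrix(0, n, nbq)
    after <- matrix(0, n, nbq)
    enter[root, ] <- (1 - eta_et) * ratio[root]
    after[root, ] <- enter[root, ] * (1 - eta[root, ])
    for (g in seq_along(levels_)[-1]) {
      idx <- levels_[[g]]
      enter[idx, ] <- after[pidx[idx], , drop = FALSE] * ratio[idx]
      after[idx, ] <- enter[idx, , drop = FALSE] * (1 - eta[idx, , drop = FALSE])
    }
    dep_insp <- enter * eta
    park <- after * (1 - passed)
    dep_res <- park * eta_r
    rel <- park - dep_res

    upacc <- matrix(0, n, nbq)
    dep_exp <- matrix(0, n, nbq)
    out_root <- numeric(nbq)
    for (g in rev(seq_along(levels_))) {
      idx <- levels_[[g]]
      up <- rel[idx, , drop = FALSE] + upacc[idx, , drop = FALSE]
      dex <- up * eta_e[idx, , drop = FALSE]
      dep_exp[idx, ] <- dex
      outm <- up - dex
      if (g > 1) {
        agg <- rowsum(outm, pidx[idx])
        tgt <- as.integer(rownames(agg))
        upacc[tgt, ] <- upacc[tgt, , drop = FALSE] + agg
      } else {
        out_root <- colSums(outm)
      }
    }

    dep <- dep + (dep_insp + dep_res + dep_exp) %*% wb
    dep_phase <- dep_phase + cbind(dep_insp %*% wb, dep_res %*% wb,
                                   dep_exp %*% wb)
    head_frac <- head_frac + sum(eta_et * wb)
    exhaled_frac <- exhaled_frac +
      sum((out_root + (1 - eta_et) * (1 - ratio[root])) * wb)
  }
  dep <- as.numeric(dep)

  balance <- head_frac + sum(dep) + exhaled_frac
  if (abs(balance - 1) > 1e-9) {
    stop(sprintf("internal mass-balance violation: %.3e", balance - 1),
         call. = FALSE)
  }

  conc <- scenario$aerosol$concentration
  total_inhaled_ug <- conc * v_t * vent$frequency_bpm * 60 *
    scenario$duration_h * 1e-3 * if_mass

  per_airway <- data.frame(
    id = a$id, generation = a$generation, region = a$region, lobe = a$lobe,
    multiplicity = m, fraction = dep, fraction_per_airway = dep / m,
    mass_per_airway_ug = dep / m * total_inhaled_ug,
    fraction_inspiratory = dep_phase[, "insp"],
    fraction_residence = dep_phase[, "res"],
    fraction_expiratory = dep_phase[, "exp"])
  per_airway <- per_airway[order(per_airway$id), ]
  rownames(per_airway) <- NULL

  per_gen <- stats::aggregate(fraction ~ generation + region, data = per_airway,
                              FUN = sum)
  per_gen <- per_gen[order(per_gen$generation, per_gen$region), ]
  per_gen$mass_ug <- per_gen$fraction * total_inhaled_ug
  rownames(per_gen) <- NULL

  regional <- data.frame(
    region = c("head", "TB", "PUL", "exhaled"),
    fraction = c(head_frac,
                 sum(dep[a$region == "TB"]),
                 sum(dep[a$region == "PUL"]),
                 exhaled_frac))
  regional$mass_ug <- regional$fraction * total_inhaled_ug
  regional$mass_ug[regional$region == "exhaled"] <- NA

  structure(list(label = scenario$label, species = species,
                 per_airway = per_airway, per_generation = per_gen,
                 regional = regional, inhalable_fraction = if_mass,
                 exhaled_fraction = exhaled_frac,
                 total_inhaled_mass_ug = total_inhaled_ug,
                 n_bins = nb),
            class = "deposition_result")
}

#' @export
print.deposition_result <- function(x, ...) {
  cat(sprintf("Deposition result '%s' (%s), %d size bins\n", x$label,
              x$species, x$n_bins))
  cat(sprintf("  inhalable fraction %.3f, total inhaled %.4g ug\n",
              x$inhalable_fraction, x$total_inhaled_mass_ug))
  reg <- x$regional
  cat(sprintf("  %-8s %6.2f%% of inhaled\n", reg$region, 100 * reg$fraction),
      sep = "")
  invisible(x)
}
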