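#' Parameters for the synthetic airway-tree generator
#'
#' The rat template emulates the monopodial branching of the rat lung: a long
#' axial trunk spanning `n_tb_generations` conducting generations, minor
#' daughters budding off at steep angles, pulmonary (acinar) outgrowths
#' allowed only where the parent conducting airway lies inside
#' `pulmonary_offshoot_range`, and every terminal bronchiole capped by
#' `terminal_pul_generations` appended pulmonary generations. The human
#' template grows a dichotomous tree (with `asymmetry = 0` it is exactly
#' symmetric, `2^(g-1)` airways per generation).
#'
#' @param species_template `"rat"` or `"human"`.
#' @param n_tb_generations Number of conducting (TB) generations; trachea = 1.
#' @param pulmonary_offshoot_range Two integers: the range of parent TB
#'   generations that may spawn pulmonary offshoots or terminate into acini.
#' @param terminal_pul_generations Pulmonary generations appended to every
#'   terminal bronchiole and offshoot.
#' @param diameter_ratio List with `major`, `minor` (mean child/parent
#'   diameter ratios, in (0, 1)) and `sd_log` (lognormal spread of the draws).
#' @param length_to_diameter List with `tb`, `pul` (mean length/diameter
#'   ratios) and `sd_log`.
#' @param asymmetry Probability that a branch point inside the offshoot range
#'   spawns a pulmonary offshoot instead of a minor conducting daughter.
#' @param termination_diameter_cm Conducting airways thinner than this become
#'   terminal bronchioles (the axial trunk is exempt and always reaches
#'   `n_tb_generations`).
#' @param trachea_diameter_cm,trachea_length_cm Root airway dimensions.
#' @param target_airway_count Approximate total airway count; when set, the
#'   termination diameter is adjusted to approach it.
#' @param alveolar_volume_cm3 Total alveolar volume apportioned equally over
#'   pulmonary airways; default from the constants file for the template
#'   species.
#' @param seed Integer seed; identical parameters and seed give an identical
#'   tree.
#' @return An object of class `tree_gen_params`.
#' @export
tree_gen_params <- function(species_template = "rat",
                            n_tb_generations = if (species_template == "rat") 28L else 17L,
                            pulmonary_offshoot_range = c(8L, 28L),
                            terminal_pul_generations = 8L,
                            diameter_ratio = NULL,
                            length_to_diameter = NULL,
                            asymmetry = if (species_template == "rat") 0.45 else 0,
                            termination_diameter_cm = 0.02,
                            trachea_diameter_cm = if (species_template == "rat") 0.26 else 1.8,
                            trachea_length_cm = if (species_template == "rat") 2.68 else 10,
                            target_airway_count = NULL,
                            alveolar_volume_cm3 = NULL,
                            seed = 1L) {
  species_template <- match.arg(species_template, c("rat", "human"))
  if (is.null(diameter_ratio)) {
    diameter_ratio <- if (species_template == "rat") {
      list(major = 0.91, minor = 0.63, sd_log = 0.04)
    } else {
      list(major = 0.79, minor = 0.79, sd_log = 0)
    }
  }
  if (is.null(length_to_diameter)) {
    length_to_diameter <- list(tb = 2.7, pul = 1.3,
                               sd_log = if (species_template == "rat") 0.15 else 0)
  }
  if (is.null(alveolar_volume_cm3)) {
    cst <- default_constants()
    alveolar_volume_cm3 <- if (species_template == "rat") {
      cst$lung$rat_alveolar_volume_cm3
    } else {
      cst$lung$human_alveolar_volume_cm3
    }
  }
  p <- list(species_template = species_template,
            n_tb_generations = as.integer(n_tb_generations),
            pulmonary_offshoot_range = as.integer(pulmonary_offshoot_range),
            terminal_pul_generations = as.integer(terminal_pul_generations),
            diameter_ratio = diameter_ratio,
            length_to_diameter = length_to_diameter,
            asymmetry = asymmetry,
            termination_diameter_cm = termination_diameter_cm,
            trachea_diameter_cm = trachea_diameter_cm,
            trachea_length_cm = trachea_length_cm,
            target_airway_count = target_airway_count,
            alveolar_volume_cm3 = alveolar_volume_cm3,
            seed = as.integer(seed))
  if (p$n_tb_generations < 1 || p$terminal_pul_generations < 1) {
    stop("generation counts must be >= 1", call. = FALSE)
  }
  if (p$asymmetry < 0 || p$asymmetry > 1) {
    stop("asymmetry must lie in [0, 1]", call. = FALSE)
  }
  rr <- unlist(diameter_ratio[c("major", "minor")])
  if (any(rr <= 0) || any(rr >= 1)) {
    stop("diameter ratios must lie in (0, 1)", call. = FALSE)
  }
  if (!is.null(target_airway_count) && target_airway_count < 1) {
    stop("target_airway_count must be >= 1", call. = FALSE)
  }
  structure(p, class = "tree_gen_params")
}

#' Generate a synthetic monopodial airway tree
#'
#' Grows a random airway tree according to [tree_gen_params()]. With the rat
#' template the result honors the structural contract of the rat-like lung:
#' `n_tb_generations` conducting generations with a complete axial path,
#' pulmonary outgrowths only from conducting generations inside
#' `pulmonary_offshoot_range`, `terminal_pul_generations` pulmonary
#' generations capping every terminal bronchiole, child diameters strictly
#' smaller than their parent, and full determinism in the seed. The surrogate
#' is sized for desk-scale computation (conducting airway counts of order
#' 10³–10⁴); it makes no claim of anatomical fidelity to any particular lung
#' cast.
#'
#' @param params A [tree_gen_params()] object.
#' @return A valid [airway_tree()] (asymmetric representation).
#' @examples
#' tr <- generate_monopodial_tree(tree_gen_params(seed = 42))
#' max(tr$airways$generation)
#' @export
generate_monopodial_tree <- function(params = tree_gen_params()) {
  stopifnot(inherits(params, "tree_gen_params"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(params$seed)
  if (is.null(params$target_airway_count)) {
    tree <- grow_tree(params)
  } else {
    # adjust the termination diameter towards the requested size
    d_term <- params$termination_diameter_cm
    tree <- NULL
    for (i in seq_len(10)) {
      set.seed(params$seed)
      p2 <- params
      p2$termination_diameter_cm <- d_term
      tree <- grow_tree(p2)
      n <- nrow(tree$airways)
      ratio <- n / params$target_airway_count
      if (ratio > 2 / 3 && ratio < 3 / 2) break
      # thinner termination -> deeper, larger tree
      d_term <- d_term * ratio^0.4
    }
    tree
  }
}

grow_tree <- function(p) {
  cap <- 4096L
  id <- integer(cap); parent <- integer(cap); gen <- integer(cap)
  region <- character(cap); len <- numeric(cap); dia <- numeric(cap)
  bang <- numeric(cap); gang <- numeric(cap); lobe <- character(cap)
  n <- 0L
  add <- function(pid, g, reg, d, L, ba, ga, lb) {
    n <<- n + 1L
    if (n > cap) {
      cap <<- cap * 2L
      for (nm in c("id", "parent", "gen", "len", "dia", "bang", "gang")) {
        assign(nm, `length<-`(get(nm), cap), inherits = TRUE)
      }
      region <<- `length<-`(region, cap); lobe <<- `length<-`(lobe, cap)
    }
    id[n] <<- n; parent[n] <<- pid; gen[n] <<- g; region[n] <<- reg
    dia[n] <<- d; len[n] <<- L; bang[n] <<- ba; gang[n] <<- ga; lobe[n] <<- lb
    n
  }
  rld <- function(mean) mean * exp(stats::rnorm(1, 0, p$length_to_diameter$sd_log))
  rratio <- function(mean) {
    min(0.98, mean * exp(stats::rnorm(1, 0, p$diameter_ratio$sd_log)))
  }
  clamp <- function(x, lo, hi) min(max(x, lo), hi)
  rgrav <- function() stats::runif(1, 10, 80)
  off_lo <- p$pulmonary_offshoot_range[1]
  off_hi <- p$pulmonary_offshoot_range[2]
  rat_lobes <- c("right-cranial", "right-middle", "right-accessory")
  side_branches <- 0L

  add_acinus <- function(pid, g0, d0, lb) {
    if (p$species_template == "human") {
      # dichotomous acinus, mirroring the symmetric human pulmonary region
      frontier <- list(c(pid, g0, d0))
      while (length(frontier)) {
        nd <- frontier[[1]]; frontier[[1]] <- NULL
        if (nd[2] - g0 >= p$terminal_pul_generations) next
        for (k in 1:2) {
          d <- nd[3] * rratio(0.79)
          ch <- add(nd[1], nd[2] + 1L, "PUL", d,
                    d * rld(p$length_to_diameter$pul),
                    clamp(stats::rnorm(1, 45, 5), 0, 90), rgrav(), lb)
          frontier[[length(frontier) + 1L]] <- c(ch, nd[2] + 1L, d)
        }
      }
    } else {
      # monopodial acinus: a single respiratory-bronchiole/alveolar-duct path
      d <- d0 * rratio(0.75)
      for (k in seq_len(p$terminal_pul_generations)) {
        pid <- add(pid, g0 + k, "PUL", d, d * rld(p$length_to_diameter$pul),
                   if (k == 1) clamp(stats::rnorm(1, 60, 10), 20, 90)
                   else clamp(stats::rnorm(1, 35, 10), 0, 90),
                   rgrav(), lb)
        d <- d * rratio(0.92)
      }
    }
  }

  root <- add(NA_integer_, 1L, "TB", p$trachea_diameter_cm,
              p$trachea_length_cm, 0, 0, NA_character_)
  # stack of conducting airways still to branch: (index, is_trunk)
  stack <- list(c(root, 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    j <- top[1]; trunk <- top[2] == 1L
    g <- gen[j]; d <- dia[j]; lb <- lobe[j]
    terminal <- g == p$n_tb_generations ||
      (!trunk && g >= off_lo && d < p$termination_diameter_cm)
    if (terminal) {
      add_acinus(j, g, d, lb)
      next
    }
    # major daughter continues the (sub)trunk
    d_maj <- d * rratio(p$diameter_ratio$major)
    lb_maj <- if (g == 1 && p$species_template == "rat") "right-caudal" else lb
    maj <- add(j, g + 1L, "TB", d_maj, d_maj * rld(p$length_to_diameter$tb),
               clamp(abs(stats::rnorm(1, 15, 5)), 0, 60), rgrav(), lb_maj)
    # second daughter: minor conducting airway or pulmonary offshoot
    spawn_offshoot <- g >= off_lo && g <= off_hi &&
      stats::runif(1) < p$asymmetry
    if (spawn_offshoot) {
      add_acinus(j, g, d * rratio(p$diameter_ratio$minor), lb)
    } else {
      d_min <- d * rratio(p$diameter_ratio$minor)
      lb_min <- lb
      if (p$species_template == "rat") {
        if (g == 1) {
          lb_min <- "left"
        } else if (trunk && side_branches < length(rat_lobes)) {
          side_branches <- side_branches + 1L
          lb_min <- rat_lobes[side_branches]
        }
      }
      mnr <- add(j, g + 1L, "TB", d_min, d_min * rld(p$length_to_diameter$tb),
                 clamp(stats::rnorm(1, 60, 10), 20, 90), rgrav(), lb_min)
      stack[[length(stack) + 1L]] <- c(mnr, 0L)
    }
    stack[[length(stack) + 1L]] <- c(maj, if (trunk) 1L else 0L)
  }

  a <- data.frame(id = id[1:n], parent_id = parent[1:n], generation = gen[1:n],
                  region = region[1:n], length_cm = len[1:n],
                  diameter_cm = dia[1:n], branching_angle_deg = bang[1:n],
                  gravity_angle_deg = gang[1:n], multiplicity = 1,
                  lobe = lobe[1:n], distal_volume_cm3 = 0)
  # distal volumes: lumen plus equal alveolar share per pulmonary airway
  lumen <- pi / 4 * a$diameter_cm^2 * a$length_cm
  n_pul <- sum(a$region == "PUL")
  if (n_pul == 0) stop("generated tree has no pulmonary airways", call. = FALSE)
  alv <- ifelse(a$region == "PUL", p$alveolar_volume_cm3 / n_pul, 0)
  distal <- lumen + alv
  for (j in rev(seq_len(n))) { # children have larger indices than parents
    pj <- a$parent_id[j]
    if (!is.na(pj)) distal[pj] <- distal[pj] + distal[j]
  }
  a$distal_volume_cm3 <- distal
  tree <- airway_tree(a, species = p$species_template,
                      representation = "asymmetric",
                      body_weight_g = if (p$species_template == "rat") 300 else NA,
                      provenance = sprintf(
                        "synthetic monopodial surrogate (template %s, seed %d)",
                        p$species_template, p$seed))
  viol <- validate_tree(tree)
  if (length(viol)) {
    stop("generated tree violates invariants: ", paste(viol, collapse = "; "),
         call. = FALSE)
  }
  tree
}
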