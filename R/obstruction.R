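#' Diameter of the coalesced deposited mass
#'
#' The total particle mass deposited in an airway over the exposure is assumed
#' to coalesce into a single sphere; its diameter `(6 V / pi)^(1/3)` with
#' `V = mass / density` is the quantity compared against the airway diameter.
#'
#' @param mass_ug Deposited mass, µg (>= 0). Vectorized.
#' @param density Particle density, g/cm³ (> 0).
#' @return Sphere diameter in cm (0 for zero mass).
#' @examples
#' coalesced_sphere_diameter(1, 1) # 1 ug at unit density -> ~0.0124 cm
#' @export
coalesced_sphere_diameter <- function(mass_ug, density = 1) {
  if (!is.finite(density) || density <= 0) {
    stop("density must be > 0", call. = FALSE)
  }
  if (any(!is.finite(mass_ug)) || any(mass_ug < 0)) {
    stop("mass must be >= 0", call. = FALSE)
  }
  v <- mass_ug * 1e-6 / density # cm3
  (6 * v / pi)^(1 / 3)
}

#' Per-airway obstruction ratios
#'
#' For every tracheobronchial and pulmonary airway (the empirically modeled
#' head is excluded), the ratio of the diameter of the coalesced deposited
#' aerosol mass in that single airway to the airway's own diameter. A ratio of
#' 1 means the deposited material would form a sphere as wide as the airway;
#' ratios above 0.5 flag vulnerability to significant obstruction. Ratios use
#' per-single-airway masses, so they are invariant to whether a symmetric tree
#' is stored per generation or expanded.
#'
#' @param result A [run_deposition()] result.
#' @param tree The [airway_tree()] the result was computed on.
#' @param density Particle density used to convert mass to volume, g/cm³.
#' @return An object of class `obstruction_profile` holding `per_airway`
#'   (id, generation, region, multiplicity, diameter_cm, mass_per_airway_ug,
#'   ratio); complete the profile with [bin_ratios()].
#' @export
obstruction_ratios <- function(result, tree, density = 1) {
  stopifnot(inherits(result, "deposition_result"),
            inherits(tree, "airway_tree"))
  pa <- result$per_airway
  aw <- tree$airways
  if (!setequal(pa$id, aw$id)) {
    stop("deposition result and tree refer to different airway ids",
         call. = FALSE)
  }
  idx <- match(pa$id, aw$id)
  per <- data.frame(
    id = pa$id, generation = pa$generation, region = pa$region,
    multiplicity = pa$multiplicity, diameter_cm = aw$diameter_cm[idx],
    mass_per_airway_ug = pa$mass_per_airway_ug,
    ratio = coalesced_sphere_diameter(pa$mass_per_airway_ug, density) /
      aw$diameter_cm[idx])
  per <- per[per$region %in% c("TB", "PUL"), ]
  rownames(per) <- NULL
  structure(list(label = result$label, per_airway = per, density = density,
                 bin_edges = NULL, histogram = NULL, by_generation = NULL),
            class = "obstruction_profile")
}

#' Bin obstruction ratios into the standard reporting intervals
#'
#' Sorts per-airway obstruction ratios into half-open intervals
#' (right-open, last bin unbounded), counting each symmetric generation row
#' with its multiplicity. The `"rat"` scheme uses quartile edges 0, 0.25, 0.5,
#' 0.75, 1 and >1; the `"human"` scheme uses 0, 0.1, 0.2, 0.3, 0.4, 0.5 and
#' >0.5. Counts and percentages are reported for TB and PUL separately and
#' combined, together with per-generation mean and maximum ratios.
#'
#' @param profile An [obstruction_ratios()] profile.
#' @param species_bins `"rat"`, `"human"`, or a numeric vector of custom bin
#'   edges starting at 0.
#' @return The completed `obstruction_profile` with elements `bin_edges`,
#'   `histogram` (data.frame: region, bin_low, bin_high, count, percent) and
#'   `by_generation` (per-generation mean/max ratio and airway count).
#' @export
bin_ratios <- function(profile, species_bins = "human") {
  stopifnot(inherits(profile, "obstruction_profile"))
  edges <- if (is.numeric(species_bins)) {
    species_bins
  } else {
    switch(match.arg(species_bins, c("rat", "human")),
           rat = c(0, 0.25, 0.5, 0.75, 1),
           human = c(0, 0.1, 0.2, 0.3, 0.4, 0.5))
  }
  if (edges[1] != 0 || is.unsorted(edges, strictly = TRUE)) {
    stop("bin edges must start at 0 and increase", call. = FALSE)
  }
  per <- profile$per_airway
  full_edges <- c(edges, Inf)
  k <- length(edges)
  hist_region <- function(sub, region_label) {
    cls <- findInterval(sub$ratio, full_edges, rightmost.closed = FALSE,
                        left.open = FALSE)
    counts <- vapply(seq_len(k), function(i) sum(sub$multiplicity[cls == i]),
                     numeric(1))
    total <- sum(sub$multiplicity)
    data.frame(region = region_label, bin_low = edges,
               bin_high = c(edges[-1], Inf), count = counts,
               percent = if (total > 0) 100 * counts / total else 0 * counts)
  }
  hist_ <- rbind(hist_region(per, "all"),
                 hist_region(per[per$region == "TB", ], "TB"),
                 hist_region(per[per$region == "PUL", ], "PUL"))
  by_gen <- do.call(rbind, lapply(split(per, per$generation), function(s) {
    data.frame(generation = s$generation[1],
               n_airways = sum(s$multiplicity),
               mean_ratio = sum(s$ratio * s$multiplicity) / sum(s$multiplicity),
               max_ratio = max(s$ratio))
  }))
  rownames(by_gen) <- NULL
  profile$bin_edges <- edges
  profile$histogram <- hist_
  profile$by_generation <- by_gen
  profile
}

#' @export
print.obstruction_profile <- function(x, ...) {
  cat(sprintf("Obstruction profile '%s' (%d airway rows, density %g g/cm3)\n",
              x$label, nrow(x$per_airway), x$density))
  cat(sprintf("  max ratio %.3g\n", max(x$per_airway$ratio)))
  if (!is.null(x$histogram)) {
    h <- x$histogram[x$histogram$region == "all", ]
    for (i in seq_len(nrow(h))) {
      cat(sprintf("  [%.2g, %.2g): %s airways (%.2f%%)\n", h$bin_low[i],
                  h$bin_high[i], format(h$count[i], big.mark = ","),
                  h$percent[i]))
    }
  }
  invisible(x)
}

#' Compare binned obstruction profiles across scenarios
#'
#' Places two or more completed profiles (identical bin edges) side by side
#' and flags, for the ordering given, whether the count of airways above each
#' bin edge increases monotonically — e.g. across increasing exposure
#' concentrations.
#'
#' @param profiles List of completed [bin_ratios()] profiles.
#' @param labels Optional labels (defaults to the profiles' own labels).
#' @return An object of class `obstruction_comparison`: a list with `table`
#'   (long data.frame of counts/percentages per profile, region and bin) and
#'   `monotonicity` (per region and bin edge, whether counts above the edge
#'   are non-decreasing and strictly increasing along the given order).
#' @export
compare_profiles <- function(profiles, labels = NULL) {
  if (length(profiles) < 2) stop("need at least two profiles", call. = FALSE)
  for (p in profiles) {
    if (!inherits(p, "obstruction_profile") || is.null(p$histogram)) {
      stop("all profiles must be completed with bin_ratios()", call. = FALSE)
    }
  }
  edges <- profiles[[1]]$bin_edges
  for (p in profiles[-1]) {
    if (!identical(p$bin_edges, edges)) {
      stop("profiles have inconsistent bin edges", call. = FALSE)
    }
  }
  if (is.null(labels)) labels <- vapply(profiles, `[[`, "", "label")
  tab <- do.call(rbind, Map(function(p, lb) {
    h <- p$histogram
    h$profile <- lb
    h
  }, profiles, labels))
  rownames(tab) <- NULL
  mono <- do.call(rbind, lapply(c("all", "TB", "PUL"), function(reg) {
    do.call(rbind, lapply(edges[-1], function(edge) {
      above <- vapply(profiles, function(p) {
        h <- p$histogram
        sum(h$count[h$region == reg & h$bin_low >= edge])
      }, numeric(1))
      data.frame(region = reg, above_edge = edge,
                 counts = I(list(above)),
                 non_decreasing = !is.unsorted(above),
                 strictly_increasing = all(diff(above) > 0))
    }))
  }))
  rownames(mono) <- NULL
  structure(list(table = tab, monotonicity = mono, labels = labels),
            class = "obstruction_comparison")
}

#' @export
print.obstruction_comparison <- function(x, ...) {
  cat("Obstruction comparison across:", paste(x$labels, collapse = ", "), "\n")
  wide <- stats::reshape(
    x$table[x$table$region == "all", c("bin_low", "bin_high", "profile", "count")],
    direction = "wide", idvar = c("bin_low", "bin_high"),
    timevar = "profile")
  print(wide, row.names = FALSE)
  invisible(x)
}
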