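#' Airway tree container
#'
#' An `airway_tree` is a directed rooted tree of conducting (TB) and pulmonary
#' (PUL) airway segments with morphometry, stored as a data.frame with one row
#' per airway (asymmetric representation) or one row per generation
#' (symmetric representation, with `multiplicity` = number of identical
#' airways the row stands for). All per-row dimensions and volumes are
#' per-single-airway values.
#'
#' Columns: `id`, `parent_id` (NA for the root), `generation` (1-based,
#' trachea = 1), `region` ("TB" or "PUL"), `length_cm`, `diameter_cm`,
#' `branching_angle_deg` (from the parent axis), `gravity_angle_deg` (from the
#' gravity vector; 0 = vertical airway), `multiplicity`, `lobe`,
#' `distal_volume_cm3` (lumen + alveolar volume of the subtended subtree,
#' including the airway itself).
#'
#' @param airways data.frame with the columns above.
#' @param species `"rat"` or `"human"`.
#' @param representation `"symmetric"` or `"asymmetric"`.
#' @param body_weight_g Body weight in grams, or NA.
#' @param provenance Free-text description of where the geometry came from.
#' @return An object of class `airway_tree`.
#' @seealso [builtin_human_tree()], [generate_monopodial_tree()],
#'   [validate_tree()]
#' @export
airway_tree <- function(airways, species, representation,
                        body_weight_g = NA_real_, provenance = "") {
  species <- match.arg(species, c("rat", "human"))
  representation <- match.arg(representation, c("symmetric", "asymmetric"))
  airways <- as.data.frame(airways)
  missing <- setdiff(tree_columns(), names(airways))
  if (length(missing)) {
    stop("airway table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  airways <- airways[tree_columns()]
  rownames(airways) <- NULL
  structure(list(airways = airways, species = species,
                 representation = representation,
                 body_weight_g = body_weight_g, provenance = provenance),
            class = "airway_tree")
}

tree_columns <- function() {
  c("id", "parent_id", "generation", "region", "length_cm", "diameter_cm",
    "branching_angle_deg", "gravity_angle_deg", "multiplicity", "lobe",
    "distal_volume_cm3")
}

#' @export
print.airway_tree <- function(x, ...) {
  a <- x$airways
  n_total <- sum(a$multiplicity)
  cat(sprintf("Airway tree: %s, %s representation\n", x$species,
              x$representation))
  cat(sprintf("  %d rows; %s airways in %d generations (TB %s, PUL %s)\n",
              nrow(a), format(n_total, big.mark = ","), max(a$generation),
              format(sum(a$multiplicity[a$region == "TB"]), big.mark = ","),
              format(sum(a$multiplicity[a$region == "PUL"]), big.mark = ",")))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Built-in symmetric human airway geometry
#'
#' Returns the symmetric typical-path human whole-lung model after Yeh & Schum
#' (1980): 17 generations of tracheobronchial airways (trachea = generation 1)
#' with 7 generations of pulmonary airways appended to each terminal
#' bronchiole, for 24 generations in total. Generation g stands for
#' `2^(g-1)` identical airways. The per-generation morphometry table ships as
#' a plain-text fixture under `extdata/yeh_schum_human.csv`; alveolar volume
#' (default from the constants file) is apportioned equally among the
#' pulmonary airways to form distal volumes.
#'
#' @param constants Constants list, see [default_constants()].
#' @return An `airway_tree` in symmetric representation.
#' @examples
#' tr <- builtin_human_tree()
#' sum(tr$airways$multiplicity) # 2^24 - 1 airways
#' @export
builtin_human_tree <- function(constants = default_constants()) {
  path <- system.file("extdata", "yeh_schum_human.csv", package = "respdose")
  if (path == "") path <- file.path("inst", "extdata", "yeh_schum_human.csv")
  tab <- utils::read.csv(path, comment.char = "#")
  n <- nrow(tab)
  mult <- 2^(tab$generation - 1)
  lumen <- pi / 4 * tab$diameter_cm^2 * tab$length_cm # per single airway
  # alveolar volume split equally across the alveolated (pulmonary)
  # generations, then equally among that generation's airways
  pul_gens <- sum(tab$region == "PUL")
  v_gen <- constants$lung$human_alveolar_volume_cm3 / pul_gens
  alv <- ifelse(tab$region == "PUL", v_gen / mult, 0)
  # distal volume per single airway, leaves upward (2 children per airway)
  distal <- numeric(n)
  for (g in rev(seq_len(n))) {
    distal[g] <- lumen[g] + alv[g] + if (g < n) 2 * distal[g + 1] else 0
  }
  airway_tree(
    data.frame(id = seq_len(n),
               parent_id = c(NA_integer_, seq_len(n - 1L)),
               generation = tab$generation,
               region = tab$region,
               length_cm = tab$length_cm,
               diameter_cm = tab$diameter_cm,
               branching_angle_deg = tab$branching_angle_deg,
               gravity_angle_deg = tab$gravity_angle_deg,
               multiplicity = mult,
               lobe = NA_character_,
               distal_volume_cm3 = distal),
    species = "human", representation = "symmetric",
    provenance = "Yeh-Schum typical-path human whole-lung model (literature morphometry table)")
}

#' Validate an airway tree
#'
#' Checks all structural and morphometric invariants of an [airway_tree()]:
#' exactly one root, no orphans or cycles, child generation = parent
#' generation + 1, positive dimensions, angles in \\[0, 180\\], multiplicity
#' >= 1 (with the symmetric doubling rule `2^(g-1)` in symmetric
#' representation), and pulmonary airways never at generation 1. Violations
#' are returned as data, not raised as errors.
#'
#' @param tree An `airway_tree`.
#' @return Character vector of human-readable violations; empty when valid.
#' @examples
#' validate_tree(builtin_human_tree())
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "airway_tree"))
  a <- tree$airways
  v <- character(0)
  if (anyDuplicated(a$id)) v <- c(v, "duplicate airway ids")
  root <- which(is.na(a$parent_id))
  if (length(root) != 1) {
    v <- c(v, sprintf("expected exactly one root, found %d", length(root)))
  }
  pi_ <- match(a$parent_id, a$id)
  orphan <- !is.na(a$parent_id) & is.na(pi_)
  if (any(orphan)) {
    v <- c(v, sprintf("orphan airway (missing parent): id %s",
                      paste(a$id[orphan], collapse = ", ")))
  }
  bad_dim <- a$length_cm <= 0 | a$diameter_cm <= 0 |
    !is.finite(a$length_cm) | !is.finite(a$diameter_cm)
  if (any(bad_dim)) {
    v <- c(v, sprintf("non-positive dimension: id %s",
                      paste(a$id[bad_dim], collapse = ", ")))
  }
  bad_ang <- a$branching_angle_deg < 0 | a$branching_angle_deg > 180 |
    a$gravity_angle_deg < 0 | a$gravity_angle_deg > 180
  if (any(bad_ang, na.rm = TRUE)) {
    v <- c(v, sprintf("angle outside [0, 180]: id %s",
                      paste(a$id[which(bad_ang)], collapse = ", ")))
  }
  if (any(a$multiplicity < 1)) v <- c(v, "multiplicity < 1")
  ok <- !is.na(pi_)
  gen_bad <- ok & (a$generation != a$generation[pi_] + 1L)
  if (any(gen_bad, na.rm = TRUE)) {
    v <- c(v, sprintf("generation not parent+1: id %s",
                      paste(a$id[which(gen_bad)], collapse = ", ")))
  }
  if (any(a$region == "PUL" & a$generation <= 1)) {
    v <- c(v, "pulmonary airway at generation 1")
  }
  if (length(root) == 1 && !any(orphan)) {
    # connectivity/acyclicity: every airway must reach the root by parents
    depth <- rep(NA_integer_, nrow(a))
    depth[root] <- 0L
    changed <- TRUE
    while (changed) {
      newd <- depth[pi_] + 1L
      upd <- which(is.na(depth) & !is.na(newd))
      changed <- length(upd) > 0
      depth[upd] <- newd[upd]
    }
    if (anyNA(depth)) {
      v <- c(v, sprintf("unreachable from root (cycle or disconnected): id %s",
                        paste(a$id[is.na(depth)], collapse = ", ")))
    }
  }
  if (tree$representation == "symmetric") {
    if (!isTRUE(all(a$multiplicity == 2^(a$generation - 1)))) {
      v <- c(v, "symmetric representation requires multiplicity 2^(generation-1)")
    }
  }
  v
}

#' Read and write airway geometry CSV files
#'
#' The geometry exchange format is a UTF-8 CSV with a header row and one row
#' per airway (or per generation in symmetric representation) with columns
#' `id,parent_id,generation,region,length_cm,diameter_cm,branching_angle_deg,
#' gravity_angle_deg,multiplicity,lobe,distal_volume_cm3`. Leading `#` lines
#' carry metadata (`species`, `representation`, `body_weight_g`,
#' `provenance`) and are written/parsed by these functions; `read_tree()`
#' after `write_tree()` is the identity on valid trees.
#'
#' @param path File path.
#' @param tree An `airway_tree`.
#' @return `read_tree()` returns an `airway_tree`; `write_tree()` returns
#'   `path` invisibly.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("geometry file not found: ", path, call. = FALSE)
  hdr <- character(0)
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line) || !startsWith(line, "#")) break
    hdr <- c(hdr, line)
  }
  close(con)
  on.exit()
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub("\\s*:.*$", "", kv)
    val <- sub("^[^:]*:\\s*", "", kv)
    meta[[key]] <- val
  }
  a <- utils::read.csv(path, comment.char = "#",
                       colClasses = c(lobe = "character"))
  missing <- setdiff(tree_columns(), names(a))
  if (length(missing)) {
    stop("geometry CSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dup <- which(duplicated(a$id))
  if (length(dup)) {
    stop("duplicate airway id in row(s) ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(a$length_cm) | !is.finite(a$diameter_cm))
  if (length(bad)) {
    stop("malformed morphometry in row(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  a$lobe[a$lobe == ""] <- NA_character_
  tree <- airway_tree(
    a,
    species = meta$species %||% "human",
    representation = meta$representation %||% "asymmetric",
    body_weight_g = suppressWarnings(as.numeric(meta$body_weight_g %||% NA)),
    provenance = meta$provenance %||% "")
  v <- validate_tree(tree)
  cyc <- grep("unreachable", v, value = TRUE)
  if (length(cyc)) stop("geometry CSV invalid: ", cyc[1], call. = FALSE)
  tree
}

#' @rdname read_tree
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "airway_tree"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# species: %s", tree$species),
    sprintf("# representation: %s", tree$representation),
    sprintf("# body_weight_g: %s", format(tree$body_weight_g)),
    sprintf("# provenance: %s", tree$provenance)), con)
  utils::write.csv(format_tree_table(tree$airways), con, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

format_tree_table <- function(a) {
  num <- c("length_cm", "diameter_cm", "branching_angle_deg",
           "gravity_angle_deg", "distal_volume_cm3")
  for (col in num) a[[col]] <- sprintf("%.10g", a[[col]])
  a
}

#' Expand a symmetric tree into explicit per-airway rows
#'
#' Materializes the dichotomous tree a symmetric per-generation representation
#' stands for, down to `max_generation`. Intended for cross-checks on
#' truncated trees; a full 24-generation human tree would have 16.7 million
#' rows and is never materialized by the package itself.
#'
#' @param tree A symmetric `airway_tree`.
#' @param max_generation Deepest generation to expand.
#' @return An `airway_tree` in asymmetric representation, whose per-generation
#'   airway counts and dimensions match the symmetric original.
#' @export
expand_symmetric <- function(tree, max_generation) {
  stopifnot(inherits(tree, "airway_tree"),
            tree$representation == "symmetric")
  a <- tree$airways[tree$airways$generation <= max_generation, ]
  a <- a[order(a$generation), ]
  rows <- list()
  next_id <- 1L
  prev_ids <- integer(0)
  for (i in seq_len(nrow(a))) {
    g <- a$generation[i]
    n_g <- 2^(g - 1)
    ids <- seq.int(next_id, length.out = n_g)
    next_id <- next_id + as.integer(n_g)
    parents <- if (g == 1) NA_integer_ else rep(prev_ids, each = 2)
    rows[[i]] <- data.frame(
      id = ids, parent_id = parents, generation = g, region = a$region[i],
      length_cm = a$length_cm[i], diameter_cm = a$diameter_cm[i],
      branching_angle_deg = a$branching_angle_deg[i],
      gravity_angle_deg = a$gravity_angle_deg[i], multiplicity = 1,
      lobe = NA_character_,
      distal_volume_cm3 = a$distal_volume_cm3[i])
    prev_ids <- ids
  }
  out <- do.call(rbind, rows)
  airway_tree(out, species = tree$species, representation = "asymmetric",
              body_weight_g = tree$body_weight_g,
              provenance = paste(tree$provenance, "(expanded)"))
}
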