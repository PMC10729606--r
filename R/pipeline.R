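#' End-to-end dosimetry pipeline
#'
#' Runs one or more exposure scenarios through deposition and obstruction
#' analysis and writes all result tables plus a reproducibility manifest to an
#' output directory. Per scenario subdirectory: `per_airway.csv`,
#' `regional.csv`, `per_generation.csv`, `obstruction_histogram.csv`,
#' `per_generation_ratios.csv`. At the top level: `comparison.csv` and
#' `comparison.txt` (when >= 2 scenarios share a bin scheme) and
#' `manifest.json` (config echo, constants, seed, package version, config
#' hash). Every CSV carries a `#` header block naming the config hash and
#' seed. On any failure the partially written output directory is removed and
#' the failing stage named.
#'
#' @param config A list (or path to a YAML/JSON file) with fields:
#'   \describe{
#'     \item{scenarios}{character vector of scenario YAML/JSON paths, or a
#'       list of [exposure_scenario()] objects.}
#'     \item{tree}{`"builtin:human"`, a geometry CSV path, `"generate"` (rat
#'       surrogate with `seed`), or an [airway_tree()]. Ignored for scenario
#'       objects, which carry their tree.}
#'     \item{out_dir}{output directory (created; must be writable).}
#'     \item{bins}{`"rat"`, `"human"` or numeric bin edges; default chosen by
#'       species per scenario.}
#'     \item{seed}{integer seed for tree generation.}
#'     \item{constants}{optional path to a constants YAML overriding the
#'       shipped one.}
#'     \item{n_bins}{aerosol size bins for the engine (default 1000).}
#'   }
#' @return Invisibly, a list with the deposition results, obstruction
#'   profiles, the comparison (or NULL) and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config needs an out_dir", call. = FALSE)
  created <- !dir.exists(out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  }
  ok <- FALSE
  written <- character(0)
  on.exit({
    if (!ok) {
      unlink(written, recursive = TRUE)
      if (created) unlink(out_dir, recursive = TRUE)
    }
  })

  seed <- as.integer(config$seed %||% 1L)
  constants <- if (!is.null(config$constants)) {
    read_constants(config$constants)
  } else {
    default_constants()
  }
  n_bins <- config$n_bins %||% 1000

  stage <- "resolve-tree"
  result <- tryCatch({
    tree <- resolve_tree(config$tree %||% "builtin:human", seed, constants)

    stage <- "load-scenarios"
    scenarios <- config$scenarios
    if (is.null(scenarios)) stop("config needs scenarios", call. = FALSE)
    if (is.character(scenarios)) {
      for (f in scenarios) {
        if (!file.exists(f)) stop("scenario file not found: ", f, call. = FALSE)
      }
      scenarios <- lapply(scenarios, read_scenario, tree = tree)
    }
    # the echo identifies the run content; file-system locations are not part
    # of the run identity, so reruns elsewhere hash identically
    cfg_echo <- config
    cfg_echo$scenarios <- vapply(scenarios, `[[`, "", "label")
    cfg_echo$out_dir <- NULL
    if (is.character(config$tree)) cfg_echo$tree <- basename(config$tree)
    cfg_hash <- config_hash(list(cfg_echo, constants, seed))

    stage <- "deposition"
    results <- lapply(scenarios, run_deposition, n_bins = n_bins,
                      constants = constants)
    names(results) <- vapply(results, `[[`, "", "label")

    stage <- "obstruction"
    profiles <- Map(function(sc, res) {
      scheme <- config$bins %||% sc$tree$species
      bin_ratios(obstruction_ratios(res, sc$tree, sc$aerosol$density), scheme)
    }, scenarios, results)
    names(profiles) <- names(results)

    stage <- "write-outputs"
    hdr <- c(sprintf("# config_hash: %s", cfg_hash),
             sprintf("# seed: %d", seed),
             sprintf("# respdose_version: %s",
                     as.character(utils::packageVersion("respdose"))))
    for (i in seq_along(results)) {
      sub <- file.path(out_dir, names(results)[i])
      dir.create(sub, showWarnings = FALSE)
      written <- c(written, sub)
      res <- results[[i]]
      prof <- profiles[[i]]
      write_csv_with_header(res$per_airway, file.path(sub, "per_airway.csv"), hdr)
      write_csv_with_header(res$regional, file.path(sub, "regional.csv"), hdr)
      write_csv_with_header(res$per_generation,
                            file.path(sub, "per_generation.csv"), hdr)
      write_csv_with_header(prof$histogram,
                            file.path(sub, "obstruction_histogram.csv"), hdr)
      write_csv_with_header(prof$by_generation,
                            file.path(sub, "per_generation_ratios.csv"), hdr)
    }

    stage <- "comparison"
    comparison <- NULL
    schemes <- vapply(profiles, function(p) paste(p$bin_edges, collapse = ","), "")
    tab <- table(schemes)
    if (length(tab) && max(tab) >= 2) {
      grp <- profiles[schemes == names(which.max(tab))]
      comparison <- compare_profiles(grp)
      cmp_tab <- comparison$table
      written <- c(written, file.path(out_dir, c("comparison.csv",
                                                 "comparison.txt")))
      write_csv_with_header(cmp_tab, file.path(out_dir, "comparison.csv"), hdr)
      txt <- utils::capture.output(print(comparison))
      writeLines(c(hdr, txt), file.path(out_dir, "comparison.txt"))
    }

    stage <- "manifest"
    manifest <- list(config = cfg_echo, constants = constants, seed = seed,
                     version = as.character(utils::packageVersion("respdose")),
                     config_hash = cfg_hash,
                     scenarios = lapply(results, function(r) {
                       list(label = r$label,
                            inhalable_fraction = r$inhalable_fraction,
                            total_inhaled_mass_ug = r$total_inhaled_mass_ug)
                     }))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(results = results, profiles = profiles, comparison = comparison,
         manifest = manifest)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  ok <- TRUE
  invisible(result)
}

resolve_tree <- function(tree, seed, constants) {
  if (inherits(tree, "airway_tree")) return(tree)
  if (identical(tree, "builtin:human")) return(builtin_human_tree(constants))
  if (identical(tree, "generate")) {
    return(generate_monopodial_tree(tree_gen_params(seed = seed)))
  }
  if (is.list(tree) && identical(tree$source %||% "", "generate")) {
    prm <- tree
    prm$source <- NULL
    prm$seed <- prm$seed %||% seed
    return(generate_monopodial_tree(do.call(tree_gen_params, prm)))
  }
  if (is.character(tree) && length(tree) == 1) return(read_tree(tree))
  stop("unrecognized tree specification", call. = FALSE)
}

write_csv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  num <- vapply(df, is.numeric, TRUE)
  for (col in names(df)[num]) df[[col]] <- sprintf("%.12g", df[[col]])
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}
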