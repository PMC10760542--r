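#' Run configuration
#'
#' Collects every tunable of the analysis pipeline. Unknown keys are
#' rejected on load, and every run writes the fully resolved
#' configuration alongside its results so outputs are self-describing.
#'
#' @param detection A [detection_params()].
#' @param line_width_px Linescan perpendicular averaging width, pixels.
#' @param baseline_method `"global_median"` or `"local_min"`.
#' @param edge_policy `"count_for_density"` (edge puncta excluded from
#'   means but counted for density; default) or `"exclude"` (dropped
#'   entirely).
#' @param um_per_px Optional calibration override; takes precedence over
#'   TIFF resolution tags and sample-sheet values.
#' @param alpha Significance level for group comparisons.
#' @param seed Optional integer seed recorded with outputs.
#' @return A `run_config` list.
#' @export
run_config <- function(detection = detection_params(),
                       line_width_px = 3L,
                       baseline_method = c("global_median", "local_min"),
                       edge_policy = c("count_for_density", "exclude"),
                       um_per_px = NULL,
                       alpha = 0.05,
                       seed = NULL) {
  structure(list(
    detection = detection,
    line_width_px = as.integer(line_width_px),
    baseline_method = match.arg(baseline_method),
    edge_policy = match.arg(edge_policy),
    um_per_px = um_per_px,
    alpha = alpha,
    seed = if (!is.null(seed)) as.integer(seed)
  ), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file; top-level keys must be arguments of
#'   [run_config()], with `detection` a mapping of [detection_params()]
#'   arguments. Unknown keys are an error, never silently ignored.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(run_config)), "detection")
  extra <- setdiff(names(raw), c(known, "detection"))
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  det <- raw$detection
  if (!is.null(det)) {
    bad <- setdiff(names(det), names(formals(detection_params)))
    if (length(bad))
      stop("unknown detection key(s): ", paste(bad, collapse = ", "))
    det <- do.call(detection_params, det)
  } else det <- detection_params()
  do.call(run_config, c(list(detection = det), raw[intersect(names(raw),
                                                             known)]))
}

#' Write the resolved configuration next to results
#' @param config A `run_config`.
#' @param dir Output directory.
#' @return The file path, invisibly.
#' @export
write_resolved_config <- function(config, dir) {
  path <- file.path(dir, "config_resolved.yaml")
  yaml::write_yaml(lapply(unclass(config), function(x)
    if (is.list(x)) unclass(x) else x), path)
  invisible(path)
}

# Resolve one sample-sheet row to an intensity profile.
load_animal_profile <- function(row, config) {
  f <- row$file
  if (!file.exists(f)) stop("file not found: ", f)
  um_override <- config$um_per_px
  sheet_um <- if (!is.null(row$um_per_px) && is.finite(row$um_per_px))
    row$um_per_px else NULL
  if (grepl("\\.csv$", f, ignore.case = TRUE)) {
    um <- um_override %||% sheet_um
    return(read_profile_csv(f, um_per_px = um))
  }
  st <- read_tiff_stack(f)
  um <- um_override %||% sheet_um %||%
    (if (is.finite(st$um_per_px)) st$um_per_px else NULL)
  if (is.null(um))
    stop("no calibration for ", f,
         ": supply um_per_px in the config or sample sheet, ",
         "or a TIFF resolution tag")
  img <- calibrated_image(max_project(st$slices), um, source_id = f)
  if (is.na(row$cord_path_file) || !nzchar(row$cord_path_file))
    stop("image input ", f, " needs a cord_path_file")
  path <- read_cord_path(row$cord_path_file,
                         line_width_px = config$line_width_px)
  extract_profile(img, path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analyze every animal of a study
#'
#' Runs the full per-animal chain (load image or profile, maximum
#' projection, linescan, smoothing, Phansalkar thresholding, size
#' filter, punctum measurement, per-animal aggregation) over a sample
#' sheet. Per-animal failures are caught, reported, and do not abort the
#' remaining animals.
#'
#' @param sample_sheet Path to a sample sheet CSV, or a data frame, with
#'   columns `file, animal_id, genotype, bead_intensity` and optionally
#'   `cord_path_file, um_per_px`.
#' @param config A [run_config()].
#' @param output_dir If given, per-punctum and per-animal CSVs plus the
#'   resolved configuration are written there.
#' @return List with `puncta` (tibble over all animals), `animals`
#'   (one row per successful animal), `failures` (tibble of animal_id,
#'   error).
#' @export
analyze_study <- function(sample_sheet, config = run_config(),
                          output_dir = NULL) {
  sheet <- if (is.character(sample_sheet))
    utils::read.csv(sample_sheet) else as.data.frame(sample_sheet)
  need <- c("file", "animal_id", "genotype", "bead_intensity")
  miss <- setdiff(need, names(sheet))
  if (length(miss))
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  puncta <- list(); animals <- list(); fails <- list()
  for (i in seq_len(nrow(sheet))) {
    row <- sheet[i, ]
    res <- tryCatch({
      prof <- load_animal_profile(row, config)
      a <- analyze_profile(prof, config$detection, row$bead_intensity,
                           animal_id = row$animal_id,
                           genotype = row$genotype,
                           baseline_method = config$baseline_method)
      if (config$edge_policy == "exclude" && nrow(a$puncta)) {
        kept <- a$puncta[!a$puncta$at_edge, ]
        a$animal <- aggregate_animal(kept, a$animal$cord_length_um,
                                     row$bead_intensity,
                                     row$animal_id, row$genotype)
        a$puncta <- kept
      }
      a
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("animal ", row$animal_id, " failed: ",
              conditionMessage(res), call. = FALSE)
      fails[[length(fails) + 1L]] <-
        tibble::tibble(animal_id = as.character(row$animal_id),
                       error = conditionMessage(res))
    } else {
      puncta[[length(puncta) + 1L]] <- res$puncta
      animals[[length(animals) + 1L]] <- res$animal
    }
  }
  out <- list(
    puncta = if (length(puncta)) do.call(rbind, puncta) else tibble::tibble(),
    animals = if (length(animals)) do.call(rbind, animals) else
      tibble::tibble(),
    failures = if (length(fails)) do.call(rbind, fails) else
      tibble::tibble(animal_id = character(), error = character())
  )
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out$puncta, file.path(output_dir, "puncta.csv"),
                     row.names = FALSE)
    utils::write.csv(out$animals, file.path(output_dir, "animals.csv"),
                     row.names = FALSE)
    write_resolved_config(config, output_dir)
  }
  out
}

#' Compare genotype groups of an analyzed study
#'
#' @param animals Per-animal tibble or path to an `animals.csv` written
#'   by [analyze_study()].
#' @param wt_genotype,mut_genotype Genotype labels.
#' @param output_dir If given, writes `comparisons.csv` and a JSON
#'   report.
#' @return Tibble from [compare_all_metrics()].
#' @export
compare_study <- function(animals, wt_genotype = "wt",
                          mut_genotype = "mut", output_dir = NULL) {
  if (is.character(animals)) animals <- utils::read.csv(animals)
  genos <- unique(animals$genotype)
  if (length(genos) < 2L)
    stop("need at least two genotypes, found: ",
         paste(genos, collapse = ", "))
  cmp <- compare_all_metrics(animals, wt_genotype, mut_genotype)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cmp, file.path(output_dir, "comparisons.csv"),
                     row.names = FALSE)
    jsonlite::write_json(cmp, file.path(output_dir, "comparisons.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  cmp
}
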