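# Run configuration and end-to-end orchestration (library face of the
# command-line tool).

.abct_version <- function() {
  as.character(utils::packageVersion("abct"))
}

#' Default run configuration
#'
#' All tunables of a counting run in one structured object: input paths,
#' voxel size, segmentation and filter parameters, conversion factors,
#' chunking and output options. Settings are explicit artifacts — every
#' output file echoes the full configuration, because grey-level
#' thresholds must be re-calibrated for each instrument.
#'
#' @return A named list (class `ab_run_config`).
#' @export
default_run_config <- function() {
  structure(list(
    inputs = character(0),
    voxel_size = 0.332,
    segmentation = unclass(segmentation_params()),
    filter = unclass(filter_params()),
    conversion = unclass(conversion_factors()),
    n_chunks = 1L,
    overlap_vox = NULL,
    output_dir = ".",
    seed = 1L,
    log_level = "info"
  ), class = "ab_run_config")
}

#' Read a run configuration from JSON
#'
#' Fields absent from the file keep their defaults
#' ([default_run_config()]); nested parameter blocks are validated
#' through their constructors.
#'
#' @param path JSON file path.
#' @return An `ab_run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_run_config()
  for (nm in names(raw)) {
    if (nm %in% c("segmentation", "filter", "conversion")) {
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], as.list(raw[[nm]]))
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  .validate_run_config(cfg)
}

.validate_run_config <- function(cfg) {
  cfg$segmentation <- unclass(do.call(segmentation_params,
                                      cfg$segmentation))
  cfg$filter <- unclass(do.call(filter_params, cfg$filter))
  cfg$conversion <- unclass(do.call(conversion_factors, cfg$conversion))
  if (cfg$voxel_size <= 0) stop("voxel_size must be positive")
  if (cfg$n_chunks < 1) stop("n_chunks must be >= 1")
  class(cfg) <- "ab_run_config"
  cfg
}

#' Write a run configuration as JSON
#'
#' @param cfg an `ab_run_config` list.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Generate a phantom volume and its ground truth
#'
#' Thin orchestration over the phantom module: samples a fibre
#' population, renders it, and writes the volume TIFF, the ground-truth
#' CSV and a spec echo JSON to `output_dir`. Identical spec and seed give
#' byte-identical outputs.
#'
#' @param spec an [phantom_spec()] object.
#' @param output_dir output directory (created if needed).
#' @param basename file stem for the three outputs.
#' @return Invisibly, list of written paths plus the rendered volume and
#'   truth records.
#' @export
cmd_phantom <- function(spec, output_dir = ".", basename = "phantom") {
  stopifnot(inherits(spec, "ab_phantom_spec"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  records <- sample_fibre_population(spec)
  vol <- render_phantom(records, spec)
  truth <- vol$meta$ground_truth
  paths <- list(
    volume = file.path(output_dir, paste0(basename, ".tif")),
    truth = file.path(output_dir, paste0(basename, "_truth.csv")),
    spec = file.path(output_dir, paste0(basename, "_spec.json"))
  )
  write_volume(vol, paths$volume, bits = 32L)
  if (nrow(truth) == 0L) {
    # header-only CSV for an empty population
    writeLines(paste(c("id", "cx_um", "cy_um", "cz_um", "ox", "oy", "oz",
                       "length_um", "width_um", "volume_um3"),
                     collapse = ","), paths$truth)
  } else {
    write_ground_truth(truth, paths$truth)
  }
  jsonlite::write_json(c(unclass(spec), list(version = .abct_version())),
                       paths$spec, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, list(volume_obj = vol, truth = truth)))
}

#' Count asbestos bodies in the configured volumes
#'
#' Runs the full workflow on every input TIFF of a run configuration:
#' detection per volume (optionally chunked), per-volume morphometry CSV,
#' replicate density statistics, conversion to bodies per gram dry lung,
#' and a JSON run summary (parameter echo, per-stage counts, `V_c`,
#' version).
#'
#' @param cfg an `ab_run_config` list with at least one input TIFF.
#' @param verbose log per-stage counts.
#' @return Invisibly, list with the per-volume `ab_table`s, the burden
#'   result, the morphometry report of the pooled accepted objects, and
#'   written paths.
#' @export
cmd_count <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "ab_run_config"))
  if (length(cfg$inputs) == 0L) stop("run config lists no input volumes")
  missing <- cfg$inputs[!file.exists(cfg$inputs)]
  if (length(missing) > 0L)
    stop("input volume(s) not found: ", paste(missing, collapse = ", "))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  seg <- do.call(segmentation_params, cfg$segmentation)
  filt <- do.call(filter_params, cfg$filter)
  fac <- do.call(conversion_factors, cfg$conversion)

  tables <- list()
  csvs <- character(0)
  for (i in seq_along(cfg$inputs)) {
    vol <- read_volume(cfg$inputs[i], cfg$voxel_size)
    tab <- detect_ab(vol, seg, filt, n_chunks = cfg$n_chunks,
                     overlap_vox = cfg$overlap_vox, verbose = verbose)
    tables[[i]] <- tab
    stem <- tools::file_path_sans_ext(basename(cfg$inputs[i]))
    csvs[i] <- file.path(cfg$output_dir,
                         paste0(stem, "_morphometry.csv"))
    write_morphometry_csv(tab, csvs[i])
  }
  counts <- vapply(tables, function(t) nrow(t$accepted), numeric(1))
  vcs <- vapply(tables, function(t) t$V_c_cm3, numeric(1))
  burden <- burden_result(counts, vcs, fac)
  pooled <- tables[[1]]
  if (length(tables) > 1L) {
    pooled$accepted <- do.call(rbind, lapply(tables, `[[`, "accepted"))
    pooled$objects <- do.call(rbind, lapply(tables, `[[`, "objects"))
  }
  report <- if (nrow(pooled$accepted) > 0L) morphometry_report(pooled)
            else NULL
  summary_path <- file.path(cfg$output_dir, "run_summary.json")
  jsonlite::write_json(list(
    version = .abct_version(),
    config = unclass(cfg),
    replicates = data.frame(input = cfg$inputs, accepted = counts,
                            V_c_cm3 = vcs,
                            density_cm3 = burden$densities_cm3),
    stages = lapply(tables, `[[`, "stages"),
    burden = list(mean_cm3 = burden$mean_cm3, sd_cm3 = burden$sd_cm3,
                  n_replicates = burden$n_replicates,
                  n_gdw = burden$n_gdw, exceeds_ers = burden$exceeds_ers),
    morphometry = if (is.null(report)) NULL else list(
      n = report$n, mean_length_um = report$mean_length_um,
      mean_width_um = report$mean_width_um,
      mean_volume_um3 = report$mean_volume_um3)
  ), summary_path, auto_unbox = TRUE, digits = NA, null = "null",
     dataframe = "rows", pretty = TRUE)
  invisible(list(tables = tables, burden = burden, report = report,
                 morphometry_csv = csvs, summary_json = summary_path))
}

#' Convert a density to bodies per gram dry lung (command form)
#'
#' @param density_cm3 number density in cm^-3, >= 0.
#' @param factors an [conversion_factors()] object.
#' @return The burden per gram of dry tissue.
#' @export
cmd_convert <- function(density_cm3, factors = conversion_factors()) {
  if (!is.numeric(density_cm3) || any(density_cm3 < 0))
    stop("density must be numeric and >= 0")
  convert_to_gdw(density_cm3, factors)
}
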