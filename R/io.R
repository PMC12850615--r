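# NIfTI and sidecar I/O, configuration handling, and the config-driven
# pipeline runner. Voxel coordinates are 0-based array indices;
# physical positions are index * voxel_size + origin.

#' Read a 3D volume from NIfTI
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @return A [volume_grid()] with the header voxel size.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D volume, got ", length(d), " dimensions")
  px <- RNifti::pixdim(img)
  if (max(px) - min(px) > 1e-6 * max(px))
    stop("anisotropic voxels (", paste(signif(px, 4), collapse = " x "),
         " mm) are not supported")
  v <- array(as.numeric(img), dim = d)
  if (!all(is.finite(v))) stop("volume contains non-finite values")
  volume_grid(v, px[1])
}

#' Write a 3D volume to NIfTI
#'
#' @param volume `volume_grid` or 3D array.
#' @param path output file (.nii or .nii.gz).
#' @param voxel_size voxel size in mm when `volume` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, voxel_size = vol_voxel_size(volume)) {
  v <- vol_values(volume)
  img <- RNifti::asNifti(v, reference = NULL)
  RNifti::pixdim(img) <- rep(voxel_size, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a label map from NIfTI with a legend sidecar
#'
#' @param path NIfTI file of integer labels.
#' @param legend tissue table data frame, or path to a JSON sidecar as
#'   written by [write_labels()].
#' @return A [label_map()].
#' @export
read_labels <- function(path, legend) {
  vol <- read_volume(path)
  if (is.character(legend)) legend <- jsonlite::fromJSON(legend)
  l <- vol$values
  if (max(abs(l - round(l))) > 1e-6)
    stop("label volume contains non-integer values")
  label_map(array(as.integer(round(l)), dim = dim(l)), vol$voxel_size, legend)
}

#' Write a label map to NIfTI plus a JSON legend sidecar
#'
#' @param labels a [label_map()].
#' @param path output NIfTI file; the legend is written next to it with
#'   a `.json` extension.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  write_volume(labels$labels, path, labels$voxel_size)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(labels$legend, side, dataframe = "rows",
                       digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' Load a run configuration
#'
#' Reads a YAML or JSON configuration and validates it against the
#' known keys; unknown keys are rejected before any computation.
#'
#' @param path YAML/JSON file, or a list of settings.
#' @return Validated configuration list.
#' @export
load_run_config <- function(path) {
  cfg <- if (is.list(path)) path
  else if (grepl("\\.json$", path)) jsonlite::fromJSON(path)
  else yaml::read_yaml(path)
  known <- c("output_dir", "preset", "grid_size", "seed", "snr",
             "n_iterations", "methods", "resolution_factor", "target_snr",
             "stc_tol", "stc_max_iter", "psf_grid_size", "fs", "verbosity")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  defaults <- list(preset = "small", seed = 1L, snr = 10, n_iterations = 5L,
                   methods = c("none", "pssr", "mlts", "gtm", "stc", "estc"),
                   resolution_factor = 2L, stc_tol = 1e-4,
                   stc_max_iter = 100L, psf_grid_size = 128, fs = 0.6)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (is.null(cfg$output_dir)) stop("configuration requires 'output_dir'")
  cfg
}

#' Run the full pipeline from a configuration
#'
#' Generates the phantom, writes its volumes, runs the Monte Carlo
#' evaluation, and writes the reports (CSV + JSON) together with a
#' provenance record (configuration, seed, package version, content
#' hash of the configuration).
#'
#' @param config path to a YAML/JSON configuration or a list (see
#'   [load_run_config()]).
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- load_run_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  geom <- if (!is.null(cfg$grid_size))
    phantom_geometry(grid_size = cfg$grid_size)
  else phantom_geometry(preset = cfg$preset)
  tt <- tissue_table(fs = cfg$fs)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           " (artifacts written so far are retained in ", cfg$output_dir,
           ")", call. = FALSE))
  }

  bundle <- stage("make-phantom", generate_phantom(geom, tt, seed = cfg$seed))
  stage("write-phantom", {
    write_volume(bundle$ground_truth,
                 file.path(cfg$output_dir, "ground_truth.nii.gz"))
    write_labels(bundle$labels, file.path(cfg$output_dir, "labels.nii.gz"))
    write_volume(make_sensitivity(geom),
                 file.path(cfg$output_dir, "sensitivity.nii.gz"))
  })

  ec <- evaluation_config(n_iterations = cfg$n_iterations, snr = cfg$snr,
                          methods = cfg$methods, seed = cfg$seed,
                          geometry = geom, tissues = tt,
                          resolution_factor = cfg$resolution_factor,
                          stc_tol = cfg$stc_tol,
                          stc_max_iter = cfg$stc_max_iter,
                          psf_grid_size = cfg$psf_grid_size)
  report <- stage("evaluate", run_monte_carlo(ec))

  utils::write.csv(report$noise_free,
                   file.path(cfg$output_dir, "noise_free.csv"),
                   row.names = FALSE)
  utils::write.csv(report$monte_carlo,
                   file.path(cfg$output_dir, "monte_carlo.csv"),
                   row.names = FALSE)
  payload <- Filter(Negate(is.null),
                    list(noise_free = report$noise_free,
                         monte_carlo = report$monte_carlo,
                         convergence = report$convergence,
                         errors = report$errors))
  jsonlite::write_json(payload, file.path(cfg$output_dir, "report.json"),
                       dataframe = "rows", digits = NA, na = "null")

  cfg_json <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                               digits = NA)
  prov <- list(
    package = "sodiumpvc",
    version = as.character(utils::packageVersion("sodiumpvc")),
    seed = cfg$seed,
    config = cfg,
    config_hash = paste0("md5:", digest_string(cfg_json)),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(prov, file.path(cfg$output_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(cfg$output_dir)
}

# md5 of a string via a temporary file (tools::md5sum is file-based).
digest_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(x), tf)
  unname(tools::md5sum(tf))
}
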