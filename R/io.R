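#' Load a run configuration from a flat key/value file
#'
#' The configuration dialect is flat YAML (`key: value` per line). Every
#' key must be a known [sim_config()] field; missing keys take the printed
#' defaults of the `"paper"` preset (line tension 0.06, contractility 0.02,
#' acceptance probability 0.05, displacement 0.005, T1 distance 0.2,
#' boundary factor 1.6, 130000 iterations/sts, 1141 cells, ramp at sts 20,
#' 50 sts in total).
#'
#' @param path Path to the config file. An empty or missing-keys file gives
#'   the full default set.
#' @param preset Base preset the file overrides (default `"paper"`).
#' @return A [sim_config()].
#' @export
load_config <- function(path, preset = "paper") {
  if (!file.exists(path)) {
    abort(sprintf("config file '%s' does not exist", path),
          class = "extrudr_parse_error")
  }
  vals <- tryCatch(yaml::read_yaml(path), error = function(e) {
    abort(sprintf("malformed config file '%s': %s", path, conditionMessage(e)),
          class = "extrudr_parse_error")
  })
  if (is.null(vals)) vals <- list()
  if (is.null(names(vals)) && length(vals) > 0) {
    abort("config must be flat key/value pairs", class = "extrudr_parse_error")
  }
  do.call(sim_config, c(list(preset = preset), vals))
}

#' Save a configuration to a flat key/value file
#'
#' @param cfg A [sim_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Write run outputs with a reproducibility manifest
#'
#' Writes tables as CSV, meshes in the versioned JSON snapshot format and
#' image grids as both CSV matrix and (rescaled) TIFF, then a
#' `manifest.json` listing every artefact with its MD5 content hash along
#' with the configuration and seed, so a published run can be reproduced
#' and checked hash-for-hash.
#'
#' @param out_dir Output directory (created if needed).
#' @param tables Named list of data frames.
#' @param meshes Named list of `tissue_mesh` objects.
#' @param images Named list of numeric matrices.
#' @param config Optional configuration list stored in the manifest.
#' @param seed Optional seed stored in the manifest.
#' @param force Overwrite existing files (default `FALSE`; a collision
#'   without `force` is refused).
#' @return The manifest, invisibly.
#' @export
write_outputs <- function(out_dir, tables = list(), meshes = list(),
                          images = list(), config = NULL, seed = NULL,
                          force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, mode = 2) != 0) {
    abort(sprintf("output directory '%s' is not writable", out_dir),
          class = "extrudr_io_error")
  }
  paths <- character()
  plan <- c(
    stats::setNames(file.path(out_dir, paste0(names(tables), ".csv")),
                    names(tables)),
    stats::setNames(file.path(out_dir, paste0(names(meshes), ".mesh.json")),
                    names(meshes)),
    stats::setNames(file.path(out_dir, paste0(names(images), ".csv")),
                    paste0(names(images), "_img")))
  existing <- plan[file.exists(plan)]
  if (length(existing) > 0 && !force) {
    abort(paste0("refusing to overwrite without `force`: ",
                 paste(basename(existing), collapse = ", ")),
          class = "extrudr_io_error")
  }
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(tables[[nm]], p)
    paths <- c(paths, p)
  }
  for (nm in names(meshes)) {
    p <- file.path(out_dir, paste0(nm, ".mesh.json"))
    write_mesh(meshes[[nm]], p)
    paths <- c(paths, p)
  }
  for (nm in names(images)) {
    img <- images[[nm]]
    p_csv <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.table(img, p_csv, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    p_tif <- file.path(out_dir, paste0(nm, ".tif"))
    rng <- max(img, 1e-300)
    tiff::writeTIFF(pmin(pmax(img / rng, 0), 1), p_tif)
    paths <- c(paths, p_csv, p_tif)
  }
  manifest <- list(
    package = "extrudr",
    version = as.character(utils::packageVersion("extrudr")),
    seed = seed, config = config,
    artefacts = lapply(paths, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
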