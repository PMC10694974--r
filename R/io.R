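# File interfaces: TIFF volumes with JSON sidecars (voxel size is
# metadata-mandatory, never inferred from TIFF tags), CSV tables for
# records and profiles, JSON for scalar results and the run manifest.

#' Read a CT volume with its metadata sidecar
#'
#' @param path multi-page TIFF stack.
#' @param sidecar path to a JSON sidecar, or a list; must contain
#'   `voxel_size_um` (hard error if missing — the voxel size is never
#'   guessed from TIFF tags) and may contain `slice_axis` (default 3).
#' @return a [voxel_volume()].
#' @export
read_volume <- function(path, sidecar) {
  if (missing(sidecar) || is.null(sidecar))
    mycomat_error("missing_metadata", "a sidecar with voxel_size_um is required")
  meta <- if (is.character(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE)
          else sidecar
  if (is.null(meta$voxel_size_um))
    mycomat_error("missing_metadata", "sidecar does not provide voxel_size_um")
  axis <- as.integer(meta$slice_axis %||% 3L)
  arr <- read_tiff_stack(path, slice_axis = axis)
  voxel_volume(arr, voxel_size_um = as.numeric(meta$voxel_size_um),
               slice_axis = axis, provenance = path)
}

#' Write a volume (plus sidecar) as a multi-page TIFF
#'
#' @param vol a [voxel_volume()] or logical array (masks are written 0/255).
#' @param path output TIFF path; the sidecar goes to `<path>.json`.
#' @param bits 8 or 16.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, bits = 8L) {
  if (is_voxel_volume(vol)) {
    write_tiff_stack(vol$values, path, bits = bits, slice_axis = vol$slice_axis)
    jsonlite::write_json(list(voxel_size_um = vol$voxel_size_um,
                              slice_axis = vol$slice_axis),
                         paste0(path, ".json"), auto_unbox = TRUE)
  } else {
    write_tiff_stack(vol, path, bits = bits)
  }
  invisible(path)
}

#' Run configuration
#'
#' @param ... named configuration entries (paths, [segmentation_params()]
#'   fields, shell width, seed, ...).
#' @param file optional JSON file to load first; `...` overrides.
#' @return list of class `run_config`.
#' @export
run_config <- function(..., file = NULL) {
  cfg <- if (!is.null(file)) jsonlite::read_json(file, simplifyVector = TRUE) else list()
  dots <- list(...)
  cfg <- utils::modifyList(cfg, dots)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  structure(cfg, class = "run_config")
}

results_to_json <- function(x) {
  strip <- function(v) {
    if (inherits(v, "qty")) list(value = qty_value(v), unit = qty_unit(v))
    else if (is.list(v) && !is.data.frame(v)) lapply(v, strip)
    else v
  }
  strip(x)
}

#' Write analysis outputs and a reproducibility manifest
#'
#' Masks are written as 8-bit TIFF stacks (0/255), shell profiles and
#' tables as CSV, scalar summaries as JSON. A `manifest.json` records the
#' written files, the configuration hash, the seed and the package
#' version, so every artifact is reproducible from the manifest.
#'
#' @param results named list; entries are dispatched on class
#'   (`shive_segmentation`, `hyphae_segmentation`, `shell_profile`,
#'   `voxel_volume`, data.frame, anything else becomes JSON).
#' @param out_dir output directory (created if needed).
#' @param config optional [run_config()] stored and hashed in the manifest.
#' @param seed seed recorded in the manifest.
#' @return the manifest, invisibly.
#' @export
write_outputs <- function(results, out_dir, config = NULL, seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) mycomat_error("io", sprintf("cannot create %s", out_dir))
  files <- character(0)
  emit <- function(name, x) {
    if (inherits(x, "shive_segmentation")) {
      f1 <- file.path(out_dir, paste0(name, "_solid.tif"))
      write_tiff_stack(x$solid_mask, f1)
      files <<- c(files, f1)
      if (!is.null(x$apparent_mask)) {
        f2 <- file.path(out_dir, paste0(name, "_apparent.tif"))
        write_tiff_stack(x$apparent_mask, f2)
        files <<- c(files, f2)
      }
      f3 <- file.path(out_dir, paste0(name, "_summary.json"))
      jsonlite::write_json(list(V_solid_um3 = x$V_solid_um3,
                                V_solid_plus_pores_um3 = x$V_solid_plus_pores_um3,
                                epsilon_substrate = x$epsilon_substrate,
                                apparent_density_kg_m3 = x$apparent_density_kg_m3),
                           f3, auto_unbox = TRUE, digits = NA)
      files <<- c(files, f3)
    } else if (inherits(x, "hyphae_segmentation")) {
      f1 <- file.path(out_dir, paste0(name, "_mask.tif"))
      write_tiff_stack(x$mask, f1)
      f2 <- file.path(out_dir, paste0(name, "_summary.json"))
      jsonlite::write_json(list(V_hyphae_um3 = x$V_hyphae_um3,
                                n_objects = x$n_objects),
                           f2, auto_unbox = TRUE, digits = NA)
      files <<- c(files, f1, f2)
    } else if (inherits(x, "shell_profile")) {
      f <- file.path(out_dir, paste0(name, ".csv"))
      write.csv(as.data.frame(x), f, row.names = FALSE)
      files <<- c(files, f)
    } else if (inherits(x, "skeleton_graph")) {
      f <- file.path(out_dir, paste0(name, "_skeleton.csv"))
      sk <- as.data.frame(x$skeleton_voxels)
      names(sk) <- c("x", "y", "z")
      write.csv(sk, f, row.names = FALSE)
      files <<- c(files, f)
    } else if (is_voxel_volume(x)) {
      f <- file.path(out_dir, paste0(name, ".tif"))
      write_volume(x, f, bits = 16L)
      files <<- c(files, f, paste0(f, ".json"))
    } else if (is.data.frame(x)) {
      f <- file.path(out_dir, paste0(name, ".csv"))
      write.csv(x, f, row.names = FALSE)
      files <<- c(files, f)
    } else {
      f <- file.path(out_dir, paste0(name, ".json"))
      jsonlite::write_json(results_to_json(x), f, auto_unbox = TRUE, digits = NA,
                           force = TRUE)
      files <<- c(files, f)
    }
  }
  for (nm in names(results)) emit(nm, results[[nm]])
  cfg_file <- file.path(out_dir, "config.json")
  jsonlite::write_json(results_to_json(unclass(config %||% list())), cfg_file,
                       auto_unbox = TRUE, force = TRUE)
  manifest <- list(files = basename(files),
                   config_hash = unname(tools::md5sum(cfg_file)),
                   seed = seed,
                   package = "mycomat",
                   version = as.character(utils::packageVersion("mycomat")),
                   r_version = R.version.string,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

#' Read a test-record CSV
#'
#' Column conventions: compression `displacement_mm,force_N`; bending
#' `deflection_mm,force_N`; vapour `time_h,mass_g`. Metadata (A0, d0,
#' geometry, area, pressure, thickness) comes from a JSON sidecar or
#' arguments.
#'
#' @param path CSV file.
#' @param type `"compression"`, `"bending"` or `"vapour"`.
#' @param meta list or JSON path with the record metadata.
#' @return the corresponding record object.
#' @export
read_record_csv <- function(path, type = c("compression", "bending", "vapour"),
                            meta = list()) {
  type <- match.arg(type)
  if (is.character(meta)) meta <- jsonlite::read_json(meta, simplifyVector = TRUE)
  df <- read.csv(path)
  switch(type,
    compression = stress_strain_curve(df$displacement_mm, df$force_N,
                                      A0_mm2 = meta$A0_mm2, d0_mm = meta$d0_mm,
                                      preload_N = meta$preload_N %||% 20),
    bending = bending_record(df$deflection_mm, df$force_N,
                             geometry = do.call(board_geometry, meta$geometry)),
    vapour = vapour_series(df$time_h, df$mass_g, A_m2 = meta$A_m2,
                           delta_p_Pa = meta$delta_p_Pa, d_m = meta$d_m,
                           condition = meta$condition)
  )
}

#' Write a test record as CSV
#' @param rec a record object.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_record_csv <- function(rec, path) {
  df <- if (inherits(rec, "stress_strain_curve")) {
    data.frame(displacement_mm = rec$displacement_mm, force_N = rec$force_N)
  } else if (inherits(rec, "bending_record")) {
    data.frame(deflection_mm = rec$deflection_mm, force_N = rec$force_N)
  } else if (inherits(rec, "vapour_series")) {
    data.frame(time_h = rec$time_h, mass_g = rec$mass_g)
  } else mycomat_error("config", "unsupported record type")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
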