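#' Serialize phantom / optics / motion specs to and from YAML
#'
#' A single YAML file can hold any subset of `phantom`, `optics`,
#' `motion` sections; reading restores validated spec objects.
#'
#' @param specs named list with any of `phantom`, `optics`, `motion`.
#' @param path YAML file.
#' @return [read_config()] returns the list of restored spec objects.
#' @export
write_config <- function(specs, path) {
  out <- list()
  if (!is.null(specs$phantom)) {
    p <- unclass(specs$phantom)
    if (!is.null(p$ventricle_centers))
      p$ventricle_centers <- apply(p$ventricle_centers, 1, as.numeric,
                                   simplify = FALSE)
    out$phantom <- p
  }
  if (!is.null(specs$optics)) {
    o <- unclass(specs$optics)
    o$surface_power_by_depth <- as.list(o$surface_power_by_depth)
    out$optics <- o
  }
  if (!is.null(specs$motion)) out$motion <- unclass(specs$motion)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @param path YAML file written by [write_config()].
#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(raw$phantom)) {
    p <- raw$phantom
    if (!is.null(p$ventricle_centers))
      p$ventricle_centers <- do.call(rbind, lapply(p$ventricle_centers,
                                                   as.numeric))
    p$ventricle_radius_range <- as.numeric(unlist(p$ventricle_radius_range))
    p$voxel_size <- as.numeric(unlist(p$voxel_size))
    out$phantom <- do.call(phantom_spec, p)
  }
  if (!is.null(raw$optics)) {
    o <- raw$optics
    o$surface_power_by_depth <-
      as.data.frame(lapply(o$surface_power_by_depth, unlist))
    out$optics <- do.call(optics_spec, o)
  }
  if (!is.null(raw$motion)) out$motion <- do.call(motion_spec, raw$motion)
  out
}

#' Read a per-depth excitation power log
#'
#' @param path CSV with columns `z_um, power_mW`.
#' @return validated data.frame sorted by depth.
#' @export
read_power_log <- function(path) {
  df <- read.csv(path)
  if (!all(c("z_um", "power_mW") %in% names(df)))
    stop("power log must have columns z_um, power_mW")
  if (any(df$power_mW <= 0)) stop("power must be > 0")
  df[order(df$z_um), , drop = FALSE]
}

#' Write / read track tables as CSV
#'
#' Columns: `track_id, frame, t_min, z_um, y_um, x_um`.
#'
#' @param tracks `track_table` data.frame or list of `track` objects.
#' @param path CSV file.
#' @export
write_tracks_csv <- function(tracks, path) {
  if (!is.data.frame(tracks)) {
    tracks <- do.call(rbind, lapply(tracks, function(tr) {
      cbind(track_id = tr$track_id,
            tr$points[, c("frame", "t_min", "z_um", "y_um", "x_um")])
    }))
  }
  cols <- c("track_id", "frame", "t_min", "z_um", "y_um", "x_um")
  write.csv(as.data.frame(tracks)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  tab <- read.csv(path)
  stopifnot(all(c("track_id", "frame", "z_um", "y_um", "x_um") %in%
                  names(tab)))
  class(tab) <- c("track_table", class(tab))
  tab
}

#' Run manifest for reproducible CLI stages
#'
#' Records the subcommand, configuration, seed, package and R versions,
#' and MD5 hashes of the input files — enough to re-run a deterministic
#' stage byte-for-byte.
#'
#' @param stage subcommand name.
#' @param config named list of parameters used.
#' @param inputs character vector of input file paths.
#' @param seed integer seed (or NULL).
#' @param path output JSON path.
#' @export
write_manifest <- function(stage, config, inputs, seed, path) {
  inputs <- inputs[file.exists(inputs)]
  man <- list(stage = stage, config = config, seed = seed,
              package_version = as.character(packageVersion("othg")),
              r_version = R.version.string,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              input_hashes = as.list(tools::md5sum(inputs)))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
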