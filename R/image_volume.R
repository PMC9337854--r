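#' Image and label volume containers
#'
#' An `image_volume` wraps a 3D `(z, y, x)` or 4D `(t, z, y, x)` intensity
#' array with its physical voxel size in micrometres and, for time-lapse
#' data, the frame interval in minutes. A `label_volume` wraps an integer
#' 3D segmentation (0 = background) sharing geometry with its source image.
#' Depth `z = 0` is the first acquired slice (the organoid surface).
#'
#' @param data numeric array, 3D `(z,y,x)` or 4D `(t,z,y,x)`.
#' @param voxel_size numeric length-3, micrometres per voxel in `(z,y,x)`.
#' @param frame_interval minutes between volumes (4D only).
#' @param channel optional channel label (e.g. `"THG"`, `"GFP"`, `"7AAD"`).
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(data, voxel_size, frame_interval = NULL,
                         channel = NULL) {
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L))
    stop("'data' must be a 3D (z,y,x) or 4D (t,z,y,x) array")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("'voxel_size' must be three positive numbers (z,y,x) in um")
  if (nd == 4L && is.null(frame_interval))
    stop("4D time-lapse volumes require 'frame_interval' (minutes)")
  if (!is.null(frame_interval)) stopifnot_scalar_pos(frame_interval,
                                                     "frame_interval")
  structure(list(data = data, voxel_size = voxel_size,
                 frame_interval = frame_interval, channel = channel),
            class = "image_volume")
}

#' @param labels integer 3D array, 0 for background.
#' @param provenance `"manual_import"` or `"semi_automatic"`.
#' @rdname image_volume
#' @export
label_volume <- function(labels, voxel_size,
                         provenance = c("semi_automatic", "manual_import")) {
  provenance <- match.arg(provenance)
  if (length(dim(labels)) != 3L) stop("'labels' must be a 3D array")
  if (any(labels < 0)) stop("labels must be non-negative integers")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("'voxel_size' must be three positive numbers (z,y,x) in um")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, voxel_size = voxel_size,
                 provenance = provenance),
            class = "label_volume")
}

is_timelapse <- function(v) length(dim(v$data)) == 4L

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  if (is_timelapse(x))
    cat(sprintf("<image_volume 4D> t=%d z=%d y=%d x=%d", d[1], d[2], d[3], d[4]))
  else
    cat(sprintf("<image_volume 3D> z=%d y=%d x=%d", d[1], d[2], d[3]))
  cat(sprintf("  voxel (z,y,x) = (%g, %g, %g) um", x$voxel_size[1],
              x$voxel_size[2], x$voxel_size[3]))
  if (!is.null(x$frame_interval))
    cat(sprintf("  dt = %g min", x$frame_interval))
  if (!is.null(x$channel)) cat(sprintf("  channel = %s", x$channel))
  cat("\n")
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> z=%d y=%d x=%d, %d label(s), %s\n",
              d[1], d[2], d[3], length(setdiff(unique(as.vector(x$labels)), 0L)),
              x$provenance))
  invisible(x)
}

#' Depth (um) of each z slice of a volume
#'
#' @param volume an `image_volume`.
#' @return numeric vector, `z = 0` at the first slice.
#' @export
slice_depths <- function(volume) {
  nz <- if (is_timelapse(volume)) dim(volume$data)[2] else dim(volume$data)[1]
  (seq_len(nz) - 1) * volume$voxel_size[1]
}

#' Convert between voxel indices and physical micrometre coordinates
#'
#' Voxel indices are 0-based; physical positions refer to voxel centres,
#' so `um = index * voxel_size` axis by axis.
#'
#' @param idx matrix (n x 3) of 0-based `(z,y,x)` voxel indices.
#' @param voxel_size `(z,y,x)` voxel size in um.
#' @return matrix of physical coordinates (um), or indices for the inverse.
#' @export
vox_to_um <- function(idx, voxel_size) {
  idx <- rbind(idx)
  sweep(idx, 2L, voxel_size, `*`)
}

#' @param um matrix (n x 3) of physical `(z,y,x)` coordinates in um.
#' @rdname vox_to_um
#' @export
um_to_vox <- function(um, voxel_size) {
  um <- rbind(um)
  round(sweep(um, 2L, voxel_size, `/`))
}
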