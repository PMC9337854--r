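#' Assemble serially acquired tiles into one volume by stage coordinates
#'
#' Tiles are placed at their nearest-voxel stage offsets (physical um,
#' y down / x right matching image axes); the output bounding box is the
#' union of tiles and overlaps are resolved by policy. Registration is by
#' stage coordinates only, with no correlation refinement, matching
#' coordinate-based serial acquisition.
#'
#' @param tiles list of [image_volume()]s (3D, equal z extent and voxel
#'   size), or file paths readable by [read_tiff()].
#' @param offsets_um n x 2 matrix of `(y, x)` stage offsets in um (must
#'   be unique).
#' @param overlap_policy `"average"`, `"max"` or `"first"`.
#' @return the stitched [image_volume()].
#' @export
assemble_mosaic <- function(tiles, offsets_um,
                            overlap_policy = c("average", "max", "first")) {
  overlap_policy <- match.arg(overlap_policy)
  if (is.character(tiles)) tiles <- lapply(tiles, read_tiff)
  stopifnot(length(tiles) >= 1L)
  offsets_um <- rbind(offsets_um)
  if (nrow(offsets_um) != length(tiles))
    stop("need one (y,x) offset per tile")
  if (anyDuplicated(offsets_um)) stop("stage offsets must be unique")
  vs <- tiles[[1]]$voxel_size
  nz <- dim(tiles[[1]]$data)[1]
  for (i in seq_along(tiles)) {
    if (dim(tiles[[i]]$data)[1] != nz)
      stop("tile ", i, ": z extent differs")
    if (any(abs(tiles[[i]]$voxel_size - vs) > 1e-9))
      stop("tile ", i, ": voxel size differs")
  }
  off_vox <- cbind(round(offsets_um[, 1] / vs[2]),
                   round(offsets_um[, 2] / vs[3]))
  ny <- vapply(tiles, function(t) dim(t$data)[2], integer(1))
  nx <- vapply(tiles, function(t) dim(t$data)[3], integer(1))
  y0 <- min(off_vox[, 1]); x0 <- min(off_vox[, 2])
  off_vox[, 1] <- off_vox[, 1] - y0
  off_vox[, 2] <- off_vox[, 2] - x0
  NY <- max(off_vox[, 1] + ny); NX <- max(off_vox[, 2] + nx)
  acc <- array(0, c(nz, NY, NX))
  cnt <- array(0L, c(nz, NY, NX))
  for (i in seq_along(tiles)) {
    yi <- off_vox[i, 1] + seq_len(ny[i])
    xi <- off_vox[i, 2] + seq_len(nx[i])
    blk <- tiles[[i]]$data
    if (overlap_policy == "average") {
      acc[, yi, xi] <- acc[, yi, xi] + blk
      cnt[, yi, xi] <- cnt[, yi, xi] + 1L
    } else if (overlap_policy == "max") {
      acc[, yi, xi] <- pmax(acc[, yi, xi], blk)
      cnt[, yi, xi] <- 1L
    } else { # first
      fresh <- cnt[, yi, xi] == 0L
      sub <- acc[, yi, xi]
      sub[fresh] <- blk[fresh]
      acc[, yi, xi] <- sub
      cnt[, yi, xi] <- 1L
    }
  }
  if (overlap_policy == "average") {
    pos <- cnt > 0L
    acc[pos] <- acc[pos] / cnt[pos]
  }
  image_volume(acc, vs, channel = tiles[[1]]$channel)
}
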