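#' Voxelwise overlap between two channels (Manders-style count overlap)
#'
#' Each channel is binarized (Otsu by default, the usual automatic
#' choice; fixed or percentile thresholds selectable) and the percentage
#' of above-threshold voxels of one channel that are also above threshold
#' in the other is reported in both directions. This is mask-based
#' "percentage of overlapping", not intensity correlation.
#'
#' @param chan_a,chan_b [image_volume()]s sharing shape and voxel size.
#' @param thresh_method `"otsu"`, `"fixed"` or `"percentile"`.
#' @param thresh_a,thresh_b fixed thresholds (signal units) or percentile
#'   levels in `[0, 100]`, per method.
#' @return a `coloc_result`: `overlap_a_in_b`, `overlap_b_in_a`
#'   (percent; `NA` when the reference mask is empty), thresholds used,
#'   and voxel counts `n_voxels_a, n_voxels_b, n_voxels_joint`.
#' @export
voxel_overlap <- function(chan_a, chan_b,
                          thresh_method = c("otsu", "fixed", "percentile"),
                          thresh_a = NULL, thresh_b = NULL) {
  thresh_method <- match.arg(thresh_method)
  stopifnot(inherits(chan_a, "image_volume"), inherits(chan_b, "image_volume"))
  if (any(dim(chan_a$data) != dim(chan_b$data)))
    stop("channels must share shape")
  if (any(abs(chan_a$voxel_size - chan_b$voxel_size) > 1e-9))
    stop("channels must share voxel size")
  get_thr <- function(x, thr) {
    switch(thresh_method,
      otsu = otsu_threshold(x),
      fixed = {
        if (is.null(thr)) stop("fixed thresholding needs a threshold")
        thr
      },
      percentile = {
        if (is.null(thr)) stop("percentile thresholding needs a level")
        stats::quantile(x, thr / 100, names = FALSE)
      })
  }
  ta <- get_thr(chan_a$data, thresh_a)
  tb <- get_thr(chan_b$data, thresh_b)
  ma <- chan_a$data > ta
  mb <- chan_b$data > tb
  na <- sum(ma); nb <- sum(mb); nj <- sum(ma & mb)
  structure(list(
    overlap_a_in_b = if (na > 0) 100 * nj / na else NA_real_,
    overlap_b_in_a = if (nb > 0) 100 * nj / nb else NA_real_,
    threshold_a = unname(ta), threshold_b = unname(tb),
    thresh_method = thresh_method,
    n_voxels_a = na, n_voxels_b = nb, n_voxels_joint = nj),
    class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "voxel overlap (%s): A in B = %.1f%%, B in A = %.1f%% (|A|=%d, |B|=%d, joint=%d)\n",
    x$thresh_method, x$overlap_a_in_b, x$overlap_b_in_a,
    x$n_voxels_a, x$n_voxels_b, x$n_voxels_joint))
  invisible(x)
}

#' Per-cell overlap: which cells of channel A carry channel-B signal
#'
#' A cell "has" channel-B signal when the mean B intensity within
#' `radius` um of its centroid exceeds `b_threshold` (Otsu of channel B
#' when not given). Mirrors counts of the form "k of n GFP-positive
#' cells emitted somatic THG signal".
#'
#' @param cells_a `spot_table` (or data.frame with `z_um,y_um,x_um`) of
#'   cell centroids in channel A.
#' @param chan_b [image_volume()] of the second channel (3D).
#' @param radius um; must be at least one voxel on every axis.
#' @param b_threshold signal units; default Otsu of channel B.
#' @return a `cell_overlap`: `n_cells_a, n_cells_a_with_b, fraction,
#'   radius_um, b_threshold`.
#' @export
cell_overlap <- function(cells_a, chan_b, radius = 5, b_threshold = NULL) {
  stopifnot(inherits(chan_b, "image_volume"))
  df <- as.data.frame(cells_a)
  stopifnot(all(c("z_um", "y_um", "x_um") %in% names(df)))
  if (!nrow(df)) stop("zero cells in channel A")
  vs <- chan_b$voxel_size
  if (any(radius < vs))
    stop("radius must be >= 1 voxel in every axis (voxel = ",
         paste(vs, collapse = ","), " um)")
  thr <- b_threshold %||% otsu_threshold(chan_b$data)
  d <- dim(chan_b$data)
  hit <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    p <- c(df$z_um[i], df$y_um[i], df$x_um[i])
    lo <- pmax(0L, as.integer(floor((p - radius) / vs)))
    hi <- pmin(d - 1L, as.integer(ceiling((p + radius) / vs)))
    if (any(lo > hi)) next
    zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
    dz2 <- (zi * vs[1] - p[1])^2
    dy2 <- (yi * vs[2] - p[2])^2
    dx2 <- (xi * vs[3] - p[3])^2
    inball <- outer(outer(dz2, dy2, "+"), dx2, "+") <= radius^2
    blk <- chan_b$data[zi + 1, yi + 1, xi + 1, drop = FALSE]
    vals <- blk[array(inball, dim(blk))]
    if (length(vals) && mean(vals) > thr) hit[i] <- TRUE
  }
  structure(list(n_cells_a = nrow(df), n_cells_a_with_b = sum(hit),
                 fraction = mean(hit), radius_um = radius,
                 b_threshold = unname(thr), hits = hit),
            class = "cell_overlap")
}

#' @export
print.cell_overlap <- function(x, ...) {
  cat(sprintf("cell overlap: %d/%d cells (%.1f%%) with channel-B signal within %g um\n",
              x$n_cells_a_with_b, x$n_cells_a, 100 * x$fraction,
              x$radius_um))
  invisible(x)
}
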