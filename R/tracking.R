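#' Detect bright somata in a 3D frame or 4D time-lapse
#'
#' Multiscale Laplacian-of-Gaussian blob detection: the image is Gaussian
#' smoothed at each scale, the anisotropy-corrected 3D Laplacian (in um)
#' is scale-normalized by `sigma^2`, and bright blobs are local maxima
#' (26-neighborhood) of the strongest response across scales, above a
#' threshold relative to the frame's maximum response (so doubling the
#' global intensity leaves detections unchanged). Centroids are refined
#' to subvoxel precision by an intensity-weighted average in a
#' one-sigma neighborhood. Deterministic.
#'
#' @param volume an [image_volume()], 3D or 4D.
#' @param sigma_range `(min, max)` blob scale in um; for a soma of radius
#'   r the matched scale is about `r / sqrt(3)`.
#' @param threshold relative response threshold in `(0, 1)`.
#' @param n_scales scales spanned log-uniformly across `sigma_range`.
#' @return a `spot_table` data.frame: `spot_id, frame, t_min, z_um, y_um,
#'   x_um, intensity` (blank frames simply contribute no rows).
#' @export
detect_spots <- function(volume, sigma_range = c(2, 4), threshold = 0.2,
                         n_scales = 3L) {
  stopifnot(inherits(volume, "image_volume"))
  vs <- volume$voxel_size
  dt <- volume$frame_interval %||% NA_real_
  sigmas <- exp(seq(log(sigma_range[1]), log(sigma_range[2]),
                    length.out = n_scales))
  frames <- if (is_timelapse(volume)) seq_len(dim(volume$data)[1]) else 1L
  out <- list()
  for (f in frames) {
    img <- if (is_timelapse(volume)) volume$data[f, , , ] else volume$data
    resp <- NULL
    for (s in sigmas) {
      sm <- gaussian_blur3(img, s / vs)
      r <- -s^2 * laplacian3_um(sm, vs)
      resp <- if (is.null(resp)) r else pmax(resp, r)
    }
    mx <- max(resp)
    if (!(mx > 0)) next
    peaks <- cpp_local_maxima(resp, as.integer(dim(resp)), threshold * mx)
    if (!length(peaks)) next
    idx <- arrayInd(peaks, dim(resp)) - 1L  # 0-based (z,y,x)
    cen <- t(vapply(seq_len(nrow(idx)), function(i)
      refine_centroid(img, idx[i, ], vs, mean(sigma_range)),
      numeric(3)))
    ord <- order(cen[, 1], cen[, 2], cen[, 3])
    out[[length(out) + 1L]] <- data.frame(
      frame = f - 1L,
      t_min = if (is.na(dt)) NA_real_ else (f - 1L) * dt,
      z_um = cen[ord, 1], y_um = cen[ord, 2], x_um = cen[ord, 3],
      intensity = resp[peaks][ord])
  }
  tab <- if (length(out)) do.call(rbind, out)
  else data.frame(frame = integer(0), t_min = numeric(0), z_um = numeric(0),
                  y_um = numeric(0), x_um = numeric(0),
                  intensity = numeric(0))
  tab <- cbind(spot_id = seq_len(nrow(tab)), tab)
  class(tab) <- c("spot_table", class(tab))
  tab
}

## 3D Laplacian with physical (um) spacing, reflect boundaries
laplacian3_um <- function(a, voxel_size) {
  d <- dim(a)
  out <- array(0, d)
  for (ax in 1:3) {
    k <- c(1, -2, 1) / voxel_size[ax]^2
    out <- out + cpp_conv_axis(a, as.integer(d), k, ax - 1L)
  }
  out
}

refine_centroid <- function(img, idx0, voxel_size, radius_um) {
  d <- dim(img)
  r_vox <- pmax(1L, as.integer(round(radius_um / voxel_size)))
  lo <- pmax(0L, idx0 - r_vox)
  hi <- pmin(d - 1L, idx0 + r_vox)
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  blk <- img[zi + 1, yi + 1, xi + 1, drop = FALSE]
  w <- blk - min(blk)
  tw <- sum(w)
  if (tw == 0) return(idx0 * voxel_size)
  wz <- apply(w, 1, sum); wy <- apply(w, 2, sum); wx <- apply(w, 3, sum)
  c(sum(zi * wz) / tw * voxel_size[1],
    sum(yi * wy) / tw * voxel_size[2],
    sum(xi * wx) / tw * voxel_size[3])
}

#' Link detected spots into tracks
#'
#' Frame-to-frame linking by globally optimal one-to-one assignment
#' (Hungarian method via `clue::solve_LSAP`) minimizing summed squared
#' displacement; candidate pairs farther than `max_step` are gated out
#' and unmatched spots start or end tracks. Optional gap closing joins a
#' track end to a later track start within `max_gap_frames` skipped
#' frames and `max_step * (gap + 1)` um; closed gaps are recorded per
#' track. Tracks shorter than `min_frames` observations are discarded
#' (count reported as an attribute).
#'
#' @param spots a `spot_table` from [detect_spots()] (or any data.frame
#'   with `frame, t_min, z_um, y_um, x_um`).
#' @param max_step maximum displacement per frame interval, um
#'   (guideline: at least 3x mean speed x dt; 20 um per 20-min frame by
#'   default).
#' @param max_gap_frames frames a track may skip (0 disables gap
#'   closing).
#' @param min_frames minimum observations for a track to be kept
#'   (default 4; short fragments inflate straightness).
#' @return list of `track` objects (`points` data.frame + `gaps` integer
#'   vector), with attributes `n_discarded_short` and
#'   `ambiguity_fraction` (fraction of links with a second candidate
#'   within `max_step`).
#' @export
link_tracks <- function(spots, max_step = 20, max_gap_frames = 1L,
                        min_frames = 4L) {
  df <- as.data.frame(spots)
  need <- c("frame", "z_um", "y_um", "x_um")
  stopifnot(all(need %in% names(df)))
  if (!nrow(df)) return(structure(list(), n_discarded_short = 0L,
                                  ambiguity_fraction = NA_real_))
  df <- df[order(df$frame), , drop = FALSE]
  df$.row <- seq_len(nrow(df))
  frames <- sort(unique(df$frame))
  nxt <- rep(NA_integer_, nrow(df))   # successor row of each spot
  n_links <- 0L; n_ambig <- 0L
  big <- 1e12
  for (k in seq_len(length(frames) - 1L)) {
    fa <- frames[k]; fb <- frames[k + 1L]
    if (fb - fa != 1L) next
    a <- df[df$frame == fa, ]; b <- df[df$frame == fb, ]
    na <- nrow(a); nb <- nrow(b)
    D2 <- outer(a$z_um, b$z_um, `-`)^2 + outer(a$y_um, b$y_um, `-`)^2 +
      outer(a$x_um, b$x_um, `-`)^2
    gate <- D2 <= max_step^2
    if (!any(gate)) next
    n_ambig <- n_ambig + sum(rowSums(gate) > 1L)
    C <- matrix(big, na + nb, na + nb)
    C[seq_len(na), seq_len(nb)][!gate] <- big
    C[seq_len(na), seq_len(nb)][gate] <- D2[gate]
    for (i in seq_len(na)) C[i, nb + i] <- max_step^2          # death
    for (j in seq_len(nb)) C[na + j, j] <- max_step^2          # birth
    C[(na + 1):(na + nb), (nb + 1):(nb + na)] <- 0             # dummy
    sol <- clue::solve_LSAP(C)
    for (i in seq_len(na)) {
      j <- sol[i]
      if (j <= nb && gate[i, j]) {
        nxt[a$.row[i]] <- b$.row[j]
        n_links <- n_links + 1L
      }
    }
  }
  # assemble tracks by following successors
  has_pred <- rep(FALSE, nrow(df))
  has_pred[nxt[!is.na(nxt)]] <- TRUE
  starts <- which(!has_pred)
  tracks <- list()
  for (s in starts) {
    rows <- s
    while (!is.na(nxt[rows[length(rows)]]))
      rows <- c(rows, nxt[rows[length(rows)]])
    tracks[[length(tracks) + 1L]] <- rows
  }
  # gap closing: join track ends to later starts
  if (max_gap_frames > 0L && length(tracks) > 1L) {
    repeat {
      ends <- vapply(tracks, function(r) r[length(r)], integer(1))
      heads <- vapply(tracks, function(r) r[1], integer(1))
      best <- NULL
      for (i in seq_along(tracks)) for (j in seq_along(tracks)) {
        if (i == j) next
        gap <- df$frame[heads[j]] - df$frame[ends[i]] - 1L
        if (gap < 1L || gap > max_gap_frames) next
        dd <- sqrt(sum((df[ends[i], c("z_um", "y_um", "x_um")] -
                        df[heads[j], c("z_um", "y_um", "x_um")])^2))
        if (dd > max_step * (gap + 1)) next
        if (is.null(best) || dd < best$d) best <- list(i = i, j = j, d = dd)
      }
      if (is.null(best)) break
      tracks[[best$i]] <- c(tracks[[best$i]], tracks[[best$j]])
      tracks[[best$j]] <- NULL
    }
  }
  keep <- vapply(tracks, length, integer(1)) >= min_frames
  n_short <- sum(!keep)
  tracks <- tracks[keep]
  out <- lapply(seq_along(tracks), function(i) {
    rows <- tracks[[i]]
    pts <- df[rows, intersect(c("frame", "t_min", "z_um", "y_um", "x_um",
                                "intensity", "spot_id"), names(df))]
    rownames(pts) <- NULL
    fr <- pts$frame
    gaps <- setdiff(seq(min(fr), max(fr)), fr)
    structure(list(track_id = i, points = pts, gaps = as.integer(gaps)),
              class = "track")
  })
  structure(out, n_discarded_short = n_short,
            ambiguity_fraction = if (n_links > 0) n_ambig / n_links
                                 else NA_real_)
}

#' Migration metrics of a single track
#'
#' Displacement is the straight start-to-end distance; path length the
#' sum of step lengths; straightness their ratio (undefined, `NA`, for a
#' zero path length); mean speed is path length / duration (the track
#' "speed" convention of common tracking software, robust for tortuous
#' tracks); instantaneous speed is step length / step interval, assigned
#' to the step's ending timepoint. All geometry in um, time in hours.
#'
#' @param track a `track` from [link_tracks()], or a data.frame with
#'   `t_min, z_um, y_um, x_um` (e.g. one ground-truth track).
#' @return a `track_metrics` list: `track_id, n_points, displacement_um,
#'   path_length_um, duration_hr, mean_speed_um_hr, straightness,
#'   instantaneous_speed_um_hr` (vector), `t_end_min` (its timepoints).
#' @export
compute_metrics <- function(track) {
  if (inherits(track, "track")) {
    pts <- track$points; id <- track$track_id
  } else {
    pts <- as.data.frame(track); id <- pts$track_id[1] %||% NA_integer_
  }
  stopifnot(all(c("t_min", "z_um", "y_um", "x_um") %in% names(pts)))
  pts <- pts[order(pts$t_min), , drop = FALSE]
  if (nrow(pts) < 2L) stop("a track needs at least 2 points")
  if (any(diff(pts$t_min) <= 0)) stop("track timepoints must be increasing")
  P <- as.matrix(pts[, c("z_um", "y_um", "x_um")])
  steps <- diff(P)
  step_len <- sqrt(rowSums(steps^2))
  dt_hr <- diff(pts$t_min) / 60
  path <- sum(step_len)
  disp <- sqrt(sum((P[nrow(P), ] - P[1, ])^2))
  dur <- (pts$t_min[nrow(pts)] - pts$t_min[1]) / 60
  structure(list(track_id = id, n_points = nrow(pts),
                 displacement_um = disp, path_length_um = path,
                 duration_hr = dur,
                 mean_speed_um_hr = path / dur,
                 straightness = if (path > 0) disp / path else NA_real_,
                 instantaneous_speed_um_hr = unname(step_len / dt_hr),
                 t_end_min = pts$t_min[-1]),
            class = "track_metrics")
}

#' Per-track metrics for a whole track table or track list
#'
#' @param tracks a list of `track` objects, or a long `track_table`
#'   data.frame (`track_id, t_min, z_um, y_um, x_um`).
#' @return data.frame, one row per track with >= 2 points.
#' @export
track_table_metrics <- function(tracks) {
  if (is.data.frame(tracks)) {
    ids <- unique(tracks$track_id)
    tracks <- lapply(ids, function(i) tracks[tracks$track_id == i, ])
  }
  rows <- lapply(tracks, function(tr) {
    pts <- if (inherits(tr, "track")) tr$points else tr
    if (nrow(pts) < 2L) return(NULL)
    m <- compute_metrics(tr)
    data.frame(track_id = m$track_id, n_points = m$n_points,
               displacement_um = m$displacement_um,
               path_length_um = m$path_length_um,
               duration_hr = m$duration_hr,
               mean_speed_um_hr = m$mean_speed_um_hr,
               straightness = m$straightness)
  })
  do.call(rbind, rows)
}

#' Group summaries and tests of migration metrics
#'
#' For each of displacement, mean speed and straightness: per-group mean
#' with SEM and 90% CI half-width, plus pairwise two-sample t-tests
#' (pooled and Welch co-reported).
#'
#' @param metrics_by_group named list mapping group name to a metrics
#'   data.frame from [track_table_metrics()] (>= 2 tracks per group).
#' @return named list per metric, each as returned by [compare_groups()].
#' @export
summarize_track_groups <- function(metrics_by_group) {
  stopifnot(is.list(metrics_by_group), !is.null(names(metrics_by_group)))
  metric_cols <- c(displacement = "displacement_um",
                   mean_speed = "mean_speed_um_hr",
                   straightness = "straightness")
  lapply(metric_cols, function(col) {
    vals <- lapply(metrics_by_group, function(df) {
      v <- df[[col]]
      v[is.finite(v)]
    })
    compare_groups(vals)
  })
}

#' Fraction of frame-to-frame links that match ground truth
#'
#' Evaluation helper: detected spots are matched to the nearest
#' ground-truth point of the same frame (within `match_radius`); a link
#' is correct when consecutive spots of one reconstructed track match
#' ground-truth points of the same true track.
#'
#' @param tracks list of `track` objects from [link_tracks()].
#' @param truth ground-truth `track_table` data.frame.
#' @param match_radius um.
#' @return list `correct, total, fraction`.
#' @export
link_accuracy <- function(tracks, truth, match_radius = 5) {
  truth <- as.data.frame(truth)
  correct <- 0L; total <- 0L
  for (tr in tracks) {
    pts <- tr$points
    gt_id <- vapply(seq_len(nrow(pts)), function(i) {
      cand <- truth[truth$frame == pts$frame[i], ]
      if (!nrow(cand)) return(NA_integer_)
      dd <- sqrt((cand$z_um - pts$z_um[i])^2 + (cand$y_um - pts$y_um[i])^2 +
                 (cand$x_um - pts$x_um[i])^2)
      if (min(dd) > match_radius) return(NA_integer_)
      as.integer(cand$track_id[which.min(dd)])
    }, integer(1))
    for (i in seq_len(nrow(pts) - 1L)) {
      total <- total + 1L
      if (!is.na(gt_id[i]) && !is.na(gt_id[i + 1L]) &&
          gt_id[i] == gt_id[i + 1L])
        correct <- correct + 1L
    }
  }
  list(correct = correct, total = total,
       fraction = if (total > 0) correct / total else NA_real_)
}
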