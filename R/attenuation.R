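#' Depth-resolved signal profile of a stack
#'
#' Summarizes signal per z slice together with the surface power delivered
#' at that depth. The default summary is the mean of the top 1% brightest
#' in-mask voxels per slice, robust to the mostly-dark field typical of
#' THG; plain mean and median are selectable. The chosen summary is
#' recorded in the profile.
#'
#' @param volume a 3D [image_volume()].
#' @param power_log data.frame `z_um, power_mW` (linearly interpolated
#'   between logged depths; must cover the stack's depth range), or a
#'   single constant power.
#' @param summary `"mean_top_fraction"`, `"mean"` or `"median"`.
#' @param top_fraction proportion of brightest voxels used by
#'   `mean_top_fraction` (1.0 makes it identical to `mean`).
#' @param mask optional [label_volume()]; only voxels with label > 0
#'   contribute.
#' @param min_voxels slices with fewer contributing voxels are excluded
#'   (counted in the result).
#' @param background constant offset subtracted from the summary before
#'   use; slices that become <= 0 are dropped, not clamped (reported).
#' @return a `depth_profile` data.frame with columns
#'   `z_um, signal, power_mW, n_pixels_used` and attributes `summary`,
#'   `n_excluded`.
#' @export
extract_depth_profile <- function(volume, power_log,
                                  summary = c("mean_top_fraction", "mean",
                                              "median"),
                                  top_fraction = 0.01, mask = NULL,
                                  min_voxels = 1L, background = 0) {
  summary <- match.arg(summary)
  stopifnot(inherits(volume, "image_volume"), !is_timelapse(volume))
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "label_volume"))
    if (any(dim(mask$labels) != dim(volume$data)))
      stop("mask and volume shapes differ")
  }
  if (top_fraction <= 0 || top_fraction > 1)
    stop("'top_fraction' must be in (0, 1]")
  if (is.numeric(power_log) && length(power_log) == 1L)
    power_log <- data.frame(z_um = range(slice_depths(volume)) + c(-1, 1),
                            power_mW = power_log)
  power_log <- as.data.frame(power_log)
  if (!all(c("z_um", "power_mW") %in% names(power_log)))
    stop("power log needs columns z_um and power_mW")
  if (any(power_log$power_mW <= 0)) stop("power must be > 0")

  z <- slice_depths(volume)
  if (min(z) < min(power_log$z_um) || max(z) > max(power_log$z_um))
    stop("power log does not cover the stack depth range")
  pz <- stats::approx(power_log$z_um, power_log$power_mW, xout = z)$y

  nz <- length(z)
  sig <- rep(NA_real_, nz)
  npx <- integer(nz)
  for (i in seq_len(nz)) {
    v <- volume$data[i, , ]
    if (!is.null(mask)) v <- v[mask$labels[i, , ] > 0]
    v <- as.numeric(v)
    npx[i] <- length(v)
    if (length(v) < min_voxels) next
    sig[i] <- switch(summary,
      mean = mean(v),
      median = median(v),
      mean_top_fraction = {
        k <- max(1L, ceiling(top_fraction * length(v)))
        mean(sort(v, decreasing = TRUE)[seq_len(k)])
      })
  }
  sig <- sig - background
  keep <- !is.na(sig)
  n_too_few <- sum(!keep)
  if (n_too_few > 0)
    warning(n_too_few, " slice(s) excluded: fewer than ", min_voxels,
            " contributing voxels")
  prof <- data.frame(z_um = z[keep], signal = sig[keep],
                     power_mW = pz[keep], n_pixels_used = npx[keep])
  attr(prof, "summary") <- summary
  attr(prof, "top_fraction") <- top_fraction
  attr(prof, "n_excluded") <- n_too_few
  class(prof) <- c("depth_profile", class(prof))
  prof
}

#' Fit the effective extinction length from a depth profile
#'
#' Ordinary least squares of `ln(S / P^n)` against depth `z`; the
#' extinction length is `l = -n / slope`. A non-negative slope is flagged
#' non-physical and reported as `l = Inf`. Slices with non-positive signal
#' are dropped (their count is recorded), matching semi-log practice.
#'
#' @param profile a `depth_profile` (or data.frame with
#'   `z_um, signal, power_mW`).
#' @param photon_order `n`; 3 for THG / three-photon signal.
#' @param z_window optional `(min, max)` um restricting the fitted range
#'   (e.g. to exclude the surface interface peak).
#' @return an `extinction_fit` with `slope` (1/um), `intercept`,
#'   `extinction_length` (um), `r_squared`, `z_range_used`,
#'   `n_slices_used`, `n_dropped_nonpositive`, `photon_order`,
#'   `non_physical`, `summary` (the profile's per-slice summary, if known).
#' @export
fit_extinction <- function(profile, photon_order = 3L, z_window = NULL) {
  df <- as.data.frame(profile)
  if (!all(c("z_um", "signal", "power_mW") %in% names(df)))
    stop("profile needs columns z_um, signal, power_mW")
  if (!is.null(z_window))
    df <- df[df$z_um >= z_window[1] & df$z_um <= z_window[2], , drop = FALSE]
  n_nonpos <- sum(df$signal <= 0)
  df <- df[df$signal > 0, , drop = FALSE]
  if (nrow(df) == 0L) stop("no positive signal in the fitted window")
  if (nrow(df) < 3L) stop("need at least 3 usable slices to fit")
  y <- log(df$signal / df$power_mW^photon_order)
  fit <- stats::lm.fit(cbind(1, df$z_um), y)
  slope <- fit$coefficients[2]
  intercept <- fit$coefficients[1]
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  non_physical <- slope >= 0
  ell <- if (non_physical) Inf else -photon_order / slope
  structure(list(slope = unname(slope), intercept = unname(intercept),
                 extinction_length = unname(ell),
                 r_squared = max(0, min(1, r2)),
                 z_range_used = range(df$z_um),
                 n_slices_used = nrow(df),
                 n_dropped_nonpositive = n_nonpos,
                 photon_order = as.integer(photon_order),
                 non_physical = non_physical,
                 summary = attr(profile, "summary")),
            class = "extinction_fit")
}

#' @export
print.extinction_fit <- function(x, ...) {
  cat(sprintf(
    "extinction fit (n=%d): l = %.4g um, slope = %.4g /um, R^2 = %.3f%s\n",
    x$photon_order, x$extinction_length, x$slope, x$r_squared,
    if (x$non_physical) "  [non-physical: slope >= 0]" else ""))
  invisible(x)
}

#' Compare extinction lengths across groups
#'
#' Per-group mean with SEM (and 90% CI half-width) plus a two-sample
#' t-test for each pair, as used to contrast wild-type and mutant
#' organoid cohorts.
#'
#' @param groups named list mapping group name to a list of
#'   `extinction_fit` objects (or numeric extinction lengths); >= 2 per
#'   group.
#' @param method `"pooled"` or `"welch"` t-test.
#' @return list with `summaries` and `tests` as in [compare_groups()].
#' @export
compare_extinction <- function(groups, method = c("pooled", "welch")) {
  vals <- lapply(groups, function(g) {
    v <- vapply(g, function(f) {
      if (inherits(f, "extinction_fit")) f$extinction_length
      else as.numeric(f)
    }, numeric(1))
    if (length(v) < 2L)
      stop("each group needs >= 2 fits (no dispersion with n = 1)")
    v
  })
  compare_groups(vals, method = method)
}
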