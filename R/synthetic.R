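#' Specification of a synthetic organoid phantom
#'
#' The phantom emulates the structure THG imaging resolves in cerebral
#' organoids: a spherical organoid body of cortical-plate-like (CP) tissue,
#' containing one or more ventricle-like cavities, each wrapped in a
#' darker ventricular-zone (VZ) shell, with bright somata scattered through
#' the CP. Intensities are arbitrary signal units with the qualitative
#' ordering cavity < VZ < CP < soma.
#'
#' @param organoid_radius radius of the organoid body, um.
#' @param n_ventricles number of ventricle cavities (>= 0).
#' @param ventricle_radius_range `(min, max)` cavity radius, um.
#' @param vz_shell_thickness VZ shell thickness around each cavity, um.
#' @param cp_soma_density bright somata per mm^3 of CP tissue.
#' @param soma_radius soma radius, um (Gaussian blob sigma = radius / 2).
#' @param vz_intensity,cp_intensity,soma_intensity,cavity_intensity signal
#'   levels (>= 0).
#' @param voxel_size `(z,y,x)` um per voxel.
#' @param margin_um dark margin around the organoid, um.
#' @param min_separation_um minimum CP clearance between two VZ shells
#'   (ventricles are distinct structures, not merged ones), um.
#' @param ventricle_centers optional n x 3 matrix of `(z,y,x)` um offsets
#'   from the organoid centre; fixes the geometry so that only soma
#'   placement is randomized.
#' @return a `phantom_spec`.
#' @export
phantom_spec <- function(organoid_radius = 150,
                         n_ventricles = 3,
                         ventricle_radius_range = c(20, 35),
                         vz_shell_thickness = 20,
                         cp_soma_density = 1e4,
                         soma_radius = 5,
                         vz_intensity = 30,
                         cp_intensity = 60,
                         soma_intensity = 400,
                         cavity_intensity = 2,
                         voxel_size = c(2, 2, 2),
                         margin_um = 10,
                         min_separation_um = 10,
                         ventricle_centers = NULL) {
  stopifnot_scalar_pos(organoid_radius, "organoid_radius")
  if (n_ventricles < 0) stop("'n_ventricles' must be >= 0")
  if (length(ventricle_radius_range) != 2L ||
      any(ventricle_radius_range <= 0) ||
      diff(ventricle_radius_range) < 0)
    stop("'ventricle_radius_range' must be increasing positive (min, max)")
  if (vz_shell_thickness <= 0) stop("'vz_shell_thickness' must be > 0")
  ints <- c(vz_intensity, cp_intensity, soma_intensity, cavity_intensity)
  if (any(ints < 0)) stop("intensities must be >= 0")
  if (n_ventricles > 0 &&
      max(ventricle_radius_range) + vz_shell_thickness >= organoid_radius)
    stop("ventricle radius + VZ shell thickness must fit inside the organoid")
  if (!is.null(ventricle_centers)) {
    ventricle_centers <- rbind(ventricle_centers)
    if (ncol(ventricle_centers) != 3L)
      stop("'ventricle_centers' must be an n x 3 (z,y,x) matrix in um")
    if (nrow(ventricle_centers) != n_ventricles)
      stop("'ventricle_centers' must have one row per ventricle")
  }
  structure(list(organoid_radius = organoid_radius,
                 n_ventricles = as.integer(n_ventricles),
                 ventricle_radius_range = as.numeric(ventricle_radius_range),
                 vz_shell_thickness = vz_shell_thickness,
                 cp_soma_density = cp_soma_density,
                 soma_radius = soma_radius,
                 vz_intensity = vz_intensity, cp_intensity = cp_intensity,
                 soma_intensity = soma_intensity,
                 cavity_intensity = cavity_intensity,
                 voxel_size = as.numeric(voxel_size),
                 margin_um = margin_um,
                 min_separation_um = min_separation_um,
                 ventricle_centers = ventricle_centers),
            class = "phantom_spec")
}

#' Optical model for rendering depth attenuation and detector noise
#'
#' Detected three-photon signal falls with depth as
#' `(P(z)/P(0))^n * exp(-n z / l)` where `l` is the effective extinction
#' length (combined scattering + absorption), `P(z)` the surface power
#' delivered when imaging depth `z`, and `n` the photon order (3 for THG).
#' Noise is Poisson on expected photon counts followed by additive
#' Gaussian read noise; both are optional.
#'
#' @param extinction_length um, > 0 (may be `Inf` for no attenuation).
#' @param surface_power_by_depth data.frame `z_um, power_mW`, or a single
#'   constant power in mW.
#' @param photon_order integer >= 1; 3 for THG / three-photon.
#' @param shot_noise_scale photons per signal unit (0 disables shot noise).
#' @param read_noise_sd additive Gaussian sd in signal units (0 disables).
#' @return an `optics_spec`.
#' @export
optics_spec <- function(extinction_length = 150,
                        surface_power_by_depth = 1,
                        photon_order = 3L,
                        shot_noise_scale = 0,
                        read_noise_sd = 0) {
  if (!(extinction_length > 0)) stop("'extinction_length' must be > 0")
  if (photon_order < 1) stop("'photon_order' must be >= 1")
  if (is.numeric(surface_power_by_depth) &&
      is.null(dim(surface_power_by_depth)) &&
      length(surface_power_by_depth) == 1L) {
    surface_power_by_depth <- data.frame(z_um = c(0, 1e7),
                                         power_mW = surface_power_by_depth)
  }
  pw <- as.data.frame(surface_power_by_depth)
  if (!all(c("z_um", "power_mW") %in% names(pw)))
    stop("power table needs columns z_um and power_mW")
  if (any(pw$power_mW <= 0)) stop("powers must be > 0")
  pw <- pw[order(pw$z_um), , drop = FALSE]
  structure(list(extinction_length = extinction_length,
                 surface_power_by_depth = pw,
                 photon_order = as.integer(photon_order),
                 shot_noise_scale = shot_noise_scale,
                 read_noise_sd = read_noise_sd),
            class = "optics_spec")
}

#' Motion model for radially migrating cells
#'
#' A persistent random walk: each step direction is drawn von
#' Mises-Fisher around the previous direction with concentration `kappa`
#' and blended with the outward radial unit vector by weight
#' `radial_bias`; the step length is `max(0, Normal(mean_speed * dt,
#' speed_sd * dt))`. With `kappa = Inf` and `radial_bias = 1` tracks are
#' straight radial lines.
#'
#' @param n_cells number of cells.
#' @param frame_interval minutes between volumes (default 20, the
#'   volumetric acquisition interval used for organoid time-lapse).
#' @param n_frames number of timepoints.
#' @param mean_speed,speed_sd um/hr.
#' @param turning_concentration kappa >= 0 (Inf allowed).
#' @param radial_bias in `[0, 1]`.
#' @return a `motion_spec`.
#' @export
motion_spec <- function(n_cells = 20, frame_interval = 20, n_frames = 19,
                        mean_speed = 23, speed_sd = 4,
                        turning_concentration = 10, radial_bias = 0.3) {
  stopifnot_scalar_pos(frame_interval, "frame_interval")
  if (mean_speed < 0) stop("'mean_speed' must be >= 0")
  if (turning_concentration < 0) stop("'turning_concentration' must be >= 0")
  if (radial_bias < 0 || radial_bias > 1)
    stop("'radial_bias' must be in [0, 1]")
  structure(list(n_cells = as.integer(n_cells),
                 frame_interval = frame_interval,
                 n_frames = as.integer(n_frames),
                 mean_speed = mean_speed, speed_sd = speed_sd,
                 turning_concentration = turning_concentration,
                 radial_bias = radial_bias),
            class = "motion_spec")
}

## one von Mises-Fisher draw on the unit sphere around mu
rvmf_one <- function(mu, kappa) {
  if (is.infinite(kappa)) return(mu)
  if (kappa == 0) {
    v <- rnorm(3)
    return(unit(v))
  }
  u <- runif(1)
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  w <- max(-1, min(1, w))
  # orthonormal basis perpendicular to mu
  a <- if (abs(mu[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit(a - sum(a * mu) * mu)
  e2 <- c(mu[2] * e1[3] - mu[3] * e1[2],
          mu[3] * e1[1] - mu[1] * e1[3],
          mu[1] * e1[2] - mu[2] * e1[1])
  th <- runif(1, 0, 2 * pi)
  s <- sqrt(1 - w^2)
  w * mu + s * (cos(th) * e1 + sin(th) * e2)
}

## add Gaussian soma blobs (peak = intensity) at physical (z,y,x) positions
render_somata <- function(arr, positions_um, voxel_size, soma_radius,
                          intensity) {
  positions_um <- rbind(positions_um)
  if (!nrow(positions_um)) return(arr)
  d <- dim(arr)
  sigma <- soma_radius / 2
  r_um <- 3 * sigma
  for (i in seq_len(nrow(positions_um))) {
    p <- positions_um[i, ]
    ctr <- p / voxel_size            # 0-based fractional voxel index
    lo <- pmax(0, floor(ctr - r_um / voxel_size))
    hi <- pmin(d - 1, ceiling(ctr + r_um / voxel_size))
    if (any(lo > hi)) next
    zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
    dz2 <- (zi * voxel_size[1] - p[1])^2
    dy2 <- (yi * voxel_size[2] - p[2])^2
    dx2 <- (xi * voxel_size[3] - p[3])^2
    g <- exp(-outer(outer(dz2, dy2, "+"), dx2, "+") / (2 * sigma^2))
    blk <- arr[zi + 1, yi + 1, xi + 1, drop = FALSE]
    arr[zi + 1, yi + 1, xi + 1] <- blk + intensity * array(g, dim(blk))
  }
  arr
}

## squared distance of every voxel centre from a physical point
dist2_grid <- function(d, voxel_size, centre) {
  dz2 <- ((seq_len(d[1]) - 1) * voxel_size[1] - centre[1])^2
  dy2 <- ((seq_len(d[2]) - 1) * voxel_size[2] - centre[2])^2
  dx2 <- ((seq_len(d[3]) - 1) * voxel_size[3] - centre[3])^2
  outer(outer(dz2, dy2, "+"), dx2, "+")
}

place_ventricles <- function(spec) {
  nv <- spec$n_ventricles
  if (nv == 0L) return(list(centres = matrix(0, 0, 3), radii = numeric(0)))
  radii <- runif(nv, spec$ventricle_radius_range[1],
                 spec$ventricle_radius_range[2])
  if (!is.null(spec$ventricle_centers)) {
    ctr <- spec$ventricle_centers
    if (any(sqrt(rowSums(ctr^2)) + radii + spec$vz_shell_thickness >
            spec$organoid_radius))
      stop("ventricle_centers: a ventricle + shell does not fit inside ",
           "the organoid")
    return(list(centres = ctr, radii = radii))
  }
  for (restart in seq_len(50L)) {
  centres <- matrix(NA_real_, nv, 3)
  placed_all <- TRUE
  for (i in seq_len(nv)) {
    ok <- FALSE
    for (try in seq_len(2000L)) {
      rmax <- spec$organoid_radius - radii[i] - spec$vz_shell_thickness -
        (spec$min_separation_um %||% 0)
      p <- runif(3, -rmax, rmax)
      if (vnorm(p) > rmax) next
      if (i > 1L) {
        sep <- sqrt(rowSums(sweep(centres[seq_len(i - 1L), , drop = FALSE],
                                  2, p)^2))
        need <- radii[seq_len(i - 1L)] + radii[i] +
          2 * spec$vz_shell_thickness + (spec$min_separation_um %||% 0)
        if (any(sep < need)) next
      }
      centres[i, ] <- p
      ok <- TRUE
      break
    }
    if (!ok) { placed_all <- FALSE; break }
  }
  if (placed_all) return(list(centres = centres, radii = radii))
  radii <- runif(nv, spec$ventricle_radius_range[1],
                 spec$ventricle_radius_range[2])
  }
  stop("could not place ", nv, " non-overlapping ventricles inside the ",
       "organoid; reduce n_ventricles or radii")
}

#' Generate a noiseless organoid phantom with ground-truth VZ labels
#'
#' Renders the intensity volume (cavity < VZ < CP, bright CP somata) and a
#' label volume in which every VZ-shell voxel carries its ventricle's
#' label. With `spec$ventricle_centers` fixed, the geometry is
#' deterministic and only soma placement consumes randomness.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed; identical seeds give identical output.
#' @return list with `image` ([image_volume()]), `labels`
#'   ([label_volume()]), `somata` (data.frame of `z_um,y_um,x_um` soma
#'   centres), `ventricles` (centres um, radii um), and `centre_um`.
#' @export
generate_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(seed, {
    half <- spec$organoid_radius + spec$margin_um
    d <- as.integer(ceiling(2 * half / spec$voxel_size)) + 1L
    centre <- (d - 1) / 2 * spec$voxel_size
    d2 <- dist2_grid(d, spec$voxel_size, centre)
    inside <- d2 <= spec$organoid_radius^2
    img <- array(0, d)
    img[inside] <- spec$cp_intensity
    labels <- array(0L, d)

    vent <- place_ventricles(spec)
    shells_or_cavity <- array(FALSE, d)
    if (spec$n_ventricles > 0L) {
      for (i in seq_len(spec$n_ventricles)) {
        vc <- centre + vent$centres[i, ]
        r_in <- vent$radii[i]
        r_out <- r_in + spec$vz_shell_thickness
        # windowed distance computation around the ventricle
        lo <- pmax(1L, as.integer(floor((vc - r_out) / spec$voxel_size)) + 1L)
        hi <- pmin(d, as.integer(ceiling((vc + r_out) / spec$voxel_size)) + 1L)
        zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
        dz2 <- ((zi - 1) * spec$voxel_size[1] - vc[1])^2
        dy2 <- ((yi - 1) * spec$voxel_size[2] - vc[2])^2
        dx2 <- ((xi - 1) * spec$voxel_size[3] - vc[3])^2
        dd <- outer(outer(dz2, dy2, "+"), dx2, "+")
        cav <- dd <= r_in^2
        shl <- dd > r_in^2 & dd <= r_out^2
        blk_img <- img[zi, yi, xi, drop = FALSE]
        blk_img[cav] <- spec$cavity_intensity
        blk_img[shl] <- spec$vz_intensity
        img[zi, yi, xi] <- blk_img
        blk_lab <- labels[zi, yi, xi, drop = FALSE]
        blk_lab[shl] <- i
        labels[zi, yi, xi] <- blk_lab
        blk_m <- shells_or_cavity[zi, yi, xi, drop = FALSE]
        blk_m[cav | shl] <- TRUE
        shells_or_cavity[zi, yi, xi] <- blk_m
      }
    }

    # somata: Poisson count from CP volume, uniform in CP
    cp_vol_mm3 <- sum(inside & !shells_or_cavity) *
      prod(spec$voxel_size) * 1e-9
    n_somata <- rpois(1, spec$cp_soma_density * cp_vol_mm3)
    somata <- matrix(NA_real_, 0, 3)
    if (n_somata > 0) {
      got <- 0L
      somata <- matrix(NA_real_, n_somata, 3)
      guard <- 0L
      while (got < n_somata && guard < 200L * n_somata + 1000L) {
        guard <- guard + 1L
        p <- runif(3, -spec$organoid_radius, spec$organoid_radius)
        if (vnorm(p) > spec$organoid_radius - spec$soma_radius) next
        if (spec$n_ventricles > 0L) {
          dd <- sqrt(rowSums(sweep(vent$centres, 2, p)^2))
          if (any(dd < vent$radii + spec$vz_shell_thickness +
                  spec$soma_radius)) next
        }
        got <- got + 1L
        somata[got, ] <- centre + p
      }
      somata <- somata[seq_len(got), , drop = FALSE]
      img <- render_somata(img, somata, spec$voxel_size, spec$soma_radius,
                           spec$soma_intensity)
    }
    list(image = image_volume(img, spec$voxel_size, channel = "THG"),
         labels = label_volume(labels, spec$voxel_size, "semi_automatic"),
         somata = data.frame(z_um = somata[, 1], y_um = somata[, 2],
                             x_um = somata[, 3]),
         ventricles = list(centres_um =
                             sweep(vent$centres, 2, centre, `+`) *
                             (spec$n_ventricles > 0),
                           radii_um = vent$radii),
         centre_um = centre)
  })
}

power_at_depth <- function(optics, z) {
  pw <- optics$surface_power_by_depth
  if (any(z < min(pw$z_um) - 1e-9) || any(z > max(pw$z_um) + 1e-9))
    stop("power log does not cover depth range [",
         round(min(z), 2), ", ", round(max(z), 2),
         "] um; refusing to extrapolate")
  stats::approx(pw$z_um, pw$power_mW, xout = z, rule = 1)$y
}

#' Apply depth attenuation of an n-photon signal
#'
#' Scales every voxel at depth `z` by `(P(z)/P(0))^n * exp(-n z / l)`.
#' Noiseless and invertible given the optics. Depth is the stack z axis
#' with `z = 0` at the first slice.
#'
#' @param volume an [image_volume()] (3D or 4D).
#' @param optics an [optics_spec()].
#' @return attenuated [image_volume()].
#' @export
apply_attenuation <- function(volume, optics) {
  stopifnot(inherits(volume, "image_volume"), inherits(optics, "optics_spec"))
  z <- slice_depths(volume)
  p <- power_at_depth(optics, z)
  p0 <- power_at_depth(optics, 0)
  n <- optics$photon_order
  scale <- (p / p0)^n * exp(-n * z / optics$extinction_length)
  out <- volume$data
  if (is_timelapse(volume)) {
    for (zi in seq_along(z)) out[, zi, , ] <- out[, zi, , ] * scale[zi]
  } else {
    for (zi in seq_along(z)) out[zi, , ] <- out[zi, , ] * scale[zi]
  }
  image_volume(out, volume$voxel_size, volume$frame_interval, volume$channel)
}

#' Add detector noise (Poisson shot noise then Gaussian read noise)
#'
#' Expected photon count per voxel is `shot_noise_scale * intensity`; the
#' Poisson draw is rescaled back to signal units, then zero-mean Gaussian
#' read noise of sd `read_noise_sd` is added. Either stage is skipped when
#' its parameter is 0.
#'
#' @param volume an [image_volume()].
#' @param optics an [optics_spec()].
#' @param seed integer seed.
#' @return noisy [image_volume()] (clamped at 0).
#' @export
add_noise <- function(volume, optics, seed = 1L) {
  stopifnot(inherits(volume, "image_volume"), inherits(optics, "optics_spec"))
  with_seed(seed, {
    x <- volume$data
    if (optics$shot_noise_scale > 0) {
      lam <- pmax(0, as.vector(x)) * optics$shot_noise_scale
      x <- array(rpois(length(lam), lam) / optics$shot_noise_scale, dim(x))
    }
    if (optics$read_noise_sd > 0)
      x <- x + array(rnorm(length(x), 0, optics$read_noise_sd), dim(x))
    x[x < 0] <- 0
    image_volume(x, volume$voxel_size, volume$frame_interval, volume$channel)
  })
}

#' Simulate ground-truth migration tracks (no rendering)
#'
#' Persistent random walk with outward radial bias (see [motion_spec()]).
#' The initial direction is radially outward from `origin`.
#'
#' @param motion a [motion_spec()].
#' @param starts n x 3 matrix of starting positions `(z,y,x)` um.
#' @param origin radial centre `(z,y,x)` um (a ventricle centre).
#' @param bounds optional 2 x 3 matrix (rows: min, max um); a cell
#'   stepping outside has its track truncated there and flagged.
#' @param seed integer seed.
#' @return a `track_table` data.frame with columns
#'   `track_id, frame, t_min, z_um, y_um, x_um` plus an attribute
#'   `truncated`: logical per track.
#' @export
simulate_tracks <- function(motion, starts, origin = c(0, 0, 0),
                            bounds = NULL, seed = 1L) {
  stopifnot(inherits(motion, "motion_spec"))
  starts <- rbind(starts)
  n <- nrow(starts)
  dt_hr <- motion$frame_interval / 60
  with_seed(seed, {
    rows <- vector("list", n)
    truncated <- logical(n)
    for (i in seq_len(n)) {
      pos <- starts[i, ]
      dir <- unit(pos - origin)
      if (vnorm(dir) == 0) dir <- unit(rnorm(3))
      pts <- matrix(NA_real_, motion$n_frames, 3)
      pts[1, ] <- pos
      nkept <- 1L
      for (f in seq_len(motion$n_frames - 1L)) {
        dv <- rvmf_one(dir, motion$turning_concentration)
        radial <- unit(pos - origin)
        if (vnorm(radial) == 0) radial <- dv
        ndir <- (1 - motion$radial_bias) * dv + motion$radial_bias * radial
        if (vnorm(ndir) == 0) ndir <- dv
        ndir <- unit(ndir)
        step <- max(0, rnorm(1, motion$mean_speed * dt_hr,
                             motion$speed_sd * dt_hr))
        cand <- pos + step * ndir
        if (!is.null(bounds) &&
            (any(cand < bounds[1, ]) || any(cand > bounds[2, ]))) {
          truncated[i] <- TRUE
          break
        }
        pos <- cand
        dir <- ndir
        nkept <- nkept + 1L
        pts[nkept, ] <- pos
      }
      pts <- pts[seq_len(nkept), , drop = FALSE]
      rows[[i]] <- data.frame(track_id = i,
                              frame = seq_len(nkept) - 1L,
                              t_min = (seq_len(nkept) - 1L) *
                                motion$frame_interval,
                              z_um = pts[, 1], y_um = pts[, 2],
                              x_um = pts[, 3])
    }
    tab <- do.call(rbind, rows)
    attr(tab, "truncated") <- truncated
    class(tab) <- c("track_table", class(tab))
    tab
  })
}

#' Map turning concentration to expected track straightness
#'
#' Pure simulation (no rendering): for each kappa on the grid, simulates
#' `n_tracks` tracks under the motion model and reports the mean
#' straightness computed by the tracking module's metric code, so users
#' can pick a kappa that hits an observed straightness.
#'
#' @param motion a [motion_spec()] (its kappa is overridden by the grid).
#' @param kappa_grid numeric vector of concentrations (Inf allowed).
#' @param n_tracks tracks per grid point (< 100 warns: unstable).
#' @param seed integer seed.
#' @return data.frame `kappa, straightness, n_tracks`.
#' @export
calibrate_straightness <- function(motion, kappa_grid, n_tracks = 500L,
                                   seed = 1L) {
  stopifnot(inherits(motion, "motion_spec"))
  if (n_tracks < 100L)
    warning("n_tracks < 100: calibration estimates will be unstable")
  res <- vapply(seq_along(kappa_grid), function(i) {
    m <- motion
    m$turning_concentration <- kappa_grid[i]
    starts <- matrix(rep(c(0, 0, 100), n_tracks), ncol = 3, byrow = TRUE)
    tab <- simulate_tracks(m, starts, origin = c(0, 0, 0),
                           seed = seed + i)
    mets <- track_table_metrics(tab)
    mean(mets$straightness, na.rm = TRUE)
  }, numeric(1))
  data.frame(kappa = kappa_grid, straightness = res, n_tracks = n_tracks)
}

#' Render a time-lapse movie of migrating cells with ground-truth tracks
#'
#' Cells are seeded inside the VZ shells of a phantom and migrate radially
#' outward from their ventricle's centre under the motion model. Each
#' frame renders the static phantom plus a bright soma blob per cell, then
#' applies depth attenuation and noise per the optics. Cells whose walk
#' leaves the volume have their ground-truth tracks truncated and flagged,
#' never silently dropped.
#'
#' @param spec a [phantom_spec()] (must have `n_ventricles >= 1`).
#' @param motion a [motion_spec()].
#' @param optics an [optics_spec()] or `NULL` for ideal rendering.
#' @param seed integer seed.
#' @return list with `movie` (4D [image_volume()]), `tracks`
#'   (ground-truth `track_table`), and `phantom` (the static scene).
#' @export
generate_timelapse <- function(spec, motion, optics = NULL, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(motion, "motion_spec"))
  if (spec$n_ventricles < 1L)
    stop("time-lapse generation needs at least one ventricle to seed cells")
  ph <- generate_phantom(spec, seed = seed)
  d <- dim(ph$image$data)
  phys_max <- (d - 1) * spec$voxel_size
  with_seed(seed + 1L, {
    # seed cells in VZ shells
    nv <- spec$n_ventricles
    which_v <- sample.int(nv, motion$n_cells, replace = TRUE)
    starts <- matrix(NA_real_, motion$n_cells, 3)
    for (i in seq_len(motion$n_cells)) {
      v <- which_v[i]
      r0 <- ph$ventricles$radii_um[v]
      rr <- runif(1, r0 + 0.2 * spec$vz_shell_thickness,
                  r0 + 0.8 * spec$vz_shell_thickness)
      dirv <- unit(rnorm(3))
      starts[i, ] <- ph$ventricles$centres_um[v, ] + rr * dirv
    }
    seeds_origin <- ph$ventricles$centres_um[which_v, , drop = FALSE]
    # simulate per cell (per-cell origin), common bounds
    bounds <- rbind(rep(0, 3), phys_max)
    tabs <- vector("list", motion$n_cells)
    trunc <- logical(motion$n_cells)
    for (i in seq_len(motion$n_cells)) {
      m1 <- motion; m1$n_cells <- 1L
      ti <- simulate_tracks(m1, starts[i, , drop = FALSE],
                            origin = seeds_origin[i, ],
                            bounds = bounds, seed = seed + 100L + i)
      ti$track_id <- i
      trunc[i] <- attr(ti, "truncated")
      tabs[[i]] <- ti
    }
    tracks <- do.call(rbind, tabs)
    attr(tracks, "truncated") <- trunc
    class(tracks) <- c("track_table", class(tracks))

    movie <- array(0, c(motion$n_frames, d))
    for (f in seq_len(motion$n_frames)) {
      fr <- ph$image$data
      pts <- tracks[tracks$frame == f - 1L, c("z_um", "y_um", "x_um")]
      fr <- render_somata(fr, as.matrix(pts), spec$voxel_size,
                          spec$soma_radius, spec$soma_intensity)
      movie[f, , , ] <- fr
    }
    mv <- image_volume(movie, spec$voxel_size,
                       frame_interval = motion$frame_interval,
                       channel = "THG")
    if (!is.null(optics)) {
      mv <- apply_attenuation(mv, optics)
      if (optics$shot_noise_scale > 0 || optics$read_noise_sd > 0)
        mv <- add_noise(mv, optics, seed = seed + 7L)
    }
    list(movie = mv, tracks = tracks, phantom = ph)
  })
}
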