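#' Phantom specification
#'
#' Parameters of a synthetic muscle phantom: packed fibers in a confocal
#' field with interstitial capillaries running predominantly along the
#' fiber axis (the stack z-axis), sinusoidally perturbed, joined by
#' transverse anastomoses at seeded branch points. Identical spec + seed
#' gives a bit-identical phantom.
#'
#' @param volume_extent named `(x, y, z)` physical extent in um.
#' @param spacing `(dz, dy, dx)` voxel spacing in um.
#' @param n_fibers number of fibers to pack.
#' @param fiber_diameter_mean,fiber_diameter_sd fiber equivalent diameter
#'   distribution, um.
#' @param n_capillaries number of axial capillaries.
#' @param capillary_radius tube radius, um.
#' @param n_branch_points number of capillary branch points to seed (even;
#'   each transverse anastomosis contributes two).
#' @param tortuosity_amplitude,tortuosity_period sinusoidal centreline
#'   perturbation, um.
#' @param transverse_fraction target fraction of capillary length in
#'   randomly oriented transverse runs (anastomoses plus lateral jogs),
#'   in `[0, 1]`; controls anisotropy.
#' @param surface_max_dist capillaries are anchored pericapillary-style,
#'   at most this far (um) from the nearest fiber surface.
#' @param branch_min_sep minimum 3D separation between seeded branch
#'   points, um.
#' @param rng_seed integer seed.
#' @param target_total_length optional total centreline length target, um;
#'   when given it overrides `n_capillaries` via
#'   `n = round((1 - tf/2) * target / extent_z)` (transverse runs and the
#'   sinusoidal excess contribute the remainder).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(volume_extent = c(x = 96.8, y = 96.8, z = 128),
                         spacing = c(dz = 1, dy = 0.756, dx = 0.756),
                         n_fibers = 3, fiber_diameter_mean = 30,
                         fiber_diameter_sd = 3, n_capillaries = 6,
                         capillary_radius = 2.5, n_branch_points = 2,
                         tortuosity_amplitude = 2, tortuosity_period = 40,
                         transverse_fraction = 0.05, branch_min_sep = 25,
                         surface_max_dist = 8,
                         rng_seed = 1, target_total_length = NULL) {
  geom <- c(volume_extent, spacing, n_fibers, fiber_diameter_mean,
            n_capillaries, capillary_radius, tortuosity_period, branch_min_sep)
  if (any(!is.finite(geom)) || any(geom <= 0))
    stop("all geometric phantom parameters must be positive and finite")
  if (fiber_diameter_sd < 0 || tortuosity_amplitude < 0 || n_branch_points < 0)
    stop("sd, amplitude and branch count must be >= 0")
  if (transverse_fraction < 0 || transverse_fraction > 1)
    stop("transverse_fraction must lie in [0, 1]")
  if (transverse_fraction == 0 && n_branch_points > 0)
    stop("n_branch_points > 0 requires transverse_fraction > 0 (anastomoses are transverse)")
  if (n_branch_points %% 2 != 0)
    stop("n_branch_points must be even (each anastomosis seeds two)")
  if (surface_max_dist <= 0)
    stop("surface_max_dist must be positive")
  if (!is.null(target_total_length))
    n_capillaries <- max(1L, round((1 - transverse_fraction / 2) *
                                     target_total_length / volume_extent[["z"]]))
  structure(list(volume_extent = volume_extent, spacing = spacing,
                 n_fibers = as.integer(n_fibers),
                 fiber_diameter_mean = fiber_diameter_mean,
                 fiber_diameter_sd = fiber_diameter_sd,
                 n_capillaries = as.integer(n_capillaries),
                 capillary_radius = capillary_radius,
                 n_branch_points = as.integer(n_branch_points),
                 tortuosity_amplitude = tortuosity_amplitude,
                 tortuosity_period = tortuosity_period,
                 transverse_fraction = transverse_fraction,
                 branch_min_sep = branch_min_sep,
                 surface_max_dist = surface_max_dist,
                 rng_seed = as.integer(rng_seed),
                 target_total_length = target_total_length),
            class = "phantom_spec")
}

# deterministic per-stage substream seed (< 2^31)
.stage_seed <- function(seed, stage) {
  (abs(as.integer(seed)) %% 1000003L) * 2011L + stage * 7919L
}

# voxel grid dimensions (nz, ny, nx) covering the physical extent
.phantom_dims <- function(spec) {
  c(round(spec$volume_extent[["z"]] / spec$spacing[["dz"]]),
    round(spec$volume_extent[["y"]] / spec$spacing[["dy"]]),
    round(spec$volume_extent[["x"]] / spec$spacing[["dx"]]))
}

#' Generate a packed fiber bundle
#'
#' Packs `n_fibers` prismatic fibers on a jittered hexagonal grid whose
#' pitch leaves an interstitial channel wide enough for the capillaries.
#' Each fiber gets mildly perturbed polygonal outlines (low-order harmonic
#' radius modulation) at four z-levels spanning the stack.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `fiber_bundle`: `fibers` (list of
#'   [fiber_geometry()] profiles), `centers` (n x 2 um), `radii` (base
#'   radii, um), `pitch`, `gap`, `spec`.
#' @export
make_fiber_bundle <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(.stage_seed(spec$rng_seed, 1L))
  ext <- spec$volume_extent
  gap <- max(10, 2 * (spec$capillary_radius + spec$tortuosity_amplitude + 1.5))
  pitch <- spec$fiber_diameter_mean + 2 * spec$fiber_diameter_sd + gap
  margin <- pitch / 2
  rows <- seq(margin, ext[["y"]] - margin, by = pitch * sqrt(3) / 2)
  cand <- NULL
  for (j in seq_along(rows)) {
    x0 <- margin + ((j - 1) %% 2) * pitch / 2
    if (x0 > ext[["x"]] - margin) next
    xs <- seq(x0, ext[["x"]] - margin, by = pitch)
    if (length(xs)) cand <- rbind(cand, cbind(xs, rows[j]))
  }
  if (is.null(cand) || nrow(cand) < spec$n_fibers)
    stop("infeasible packing: n_fibers = ", spec$n_fibers,
         " does not fit extent at fiber_diameter_mean = ",
         spec$fiber_diameter_mean)
  centers <- cand[seq_len(spec$n_fibers), , drop = FALSE] +
    matrix(runif(2 * spec$n_fibers, -1, 1), ncol = 2)
  # symmetric +/- 2 sd truncation keeps the mean diameter unbiased while
  # guaranteeing every fiber fits its hexagonal cell
  r_lo <- max(4, spec$fiber_diameter_mean - 2 * spec$fiber_diameter_sd) / 2
  r_hi <- (pitch - gap) / 2
  radii <- pmin(pmax(rnorm(spec$n_fibers, spec$fiber_diameter_mean / 2,
                           spec$fiber_diameter_sd / 2), r_lo), r_hi)
  zlev <- seq(0, ext[["z"]], length.out = 4)
  nv <- 24L
  th <- seq(0, 2 * pi, length.out = nv + 1)[-(nv + 1)]
  fibers <- vector("list", spec$n_fibers)
  for (i in seq_len(spec$n_fibers)) {
    e1 <- runif(1, 0, 0.02); e2 <- runif(1, 0, 0.015)
    ph1 <- runif(1, 0, 2 * pi); ph2 <- runif(1, 0, 2 * pi)
    outlines <- lapply(zlev, function(z) {
      wob <- 1 + rnorm(1, 0, 0.005)
      r <- radii[i] * wob * (1 + e1 * cos(2 * th + ph1) + e2 * cos(3 * th + ph2))
      list(z = z, xy = cbind(centers[i, 1] + r * cos(th),
                             centers[i, 2] + r * sin(th)))
    })
    fibers[[i]] <- fiber_geometry(outlines, fiber_id = i)
  }
  structure(list(fibers = fibers, centers = centers, radii = radii,
                 pitch = pitch, gap = gap, spec = spec),
            class = "fiber_bundle")
}

# vectorized point-in-polygon (even-odd)
.points_in_polygon <- function(pts, poly) {
  n <- nrow(poly)
  a <- poly; b <- poly[c(2:n, 1), , drop = FALSE]
  inside <- rep(FALSE, nrow(pts))
  px <- pts[, 1]; py <- pts[, 2]
  for (i in seq_len(n)) {
    ay <- a[i, 2]; by <- b[i, 2]
    if (ay == by) next
    cross <- ((ay > py) != (by > py)) &
      (px < (b[i, 1] - a[i, 1]) * (py - ay) / (by - ay) + a[i, 1])
    inside <- xor(inside, cross)
  }
  inside
}

#' Rasterize fiber labels into a voxel volume
#'
#' Voxel labels by fiber id (0 = interstitium). Each z-slice uses the
#' nearest outline level's polygon, so the label volume is piecewise
#' prismatic.
#'
#' @param bundle a [make_fiber_bundle()] result.
#' @return An integer-labelled [voxel_volume()] (not binary).
#' @export
make_fiber_label_volume <- function(bundle) {
  spec <- bundle$spec
  d <- .phantom_dims(spec)
  sp <- c(spec$spacing[["dz"]], spec$spacing[["dy"]], spec$spacing[["dx"]])
  arr <- array(0L, dim = d)
  zc <- (seq_len(d[1]) - 0.5) * sp[1]
  yc <- (seq_len(d[2]) - 0.5) * sp[2]
  xc <- (seq_len(d[3]) - 0.5) * sp[3]
  for (f in bundle$fibers) {
    zlev <- f$levels$z
    # per-level 2D masks over the fiber bounding box, reused across slices
    masks <- lapply(f$outlines, function(o) {
      bb <- apply(o$xy, 2, range)
      ys <- which(yc >= bb[1, 2] - sp[2] & yc <= bb[2, 2] + sp[2])
      xs <- which(xc >= bb[1, 1] - sp[3] & xc <= bb[2, 1] + sp[3])
      if (!length(ys) || !length(xs)) return(NULL)
      g <- cbind(rep(xc[xs], each = length(ys)), rep(yc[ys], times = length(xs)))
      list(ys = ys, xs = xs,
           m = matrix(.points_in_polygon(g, o$xy), nrow = length(ys)))
    })
    for (iz in seq_len(d[1])) {
      lv <- which.min(abs(zlev - zc[iz]))
      mk <- masks[[lv]]
      if (is.null(mk)) next
      sl <- arr[iz, mk$ys, mk$xs]
      sl[mk$m] <- f$fiber_id
      arr[iz, mk$ys, mk$xs] <- sl
    }
  }
  voxel_volume(arr, spec$spacing, is_binary = FALSE)
}
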