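#' Resample a polyline at a fixed arc-length step
#'
#' Linear interpolation along the cumulative arc length. The first and last
#' points are always retained, so the resampled curve has the same
#' endpoints; intermediate points sit at multiples of `step`.
#'
#' @param p numeric matrix `n x 3`.
#' @param step arc-length step in um (`> 0`).
#' @return A resampled polyline matrix.
#' @export
resample_polyline <- function(p, step) {
  stopifnot(step > 0)
  p <- matrix(as.numeric(p), ncol = 3)
  if (nrow(p) < 2) return(p)
  seg <- sqrt(rowSums(diff(p)^2))
  keep <- seg > 1e-12
  if (!all(keep)) p <- p[c(TRUE, keep), , drop = FALSE]
  if (nrow(p) < 2) return(p)
  seg <- sqrt(rowSums(diff(p)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (L <= step) return(p[c(1, nrow(p)), , drop = FALSE])
  si <- unique(c(seq(0, L, by = step), L))
  out <- cbind(approx(s, p[, 1], xout = si)$y,
               approx(s, p[, 2], xout = si)$y,
               approx(s, p[, 3], xout = si)$y)
  # drop a penultimate sample closer than step/2 to the endpoint, which
  # would otherwise introduce a spurious short chord
  m <- nrow(out)
  if (m > 2 && sqrt(sum((out[m, ] - out[m - 1, ])^2)) < step / 2)
    out <- out[-(m - 1), , drop = FALSE]
  colnames(out) <- c("x", "y", "z")
  out
}

#' Capillary length density
#'
#' Total centreline length per unit reference tissue volume,
#' `LV = total_length / volume` (um/um^3 = um^-2).
#'
#' @param graph a [skeleton_graph()].
#' @param volume reference volume in um^3 (`> 0`).
#' @return `LV` in um^-2.
#' @export
length_density <- function(graph, volume) {
  stopifnot(inherits(graph, "skeleton_graph"))
  if (!is.finite(volume) || volume <= 0) stop("`volume` must be > 0")
  graph$total_length / volume
}

#' Branch-point density
#'
#' Number of branch points (nodes of degree >= 3, each counted once
#' regardless of degree) per unit reference volume (um^-3).
#'
#' @inheritParams length_density
#' @return `NV` in um^-3.
#' @export
branch_density <- function(graph, volume) {
  stopifnot(inherits(graph, "skeleton_graph"))
  if (!is.finite(volume) || volume <= 0) stop("`volume` must be > 0")
  sum(graph$nodes$degree >= 3) / volume
}

#' Mean capillary length
#'
#' Two thirds of the total capillary length divided by the number of branch
#' points: `lbar = (2/3) * LV / NV` (um). With `NV = 0` the quantity is
#' undefined and `NA` is returned.
#'
#' @param LV length density, um^-2.
#' @param NV branch density, um^-3.
#' @return Mean capillary length in um, or `NA_real_` when `NV = 0`.
#' @export
mean_capillary_length <- function(LV, NV) {
  stopifnot(is.finite(LV), LV >= 0, is.finite(NV), NV >= 0)
  if (NV == 0) return(NA_real_)
  (2 / 3) * LV / NV
}

# turning angles between consecutive unit directions of one polyline
.turning_angles <- function(p) {
  if (nrow(p) < 3) return(numeric(0))
  d <- diff(p)
  len <- sqrt(rowSums(d^2))
  ok <- len > 1e-12
  d <- d[ok, , drop = FALSE]; len <- len[ok]
  if (nrow(d) < 2) return(numeric(0))
  u <- d / len
  dots <- rowSums(u[-nrow(u), , drop = FALSE] * u[-1, , drop = FALSE])
  acos(pmin(1, pmax(-1, dots)))
}

#' Capillary tortuosity
#'
#' Sum of exterior (turning) angles between consecutive line segments,
#' divided by the total capillary length (rad um^-1). Angles are
#' accumulated within each edge polyline only — a branch point has no
#' unique continuation, so no angle is charged across nodes. Polylines are
#' resampled at a fixed arc-length step first, decoupling the statistic
#' from voxel-level jaggedness.
#'
#' @param graph a [skeleton_graph()] with `total_length > 0`.
#' @param resample_step arc-length resampling step in um (default 2);
#'   `NULL` uses the raw polylines.
#' @param smooth_window half-window of an arc-length moving average (um,
#'   default 1) applied before resampling (see [smooth_polyline()]); it
#'   suppresses residual sub-voxel jitter while leaving the turning sum of
#'   well-separated bends unchanged. `0` disables.
#' @return Tortuosity in rad um^-1.
#' @export
tortuosity <- function(graph, resample_step = 2, smooth_window = 1) {
  stopifnot(inherits(graph, "skeleton_graph"))
  if (graph$total_length <= 0) stop("graph has zero total length")
  ang <- vapply(graph$polylines, function(p) {
    if (smooth_window > 0) p <- smooth_polyline(p, smooth_window)
    if (!is.null(resample_step)) p <- resample_polyline(p, resample_step)
    sum(.turning_angles(p))
  }, numeric(1))
  sum(ang) / graph$total_length
}

#' Structure-tensor anisotropy index
#'
#' Builds the length-weighted structure tensor
#' `T = sum_i l_i d_i d_i^T / sum_i l_i` over polyline segments (`d_i` unit
#' directions; the outer product makes it sign-invariant), with unit trace
#' `lambda1 + lambda2 + lambda3 = 1`, and returns `3 * lambda1`: 1 for an
#' isotropic direction distribution, 1.5 for directions uniform in a plane,
#' 3 for perfect alignment. Polylines are resampled at `chord_step` um
#' before directions are extracted so that voxel-scale jaggedness does not
#' dilute the alignment signal; on exact (non-voxel) polylines the step has
#' no effect beyond chord averaging.
#'
#' @param graph a [skeleton_graph()] with `total_length > 0`.
#' @param chord_step chord length in um for direction extraction; `NULL`
#'   (default) uses raw polyline segments, correct for exact centrelines.
#'   Voxel-derived graphs should use ~5 um chords ([capillary_metrics()]
#'   does) so staircase jitter does not dilute the alignment signal.
#' @return The anisotropy index in `[1, 3]`, with the eigenvalues of the
#'   structure tensor attached as attribute `"eigenvalues"`.
#' @export
anisotropy <- function(graph, chord_step = NULL) {
  stopifnot(inherits(graph, "skeleton_graph"))
  if (graph$total_length <= 0) stop("graph has zero total length")
  Tm <- matrix(0, 3, 3)
  wsum <- 0
  for (p in graph$polylines) {
    if (!is.null(chord_step)) p <- resample_polyline(p, chord_step)
    if (nrow(p) < 2) next
    d <- diff(p)
    len <- sqrt(rowSums(d^2))
    ok <- len > 1e-12
    d <- d[ok, , drop = FALSE]; len <- len[ok]
    if (!nrow(d)) next
    u <- d / len
    Tm <- Tm + crossprod(u * sqrt(len)) # sum_i l_i u_i u_i^T
    wsum <- wsum + sum(len)
  }
  if (wsum <= 0) stop("graph has no usable segments")
  ev <- sort(eigen(Tm / wsum, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  structure(3 * ev[1], eigenvalues = ev)
}

#' All capillary network metrics of a skeleton graph
#'
#' Computes length density `LV`, branch density `NV` (branch-point density),
#' mean capillary length `lbar = (2/3) LV / NV`, tortuosity, and the
#' structure-tensor anisotropy index against a reference volume (by default
#' the full calibrated stack volume).
#'
#' @param graph a [skeleton_graph()].
#' @param volume reference volume in um^3.
#' @param resample_step tortuosity resampling step, um (see [tortuosity()]).
#' @param chord_step anisotropy chord step, um (see [anisotropy()]).
#' @param smooth_window tortuosity smoothing half-window, um (see
#'   [tortuosity()]).
#' @return An object of class `capillary_metrics`: list with `LV`, `NV`,
#'   `mean_capillary_length`, `tortuosity`, `anisotropy`, `eigenvalues`,
#'   `total_length`, `n_branch_points`, `reference_volume`.
#' @export
capillary_metrics <- function(graph, volume, resample_step = 2, chord_step = 5,
                              smooth_window = 1) {
  LV <- length_density(graph, volume)
  NV <- branch_density(graph, volume)
  out <- list(
    LV = LV, NV = NV,
    mean_capillary_length = mean_capillary_length(LV, NV),
    tortuosity = if (graph$total_length > 0)
      tortuosity(graph, resample_step, smooth_window) else NA_real_,
    anisotropy = NA_real_, eigenvalues = rep(NA_real_, 3),
    total_length = graph$total_length,
    n_branch_points = sum(graph$nodes$degree >= 3),
    reference_volume = volume)
  if (graph$total_length > 0) {
    a <- anisotropy(graph, chord_step)
    out$anisotropy <- as.numeric(a)
    out$eigenvalues <- attr(a, "eigenvalues")
  }
  class(out) <- "capillary_metrics"
  out
}

#' @export
print.capillary_metrics <- function(x, ...) {
  cat("<capillary_metrics>\n")
  cat(sprintf("  LV          %10.4g um^-2  (x1e6: %.1f)\n", x$LV, x$LV * 1e6))
  cat(sprintf("  Br dens     %10.4g um^-3  (x1e6: %.2f)\n", x$NV, x$NV * 1e6))
  cat(sprintf("  mean length %10.4g um\n", x$mean_capillary_length))
  cat(sprintf("  tortuosity  %10.4g rad/um (x1e3: %.1f)\n",
              x$tortuosity, x$tortuosity * 1e3))
  cat(sprintf("  anisotropy  %10.4g        [1 iso .. 3 aligned]\n", x$anisotropy))
  cat(sprintf("  total length %.1f um in %.4g um^3 (%d branch points)\n",
              x$total_length, x$reference_volume, x$n_branch_points))
  invisible(x)
}

#' Serialize capillary metrics to JSON
#'
#' Emits both raw SI-um units and the conventional scaled units
#' (`LV x 1e6` um^-2, `NV x 1e6` um^-3, tortuosity `x 1e3` rad um^-1).
#'
#' @param x a [capillary_metrics()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_capillary_metrics <- function(x, path) {
  stopifnot(inherits(x, "capillary_metrics"))
  payload <- list(
    raw = list(LV_um2 = x$LV, NV_um3 = x$NV,
               mean_capillary_length_um = x$mean_capillary_length,
               tortuosity_rad_per_um = x$tortuosity,
               anisotropy = x$anisotropy,
               eigenvalues = as.numeric(x$eigenvalues),
               total_length_um = x$total_length,
               n_branch_points = x$n_branch_points,
               reference_volume_um3 = x$reference_volume),
    scaled = list(LV_um2_x1e6 = x$LV * 1e6, Br_dens_um3_x1e6 = x$NV * 1e6,
                  tortuosity_rad_per_um_x1e3 = x$tortuosity * 1e3,
                  anisotropy = x$anisotropy,
                  mean_capillary_length_um = x$mean_capillary_length))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
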