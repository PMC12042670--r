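#' Polygon utilities
#'
#' Planar polygon helpers used by the fiber morphometry: polygons are
#' `n x 2` matrices of `(x, y)` vertices in um, implicitly closed (the last
#' vertex connects back to the first), simple (non-self-intersecting), in
#' either orientation.
#'
#' @param poly numeric matrix `n x 2`.
#' @return `polygon_area`: area in um^2 (shoelace formula, orientation
#'   independent); `polygon_perimeter`: perimeter in um;
#'   `polygon_centroid`: `(x, y)` area centroid.
#' @name polygon-utils
NULL

#' @rdname polygon-utils
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

#' @rdname polygon-utils
#' @export
polygon_perimeter <- function(poly) {
  d <- poly[c(seq_len(nrow(poly))[-1], 1), ] - poly
  sum(sqrt(rowSums(d^2)))
}

#' @rdname polygon-utils
#' @export
polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(poly))
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * a)
}

# TRUE if the closed polygon has any pair of non-adjacent intersecting edges
.polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  if (n < 4) return(FALSE)
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (seg_int(a[i, ], b[i, ], a[j, ], b[j, ])) return(TRUE)
    }
  }
  FALSE
}

#' Minimal caliper (lesser) diameter of a polygon
#'
#' Minimum width over all directions of the convex hull — the "lesser
#' diameter" convention, robust to oblique sectioning.
#'
#' @param poly numeric matrix `n x 2`.
#' @return Width in um.
#' @export
lesser_diameter <- function(poly) {
  h <- poly[grDevices::chull(poly), , drop = FALSE]
  n <- nrow(h)
  if (n < 3) return(0)
  e <- h[c(2:n, 1), ] - h
  len <- sqrt(rowSums(e^2))
  widths <- vapply(which(len > 1e-12), function(i) {
    nrm <- c(-e[i, 2], e[i, 1]) / len[i]
    pr <- h %*% nrm
    max(pr) - min(pr)
  }, numeric(1))
  min(widths)
}

#' Fiber geometry from outlines at stack levels
#'
#' Derives the geometric descriptors of one muscle fiber from closed planar
#' outlines observed at two or more z-levels of the image stack (the
#' acquisition protocol uses four). Per level, the outline area comes from
#' the shoelace formula; fiber volume is the trapezoidal integral of area
#' over z; the lateral surface sums frustum strips, mean perimeter of
#' adjacent levels times the slant-corrected gap
#' `sqrt(dz^2 + d(r_eq)^2)` (exact for cylinders and cones); fiber length
#' is the path length through the level area-centroids.
#'
#' @param outlines list with one element per level, each a list with `z`
#'   (um) and `xy` (an `n x 2` vertex matrix in um); z strictly increasing.
#' @param fiber_id optional identifier stored in the result.
#' @return An object of class `fiber_profile`: `fiber_id`, `outlines`,
#'   `levels` (data.frame `z, area, perimeter, cx, cy`),
#'   `cross_sectional_area` (mean over levels, um^2), `equivalent_diameter`
#'   (`2 sqrt(CSA/pi)`, um), `lesser_diameter` (mean minimal caliper, um),
#'   `fiber_length` (um), `lateral_surface` (um^2), `fiber_volume` (um^3).
#' @export
fiber_geometry <- function(outlines, fiber_id = NA) {
  if (length(outlines) < 2)
    stop("at least two outline levels are required")
  z <- vapply(outlines, function(o) as.numeric(o$z), numeric(1))
  if (any(diff(z) <= 0)) stop("outline z-positions must be strictly increasing")
  polys <- lapply(outlines, function(o) {
    p <- matrix(as.numeric(o$xy), ncol = 2)
    if (nrow(p) < 3) stop("outline polygons need at least 3 vertices")
    if (.polygon_self_intersects(p)) stop("self-intersecting outline polygon")
    p
  })
  area <- vapply(polys, polygon_area, numeric(1))
  if (any(area <= 0)) stop("outline polygons must have positive area")
  per <- vapply(polys, polygon_perimeter, numeric(1))
  cen <- t(vapply(polys, polygon_centroid, numeric(2)))
  r_eq <- sqrt(area / pi)
  dz <- diff(z)
  volume <- sum((area[-length(area)] + area[-1]) / 2 * dz)
  slant <- sqrt(dz^2 + diff(r_eq)^2)
  lateral <- sum((per[-length(per)] + per[-1]) / 2 * slant)
  path <- cbind(cen, z)
  flen <- sum(sqrt(rowSums(diff(path)^2)))
  structure(list(
    fiber_id = fiber_id,
    outlines = Map(function(zz, p) list(z = zz, xy = p), z, polys),
    levels = data.frame(z = z, area = area, perimeter = per,
                        cx = cen[, 1], cy = cen[, 2]),
    cross_sectional_area = mean(area),
    equivalent_diameter = 2 * sqrt(mean(area) / pi),
    lesser_diameter = mean(vapply(polys, lesser_diameter, numeric(1))),
    fiber_length = flen,
    lateral_surface = lateral,
    fiber_volume = volume), class = "fiber_profile")
}

#' @export
print.fiber_profile <- function(x, ...) {
  cat(sprintf("<fiber_profile> id %s: %d levels over z %.1f..%.1f um\n",
              as.character(x$fiber_id), nrow(x$levels),
              min(x$levels$z), max(x$levels$z)))
  cat(sprintf("  CSA %.1f um^2, d_eq %.1f um, d_lesser %.1f um\n",
              x$cross_sectional_area, x$equivalent_diameter, x$lesser_diameter))
  cat(sprintf("  length %.1f um, surface %.1f um^2, volume %.1f um^3\n",
              x$fiber_length, x$lateral_surface, x$fiber_volume))
  invisible(x)
}

#' Write / read fiber outlines CSV
#'
#' One row per outline level: `fiber_id, level, z_um, vertices`, where
#' `vertices` packs the polygon as semicolon-separated `x,y` pairs in um.
#'
#' @param fibers list of [fiber_geometry()] profiles (or raw outline lists
#'   with `fiber_id` and `outlines`).
#' @param path CSV path.
#' @param digits printed coordinate precision.
#' @return `write_fiber_outlines`: `path`, invisibly;
#'   `read_fiber_outlines`: a list of `fiber_profile` objects.
#' @export
write_fiber_outlines <- function(fibers, path, digits = 4) {
  fmt <- function(x) sprintf(paste0("%.", digits, "f"), x)
  rows <- do.call(rbind, lapply(fibers, function(f) {
    do.call(rbind, lapply(seq_along(f$outlines), function(i) {
      o <- f$outlines[[i]]
      data.frame(fiber_id = f$fiber_id, level = i, z_um = o$z,
                 vertices = paste(apply(o$xy, 1, function(r)
                   paste(fmt(r), collapse = ",")), collapse = ";"))
    }))
  }))
  write.csv(rows, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_fiber_outlines
#' @export
read_fiber_outlines <- function(path) {
  d <- read.csv(path)
  lapply(split(d, d$fiber_id), function(g) {
    g <- g[order(g$z_um), ]
    outlines <- lapply(seq_len(nrow(g)), function(i) {
      pts <- strsplit(strsplit(g$vertices[i], ";", fixed = TRUE)[[1]],
                      ",", fixed = TRUE)
      list(z = g$z_um[i],
           xy = matrix(as.numeric(unlist(pts)), ncol = 2, byrow = TRUE))
    })
    fiber_geometry(outlines, fiber_id = g$fiber_id[1])
  })
}
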