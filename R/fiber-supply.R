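#' Distance from planar points to a polygon, outside only
#'
#' Minimum Euclidean distance from each point to the closed polygon
#' boundary; points inside (or on) the polygon get distance 0. Used for the
#' capillary neighbourhood rule, where the fiber interior counts as
#' distance zero.
#'
#' @param pts numeric matrix `m x 2`.
#' @param poly numeric matrix `n x 2` (closed implicitly).
#' @return Numeric vector of `m` distances (um).
#' @export
polygon_outside_distance <- function(pts, poly) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  n <- nrow(poly)
  m <- nrow(pts)
  if (m == 0) return(numeric(0))
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  d2 <- rep(Inf, m)
  inside <- rep(FALSE, m)
  px <- pts[, 1]; py <- pts[, 2]
  for (i in seq_len(n)) {
    ax <- a[i, 1]; ay <- a[i, 2]; bx <- b[i, 1]; by <- b[i, 2]
    vx <- bx - ax; vy <- by - ay
    vv <- vx * vx + vy * vy
    t <- if (vv > 0) pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / vv)) else 0
    ex <- px - ax - t * vx; ey <- py - ay - t * vy
    d2 <- pmin(d2, ex * ex + ey * ey)
    # even-odd ray casting (horizontal ray to +x)
    cross <- ((ay > py) != (by > py)) &
      (px < (bx - ax) * (py - ay) / (by - ay) + ax)
    inside <- xor(inside, cross & (by != ay))
  }
  out <- sqrt(d2)
  out[inside] <- 0
  out
}

# subdivide all polyline segments of a graph at ~`step` um; returns midpoints
# (m x 3) and piece lengths (m)
.subdivide_graph <- function(graph, step) {
  mids <- list(); lens <- list()
  for (p in graph$polylines) {
    if (nrow(p) < 2) next
    d <- diff(p)
    seglen <- sqrt(rowSums(d^2))
    for (i in which(seglen > 1e-12)) {
      k <- max(1L, ceiling(seglen[i] / step))
      tt <- (seq_len(k) - 0.5) / k
      mids[[length(mids) + 1L]] <- cbind(p[i, 1] + tt * d[i, 1],
                                         p[i, 2] + tt * d[i, 2],
                                         p[i, 3] + tt * d[i, 3])
      lens[[length(lens) + 1L]] <- rep(seglen[i] / k, k)
    }
  }
  if (!length(mids)) return(list(mid = matrix(numeric(0), ncol = 3), len = numeric(0)))
  list(mid = do.call(rbind, mids), len = unlist(lens))
}

#' Capillary length assigned to a fiber neighbourhood
#'
#' Sums the centreline length running within `neighborhood` um of the fiber
#' surface. Each polyline segment is subdivided at ~1 um steps; a piece
#' contributes its length iff its midpoint lies within the neighbourhood of
#' the outline polygon at the piece's z (outside-only distance: the fiber
#' interior counts as distance 0). The outline used at a given z is the
#' nearest-level polygon translated to the linearly interpolated area
#' centroid. Pieces outside the fiber's z-range are never assigned; the
#' same capillary length may be assigned to several fibers with overlapping
#' neighbourhoods.
#'
#' @param graph a [skeleton_graph()] in the same um frame as the fiber.
#' @param fiber a [fiber_geometry()] profile.
#' @param neighborhood neighbourhood radius in um (`> 0`), default 10.
#' @param step subdivision step in um, default 1.
#' @return Assigned capillary length in um.
#' @export
assign_capillary_length <- function(graph, fiber, neighborhood = 10, step = 1) {
  stopifnot(inherits(graph, "skeleton_graph"), inherits(fiber, "fiber_profile"),
            neighborhood > 0, step > 0)
  sub <- .subdivide_graph(graph, step)
  if (!nrow(sub$mid)) return(0)
  zlev <- fiber$levels$z
  zr <- range(zlev)
  gz <- range(sub$mid[, 3])
  if (gz[2] < zr[1] || gz[1] > zr[2]) {
    warning("graph and fiber z-ranges do not overlap; assigned length is 0")
    return(0)
  }
  inz <- sub$mid[, 3] >= zr[1] & sub$mid[, 3] <= zr[2]
  if (!any(inz)) return(0)
  mid <- sub$mid[inz, , drop = FALSE]
  len <- sub$len[inz]
  cx <- approx(zlev, fiber$levels$cx, xout = mid[, 3])$y
  cy <- approx(zlev, fiber$levels$cy, xout = mid[, 3])$y
  nearest <- vapply(mid[, 3], function(z) which.min(abs(zlev - z)), integer(1))
  assigned <- 0
  for (lv in unique(nearest)) {
    sel <- nearest == lv
    poly <- fiber$outlines[[lv]]$xy
    # translate points into the level frame instead of moving the polygon
    q <- cbind(mid[sel, 1] - (cx[sel] - fiber$levels$cx[lv]),
               mid[sel, 2] - (cy[sel] - fiber$levels$cy[lv]))
    dd <- polygon_outside_distance(q, poly)
    assigned <- assigned + sum(len[sel][dd <= neighborhood])
  }
  assigned
}

#' Per-fiber capillary supply statistics
#'
#' Ratios of assigned capillary length to fiber length (`LL`,
#' dimensionless), lateral surface (`LS`, um^-1) and volume (`LVf`, um^-2).
#'
#' @param fiber a [fiber_geometry()] profile with positive geometry fields.
#' @param assigned assigned capillary length in um (`>= 0`).
#' @return A list `fiber_id, assigned_capillary_length, LL, LS, LVf` of
#'   class `fiber_capillary_stats`.
#' @export
fiber_supply_stats <- function(fiber, assigned) {
  stopifnot(inherits(fiber, "fiber_profile"), assigned >= 0)
  if (fiber$fiber_length <= 0 || fiber$lateral_surface <= 0 ||
      fiber$fiber_volume <= 0)
    stop("fiber length, surface and volume must all be positive")
  structure(list(fiber_id = fiber$fiber_id,
                 assigned_capillary_length = assigned,
                 LL = assigned / fiber$fiber_length,
                 LS = assigned / fiber$lateral_surface,
                 LVf = assigned / fiber$fiber_volume),
            class = "fiber_capillary_stats")
}

# fraction of outline vertices within `margin` um of the field border
.border_fraction <- function(fiber, extent_xy, margin = 1) {
  v <- do.call(rbind, lapply(fiber$outlines, `[[`, "xy"))
  near <- v[, 1] < margin | v[, 2] < margin |
    v[, 1] > extent_xy[1] - margin | v[, 2] > extent_xy[2] - margin
  mean(near)
}

#' Field-level capillary supply summary
#'
#' Runs [assign_capillary_length()] and [fiber_supply_stats()] over all
#' fibers of a field and averages the per-fiber ratios (unweighted means,
#' the field-level convention; subject-level values are means over fields).
#' Fibers clipped by the field border can be excluded when more than
#' `border_max_frac` of their outline vertices lie within `border_margin`
#' um of the border.
#'
#' @param graph a [skeleton_graph()].
#' @param fibers list of [fiber_geometry()] profiles.
#' @param neighborhood neighbourhood radius, um.
#' @param extent_xy optional `(x, y)` field extent in um enabling border
#'   exclusion.
#' @param border_max_frac exclusion threshold on the border fraction
#'   (default 0.2); `Inf` disables exclusion.
#' @param border_margin border margin in um (default 1).
#' @return A list with `per_fiber` (data.frame `fiber_id, assigned_um, LL,
#'   LS, LVf, excluded`) and `summary` (means over included fibers).
#' @export
field_supply_summary <- function(graph, fibers, neighborhood = 10,
                                 extent_xy = NULL, border_max_frac = 0.2,
                                 border_margin = 1) {
  rows <- lapply(fibers, function(f) {
    st <- fiber_supply_stats(f, assign_capillary_length(graph, f, neighborhood))
    excl <- if (!is.null(extent_xy))
      .border_fraction(f, extent_xy, border_margin) > border_max_frac
    else FALSE
    data.frame(fiber_id = f$fiber_id, assigned_um = st$assigned_capillary_length,
               LL = st$LL, LS = st$LS, LVf = st$LVf, excluded = excl)
  })
  per <- do.call(rbind, rows)
  inc <- per[!per$excluded, , drop = FALSE]
  list(per_fiber = per,
       summary = list(n_fibers = nrow(inc),
                      LL = mean(inc$LL), LS = mean(inc$LS), LVf = mean(inc$LVf),
                      assigned_um = mean(inc$assigned_um)))
}
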