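#' Ground-truth metrics of an exact centreline graph
#'
#' Computes total length, tortuosity, anisotropy, transverse length
#' fraction and (optionally) per-fiber assigned capillary lengths directly
#' on exact polylines by straightforward dense-sampling formulas. This is
#' the validation oracle for the voxel pipeline and deliberately shares no
#' code with [capillary_metrics()] or [assign_capillary_length()]: turning
#' angles, the orientation tensor, and point-to-outline distances are all
#' recomputed here from first principles.
#'
#' @param graph a [skeleton_graph()] with exact (non-voxel) polylines.
#' @param fibers optional list of [fiber_geometry()] profiles; if given,
#'   per-fiber assigned lengths are computed by dense midpoint sampling
#'   against densely resampled outline boundaries.
#' @param neighborhood neighbourhood radius for the per-fiber oracle, um.
#' @return List `total_length_um, tortuosity, anisotropy,
#'   transverse_fraction, per_fiber_assigned_um` (named by fiber id, or
#'   `NULL`).
#' @export
phantom_ground_truth <- function(graph, fibers = NULL, neighborhood = 10) {
  polys <- graph$polylines
  total <- 0
  lateral <- 0
  angle_sum <- 0
  Tm <- matrix(0, 3, 3)
  for (p in polys) {
    d <- diff(p)
    len <- sqrt(rowSums(d^2))
    keep <- len > 1e-12
    d <- d[keep, , drop = FALSE]; len <- len[keep]
    if (!length(len)) next
    total <- total + sum(len)
    lateral <- lateral + sum(sqrt(d[, 1]^2 + d[, 2]^2))
    u <- d / len
    for (s in seq_len(nrow(u)))
      Tm <- Tm + len[s] * tcrossprod(u[s, ])
    if (nrow(u) >= 2) {
      dots <- rowSums(u[-nrow(u), , drop = FALSE] * u[-1, , drop = FALSE])
      angle_sum <- angle_sum + sum(acos(pmin(1, pmax(-1, dots))))
    }
  }
  ev <- sort(eigen(Tm / total, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  per_fiber <- NULL
  if (!is.null(fibers)) {
    mids <- list(); lens <- list()
    for (p in polys) {
      d <- diff(p)
      len <- sqrt(rowSums(d^2))
      for (s in which(len > 1e-12)) {
        k <- max(1L, ceiling(len[s] / 0.5))
        tt <- (seq_len(k) - 0.5) / k
        mids[[length(mids) + 1L]] <- cbind(p[s, 1] + tt * d[s, 1],
                                           p[s, 2] + tt * d[s, 2],
                                           p[s, 3] + tt * d[s, 3])
        lens[[length(lens) + 1L]] <- rep(len[s] / k, k)
      }
    }
    mid <- do.call(rbind, mids)
    ln <- unlist(lens)
    per_fiber <- vapply(fibers, function(f) {
      zlev <- f$levels$z
      sel <- mid[, 3] >= min(zlev) & mid[, 3] <= max(zlev)
      if (!any(sel)) return(0)
      m <- mid[sel, , drop = FALSE]; w <- ln[sel]
      lv <- vapply(m[, 3], function(z) which.min(abs(zlev - z)), integer(1))
      tot <- 0
      for (l in unique(lv)) {
        ssel <- lv == l
        tot <- tot + sum(w[ssel][.oracle_outline_dist(m[ssel, 1:2, drop = FALSE],
                                                      f$outlines[[l]]$xy) <= neighborhood])
      }
      tot
    }, numeric(1))
    names(per_fiber) <- vapply(fibers, function(f) as.character(f$fiber_id),
                               character(1))
  }
  list(total_length_um = total,
       tortuosity = angle_sum / total,
       anisotropy = 3 * ev[1],
       transverse_fraction = lateral / total,
       per_fiber_assigned_um = per_fiber)
}

# Oracle distance from points to a closed outline, inside -> 0. Implemented
# independently of polygon_outside_distance(): the boundary is densely
# resampled (0.2 um) and the minimum point-to-boundary-sample distance is
# taken; insideness comes from the winding angle sum.
.oracle_outline_dist <- function(pts, poly) {
  n <- nrow(poly)
  cl <- rbind(poly, poly[1, ])
  seg <- sqrt(rowSums(diff(cl)^2))
  bnd <- list()
  for (i in seq_len(n)) {
    k <- max(1L, ceiling(seg[i] / 0.2))
    tt <- seq(0, 1, length.out = k + 1)[-(k + 1)]
    bnd[[i]] <- cbind(cl[i, 1] + tt * (cl[i + 1, 1] - cl[i, 1]),
                      cl[i, 2] + tt * (cl[i + 1, 2] - cl[i, 2]))
  }
  bnd <- do.call(rbind, bnd)
  out <- numeric(nrow(pts))
  for (q in seq_len(nrow(pts))) {
    dx <- bnd[, 1] - pts[q, 1]; dy <- bnd[, 2] - pts[q, 2]
    dmin <- sqrt(min(dx * dx + dy * dy))
    # winding angle of the vertex loop around the point
    vx <- poly[, 1] - pts[q, 1]; vy <- poly[, 2] - pts[q, 2]
    a1 <- atan2(vy, vx)
    turns <- diff(c(a1, a1[1]))
    turns <- (turns + pi) %% (2 * pi) - pi
    out[q] <- if (abs(sum(turns)) > pi) 0 else dmin
  }
  out
}
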