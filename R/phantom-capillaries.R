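#' Generate the ground-truth capillary network of a phantom
#'
#' Builds axis-aligned sinusoidal capillaries in the interstitial space of
#' a fiber bundle, adds lateral jogs until the target transverse length
#' fraction is reached, and joins neighbouring capillaries with straight
#' transverse anastomoses at seeded branch points (two per anastomosis,
#' kept at least `branch_min_sep` um apart). Returns the exact centreline
#' graph plus a ground-truth record whose metrics are computed by
#' independent dense-sampling formulas (see [phantom_ground_truth()]),
#' sharing no code with the voxel pipeline.
#'
#' @param spec a [phantom_spec()].
#' @param bundle the matching [make_fiber_bundle()] result.
#' @param per_fiber_truth also compute ground-truth per-fiber assigned
#'   capillary lengths (slower); default `TRUE`.
#' @return A list of class `capillary_phantom`: `graph` (a
#'   [skeleton_graph()]), `truth` (list: `total_length_um`,
#'   `n_branch_points`, `tortuosity`, `anisotropy`,
#'   `transverse_fraction`, `per_fiber_assigned_um`), and `spec`.
#' @export
make_capillary_graph <- function(spec, bundle, per_fiber_truth = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(bundle, "fiber_bundle"))
  set.seed(.stage_seed(spec$rng_seed, 2L))
  ext <- spec$volume_extent
  ez <- ext[["z"]]
  a <- spec$tortuosity_amplitude
  Tp <- spec$tortuosity_period
  rc <- spec$capillary_radius
  centers <- bundle$centers
  # clearance radius per fiber: outline radius (incl. perturbation headroom)
  # plus tube radius plus slack
  fib_clear <- bundle$radii * 1.05 + rc + 0.5

  # --- pericapillary anchors, round-robin over fibers --------------------
  # each capillary is anchored in the perivascular ring of one host fiber
  # (fibers visited round-robin, so supply is spread evenly), between the
  # clearance ring and `surface_max_dist` from the surface
  m2 <- rc + a + 0.5
  sep <- 2 * a + 2 * rc + 1
  anchors <- matrix(numeric(0), ncol = 2)
  host_tangent <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(spec$n_capillaries)) {
    f <- ((i - 1L) %% nrow(centers)) + 1L
    # the sinusoid swings tangentially along the host surface, so the host
    # clearance needs no amplitude headroom
    s_lo <- max(fib_clear[f] - bundle$radii[f], 0.5)
    if (s_lo > spec$surface_max_dist)
      stop("infeasible pericapillary placement: surface_max_dist = ",
           spec$surface_max_dist, " below the clearance ring")
    placed <- FALSE
    for (k in seq_len(5000L)) {
      th <- runif(1, 0, 2 * pi)
      rr <- bundle$radii[f] + runif(1, s_lo, spec$surface_max_dist)
      p <- centers[f, ] + rr * c(cos(th), sin(th))
      if (p[1] < m2 || p[1] > ext[["x"]] - m2 ||
          p[2] < m2 || p[2] > ext[["y"]] - m2) next
      dfib <- sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2)
      req <- fib_clear + a
      req[f] <- fib_clear[f]
      if (any(dfib < req)) next
      if (nrow(anchors) &&
          min(sqrt((anchors[, 1] - p[1])^2 + (anchors[, 2] - p[2])^2)) < sep) next
      anchors <- rbind(anchors, p)
      host_tangent <- rbind(host_tangent, c(-sin(th), cos(th)))
      placed <- TRUE
      break
    }
    if (!placed)
      stop("infeasible interstitial placement: n_capillaries = ",
           spec$n_capillaries, " at this packing/amplitude")
  }

  # --- axial sinusoidal runs --------------------------------------------
  zs <- seq(0, ez, by = 1)
  nzs <- length(zs)
  paths <- vector("list", spec$n_capillaries)
  for (i in seq_len(spec$n_capillaries)) {
    phi <- runif(1, 0, 2 * pi)
    u <- host_tangent[i, ]
    lat <- a * sin(2 * pi * zs / Tp + phi)
    paths[[i]] <- cbind(x = anchors[i, 1] + lat * u[1],
                        y = anchors[i, 2] + lat * u[2], z = zs)
  }

  path_clear_ok <- function(xy) {
    if (any(xy[, 1] < rc + 0.5) || any(xy[, 1] > ext[["x"]] - rc - 0.5) ||
        any(xy[, 2] < rc + 0.5) || any(xy[, 2] > ext[["y"]] - rc - 0.5))
      return(FALSE)
    for (f in seq_len(nrow(centers))) {
      d2 <- (xy[, 1] - centers[f, 1])^2 + (xy[, 2] - centers[f, 2])^2
      if (any(d2 < (fib_clear[f] - 0.2)^2)) return(FALSE)
    }
    TRUE
  }

  lateral_len <- function(p) sum(sqrt(rowSums(diff(p[, 1:2, drop = FALSE])^2)))
  total_len <- function(p) sum(sqrt(rowSums(diff(p)^2)))

  # --- lateral jogs toward the target transverse fraction ----------------
  jog_z <- vector("list", spec$n_capillaries) # protected z per capillary
  tf_now <- function() {
    tl <- sum(vapply(paths, total_len, numeric(1)))
    ll <- sum(vapply(paths, lateral_len, numeric(1)))
    ll / tl
  }
  jl <- 6; jdz <- 5
  attempts <- 0L
  while (spec$transverse_fraction > 0 && tf_now() < spec$transverse_fraction &&
         attempts < 400L) {
    attempts <- attempts + 1L
    i <- sample.int(spec$n_capillaries, 1)
    z1 <- runif(1, 10, ez - 10 - 2 * jdz)
    if (length(jog_z[[i]]) && min(abs(jog_z[[i]] - z1)) < 2 * jdz + 6) next
    ok <- FALSE
    for (k in seq_len(20)) {
      ang <- runif(1, 0, 2 * pi)
      v <- jl * c(cos(ang), sin(ang))
      # triangular excursion: out and back, so the run returns to its host
      ramp <- pmax(0, 1 - abs(zs - (z1 + jdz)) / jdz)
      newp <- paths[[i]]
      newp[, 1] <- newp[, 1] + ramp * v[1]
      newp[, 2] <- newp[, 2] + ramp * v[2]
      if (!path_clear_ok(newp[, 1:2, drop = FALSE])) next
      # keep tubes from merging: same-z distance to all other runs
      clash <- FALSE
      for (m in seq_len(spec$n_capillaries)) {
        if (m == i) next
        d2 <- (newp[, 1] - paths[[m]][, 1])^2 + (newp[, 2] - paths[[m]][, 2])^2
        if (min(d2) < (2 * rc + 1.5)^2) { clash <- TRUE; break }
      }
      if (clash) next
      paths[[i]] <- newp
      jog_z[[i]] <- c(jog_z[[i]], z1)
      ok <- TRUE
      break
    }
    if (!ok) next
  }

  # --- transverse anastomoses at seeded branch points --------------------
  n_conn <- spec$n_branch_points %/% 2L
  conns <- list()          # list of (i, ki, j, kj)
  branch_pts <- matrix(numeric(0), ncol = 3)
  if (n_conn > 0) {
    # candidate pairs whose anchors sit within connector range
    ad <- as.matrix(dist(anchors))
    lo <- max(8, spec$branch_min_sep)
    cand_pairs <- which(upper.tri(ad) & ad >= lo - 2 * a & ad <= 60 + 2 * a,
                        arr.ind = TRUE)
    if (!nrow(cand_pairs))
      stop("could not seed n_branch_points = ", spec$n_branch_points,
           ": no capillary pair within connector range at branch_min_sep = ",
           spec$branch_min_sep)
    ctries <- 0L
    while (length(conns) < n_conn) {
      ctries <- ctries + 1L
      if (ctries > 20000L)
        stop("could not seed n_branch_points = ", spec$n_branch_points,
             " at branch_min_sep = ", spec$branch_min_sep)
      pr <- cand_pairs[sample.int(nrow(cand_pairs), 1), ]
      i <- pr[1]; j <- pr[2]
      k <- sample(which(zs >= 10 & zs <= ez - 10), 1)
      if (length(jog_z[[i]]) && min(abs(jog_z[[i]] + jdz - zs[k])) < 2 * jdz + 4) next
      if (length(jog_z[[j]]) && min(abs(jog_z[[j]] + jdz - zs[k])) < 2 * jdz + 4) next
      A <- paths[[i]][k, ]; B <- paths[[j]][k, ]
      span <- sqrt(sum((A[1:2] - B[1:2])^2))
      # the two junctions of one anastomosis are its endpoints, so the span
      # itself should respect the branch separation; when the geometry is
      # too tight the bound is relaxed stepwise (separation between
      # different anastomoses is always enforced)
      span_lo <- if (ctries <= 8000L) max(8, spec$branch_min_sep)
                 else if (ctries <= 14000L) max(8, spec$branch_min_sep / 2)
                 else 8
      if (span < span_lo || span > 60) next
      if (nrow(branch_pts)) {
        dmin <- min(sqrt((branch_pts[, 1] - A[1])^2 + (branch_pts[, 2] - A[2])^2 +
                           (branch_pts[, 3] - A[3])^2),
                    sqrt((branch_pts[, 1] - B[1])^2 + (branch_pts[, 2] - B[2])^2 +
                           (branch_pts[, 3] - B[3])^2))
        if (dmin < spec$branch_min_sep) next
      }
      # route the connector at constant z: straight if it clears every
      # fiber, otherwise detour around the worst offender (anastomoses
      # curve around fibers in tissue too)
      wp <- .route_connector(A[1:2], B[1:2], centers, fib_clear, ext, rc)
      if (is.null(wp)) next
      # keep clear of every other capillary run at this depth
      clash <- FALSE
      for (m in seq_len(spec$n_capillaries)) {
        if (m == i || m == j) next
        pm <- paths[[m]][k, 1:2]
        for (sgi in seq_len(nrow(wp) - 1)) {
          P <- wp[sgi, ]; Q <- wp[sgi + 1, ]
          v <- Q - P; vv <- sum(v^2)
          t0 <- if (vv > 0) min(1, max(0, sum((pm - P) * v) / vv)) else 0
          if (sqrt(sum((P + t0 * v - pm)^2)) < 2 * rc + 1.5) { clash <- TRUE; break }
        }
        if (clash) break
      }
      if (clash) next
      conns[[length(conns) + 1L]] <- list(i = i, ki = k, j = j, kj = k, wp = wp)
      branch_pts <- rbind(branch_pts, A, B)
    }
  }

  # --- assemble the exact skeleton graph --------------------------------
  node_pos <- list(); node_key <- new.env(hash = TRUE)
  get_node <- function(cap, k) {
    key <- paste(cap, k, sep = "_")
    id <- node_key[[key]]
    if (is.null(id)) {
      id <- length(node_pos) + 1L
      node_pos[[id]] <<- paths[[cap]][k, ]
      node_key[[key]] <- id
    }
    id
  }
  edges <- NULL; plist <- list()
  add_edge <- function(aid, bid, poly) {
    edges <<- rbind(edges, c(aid, bid))
    plist[[length(plist) + 1L]] <<- poly
  }
  for (i in seq_len(spec$n_capillaries)) {
    ks <- sort(unique(c(1L, nzs,
                        unlist(lapply(conns, function(cn)
                          c(if (cn$i == i) cn$ki, if (cn$j == i) cn$kj))))))
    for (s in seq_len(length(ks) - 1)) {
      ka <- ks[s]; kb <- ks[s + 1]
      add_edge(get_node(i, ka), get_node(i, kb),
               paths[[i]][ka:kb, , drop = FALSE])
    }
  }
  for (cn in conns) {
    zc <- paths[[cn$i]][cn$ki, 3]
    poly <- NULL
    for (sgi in seq_len(nrow(cn$wp) - 1)) {
      P <- cn$wp[sgi, ]; Q <- cn$wp[sgi + 1, ]
      ns <- max(1L, ceiling(sqrt(sum((Q - P)^2))))
      tt <- seq(0, 1, length.out = ns + 1)
      seg <- cbind(P[1] + tt * (Q[1] - P[1]), P[2] + tt * (Q[2] - P[2]), zc)
      poly <- if (is.null(poly)) seg else rbind(poly, seg[-1, , drop = FALSE])
    }
    add_edge(get_node(cn$i, cn$ki), get_node(cn$j, cn$kj), poly)
  }
  graph <- skeleton_graph(do.call(rbind, node_pos), edges, plist)

  truth <- phantom_ground_truth(graph,
                                fibers = if (per_fiber_truth) bundle$fibers else NULL)
  truth$n_branch_points <- 2L * n_conn
  structure(list(graph = graph, truth = truth, spec = spec),
            class = "capillary_phantom")
}

#' Rasterize centreline tubes into a binary voxel volume
#'
#' Foreground = every voxel whose centre lies within `radius` of any
#' centreline segment of the graph (exact point-to-segment distances,
#' deterministic). Segments reaching outside the extent are clipped with a
#' warning.
#'
#' @param graph a [skeleton_graph()].
#' @param radius tube radius, um (`>= max(spacing)` for a connected tube).
#' @param spacing `(dz, dy, dx)` voxel spacing, um.
#' @param dims `(nz, ny, nx)` voxel grid dimensions.
#' @return A binary [voxel_volume()].
#' @export
rasterize_tubes <- function(graph, radius, spacing, dims) {
  stopifnot(inherits(graph, "skeleton_graph"))
  if (radius < max(spacing))
    warning("radius below voxel spacing: tube may be disconnected")
  segs <- do.call(rbind, lapply(graph$polylines, function(p) {
    if (nrow(p) < 2) return(NULL)
    cbind(p[-nrow(p), , drop = FALSE], p[-1, , drop = FALSE])
  }))
  if (is.null(segs))
    return(voxel_volume(array(0L, dim = dims), spacing, is_binary = TRUE))
  arr <- .rasterize_segments_cpp(segs, radius, as.integer(dims),
                                 as.numeric(spacing))
  if (isTRUE(attr(arr, "clipped")))
    warning("graph exceeds the volume extent: tubes clipped at the border")
  attr(arr, "clipped") <- NULL
  voxel_volume(arr, spacing, is_binary = TRUE)
}

#' Rasterize a phantom's capillary network
#'
#' Convenience wrapper producing the binary stack of a
#' [make_capillary_graph()] phantom at its spec's spacing and extent.
#'
#' @param phantom a `capillary_phantom`.
#' @return A binary [voxel_volume()].
#' @export
rasterize_phantom <- function(phantom) {
  spec <- phantom$spec
  rasterize_tubes(phantom$graph, spec$capillary_radius,
                  spacing = c(spec$spacing[["dz"]], spec$spacing[["dy"]],
                              spec$spacing[["dx"]]),
                  dims = .phantom_dims(spec))
}

# Route a constant-z connector from A to B (2D points) around blocking
# fibers: start straight; while some segment dips inside a fiber clearance
# ring, insert a waypoint pushed radially out of the worst offender.
# Returns an m x 2 waypoint matrix or NULL if no clear route is found.
.route_connector <- function(A, B, centers, fib_clear, ext, rc) {
  wp <- rbind(A, B)
  for (iter in 1:4) {
    worst <- NULL
    for (sgi in seq_len(nrow(wp) - 1)) {
      P <- wp[sgi, ]; Q <- wp[sgi + 1, ]
      ns <- max(2L, ceiling(sqrt(sum((Q - P)^2))))
      tt <- seq(0, 1, length.out = ns + 1)
      cx <- P[1] + tt * (Q[1] - P[1]); cy <- P[2] + tt * (Q[2] - P[2])
      for (f in seq_len(nrow(centers))) {
        d <- sqrt((cx - centers[f, 1])^2 + (cy - centers[f, 2])^2)
        pen <- (fib_clear[f] - 0.3) - min(d)
        if (pen > 0 && (is.null(worst) || pen > worst$pen)) {
          kk <- which.min(d)
          worst <- list(pen = pen, f = f, sgi = sgi, pt = c(cx[kk], cy[kk]))
        }
      }
    }
    if (is.null(worst)) return(wp)
    ctr <- centers[worst$f, ]
    dir <- worst$pt - ctr
    nd <- sqrt(sum(dir^2))
    dir <- if (nd > 1e-9) dir / nd else c(1, 0)
    w <- ctr + dir * (fib_clear[worst$f] + 1)
    if (w[1] < rc + 0.5 || w[1] > ext[["x"]] - rc - 0.5 ||
        w[2] < rc + 0.5 || w[2] > ext[["y"]] - rc - 0.5) return(NULL)
    wp <- rbind(wp[seq_len(worst$sgi), , drop = FALSE], w,
                wp[(worst$sgi + 1):nrow(wp), , drop = FALSE])
  }
  NULL
}
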