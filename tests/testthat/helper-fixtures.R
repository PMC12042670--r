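# shared in-code fixtures

# solid axis-aligned tube mask: dims (nz, ny, nx), circular cross-section of
# `radius` voxels centred in the y/x plane, spanning all z
tube_mask <- function(nz = 50, ny = 20, nx = 20, radius = 3, spacing = c(1, 1, 1)) {
  arr <- array(0L, dim = c(nz, ny, nx))
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  for (y in seq_len(ny)) for (x in seq_len(nx))
    if ((y - cy)^2 + (x - cx)^2 <= radius^2) arr[, y, x] <- 1L
  voxel_volume(arr, spacing)
}

# circular outline polygon as an n-gon
circle_poly <- function(r, centre = c(0, 0), n = 96) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(centre[1] + r * cos(th), centre[2] + r * sin(th))
}

# cylinder fiber profile: radius r, levels at z
cylinder_fiber <- function(r = 20, z = c(0, 33, 66, 99), centre = c(0, 0), id = 1) {
  fiber_geometry(lapply(z, function(zz) list(z = zz, xy = circle_poly(r, centre))),
                 fiber_id = id)
}

# single-polyline graph through the given points
polyline_graph <- function(pts) {
  pts <- matrix(pts, ncol = 3)
  skeleton_graph(rbind(pts[1, ], pts[nrow(pts), ]),
                 cbind(1L, 2L), list(pts))
}

# number of 26-connected components of a binary (z,y,x) array
n_components26 <- function(arr) {
  d <- dim(arr)
  fg <- which(arr != 0)
  if (!length(fg)) return(0L)
  i0 <- fg - 1L
  iz <- i0 %% d[1]; iy <- (i0 %/% d[1]) %% d[2]; ix <- i0 %/% (d[1] * d[2])
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  lab <- integer(length(fg))
  comp <- 0L
  for (s in seq_along(fg)) {
    if (lab[s]) next
    comp <- comp + 1L
    queue <- s; lab[s] <- comp
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        zz <- iz[cur] + offs[k, 1]; yy <- iy[cur] + offs[k, 2]; xx <- ix[cur] + offs[k, 3]
        if (zz < 0 || zz >= d[1] || yy < 0 || yy >= d[2] || xx < 0 || xx >= d[3]) next
        j <- match(zz + d[1] * (yy + d[2] * xx) + 1L, fg)
        if (!is.na(j) && !lab[j]) { lab[j] <- comp; queue <- c(queue, j) }
      }
    }
  }
  comp
}

# cycle rank (independent loops) of a skeleton graph: E - N + C
cycle_rank <- function(g) {
  ne <- nrow(g$edges); nn <- nrow(g$nodes)
  if (nn == 0) return(0L)
  # components via union-find over edges
  parent <- seq_len(nn)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (e in seq_len(ne)) {
    a <- find(g$edges$node_a[e]); b <- find(g$edges$node_b[e])
    if (a != b) parent[a] <- b
  }
  comps <- length(unique(vapply(seq_len(nn), find, integer(1))))
  ne - nn + comps
}
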