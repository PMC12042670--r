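#' Skeleton graphs
#'
#' A `skeleton_graph` is the geometric model of a capillary network: nodes
#' (branch points, end points, isolated points) with positions in um, and
#' edges carrying ordered polylines of um points. Cycles and self-loops are
#' permitted — capillary networks are not trees.
#'
#' @param node_pos numeric matrix `K x 3` (columns x, y, z in um).
#' @param edge_nodes integer matrix `E x 2` of node indices (`node_a`,
#'   `node_b`).
#' @param polylines list of `E` numeric matrices (`n_i x 3`); the first and
#'   last points of polyline `i` must equal the positions of its end nodes.
#' @return An object of class `skeleton_graph` with components `nodes`
#'   (data.frame `id, x, y, z, degree`), `edges` (data.frame
#'   `id, node_a, node_b, length_um`), `polylines`, and `total_length` (um).
#' @export
skeleton_graph <- function(node_pos, edge_nodes, polylines) {
  node_pos <- matrix(as.numeric(node_pos), ncol = 3)
  if (is.null(edge_nodes) || length(edge_nodes) == 0) {
    edge_nodes <- matrix(integer(0), ncol = 2)
    polylines <- list()
  }
  edge_nodes <- matrix(as.integer(edge_nodes), ncol = 2)
  if (length(polylines) != nrow(edge_nodes))
    stop("one polyline required per edge")
  polylines <- lapply(polylines, function(p) {
    p <- matrix(as.numeric(p), ncol = 3)
    colnames(p) <- c("x", "y", "z")
    p
  })
  lens <- vapply(polylines, polyline_length, numeric(1))
  for (i in seq_along(polylines)) {
    p <- polylines[[i]]
    if (nrow(p) < 2 || lens[i] <= 0)
      stop("edge ", i, " has a degenerate polyline (length must be > 0)")
    a <- edge_nodes[i, 1]; b <- edge_nodes[i, 2]
    if (max(abs(p[1, ] - node_pos[a, ])) > 1e-6 ||
        max(abs(p[nrow(p), ] - node_pos[b, ])) > 1e-6)
      stop("edge ", i, " polyline endpoints do not match node positions")
  }
  deg <- tabulate(c(edge_nodes[, 1], edge_nodes[, 2]), nbins = nrow(node_pos))
  nodes <- data.frame(id = seq_len(nrow(node_pos)), x = node_pos[, 1],
                      y = node_pos[, 2], z = node_pos[, 3], degree = deg)
  edges <- data.frame(id = seq_len(nrow(edge_nodes)),
                      node_a = edge_nodes[, 1], node_b = edge_nodes[, 2],
                      length_um = lens)
  structure(list(nodes = nodes, edges = edges, polylines = polylines,
                 total_length = sum(lens)),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d nodes (%d branch points), %d edges, total length %.2f um\n",
              nrow(x$nodes), sum(x$nodes$degree >= 3), nrow(x$edges),
              x$total_length))
  invisible(x)
}

#' Polyline arc length
#'
#' Sum of Euclidean distances between consecutive points.
#'
#' @param p numeric matrix `n x 3`.
#' @return length in the units of `p`.
#' @export
polyline_length <- function(p) {
  if (is.null(dim(p)) || nrow(p) < 2) return(0)
  d <- diff(p)
  sum(sqrt(rowSums(d * d)))
}

#' Topology-preserving 3D curve thinning
#'
#' Reduces a binary tubular volume to a one-voxel-wide curve skeleton by
#' iterative six-subiteration directional thinning: each subiteration
#' collects border points of one face direction (U, D, N, S, E, W) and
#' deletes them sequentially, re-testing the simple-point condition against
#' the current image at deletion time, so every deletion preserves both the
#' number of 26-connected foreground components and the cycle structure.
#' Curve end points (voxels with at most one foreground neighbour) are never
#' deleted.
#'
#' @param mask a binary [voxel_volume()].
#' @return A binary [voxel_volume()] whose foreground is a subset of the
#'   input foreground.
#' @export
thin <- function(mask) {
  stopifnot(inherits(mask, "voxel_volume"))
  if (!mask$is_binary) stop("`mask` must be binary (run binarize() first)")
  if (!any(mask$data != 0)) {
    warning("empty foreground: returning empty skeleton")
    return(mask)
  }
  arr <- mask$data
  storage.mode(arr) <- "integer"
  mask$data <- .thin3d_cpp(arr, dim(arr))
  mask
}

# um position of 0-based voxel indices (iz, iy, ix): voxel centres.
.voxel_um <- function(iz, iy, ix, sp) {
  cbind(x = (ix + 0.5) * sp[3], y = (iy + 0.5) * sp[2], z = (iz + 0.5) * sp[1])
}

#' Convert a thinned skeleton volume to a geometric graph
#'
#' Skeleton voxels with a number of 26-neighbours different from 2 become
#' nodes (end points, branch points, isolated points); maximal chains of
#' 2-neighbour voxels become polyline edges. Clusters of mutually adjacent
#' junction voxels (each with >= 3 neighbours) collapse to a single node at
#' the cluster centroid, avoiding spurious zero-length edges. Pure cycles
#' with no junction receive one artificial node. Coordinates are converted
#' to um using the calibrated spacing; edge lengths therefore use
#' anisotropic physical step distances.
#'
#' @param skel a thinned binary [voxel_volume()].
#' @return A [skeleton_graph()].
#' @export
graph_from_skeleton <- function(skel) {
  stopifnot(inherits(skel, "voxel_volume"))
  if (!skel$is_binary) stop("`skel` must be binary")
  d <- dim(skel$data); nz <- d[1]; ny <- d[2]; nx <- d[3]
  sp <- voxel_spacing(skel)
  fg <- which(skel$data != 0)
  if (length(fg) == 0)
    return(skeleton_graph(matrix(numeric(0), ncol = 3), NULL, list()))
  i0 <- fg - 1L
  iz <- i0 %% nz; iy <- (i0 %/% nz) %% ny; ix <- i0 %/% (nz * ny)
  n <- length(fg)
  pos <- .voxel_um(iz, iy, ix, sp)

  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    zz <- iz + offs[k, 1]; yy <- iy + offs[k, 2]; xx <- ix + offs[k, 3]
    ok <- zz >= 0 & zz < nz & yy >= 0 & yy < ny & xx >= 0 & xx < nx
    j <- match(zz[ok] + nz * (yy[ok] + ny * xx[ok]) + 1L, fg)
    hit <- !is.na(j)
    from <- c(from, which(ok)[hit]); to <- c(to, j[hit])
  }
  deg <- tabulate(from, nbins = n)
  adj <- split(to, factor(from, levels = seq_len(n)))

  # --- nodes: junction clusters, end points, isolated points -------------
  node_of <- rep(NA_integer_, n)
  node_pos <- list()
  next_id <- 0L
  jv <- deg >= 3
  seen <- logical(n)
  for (v in which(jv)) {
    if (seen[v]) next
    # BFS over mutually adjacent junction voxels
    comp <- v; seen[v] <- TRUE; queue <- v
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      nb <- adj[[cur]]
      nb <- nb[jv[nb] & !seen[nb]]
      if (length(nb)) {
        seen[nb] <- TRUE
        comp <- c(comp, nb); queue <- c(queue, nb)
      }
    }
    next_id <- next_id + 1L
    node_of[comp] <- next_id
    node_pos[[next_id]] <- colMeans(pos[comp, , drop = FALSE])
  }
  for (v in which(deg == 1L | deg == 0L)) {
    next_id <- next_id + 1L
    node_of[v] <- next_id
    node_pos[[next_id]] <- pos[v, ]
  }

  # --- edges: trace maximal chains of 2-neighbour voxels -----------------
  visited <- logical(n)
  e_a <- integer(0); e_b <- integer(0); plist <- list()
  direct_seen <- new.env(hash = TRUE)
  add_edge <- function(a, b, pts) {
    pts <- pts[c(TRUE, rowSums(abs(diff(pts))) > 1e-12), , drop = FALSE]
    if (nrow(pts) < 2) return(invisible(NULL))
    e_a <<- c(e_a, a); e_b <<- c(e_b, b)
    plist[[length(plist) + 1L]] <<- pts
    invisible(NULL)
  }
  node_voxels <- which(!is.na(node_of))
  for (v in node_voxels) {
    for (w in adj[[v]]) {
      nw <- node_of[w]
      if (!is.na(nw)) {
        # direct node-node adjacency; one edge per unordered node pair
        na_ <- node_of[v]
        if (nw == na_) next
        key <- paste(min(na_, nw), max(na_, nw), sep = "_")
        if (!is.null(direct_seen[[key]])) next
        direct_seen[[key]] <- TRUE
        add_edge(na_, nw, rbind(node_pos[[na_]], pos[v, ], pos[w, ], node_pos[[nw]]))
      } else if (!visited[w]) {
        visited[w] <- TRUE
        chain <- w; prev <- v; cur <- w
        end_node <- NA_integer_
        repeat {
          nb <- adj[[cur]]
          nxt <- nb[nb != prev]
          if (length(nxt) == 0L) break # half-open chain (should not occur)
          nxt <- nxt[1]
          if (!is.na(node_of[nxt])) { end_node <- node_of[nxt]; last_vox <- nxt; break }
          visited[nxt] <- TRUE
          chain <- c(chain, nxt); prev <- cur; cur <- nxt
        }
        if (is.na(end_node)) next
        a <- node_of[v]
        add_edge(a, end_node,
                 rbind(node_pos[[a]], pos[chain, , drop = FALSE], node_pos[[end_node]]))
      }
    }
  }
  # pure cycles: remaining unvisited 2-neighbour voxels
  for (s in which(deg == 2L)) {
    if (visited[s]) next
    next_id <- next_id + 1L
    node_of[s] <- next_id
    node_pos[[next_id]] <- pos[s, ]
    visited[s] <- TRUE
    chain <- s; prev <- s; cur <- adj[[s]][1]
    while (cur != s) {
      visited[cur] <- TRUE
      chain <- c(chain, cur)
      nb <- adj[[cur]]
      nxt <- nb[nb != prev][1]
      prev <- cur; cur <- nxt
    }
    add_edge(next_id, next_id, pos[c(chain, s), , drop = FALSE])
  }

  skeleton_graph(do.call(rbind, node_pos),
                 cbind(e_a, e_b), plist)
}

#' Prune short terminal spurs
#'
#' Iteratively removes terminal edges (at least one endpoint of degree 1)
#' shorter than `min_spur_len`, then dissolves degree-2 junction nodes left
#' behind by merging their two incident edges. Total length never increases.
#'
#' @param graph a [skeleton_graph()].
#' @param min_spur_len minimum terminal edge length to keep, um (`>= 0`).
#'   With 0 the graph is returned unchanged.
#' @return A pruned [skeleton_graph()].
#' @export
prune <- function(graph, min_spur_len) {
  stopifnot(inherits(graph, "skeleton_graph"), min_spur_len >= 0)
  if (min_spur_len == 0 || nrow(graph$edges) == 0) return(graph)
  pos <- as.matrix(graph$nodes[, c("x", "y", "z")])
  en <- as.matrix(graph$edges[, c("node_a", "node_b")])
  pl <- graph$polylines
  orig_deg0 <- graph$nodes$degree == 0
  repeat {
    deg <- tabulate(c(en[, 1], en[, 2]), nbins = nrow(pos))
    len <- vapply(pl, polyline_length, numeric(1))
    term <- (deg[en[, 1]] == 1 | deg[en[, 2]] == 1) & len < min_spur_len &
      en[, 1] != en[, 2]
    if (!any(term)) break
    en <- en[!term, , drop = FALSE]; pl <- pl[!term]
  }
  # dissolve degree-2 nodes joining two distinct non-loop edges
  repeat {
    deg <- tabulate(c(en[, 1], en[, 2]), nbins = nrow(pos))
    cand <- which(deg == 2)
    merged <- FALSE
    for (v in cand) {
      inc <- which(en[, 1] == v | en[, 2] == v)
      if (length(inc) != 2) next # self-loop: keep
      i1 <- inc[1]; i2 <- inc[2]
      p1 <- pl[[i1]]; p2 <- pl[[i2]]
      if (en[i1, 2] != v) { p1 <- p1[nrow(p1):1, , drop = FALSE]; en[i1, ] <- rev(en[i1, ]) }
      if (en[i2, 1] != v) { p2 <- p2[nrow(p2):1, , drop = FALSE]; en[i2, ] <- rev(en[i2, ]) }
      pl[[i1]] <- rbind(p1, p2[-1, , drop = FALSE])
      en[i1, ] <- c(en[i1, 1], en[i2, 2])
      en <- en[-i2, , drop = FALSE]; pl <- pl[-i2]
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  deg <- tabulate(c(en[, 1], en[, 2]), nbins = nrow(pos))
  keep <- deg > 0 | orig_deg0
  remap <- cumsum(keep)
  en <- matrix(remap[en], ncol = 2)
  skeleton_graph(pos[keep, , drop = FALSE], en, pl)
}

#' Write a skeleton graph to a directory
#'
#' Writes `nodes.csv` (`id, x_um, y_um, z_um, degree`), `edges.csv`
#' (`id, node_a, node_b, length_um, polyline` — semicolon-separated
#' `x,y,z` triples) and `header.json` (spacing and provenance). Coordinates
#' are printed at fixed precision; [read_skeleton_graph()] round-trips them
#' bit-exactly.
#'
#' @param graph a [skeleton_graph()].
#' @param dir output directory (created if missing).
#' @param spacing optional `(dz, dy, dx)` um recorded in the header.
#' @param digits decimal places for printed coordinates (default 6).
#' @return `dir`, invisibly.
#' @export
write_skeleton_graph <- function(graph, dir, spacing = NULL, digits = 6) {
  stopifnot(inherits(graph, "skeleton_graph"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x) sprintf(paste0("%.", digits, "f"), x)
  nodes <- data.frame(id = graph$nodes$id, x_um = fmt(graph$nodes$x),
                      y_um = fmt(graph$nodes$y), z_um = fmt(graph$nodes$z),
                      degree = graph$nodes$degree)
  write.csv(nodes, file.path(dir, "nodes.csv"), row.names = FALSE, quote = FALSE)
  poly_str <- vapply(graph$polylines, function(p)
    paste(apply(p, 1, function(r) paste(fmt(r), collapse = ",")), collapse = ";"),
    character(1))
  edges <- data.frame(id = graph$edges$id, node_a = graph$edges$node_a,
                      node_b = graph$edges$node_b,
                      length_um = fmt(graph$edges$length_um),
                      polyline = poly_str)
  write.csv(edges, file.path(dir, "edges.csv"), row.names = FALSE, quote = TRUE)
  hdr <- list(format = "capmorph skeleton_graph v1",
              spacing_um = spacing, coordinate_digits = digits,
              n_nodes = nrow(graph$nodes), n_edges = nrow(graph$edges))
  jsonlite::write_json(hdr, file.path(dir, "header.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}

#' Read a skeleton graph written by [write_skeleton_graph()]
#'
#' @param dir directory holding `nodes.csv` and `edges.csv`.
#' @return A [skeleton_graph()].
#' @export
read_skeleton_graph <- function(dir) {
  nodes <- read.csv(file.path(dir, "nodes.csv"))
  edges <- read.csv(file.path(dir, "edges.csv"))
  pos <- as.matrix(nodes[, c("x_um", "y_um", "z_um")])
  pl <- lapply(as.character(edges$polyline), function(s) {
    pts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ",", fixed = TRUE)
    matrix(as.numeric(unlist(pts)), ncol = 3, byrow = TRUE)
  })
  skeleton_graph(pos, as.matrix(edges[, c("node_a", "node_b")]), pl)
}
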