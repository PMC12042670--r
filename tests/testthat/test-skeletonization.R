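test_that("thinning preserves trivial and tubular foregrounds", {
  # single voxel survives
  arr <- array(0L, c(5, 5, 5)); arr[3, 3, 3] <- 1L
  v <- voxel_volume(arr, c(1, 1, 1))
  expect_identical(thin(v)$data, arr)

  # empty foreground warns and returns empty
  expect_warning(s0 <- thin(voxel_volume(array(0L, c(4, 4, 4)), c(1, 1, 1))),
                 "empty")
  expect_true(all(s0$data == 0))
  expect_error(thin(voxel_volume(array(2, c(3, 3, 3)), c(1, 1, 1),
                                 is_binary = FALSE)), "binary")

  # solid z-tube, radius 3, 50 voxels: one 26-connected path near the axis
  tube <- tube_mask(50, 20, 20, radius = 3)
  sk <- thin(tube)
  expect_true(all(sk$data <= tube$data)) # subset of foreground
  expect_equal(n_components26(sk$data), 1)
  g <- graph_from_skeleton(sk)
  expect_equal(nrow(g$edges), 1)
  expect_lte(abs(g$total_length - 50) / 50, 0.10)
  expect_equal(cycle_rank(g), 0)
})

test_that("thinning preserves loops", {
  # hollow voxel ring in one slice
  arr <- array(0L, c(3, 20, 20))
  for (y in 1:20) for (x in 1:20) {
    r <- sqrt((y - 10.5)^2 + (x - 10.5)^2)
    if (r >= 4 && r <= 7) arr[2, y, x] <- 1L
  }
  v <- voxel_volume(arr, c(1, 1, 1))
  expect_equal(cycle_rank(graph_from_skeleton(thin(v))), 1)
})

test_that("graph extraction recovers paths, junctions and loops", {
  # straight 11-voxel path along y, dy = 0.756
  arr <- array(0L, c(3, 15, 3)); arr[2, 3:13, 2] <- 1L
  g <- graph_from_skeleton(voxel_volume(arr, c(1, 0.756, 0.756)))
  expect_equal(nrow(g$nodes), 2)
  expect_equal(nrow(g$edges), 1)
  expect_equal(sum(g$nodes$degree == 1), 2)
  expect_equal(g$total_length, 10 * 0.756)

  # symmetric Y: three straight arms meeting at one voxel
  arr <- array(0L, c(3, 21, 21))
  arr[2, 11, 11:20] <- 1L        # +x arm
  arr[2, 11:20, 11] <- 1L        # +y arm
  for (k in 0:9) arr[2, 11 - k, 11 - k] <- 1L # diagonal arm
  g <- graph_from_skeleton(voxel_volume(arr, c(1, 1, 1)))
  expect_equal(sum(g$nodes$degree >= 3), 1)
  expect_equal(sum(g$nodes$degree == 1), 3)
  expect_equal(nrow(g$edges), 3)
  expect_equal(max(g$nodes$degree), 3)

  # closed square loop (thinned: corners cut to diagonals): at most one
  # node, one cycle, length = brute-force sum of voxel steps
  arr <- array(0L, c(3, 12, 12))
  arr[2, 3:9, 3] <- 1L; arr[2, 3:9, 9] <- 1L
  arr[2, 3, 3:9] <- 1L; arr[2, 9, 3:9] <- 1L
  g <- graph_from_skeleton(thin(voxel_volume(arr, c(1, 1, 1))))
  expect_lte(nrow(g$nodes), 1)
  expect_equal(cycle_rank(g), 1)
  expect_equal(g$total_length, 16 + 4 * sqrt(2)) # 4x4 straight + 4 diagonal steps
})

test_that("isolated voxels become degree-0 nodes", {
  arr <- array(0L, c(3, 9, 9)); arr[2, 2, 2] <- 1L; arr[2, 7, 7] <- 1L
  g <- graph_from_skeleton(voxel_volume(arr, c(1, 1, 1)))
  expect_equal(nrow(g$nodes), 2)
  expect_true(all(g$nodes$degree == 0))
  expect_equal(nrow(g$edges), 0)
})

test_that("graph invariants hold: lengths sum, endpoints and degrees agree", {
  spec <- phantom_spec(rng_seed = 3)
  ph <- make_capillary_graph(spec, make_fiber_bundle(spec), per_fiber_truth = FALSE)
  g <- ph$graph
  lens <- vapply(g$polylines, polyline_length, numeric(1))
  expect_equal(sum(lens), g$total_length)
  expect_equal(g$edges$length_um, lens)
  for (e in seq_len(nrow(g$edges))) {
    p <- g$polylines[[e]]
    expect_equal(unname(p[1, ]),
                 unlist(g$nodes[g$edges$node_a[e], c("x", "y", "z")],
                        use.names = FALSE))
    expect_equal(unname(p[nrow(p), ]),
                 unlist(g$nodes[g$edges$node_b[e], c("x", "y", "z")],
                        use.names = FALSE))
  }
  expect_equal(g$nodes$degree,
               tabulate(c(g$edges$node_a, g$edges$node_b), nrow(g$nodes)))
})

test_that("thinning preserves topology across seeded phantoms", {
  for (s in c(11, 12, 13, 14, 15)) {
    spec <- phantom_spec(volume_extent = c(x = 72, y = 72, z = 64),
                         n_fibers = 1, fiber_diameter_mean = 24,
                         fiber_diameter_sd = 2, n_capillaries = 3,
                         n_branch_points = 2, branch_min_sep = 15,
                         rng_seed = s)
    ph <- make_capillary_graph(spec, make_fiber_bundle(spec), per_fiber_truth = FALSE)
    vol <- rasterize_phantom(ph)
    sk <- thin(vol)
    expect_equal(n_components26(sk$data), n_components26(vol$data))
    g <- prune(graph_from_skeleton(sk), 5)
    expect_equal(cycle_rank(g), cycle_rank(ph$graph))
  }
})

test_that("pruning removes short spurs and dissolves pass-through nodes", {
  # hand-built Y with one 2 um arm
  n <- rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0), c(10, 2, 5))
  e <- rbind(c(1, 2), c(2, 3), c(2, 4))
  pl <- list(rbind(n[1, ], n[2, ]), rbind(n[2, ], n[3, ]),
             rbind(n[2, ], n[4, ])) # third arm sqrt(29) > 5 um: stays
  g <- skeleton_graph(n, e, pl)
  expect_identical(prune(g, 0), g)
  # short 2 um arm instead
  n2 <- rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0), c(10, 2, 0))
  pl2 <- list(rbind(n2[1, ], n2[2, ]), rbind(n2[2, ], n2[3, ]),
              rbind(n2[2, ], n2[4, ]))
  g2 <- prune(skeleton_graph(n2, e, pl2), 5)
  expect_equal(nrow(g2$edges), 1)       # branch node dissolved
  expect_equal(g2$total_length, 20)
  expect_lte(g2$total_length, skeleton_graph(n2, e, pl2)$total_length)

  # cycle-only graph untouched at any threshold
  sq <- rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0), c(0, 10, 0), c(0, 0, 0))
  gc <- skeleton_graph(sq[1, , drop = FALSE], cbind(1L, 1L), list(sq))
  expect_identical(prune(gc, 50), gc)
})

test_that("graph serialization round-trips printed coordinates bit-exactly", {
  spec <- phantom_spec(rng_seed = 5)
  g <- make_capillary_graph(spec, make_fiber_bundle(spec),
                            per_fiber_truth = FALSE)$graph
  d1 <- file.path(tempdir(), "g1"); d2 <- file.path(tempdir(), "g2")
  write_skeleton_graph(g, d1, spacing = c(1, 0.756, 0.756))
  g2 <- read_skeleton_graph(d1)
  write_skeleton_graph(g2, d2, spacing = c(1, 0.756, 0.756))
  expect_identical(readLines(file.path(d1, "nodes.csv")),
                   readLines(file.path(d2, "nodes.csv")))
  e1 <- read.csv(file.path(d1, "edges.csv")); e2 <- read.csv(file.path(d2, "edges.csv"))
  expect_identical(e1$polyline, e2$polyline) # coordinates are bit-stable
  expect_identical(e1[c("id", "node_a", "node_b")], e2[c("id", "node_a", "node_b")])
  expect_equal(g2$total_length, g$total_length, tolerance = 1e-5)
})
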