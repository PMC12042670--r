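test_that("length and branch densities follow their definitions", {
  g <- polyline_graph(rbind(c(0, 0, 0), c(0, 0, 100)))
  expect_equal(length_density(g, 100^3), 1e-4)
  expect_error(length_density(g, 0), "volume")
  expect_error(length_density(g, -5), "volume")
  expect_equal(branch_density(g, 100^3), 0)

  # Y graph: one degree-3 node in (100 um)^3
  n <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  e <- rbind(c(1, 2), c(1, 3), c(1, 4))
  pl <- lapply(2:4, function(i) rbind(n[1, ], n[i, ]))
  y <- skeleton_graph(n, e, pl)
  expect_equal(branch_density(y, 1e6), 1e-6)

  empty <- skeleton_graph(matrix(numeric(0), ncol = 3), NULL, list())
  expect_equal(length_density(empty, 1e6), 0)
})

test_that("mean capillary length follows the 2/3 LV/NV rule", {
  expect_equal(mean_capillary_length(3e-6, 2e-6), 1.0)
  expect_true(is.na(mean_capillary_length(1e-4, 0)))
  # printed splenius means: 408.7e-6 / 0.92e-6
  expect_equal(mean_capillary_length(408.7e-6, 0.92e-6), 296.159, tolerance = 1e-3)
  # metrics computed jointly always satisfy lbar * NV * 3/2 = LV
  spec <- phantom_spec(rng_seed = 2)
  ph <- make_capillary_graph(spec, make_fiber_bundle(spec), per_fiber_truth = FALSE)
  m <- capillary_metrics(ph$graph, prod(spec$volume_extent))
  expect_equal(m$mean_capillary_length * m$NV * 1.5, m$LV)
})

test_that("tortuosity measures turning per unit length", {
  # straight edges turn nowhere
  g <- polyline_graph(rbind(c(0, 0, 0), c(0, 0, 25), c(0, 0, 50)))
  expect_equal(tortuosity(g), 0)
  # one right-angle bend over 100 um
  bend <- polyline_graph(rbind(c(0, 0, 0), c(0, 0, 50), c(0, 50, 50)))
  expect_equal(tortuosity(bend), (pi / 2) / 100, tolerance = 1e-9)
  # zero-length graph errors
  expect_error(tortuosity(skeleton_graph(matrix(numeric(0), ncol = 3),
                                         NULL, list())), "zero")
})

test_that("anisotropy index spans isotropic to aligned", {
  # all segments parallel to z -> 3
  g <- skeleton_graph(rbind(c(0, 0, 0), c(0, 0, 30), c(5, 5, 0), c(5, 5, 30)),
                      rbind(c(1, 2), c(3, 4)),
                      list(rbind(c(0, 0, 0), c(0, 0, 30)),
                           rbind(c(5, 5, 0), c(5, 5, 30))))
  expect_equal(as.numeric(anisotropy(g)), 3)
  # segments uniform in the xy-plane -> 1.5
  k <- 36
  th <- seq(0, pi, length.out = k + 1)[-(k + 1)]
  nodes <- NULL; edges <- NULL; pl <- list()
  for (i in seq_len(k)) {
    a <- c(0, 0, 0) + i * c(100, 0, 0)
    b <- a + 10 * c(cos(th[i]), sin(th[i]), 0)
    nodes <- rbind(nodes, a, b)
    edges <- rbind(edges, c(2 * i - 1, 2 * i))
    pl[[i]] <- rbind(a, b)
  }
  expect_equal(as.numeric(anisotropy(skeleton_graph(nodes, edges, pl))), 1.5,
               tolerance = 1e-9)
  ev <- attr(anisotropy(skeleton_graph(nodes, edges, pl)), "eigenvalues")
  expect_equal(sum(ev), 1)
})

test_that("tortuosity and anisotropy are rotation invariant on exact polylines", {
  set.seed(5)
  zs <- seq(0, 60, by = 0.5)
  p <- cbind(3 * sin(2 * pi * zs / 25), 2 * cos(2 * pi * zs / 40), zs)
  g <- polyline_graph(p)
  # a rigid rotation
  ax <- c(1, 2, 3) / sqrt(14); ang <- 0.83
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
  g2 <- polyline_graph(p %*% t(R))
  expect_lt(abs(tortuosity(g) - tortuosity(g2)), 1e-9)
  expect_lt(abs(as.numeric(anisotropy(g)) - as.numeric(anisotropy(g2))), 1e-9)
})

test_that("metrics scale correctly with coordinates", {
  # piecewise-straight polyline with well-separated bends
  p <- rbind(c(0, 0, 0), c(0, 0, 40), c(0, 30, 70), c(20, 30, 90))
  g1 <- polyline_graph(p)
  s <- 2.5
  g2 <- polyline_graph(p * s)
  expect_equal(as.numeric(anisotropy(g2)), as.numeric(anisotropy(g1)),
               tolerance = 1e-9)
  expect_equal(tortuosity(g2), tortuosity(g1) / s, tolerance = 1e-6)
  expect_equal(length_density(g2, 1e6 * s^3), length_density(g1, 1e6) / s^2)
})

test_that("anisotropy of uniformly random directions is near 1", {
  set.seed(11)
  n <- 1e4
  z <- runif(n, -1, 1); phi <- runif(n, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  starts <- cbind(runif(n, 0, 1000), runif(n, 0, 1000), runif(n, 0, 1000))
  nodes <- rbind(starts, starts + dirs)
  edges <- cbind(seq_len(n), n + seq_len(n))
  pl <- lapply(seq_len(n), function(i) rbind(starts[i, ], starts[i, ] + dirs[i, ]))
  a <- as.numeric(anisotropy(skeleton_graph(nodes, edges, pl)))
  expect_lt(abs(a - 1), 0.05)
})

test_that("capillary metrics serialize with scaled units", {
  g <- polyline_graph(rbind(c(0, 0, 0), c(0, 0, 100)))
  m <- capillary_metrics(g, 1e6)
  path <- tempfile(fileext = ".json")
  write_capillary_metrics(m, path)
  j <- jsonlite::read_json(path)
  expect_equal(j$raw$LV_um2, 1e-4)
  expect_equal(j$scaled$LV_um2_x1e6, 100)
})
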