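test_that("cylinder geometry matches closed forms", {
  f <- cylinder_fiber(r = 20, z = c(0, 33, 66, 99))
  expect_equal(f$fiber_volume, pi * 400 * 99, tolerance = 1e-3)
  expect_equal(f$lateral_surface, 2 * pi * 20 * 99, tolerance = 1e-3)
  expect_equal(f$equivalent_diameter, 40, tolerance = 1e-3)
  expect_equal(f$lesser_diameter, 40, tolerance = 2e-3)
  expect_equal(f$fiber_length, 99)
})

test_that("square prism geometry matches closed forms", {
  sq <- rbind(c(0, 0), c(30, 0), c(30, 30), c(0, 30))
  f <- fiber_geometry(list(list(z = 0, xy = sq), list(z = 50, xy = sq)))
  expect_equal(f$fiber_volume, 45000)
  expect_equal(f$lateral_surface, 6000)
  expect_equal(f$lesser_diameter, 30)
  expect_equal(f$cross_sectional_area, 900)
  expect_equal(f$fiber_length, 50)
})

test_that("four-level frustum volume is within 2% of the exact cone formula", {
  h <- 60; r0 <- 10; r1 <- 20
  z <- c(0, 20, 40, 60)
  f <- fiber_geometry(lapply(z, function(zz)
    list(z = zz, xy = circle_poly(r0 + (r1 - r0) * zz / h))))
  exact <- pi * h / 3 * (r1^2 + r1 * r0 + r0^2)
  expect_lt(abs(f$fiber_volume - exact) / exact, 0.02)
  # frustum lateral surface with slant correction is near-exact too
  slant <- sqrt(h^2 + (r1 - r0)^2)
  expect_equal(f$lateral_surface, pi * (r0 + r1) * slant, tolerance = 5e-3)
})

test_that("fiber geometry validates its inputs", {
  expect_error(fiber_geometry(list(list(z = 0, xy = circle_poly(10)))),
               "at least two")
  bow <- rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))
  expect_error(fiber_geometry(list(list(z = 0, xy = bow),
                                   list(z = 10, xy = bow))),
               "self-intersecting")
  expect_error(fiber_geometry(list(list(z = 10, xy = circle_poly(5)),
                                   list(z = 0, xy = circle_poly(5)))),
               "increasing")
})

test_that("neighborhood assignment matches analytic shell geometry", {
  f <- cylinder_fiber(r = 20, z = c(0, 27, 54, 80))
  # capillary parallel to the fiber, 5 um off the surface, co-extensive
  par5 <- polyline_graph(rbind(c(25, 0, 0), c(25, 0, 80)))
  expect_equal(assign_capillary_length(par5, f, 10), 80, tolerance = 1e-6)
  # 15 um off the surface: outside the 10 um shell
  par15 <- polyline_graph(rbind(c(35, 0, 0), c(35, 0, 80)))
  expect_equal(assign_capillary_length(par15, f, 10), 0)
  # straight chord crossing the shell: assigned ~ analytic chord length
  chord <- polyline_graph(rbind(c(25, -60, 40), c(25, 60, 40)))
  analytic <- 2 * sqrt(30^2 - 25^2)
  expect_lt(abs(assign_capillary_length(chord, f, 10, step = 0.5) - analytic) /
              analytic, 0.02)
  # interior counts as distance zero
  inside <- polyline_graph(rbind(c(0, 0, 10), c(0, 0, 70)))
  expect_equal(assign_capillary_length(inside, f, 10), 60, tolerance = 1e-6)
})

test_that("assignment is monotone in the radius and additive over edges", {
  f <- cylinder_fiber(r = 15, z = c(0, 20, 40, 60))
  set.seed(8)
  pts1 <- cbind(20 + cumsum(rnorm(30, 0, 1)), cumsum(rnorm(30, 0, 2)),
                seq(0, 58, length.out = 30))
  pts2 <- cbind(-25 + cumsum(rnorm(20, 0, 1)), cumsum(rnorm(20, 0, 2)),
                seq(5, 43, length.out = 20))
  both <- skeleton_graph(rbind(pts1[1, ], pts1[30, ], pts2[1, ], pts2[20, ]),
                         rbind(c(1, 2), c(3, 4)), list(pts1, pts2))
  g1 <- polyline_graph(pts1); g2 <- polyline_graph(pts2)
  prev <- -1
  for (r in c(5, 10, 15, 20)) {
    cur <- assign_capillary_length(both, f, r)
    expect_gte(cur, prev)
    prev <- cur
  }
  expect_equal(assign_capillary_length(both, f, 10),
               assign_capillary_length(g1, f, 10) +
                 assign_capillary_length(g2, f, 10),
               tolerance = 1)
  # non-overlapping z-ranges warn and yield 0
  away <- polyline_graph(rbind(c(16, 0, 100), c(16, 0, 150)))
  expect_warning(a0 <- assign_capillary_length(away, f, 10), "z-range")
  expect_equal(a0, 0)
})

test_that("supply ratios follow their definitions and scaling", {
  f <- cylinder_fiber(r = 20, z = c(0, 33, 66, 99))
  st <- fiber_supply_stats(f, 200)
  expect_equal(st$LL, 200 / f$fiber_length)
  expect_equal(st$LL, 2.02, tolerance = 1e-2)
  expect_equal(st$LS, 200 / f$lateral_surface)
  expect_equal(st$LS, 160.8e-4, tolerance = 1e-2)
  expect_equal(st$LVf, 200 / f$fiber_volume)
  expect_equal(st$LVf, 16.1e-4, tolerance = 1e-2)
  z0 <- fiber_supply_stats(f, 0)
  expect_equal(c(z0$LL, z0$LS, z0$LVf), c(0, 0, 0))
  # doubling the fiber scale at fixed assigned length
  f2 <- cylinder_fiber(r = 40, z = 2 * c(0, 33, 66, 99))
  st2 <- fiber_supply_stats(f2, 200)
  expect_equal(st2$LL, st$LL / 2, tolerance = 1e-6)
  expect_equal(st2$LS, st$LS / 4, tolerance = 1e-6)
  expect_equal(st2$LVf, st$LVf / 8, tolerance = 1e-6)
})

test_that("per-fiber supply recovers generator ground truth", {
  spec <- phantom_spec(rng_seed = 9)
  b <- make_fiber_bundle(spec)
  ph <- make_capillary_graph(spec, b)
  res <- measure_stack(rasterize_phantom(ph))
  for (f in b$fibers) {
    gt <- ph$truth$per_fiber_assigned_um[[as.character(f$fiber_id)]]
    got <- assign_capillary_length(res$graph, f, 10)
    if (gt > 50) expect_lt(abs(got - gt) / gt, 0.05)
  }
})

test_that("fiber outlines round-trip through the CSV dialect", {
  spec <- phantom_spec(rng_seed = 4)
  b <- make_fiber_bundle(spec)
  path <- tempfile(fileext = ".csv")
  write_fiber_outlines(b$fibers, path)
  back <- read_fiber_outlines(path)
  expect_equal(length(back), length(b$fibers))
  f0 <- b$fibers[[1]]; f1 <- back[[as.character(f0$fiber_id)]]
  expect_equal(f1$cross_sectional_area, f0$cross_sectional_area, tolerance = 1e-3)
  expect_equal(f1$fiber_volume, f0$fiber_volume, tolerance = 1e-3)
})
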