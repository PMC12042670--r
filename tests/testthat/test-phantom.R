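test_that("phantom specs validate their parameters", {
  expect_error(phantom_spec(transverse_fraction = 1.2), "\\[0, 1\\]")
  expect_error(phantom_spec(transverse_fraction = 0, n_branch_points = 2),
               "transverse")
  expect_error(phantom_spec(n_branch_points = 3), "even")
  expect_error(phantom_spec(capillary_radius = -1), "positive")
  expect_error(make_fiber_bundle(phantom_spec(n_fibers = 50)), "packing")
})

test_that("phantom generation is deterministic for a fixed spec and seed", {
  spec <- phantom_spec(rng_seed = 17)
  b1 <- make_fiber_bundle(spec); b2 <- make_fiber_bundle(spec)
  expect_identical(b1$centers, b2$centers)
  expect_identical(b1$fibers[[1]]$outlines, b2$fibers[[1]]$outlines)
  p1 <- make_capillary_graph(spec, b1, per_fiber_truth = FALSE)
  p2 <- make_capillary_graph(spec, b2, per_fiber_truth = FALSE)
  expect_identical(p1$graph$polylines, p2$graph$polylines)
  s1 <- make_stain_table(50, seed = 17); s2 <- make_stain_table(50, seed = 17)
  expect_identical(s1, s2)
  c1 <- make_cohort(seed = 17); c2 <- make_cohort(seed = 17)
  expect_identical(c1$value, c2$value)
})

test_that("a single circular fiber matches cylinder closed forms", {
  spec <- phantom_spec(volume_extent = c(x = 70, y = 70, z = 100),
                       n_fibers = 1, fiber_diameter_mean = 40,
                       fiber_diameter_sd = 0, n_capillaries = 2,
                       n_branch_points = 0, transverse_fraction = 0,
                       tortuosity_amplitude = 0, rng_seed = 1)
  b <- make_fiber_bundle(spec)
  f <- b$fibers[[1]]
  expect_equal(f$equivalent_diameter, 40, tolerance = 0.05)
  expect_equal(f$fiber_volume, pi * 20^2 * 100, tolerance = 0.1)
  expect_equal(f$lateral_surface, 2 * pi * 20 * 100, tolerance = 0.1)
})

test_that("generated fiber diameters track the requested distribution", {
  for (fd in list(c(37.5, 8.6), c(56.2, 7.9))) {
    spec <- phantom_spec(volume_extent = c(x = 900, y = 900, z = 60),
                         n_fibers = 100, fiber_diameter_mean = fd[1],
                         fiber_diameter_sd = fd[2], n_capillaries = 1,
                         n_branch_points = 0, transverse_fraction = 0.1,
                         rng_seed = 23)
    b <- make_fiber_bundle(spec)
    dmean <- mean(vapply(b$fibers, function(f) f$equivalent_diameter, numeric(1)))
    expect_lt(abs(dmean - fd[1]) / fd[1], 0.05)
  }
})

test_that("straight phantoms have trivial ground-truth tortuosity and anisotropy", {
  spec <- phantom_spec(tortuosity_amplitude = 0, n_branch_points = 0,
                       transverse_fraction = 0, rng_seed = 2)
  ph <- make_capillary_graph(spec, make_fiber_bundle(spec), per_fiber_truth = FALSE)
  expect_equal(ph$truth$tortuosity, 0)
  expect_equal(ph$truth$anisotropy, 3.0)
  expect_equal(ph$truth$n_branch_points, 0L)
})

test_that("seeded branch counts are exact in the ground truth", {
  spec <- phantom_spec(volume_extent = c(x = 194, y = 194, z = 128),
                       n_fibers = 8, fiber_diameter_mean = 30,
                       fiber_diameter_sd = 3, n_capillaries = 16,
                       n_branch_points = 20, transverse_fraction = 0.05,
                       branch_min_sep = 20, rng_seed = 3)
  ph <- make_capillary_graph(spec, make_fiber_bundle(spec), per_fiber_truth = FALSE)
  expect_equal(ph$truth$n_branch_points, 20L)
  expect_equal(sum(ph$graph$nodes$degree >= 3), 20)
})

test_that("ground-truth tortuosity matches the analytic sinusoid integral", {
  spec <- phantom_spec(n_capillaries = 4, n_branch_points = 0,
                       transverse_fraction = 0.15, # below the sinusoid's own lateral content: no jogs
                       tortuosity_amplitude = 2, tortuosity_period = 40,
                       rng_seed = 5)
  ph <- make_capillary_graph(spec, make_fiber_bundle(spec), per_fiber_truth = FALSE)
  # analytic: dense quadrature of the turning of x(z) = a sin(2 pi z / T)
  a <- 2; Tp <- 40; ez <- 128
  z <- seq(0, ez, by = 0.01)
  slope <- a * 2 * pi / Tp * cos(2 * pi * z / Tp)
  ang <- abs(diff(atan(slope)))
  len <- sum(sqrt(1 + slope^2) * 0.01)
  analytic <- sum(ang) / len
  expect_lt(abs(ph$truth$tortuosity - analytic) / analytic, 0.03)
})

test_that("tube rasterization matches analytic volumes and components", {
  # single straight tube: voxel count ~ pi r^2 L / voxel volume
  g <- polyline_graph(rbind(c(13, 13, 0), c(17, 18, 100)))
  sp <- c(1, 0.756, 0.756)
  vol <- rasterize_tubes(g, 2.5, sp, dims = c(100, 40, 40))
  expected <- pi * 2.5^2 * sqrt(4^2 + 5^2 + 100^2) / prod(sp)
  expect_lt(abs(sum(vol$data) - expected) / expected, 0.05)
  expect_true(vol$is_binary)

  # empty graph -> empty mask
  empty <- skeleton_graph(matrix(numeric(0), ncol = 3), NULL, list())
  expect_equal(sum(rasterize_tubes(empty, 2.5, sp, c(20, 20, 20))$data), 0)

  # two parallel tubes 30 um apart: two 26-connected components
  g2 <- skeleton_graph(rbind(c(10, 10, 0), c(10, 10, 60),
                             c(40, 10, 0), c(40, 10, 60)),
                       rbind(c(1, 2), c(3, 4)),
                       list(rbind(c(10, 10, 0), c(10, 10, 60)),
                            rbind(c(40, 10, 0), c(40, 10, 60))))
  v2 <- rasterize_tubes(g2, 2.5, c(1, 1, 1), c(60, 20, 55))
  expect_equal(n_components26(v2$data), 2)

  # graph outside the extent clips with a warning
  gz <- polyline_graph(rbind(c(15, 15, 0), c(15, 15, 100)))
  expect_warning(rasterize_tubes(gz, 2.5, sp, dims = c(50, 40, 40)), "clip")
})

test_that("simulated fields are byte-identical across runs", {
  spec <- phantom_spec(volume_extent = c(x = 60, y = 60, z = 48),
                       n_fibers = 1, fiber_diameter_mean = 24,
                       fiber_diameter_sd = 2, n_capillaries = 2,
                       n_branch_points = 0, transverse_fraction = 0.05,
                       rng_seed = 19)
  d1 <- file.path(tempdir(), "field1"); d2 <- file.path(tempdir(), "field2")
  simulate_field(spec, d1, n_stain_fibers = 40)
  simulate_field(spec, d2, n_stain_fibers = 40)
  for (f in c("stack.tif", "fibers.csv", "truth.json", "stains.csv", "cohort.csv"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
})

test_that("fiber label volumes mark fibers where their outlines are", {
  spec <- phantom_spec(volume_extent = c(x = 70, y = 70, z = 40),
                       n_fibers = 1, fiber_diameter_mean = 30,
                       fiber_diameter_sd = 0, n_capillaries = 1,
                       n_branch_points = 0, transverse_fraction = 0.1,
                       rng_seed = 8)
  b <- make_fiber_bundle(spec)
  lab <- make_fiber_label_volume(b)
  area_vox <- sum(lab$data[20, , ] == 1) * 0.756^2
  expect_lt(abs(area_vox - b$fibers[[1]]$cross_sectional_area) /
              b$fibers[[1]]$cross_sectional_area, 0.05)
})

test_that("the oracle outline distance agrees with the pipeline's on circles", {
  poly <- circle_poly(15, centre = c(3, -2), n = 48)
  set.seed(10)
  pts <- cbind(runif(50, -30, 30), runif(50, -30, 30))
  a <- capmorph:::.oracle_outline_dist(pts, poly)
  b <- polygon_outside_distance(pts, poly)
  expect_lt(max(abs(a - b)), 0.15) # boundary sampling granularity
})
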