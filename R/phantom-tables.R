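#' Reference fiber-type composition and size presets
#'
#' Type proportions (order `1, 2a, 2x, 1/2a, 2a/2x`), diameters (um) and
#' cross-sectional areas (um^2) characteristic of the splenius capitis and
#' vastus lateralis muscles of young adult males, used to parameterize the
#' stain-table generator. Proportions are normalized to sum to 1 (printed
#' per-type percentages are subject means and need not sum to exactly 100).
#'
#' @param muscle `"splenius"` or `"vastus"`.
#' @return List `proportions` (named, sums to 1), `diameter` (5 x 2 matrix
#'   mean/sd), `csa` (5 x 2 matrix mean/sd).
#' @export
fiber_type_preset <- function(muscle = c("splenius", "vastus")) {
  muscle <- match.arg(muscle)
  typ <- c("1", "2a", "2x", "1/2a", "2a/2x")
  if (muscle == "splenius") {
    pr <- c(51.2, 16.3, 17.4, 2.6, 13.0)
    dm <- cbind(mean = c(37.5, 38.1, 41.7, 38.9, 35.2),
                sd = c(8.6, 10.0, 13.6, 8.0, 9.6))
    cs <- cbind(mean = c(3849, 3880, 3072, 3460, 3548),
                sd = c(1031, 1219, 1453, 1095, 1342))
  } else {
    pr <- c(39.8, 31.4, 14.1, 1.8, 12.9)
    dm <- cbind(mean = c(56.2, 55.1, 47.1, 53.3, 54.2),
                sd = c(7.9, 8.7, 13.8, 12.2, 11.0))
    cs <- cbind(mean = c(7663, 8387, 6247, 7017, 7314),
                sd = c(2214, 2438, 1824, 1985, 2061))
  }
  rownames(dm) <- rownames(cs) <- typ
  list(proportions = setNames(pr / sum(pr), typ), diameter = dm, csa = cs)
}

#' Generate a synthetic stain-intensity table
#'
#' Draws multinomial fiber-type labels at the given proportions, then
#' channel intensities from type-conditional truncated-normal
#' distributions consistent with the antibody reactivities: positive
#' channels ~ N(0.8, 0.1), the weak SC-71 cross-reaction of pure 2x fibers
#' ~ N(0.45, 0.05), negative channels ~ N(0.1, 0.05), all clipped to
#' `[0, 1]`. Per-fiber diameter and CSA are drawn from type-conditional
#' normals (truncated positive).
#'
#' @param n_fibers number of fibers.
#' @param proportions named numeric over types `1, 2a, 2x, 1/2a, 2a/2x`,
#'   `>= 0`, summing to 1 (+/- 1e-6).
#' @param seed integer seed.
#' @param intensity list with `pos`, `weak`, `neg`, each `c(mean, sd)`.
#' @param size optional list with `diameter` and `csa` matrices as in
#'   [fiber_type_preset()]; default splenius values.
#' @return data.frame `fiber_id, intensity_bad5, intensity_sc71,
#'   intensity_6h1, diameter, csa, true_type`.
#' @export
make_stain_table <- function(n_fibers,
                             proportions = fiber_type_preset("splenius")$proportions,
                             seed = 1,
                             intensity = list(pos = c(0.8, 0.1),
                                              weak = c(0.45, 0.05),
                                              neg = c(0.1, 0.05)),
                             size = NULL) {
  typ <- c("1", "2a", "2x", "1/2a", "2a/2x")
  if (is.null(names(proportions))) names(proportions) <- typ
  proportions <- proportions[typ]
  if (any(is.na(proportions)) || any(proportions < 0))
    stop("proportions must be named over ", paste(typ, collapse = ", "),
         " and non-negative")
  if (abs(sum(proportions) - 1) > 1e-6)
    stop("proportions must sum to 1 (+/- 1e-6)")
  if (is.null(size)) size <- fiber_type_preset("splenius")
  set.seed(.stage_seed(seed, 4L))
  labels <- sample(typ, n_fibers, replace = TRUE, prob = proportions)
  draw <- function(par, n) pmin(1, pmax(0, rnorm(n, par[1], par[2])))
  # channel means per type: BA-D5 (slow 1), SC-71 (2a strongly, 2x weakly),
  # 6H1 (2x)
  chan <- list(
    "1"     = list(b = "pos", s = "neg", h = "neg"),
    "2a"    = list(b = "neg", s = "pos", h = "neg"),
    "2x"    = list(b = "neg", s = "weak", h = "pos"),
    "1/2a"  = list(b = "pos", s = "pos", h = "neg"),
    "2a/2x" = list(b = "neg", s = "pos", h = "pos"))
  n <- n_fibers
  b <- s <- h <- d <- cs <- numeric(n)
  for (t in typ) {
    i <- labels == t
    if (!any(i)) next
    b[i] <- draw(intensity[[chan[[t]]$b]], sum(i))
    s[i] <- draw(intensity[[chan[[t]]$s]], sum(i))
    h[i] <- draw(intensity[[chan[[t]]$h]], sum(i))
    d[i] <- pmax(5, rnorm(sum(i), size$diameter[t, "mean"], size$diameter[t, "sd"]))
    cs[i] <- pmax(100, rnorm(sum(i), size$csa[t, "mean"], size$csa[t, "sd"]))
  }
  data.frame(fiber_id = seq_len(n), intensity_bad5 = b, intensity_sc71 = s,
             intensity_6h1 = h, diameter = d, csa = cs, true_type = labels)
}

#' Table of between-muscle capillary metric distributions
#'
#' Per-metric means and SDs for the splenius capitis and vastus lateralis
#' muscles (in the conventional scaled units: LV x 1e-6 um^-2, LS x 1e-4
#' um^-1, LVf x 1e-4 um^-2, tortuosity x 1e-3 rad/um, Br dens x 1e-6
#' um^-3), used as planted effects by [make_cohort()].
#'
#' @return data.frame `metric, mean_splenius, sd_splenius, mean_vastus,
#'   sd_vastus`.
#' @export
capillary_metric_effects <- function() {
  data.frame(
    metric = c("LV", "LL", "LS", "LVf", "tortuosity", "anisotropy", "br_dens"),
    mean_splenius = c(408.7, 2.1, 132, 13.1, 33.8, 2.35, 0.92),
    sd_splenius = c(70.5, 0.3, 17, 3.7, 11.7, 0.44, 0.24),
    mean_vastus = c(409.2, 3.9, 165, 10.9, 40.9, 1.61, 1.44),
    sd_vastus = c(70.6, 0.8, 32, 2.6, 8.6, 0.14, 0.46))
}

#' Generate a synthetic paired cohort table
#'
#' Draws per-subject, per-muscle metric values with specified means/SDs,
#' a between-subject correlation across muscles (shared subject effect),
#' and an optional monotone BMI dependence planted via a Gaussian copula
#' component (`value` gains a `rho * z_bmi` share of its SD).
#'
#' @param n_subjects number of subjects (`>= 3`), default 13.
#' @param effects data.frame as [capillary_metric_effects()].
#' @param subject_cor between-muscle correlation of a metric within
#'   subject, in `[0, 1)`; default 0.5.
#' @param bmi_rho optional named numeric: target (Pearson) correlation of
#'   a metric with BMI, per metric, applied within both muscles; must
#'   satisfy `subject_cor + bmi_rho^2 <= 1`.
#' @param age_range,bmi_mean,bmi_sd cohort demographics.
#' @param seed integer seed.
#' @return A [cohort_table()]-valid data.frame with attribute `"truth"`.
#' @export
make_cohort <- function(n_subjects = 13, effects = capillary_metric_effects(),
                        subject_cor = 0.5, bmi_rho = NULL,
                        age_range = c(23, 48), bmi_mean = 26.5, bmi_sd = 4.4,
                        seed = 1) {
  if (n_subjects < 3) stop("n_subjects must be >= 3")
  if (subject_cor < 0 || subject_cor >= 1)
    stop("subject_cor must lie in [0, 1)")
  set.seed(.stage_seed(seed, 5L))
  age <- round(runif(n_subjects, age_range[1], age_range[2]))
  bmi <- pmin(42, pmax(18, rnorm(n_subjects, bmi_mean, bmi_sd)))
  zb <- as.numeric(scale(bmi))
  rows <- list()
  for (r in seq_len(nrow(effects))) {
    m <- effects$metric[r]
    rho <- if (!is.null(bmi_rho) && m %in% names(bmi_rho)) bmi_rho[[m]] else 0
    if (subject_cor + rho^2 > 1)
      stop("invalid covariance spec for metric ", m,
           ": subject_cor + bmi_rho^2 must be <= 1")
    zs <- rnorm(n_subjects)
    resid_sd <- sqrt(1 - subject_cor - rho^2)
    for (mus in c("splenius", "vastus")) {
      mu <- effects[[paste0("mean_", mus)]][r]
      sdv <- effects[[paste0("sd_", mus)]][r]
      val <- mu + sdv * (sqrt(subject_cor) * zs + rho * zb +
                           resid_sd * rnorm(n_subjects))
      rows[[length(rows) + 1L]] <-
        data.frame(subject_id = seq_len(n_subjects), age = age, bmi = bmi,
                   muscle = mus, metric = m, value = val)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- list(effects = effects, subject_cor = subject_cor,
                             bmi_rho = bmi_rho)
  cohort_table(out)
}

#' Phantom presets for the two muscles
#'
#' Parameterizes a [phantom_spec()] from the printed tissue values of each
#' muscle: fiber diameters, capillary length density (which fixes the
#' total centreline length for the chosen field), branch density (which
#' fixes the seeded branch count), sinusoid amplitude/period matched to
#' the printed tortuosity, and a transverse fraction reflecting the
#' relative anisotropy of the two networks (the splenius network is more
#' axially aligned).
#'
#' @param muscle `"splenius"` or `"vastus"`.
#' @param volume_extent `(x, y, z)` field extent in um; default a
#'   384 x 384 x 65 voxel field at confocal spacing.
#' @param rng_seed integer seed.
#' @return A [phantom_spec()].
#' @export
phantom_preset <- function(muscle = c("splenius", "vastus"),
                           volume_extent = c(x = 290.304, y = 290.304, z = 65),
                           rng_seed = 1) {
  muscle <- match.arg(muscle)
  vol <- prod(volume_extent)
  if (muscle == "splenius") {
    LV <- 408.7e-6; NV <- 0.92e-6
    fd <- c(37.5, 8.6); tf <- 0.10; amp <- 2.15; per <- 40
    n_fib <- 14
  } else {
    LV <- 409.2e-6; NV <- 1.44e-6
    fd <- c(56.2, 7.9); tf <- 0.30; amp <- 2.0; per <- 35
    n_fib <- 7
  }
  phantom_spec(volume_extent = volume_extent,
               spacing = c(dz = 1, dy = 0.756, dx = 0.756),
               n_fibers = n_fib, fiber_diameter_mean = fd[1],
               fiber_diameter_sd = fd[2],
               capillary_radius = 2.5,
               n_branch_points = 2L * max(1L, round(NV * vol / 2)),
               tortuosity_amplitude = amp, tortuosity_period = per,
               transverse_fraction = tf, branch_min_sep = 25,
               rng_seed = rng_seed,
               target_total_length = LV * vol)
}

#' Simulate a full synthetic field
#'
#' Runs the whole generator at one seed and writes every artifact in the
#' dialects the analysis modules consume: `stack.tif` (binary capillary
#' volume), `fibers.csv` (outlines), `truth.json`, `stains.csv`,
#' `cohort.csv`.
#'
#' @param spec a [phantom_spec()] (e.g. from [phantom_preset()]).
#' @param out_dir output directory.
#' @param n_stain_fibers fibers in the stain table.
#' @param proportions type proportions for the stain table.
#' @param stain_size optional [fiber_type_preset()]-style size list for the
#'   stain table (diameter/CSA distributions).
#' @return Invisibly, a list with the in-memory `bundle`, `phantom`,
#'   `volume`, `stains`, `cohort`.
#' @export
simulate_field <- function(spec, out_dir, n_stain_fibers = 300,
                           proportions = fiber_type_preset("splenius")$proportions,
                           stain_size = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- make_fiber_bundle(spec)
  phantom <- make_capillary_graph(spec, bundle)
  vol <- rasterize_phantom(phantom)
  write_stack(vol, file.path(out_dir, "stack.tif"))
  write_fiber_outlines(bundle$fibers, file.path(out_dir, "fibers.csv"))
  tr <- phantom$truth
  tr$per_fiber_assigned_um <- as.list(tr$per_fiber_assigned_um)
  jsonlite::write_json(tr, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  stains <- make_stain_table(n_stain_fibers, proportions, seed = spec$rng_seed,
                             size = stain_size)
  write.csv(stains, file.path(out_dir, "stains.csv"), row.names = FALSE)
  cohort <- make_cohort(seed = spec$rng_seed)
  write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  invisible(list(bundle = bundle, phantom = phantom, volume = vol,
                 stains = stains, cohort = cohort))
}

#' Run the full voxel pipeline on a binary capillary volume
#'
#' The production path from a binary stack to network metrics: thinning,
#' graph extraction, optional spur pruning, then [capillary_metrics()]
#' against the calibrated stack volume.
#'
#' @param vol a binary [voxel_volume()].
#' @param min_spur_len spur-pruning threshold, um (0 disables; default 5,
#'   about one capillary diameter).
#' @param refine apply [refine_centerline()] sub-voxel recentring and tip
#'   extension against the mask (default `TRUE`).
#' @param refine_radius neighbourhood radius for the refinement, um.
#' @param refine_passes number of refinement passes (default 2; the second
#'   pass further suppresses residual staircase ripple).
#' @param ... passed to [capillary_metrics()].
#' @return List `graph` (pruned, refined [skeleton_graph()]) and `metrics`
#'   ([capillary_metrics()]).
#' @export
measure_stack <- function(vol, min_spur_len = 5, refine = TRUE,
                          refine_radius = 4, refine_passes = 2, ...) {
  skel <- thin(vol)
  graph <- graph_from_skeleton(skel)
  if (min_spur_len > 0) graph <- prune(graph, min_spur_len)
  if (refine) for (i in seq_len(refine_passes))
    graph <- refine_centerline(graph, vol, radius = refine_radius)
  list(graph = graph, metrics = capillary_metrics(graph, physical_volume(vol), ...))
}
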