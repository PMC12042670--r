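# capmorph

Three-dimensional morphometry of the capillary network in skeletal muscle.

Muscle capillaries form a 3D network that runs predominantly along the
fibers, bends, and branches through transverse anastomoses. Quantifying
that architecture from confocal stacks of stained vessels — rather than
from single 2D sections — is the purpose of this package. It is written
for muscle physiologists and image analysts working with thick-section
immunofluorescence (e.g. lectin/collagen-IV stained 100 µm sections imaged
at ~0.756 × 0.756 × 1 µm voxels), and for anyone who needs a validated,
fully scriptable version of this workflow.

## What it computes

From a binary capillary volume the pipeline extracts a one-voxel-wide
curve skeleton (topology-preserving six-subiteration thinning), converts
it to a geometric graph of polyline segments in µm, refines it to
sub-voxel accuracy against the mask, and reports:

* **L**<sub>V</sub> — capillary length per unit tissue volume (µm⁻²),
* **Br dens** (N<sub>V</sub>) — branch points per unit volume (µm⁻³),
* **mean capillary length** ℓ̄ = (2/3) · L<sub>V</sub> / N<sub>V</sub>,
* **tortuosity** — Σ exterior angles / total length (rad µm⁻¹),
* **anisotropy** — 3λ₁ of the length-weighted structure tensor of segment
  directions (1 = isotropic, 3 = perfectly aligned),
* **LL, LS, LVf** — capillary length within a 10 µm neighbourhood of each
  muscle fiber, per fiber length, surface, and volume, from fiber outlines
  at several stack levels.

Companion modules classify fibers into MyHC types (1, 2a, 2x, 1/2a,
2a/2x) from BA-D5 / SC-71 / 6H1 antibody intensities, run the paired
between-muscle tests and BMI rank correlations (exact Spearman permutation
p at cohort sizes ≤ 13), and generate synthetic phantoms with exact ground
truth so the whole pipeline is verifiable without tissue data.

## Worked example

Simulate a small validation field, run the full voxel pipeline, and
compare with the generator's exact ground truth:

```r
library(capmorph)
spec    <- phantom_spec(rng_seed = 1)   # 128^3-voxel field, 3 fibers, 6 capillaries
bundle  <- make_fiber_bundle(spec)
phantom <- make_capillary_graph(spec, bundle)
stack   <- rasterize_phantom(phantom)
res <- measure_stack(stack)             # thin -> graph -> prune -> refine -> metrics
res$metrics
#> <capillary_metrics>
#>   LV            0.000691 um^-2  (x1e6: 691.0)
#>   Br dens      1.669e-06 um^-3  (x1e6: 1.67)
#>   mean length      276.1 um
#>   tortuosity     0.02896 rad/um (x1e3: 29.0)
#>   anisotropy       2.711        [1 iso .. 3 aligned]
#>   total length 828.3 um in 1.199e+06 um^3 (2 branch points)
```

The ground truth for this phantom is 834 µm of centreline, tortuosity
0.0298 rad/µm, anisotropy 2.70, and 2 seeded branch points: the pipeline
recovers the length within 1%, tortuosity within 3%, anisotropy within
0.01, and the branch count exactly. Per-fiber supply follows from the
fiber outlines:

```r
sup <- field_supply_summary(res$graph, bundle$fibers)
as.data.frame(sup$summary)
#>   n_fibers       LL         LS         LVf assigned_um
#> 1        3 2.156906 0.02485247 0.003623893     276.084
```

Real data enter the same way via `read_stack("stack.tif", spacing =
c(dz, dy, dx))`, `apply_axial_calibration()`, and `binarize()`; fiber
outlines via `read_fiber_outlines()`.

## The analysis workflow

The `analysis/` scripts run the study end to end on synthetic fields whose
parameters (fiber sizes, capillary length and branch densities, alignment)
come from published values for the splenius capitis and vastus lateralis
muscles of young men:

```sh
Rscript analysis/01_simulate_fields.R      # phantoms + stains + cohort -> results/fields/
Rscript analysis/02_capillary_morphometry.R# stacks -> skeleton graphs -> network metrics
Rscript analysis/03_fiber_supply.R         # LL / LS / LVf per fiber and per field
Rscript analysis/04_fiber_typing.R         # MyHC type calls and proportions
Rscript analysis/05_cohort_stats.R         # paired t + Spearman-vs-BMI tables
```

Tables land under `results/`. The splenius-like field comes out less
branched, more axially aligned, with lower LL/LS and higher LVf than the
vastus-like field — the direction of every reported between-muscle
difference.

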