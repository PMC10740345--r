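# siteFidelity

Site fidelity — the tendency of an individual to return to, or remain at, a
previously used site — shapes how migratory shorebirds cope with habitat
loss. `siteFidelity` is an R package for quantifying site fidelity of two
sympatric long-distance migrants, the Bar-tailed Godwit (*Limosa lapponica*,
`BTG`) and the Great Knot (*Calidris tenuirostris*, `GK`), from the two data
types available for such populations:

* **Argos satellite telemetry** — duty-cycled (8 h on / 25 h off) fixes with
  class-dependent location error (standard classes 3/2/1, 68th error
  percentile < 2.5 km; auxiliary classes 0/A/B/Z, 10–30 km), and
* **mark-resighting histories** — survey-based re-observations of
  colour-banded individuals with imperfect detection.

The package implements the full analysis chain:

1. **Argos quality control** (`hybridFilter`): all standard fixes are kept;
   an auxiliary fix survives only if it is within the maximum redundant
   distance (10 km) of an adjacent retained fix or both of its implied
   segment speeds are below the maximum sustainable movement rate
   (120 km/h). Violators are removed iteratively, worst offender first.
2. **State-space smoothing** (`fitRwSsm`, optional): a continuous-time
   random-walk model in a local azimuthal-equidistant plane. The true
   position `x(t)` diffuses with covariance `sigma^2 * dt * I`; each fix
   observes it with the 2×2 covariance built from its Argos error ellipse
   (or class defaults). A Kalman filter plus RTS smoother yields fitted
   locations; `sigma` is estimated by maximising the innovations likelihood.
3. **Stopover-site identification** (`buildItinerary`): Yellow Sea fixes
   moving slower than 5 km/h are "stationary"; complete-linkage clustering
   on great-circle distances with the number of clusters chosen by maximum
   mean silhouette width; clusters must hold ≥ 95% of members within 25 km
   of their centroid (re-clustering with k+1 otherwise); centroids closer
   than 50 km are merged; sites need ≥ 3 fixes spanning ≥ 2 h; arrival and
   departure times are extrapolated across the 25 km site radius.
4. **Fidelity metrics**: non-breeding single-site residency
   (`nonbreedingUsage`), post-migration return (`returnedAfterMigration`),
   seasonal revisitation of northward sites during southward migration
   within 50 km (`seasonalRevisit`), and the resighting analogues
   (`periodUsage`, `seasonalMatch`, `betweenYearMatch`) with the ≥ 2
   sightings rule, the 1 November window and max-across-years collapsing.
5. **Inference** (`fisherExact2x2`, `fractionalLogit`): exact two-sided
   Fisher tests (probability-mass convention, log-gamma enumeration) for
   the 2×2 species contrasts, and quasi-binomial logit regression with
   Pearson-dispersion Wald tests for proportion-of-time comparisons.
6. **Simulation with known truth** (`simConfig`, `makeBenchmark`):
   duty-cycled telemetry and survey-based resightings generated from true
   itineraries (non-breeding residency with optional within-season moves,
   1–4 Yellow Sea staging sites, Arctic breeding, southward site reuse), so
   every stage can be validated against ground truth.

## Worked example

Simulate the study cohort (24 godwits, 41 knots, of which exactly 7 are
programmed to move between non-breeding sites), run the pipeline, and
compare the species:

```r
library(siteFidelity)

cfg <- pipelineConfig()          # every analysis constant, overridable
sc  <- studyCohortConfig()         # the study-cohort simulation preset
b   <- makeBenchmark(sc, seed = 7)

usages <- analyzeNonbreeding(b$tracks, cfg)   # filter + site detection
ss     <- speciesSummary(usages = usages)
ss$nonbreedingStay$table
#>     stayed moved
#> BTG     24     0
#> GK      34     7
round(ss$nonbreedingStay$percentStayed, 1)
#>   BTG    GK
#> 100.0  82.9
ss$nonbreedingStay$fisher$pTwoSided
#> [1] 0.04071655
```

All 24 godwits stayed at a single non-breeding site while 7 of 41 knots
moved (displacements of 80–920 km), and the exact test flags the species
difference (p = 0.041) — the pipeline recovers the programmed contrast
exactly, since `b$truth$mover` matches `usages$moved` bird for bird.

The published species comparisons can be recomputed directly from their
cohort counts, e.g. the resighting-based non-breeding contrast
(624/641 one-site godwits vs 727/775 one-site knots):

```r
fisherExact2x2(624, 17, 727, 48)
#> Exact two-sided Fisher test
#>      [,1] [,2]
#> [1,]  624   17
#> [2,]  727   48
#> p = 0.001, sample odds ratio = 2.42
```

A thin command-line wrapper over these functions is included at
`inst/cli/sitefidelity.R` (subcommands `simulate`, `filter`, `smooth`,
`sites`, `fidelity-track`, `fidelity-resight`, `report`).

## Scope

The package analyses movement and resighting data only: survival modelling,
population-trend estimation and cartographic figure production are out of
scope (sites export to plain CSV/GeoJSON for mapping elsewhere).
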