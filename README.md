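# condylomorph

CT-based condylar morphometry and cohort analysis for temporomandibular
joint (TMJ) disc-displacement studies.

Anterior disc displacement of the TMJ is associated with degenerative
remodeling of the mandibular condyle, and disc repositioning surgery with
renewed bone apposition.  Quantifying that remodeling longitudinally
requires a reproducible, three-dimensional measurement protocol on
CT-derived surface meshes — not single-slice estimates.  `condylomorph`
implements such a protocol end to end for researchers analyzing condylar
bone modeling in two-group (untreated vs disc-repositioned) designs:

* **Condylar block volume** — the primary outcome.  The osteotomy plane C
  is constructed parallel to the Frankfort horizontal plane (through the
  bilateral porions and orbitale) passing through *s*, the lowest point of
  the mandibular sigmoid notch.  The mandible mesh is cut at C, capped, and
  the block volume *V* is computed by the divergence theorem:
  *V* = (1/6) Σ det(v₁, v₂, v₃) over the capped triangles.
* **Seven-landmark heights** — the secondary outcome.  The crest poles *i*
  (medial) and *o* (lateral); section planes M (⊥ C through *i*, *o*), N
  (⊥ IO and C through the IO midpoint) and N1/N2 (± 45°); the apex *up* on
  M; the anterior/posterior slope points *a*, *p* on N; and *pi*, *po* on
  N1/N2 assigned by proximity to *i*/*o*.  Each landmark's height is its
  signed distance to C; the asymmetry indices are D_i−o and D_pi−po.
* **Cephalometric indices** ANB (midsagittal subspinale–nasion–supramentale
  angle), PN (pogonion to the nasion vertical), ME (menton to the facial
  midline).
* **Cohort statistics** — quartile summaries under the (n+1)p percentile
  convention, exact/asymptotic Mann–Whitney U, pooled/Welch t tests (raw or
  summary input), ICC(A,1) with F-based confidence intervals, dummy-coded
  multiple regression of volume change, bilateral per-patient summation,
  and a noncentral-t sample-size calculation.
* **Synthetic data** — a parametric condyle generator (ellipsoidal head,
  cosh neck with an analytically placed head–neck inflection, sub-notch
  stub), a regional remodeling-field simulator, and measurement-level or
  mesh-level cohort simulation with a ground-truth ledger, so the entire
  pipeline is testable without patient data.

Meshes are read and written as STL (binary or ASCII) or PLY (ASCII), units
millimetres; landmarks as JSON name → [x, y, z].

## Worked example

```r
library(condylomorph)

# a synthetic right condyle with consistent cranial landmarks
gen <- generate_condyle(condyle_params(side = "right", subdivision = 3))
m   <- measure_condyle(gen$mesh, gen$landmarks, side = "right")

round(m$volume, 1)
#> [1] 1529.6
round(m$heights, 2)
#>     i     o     a     p    pi    po    up
#> 10.96 10.96  5.38  5.59  5.62  5.62 17.50
```

The block volume (1529.6 mm³) agrees with the generator's analytic
quadrature oracle (1533.3 mm³) to 0.24%; the crest poles *i*/*o* sit at the
head equator (height ≈ 11 mm), the slope points land within half a mesh
edge of the generator's 6 mm neck inflection, and *up* recovers the apex
height 17.5 mm.  A full simulated trial:

```r
tab <- simulate_cohort(cohort_spec(n_per_group = 30, seed = 1))
res <- run_full_analysis(tab)
res$volume_change$summary
#> # A tibble: 2 × 7
#>   group     n median   q25   q75   mean    sd
#>   <chr> <int>  <dbl> <dbl> <dbl>  <dbl> <dbl>
#> 1 DD       30   25.6 -125.  114.  -4.43  167.
#> 2 DR       30  258.   167.  466. 316.    230.
res$volume_change$p_value
#> [1] 3.81e-07
```

i.e. the disc-repositioned group's summed condylar volume change is larger
by ~250 mm³ at the simulated effect size, detected by the two-tailed
Mann–Whitney test.

A thin CLI wrapping these functions ships in `inst/cli/condylomorph.R`
(commands `cut`, `landmarks`, `cephalo`, `measure`, `analyze`, `simulate`,
`power`).

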