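---
title: "Automated tangential whole-breast planning: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated tangential whole-breast planning: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`autotangent` implements an automated planning algorithm for hypofractionated
whole-breast irradiation (42.56 Gy in 16 daily fractions) with a six-field
tangential IMRT layout, and everything needed to exercise it end-to-end on a
desk: a synthetic phantom generator, a transparent pencil-beam dose engine, a
fluence optimizer, and a plan-evaluation/statistics layer. This vignette is
the package's own account of the models it uses, the conventions it fixes,
and the choices made where the design was genuinely open.

## The planning algorithm

The automated sequence run by `autoplan()` is:

1. Create the posterior ring structures Ring_1 and Ring_2 behind the PTV.
2. Place the isocenter at the PTV centroid.
3. Find the two opposed tangential major fields by exhaustive search: for F1
   every integer gantry angle in 270-330 degrees, for F2 every integer gantry
   angle in 90-150 degrees, each crossed with every integer collimator angle
   in 330-30 degrees (61 x 61 = 3721 pairs per field). For each pair the jaws
   are fitted to the beam's-eye-view projection of the PTV and the pair with
   the smallest jaw area wins.
4. Add four minor fields at fixed offsets: F3/F4/F5 at F1 + 15/30/45 degrees,
   F6 at F2 - 15 degrees, collimators copied from the parent field; minor
   jaws are fitted to the PTV and the inner X jaw is then opened to 1.5 cm
   beyond the isocenter projection.
5. Optimize all beamlet weights against the dose-volume objective template.
6. Measure the volume above the 105% isodose; if it is below 0.5 cc the plan
   is complete.
7. Otherwise the 105% region becomes a constraint structure, is appended to
   the template, and optimization runs exactly once more.
8. Done; metrics and provenance are recorded.

## Coordinate and machine conventions

One convention is fixed package-wide: grid axis 1 runs right to left, axis 2
anterior to posterior, axis 3 inferior to superior; voxel `(i,j,k)` (1-based)
has its centre at `origin + (i-1, j-1, k-1) * spacing` mm, and volumes are
voxel count times voxel volume. Beam angles follow IEC 61217: gantry 0 is a
beam from the anterior, increasing clockwise seen from the patient's feet, so
gantry 90 enters from the patient's left; the source sits 1000 mm from the
isocenter (standard linac SAD, the source-axis distance). "Posterior" for the
ring construction is the +y grid axis. Distances are Euclidean between voxel
centres; ball dilation/erosion includes a voxel when its centre distance is
within the radius, which makes every morphological result checkable by
brute-force enumeration.

## The synthetic phantom generator

`generate_phantom()` stands in for a planning CT with approved contours. It
emulates a supine left-sided breast case: an elliptic-cylinder torso, a
breast CTV modelled as an ellipsoid centred on the anterior-left chest
surface, two lungs, a heart displaced toward the left, and a mirrored
contralateral breast. The PTV is the CTV expanded isotropically by 5 mm,
clipped to the body and kept 4 mm away from the skin surface; the default
grid uses 4 mm in-plane spacing and 3 mm slices (the slice thickness of the
emulated CT protocol).

Size classes follow the 300/600 ml CTV stratification (small < 300 ml,
medium 300-600 ml, large > 600 ml) with generator targets of 200, 450 and
800 ml; these sit comfortably inside their class so that the achieved volume
(guaranteed within 10% of target by a single voxelization-correction pass)
never straddles a cutoff. All shape parameters are drawn once per seed from
uniform jitter inside anatomically plausible ranges (torso semi-axes 140-165
by 90-110 mm, breast azimuth 35-50 degrees from the anterior, aspect ratios
1.05-1.45) and recorded in the phantom's provenance, so a phantom is fully
reproducible from `(size, seed, grid)`.

What the phantom deliberately does not model: tissue heterogeneity (lungs are
geometric regions, not low-density media, unless the engine is configured
otherwise), breathing motion, realistic chest-wall curvature, seromas or
surgical clips, and inter-patient anatomical correlation. Tests passing on
these phantoms therefore validate the *algorithm* - the geometry, search,
optimization and bookkeeping - not clinical dosimetry.

## The dose engine

`beamlet_influence()` implements a simplified divergent pencil-beam model,
written for transparency and analytic testability rather than clinical
accuracy. The jaw rectangle is tiled with beamlets of `beamlet_size_mm`
(default 5 mm) pitch; each beamlet casts a ray from the source through its
centre and deposits, at every body voxel within the lateral cutoff,

    d = (SAD / r)^2 * exp(-mu * depth) * exp(-s^2 / (2 * sigma^2))

where `r` is the source-voxel distance, `depth` the in-body path length to
the voxel's axial position (uniform ray stepping at half the smallest voxel
pitch, linear interpolation between steps), `s` the perpendicular distance to
the ray, `mu` an effective attenuation of 0.005/mm (6 MV-like water value)
and `sigma` the lateral spread (default 3 mm). Contributions below 1/1000 of
the lateral peak are dropped, which keeps the influence matrices sparse. A
parallel-geometry test mode disables divergence and the inverse-square
factor so that slab attenuation ratios can be checked against `exp(-mu*d)`
to 1e-6.

The lateral spread must be commensurate with the beamlet pitch: a lattice of
3 mm pencils at 10 mm pitch would leave ~50% dose valleys between beamlet
axes. The default pairs 5 mm beamlets with sigma 3 mm (ripple well under 5%),
and the coarse preset pairs 10 mm beamlets with sigma 6 mm - the same 0.6
ratio. The engine has no build-up region, no heterogeneity correction by
default (an optional relative-density volume can scale the radiological
depth, e.g. to give the lungs a reduced density), no electron contamination
and no absolute calibration; plan doses are internally consistent Gy but not
comparable with a commercial system's.

## The objective template

The supplementary template used clinically is not reproducible here, so the
package defines a configurable default (`default_objective_template()`):

| structure     | kind       | dose             | volume | weight |
|---------------|-----------|------------------|--------|--------|
| PTV           | lower_dv  | 42.56 Gy         | 98%    | 100    |
| PTV           | upper_dv  | 44.69 Gy (105%)  | 0%     | 80     |
| Ring_1        | max_upper | 40.43 Gy (95%)   | -      | 30     |
| Ring_2        | max_upper | 34.05 Gy (80%)   | -      | 20     |
| LungIpsi      | mean_upper| 6 Gy             | -      | 20     |
| Heart         | mean_upper| 1.5 Gy           | -      | 20     |
| BreastContra  | max_upper | 3 Gy             | -      | 20     |

The organ-at-risk levels echo routinely achieved whole-breast constraint
values; the numbers are explicitly non-canonical and every entry can be
replaced. The rings act as dose-falloff controls behind the target; their
extents (10 and 20 mm posterior) are likewise configurable defaults, since
only their purpose, not their geometry, is fixed by the algorithm.

The composite objective is a weighted sum of mean squared violations:
`lower_dv` penalizes voxels below the threshold while the volume above it is
short of the volume goal, `upper_dv` symmetrically, `mean_upper` penalizes
the squared positive excess of the structure mean, and `max_upper` penalizes
every voxel's positive excess. A value of zero is equivalent to all
positively-weighted objectives being met.

## Optimizer

`optimize_fluence()` runs projected gradient descent over nonnegative
beamlet weights with a quadratic neighbour-difference smoothing term
(weight 1e-3) on each fluence map. Weights start uniform, scaled so the mean
PTV dose matches the leading PTV target; each step is backtracked until the
objective does not increase, so the logged objective sequence is monotone
non-increasing by construction. Defaults: 200 iterations, relative-change
tolerance 1e-5. Diagonally preconditioned variants were evaluated and
rejected: the volume gates make the objective only piecewise smooth, and
aggressive per-beamlet scaling caused stalls.

### Coverage normalization

With this engine and a quadratic penalty equilibrium, the raw optimum leaves
the PTV D95 a few percent short of prescription regardless of iteration
budget - the penumbra of the jaw-fitted fields and the opposing upper
objectives balance mid-violation. Clinical practice resolves exactly this
with a plan normalization, so `autoplan()` applies one terminal global
fluence rescale making the PTV D95 equal the prescription (`normalize =
FALSE` turns it off). The hotspot loop intentionally runs *before*
normalization, at optimizer scale, so its pre/post V105 volumes are directly
comparable; the delivered-dose hotspot volume and the scale factor are
recorded separately in the plan.

### Hotspot loop

The 105% isodose volume uses a strict inequality (a voxel at exactly 105.0%
is excluded - the boundary convention is documented rather than meaningful).
If it exceeds 0.5 cc after the first pass, the region is added to the
template as a `max_upper` objective at 105% of prescription with weight 150
and optimization repeats exactly once, warm-started from the first-pass
fluence; there is never a third pass. On a compliant plan the loop does not
run at all.

## Evaluation conventions

`Vx` counts voxels with dose at least the threshold. `Dx` (dose to the
hottest x%) uses the exact voxel quantile - the largest dose received by at
least x% of the structure - so a uniform dose returns itself for every x and
the generalized-inverse identities `V(Dx) >= x`, `V(Dx + e) <= x` hold
exactly; the binned cumulative curve additionally offers a
linear-interpolation inverse. HI is D5/D95 on the PTV (1 is perfectly
homogeneous); CI is BV95/PTV with BV95 the *body* volume receiving at least
95% of prescription. The mean DVH band uses the t-based confidence interval
of the per-bin mean (a coverage band across plans is a config switch away in
`mean_dvh_band()`); the t distribution was chosen over the normal because
cohort sizes here are small. Breast-size stratification assigns the
boundaries 300 and 600 ml to the medium class. Cohort comparisons use the
classical paired two-tailed t-test and one-way ANOVA, with degenerate inputs
(all differences zero; all groups constant and equal) reported as p = 1
rather than errors.

## Problem sizes and determinism

The default phantom lattice is 96 x 76 x 44 voxels at 4 x 4 x 3 mm; the test
suite mostly uses 48 x 38 x 22 at 8 x 8 x 6 mm with 10-12 mm beamlets, which
plans in a few seconds while exercising every code path - these sizes are
the package's chosen desk-scale working points, and all quality statements in
the tests are made at them. Every stochastic element (phantom jitter) is
driven by an explicit integer seed, the optimizer is deterministic, and a
plan serialized with `plan_to_json()` is byte-identical across reruns of the
same configuration; each artifact embeds an MD5 hash of its configuration.

## Known limitations

Plans are not dosimetrically comparable to clinical systems (engine
simplifications above); there is no MLC leaf sequencing, couch rotation,
non-coplanar geometry or deliverability constraint; the F1/F2 searches are
independent rather than joint; monitor units are a relative fluence-integral
proxy; and the phantom population is a geometric caricature of breast
anatomy, useful for algorithmic validation only.
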