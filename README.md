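# autotangent

Automated six-field tangential IMRT planning for hypofractionated
whole-breast irradiation, as a self-contained R pipeline that runs on
synthetic voxel phantoms.

Whole-breast radiotherapy after breast-conserving surgery is planned with two
opposed tangential beams that skim the chest wall, covering the breast while
sparing the heart, lungs and contralateral breast. It is routine, high-volume
work and a natural target for automation. `autotangent` implements the full
automated planning sequence for the common hypofractionated prescription
(42.56 Gy in 16 daily fractions) and everything needed to exercise it at desk
scale, with no treatment-planning system attached: phantom generation,
beam's-eye-view geometry, a transparent dose engine, fluence optimization and
plan evaluation. It is aimed at medical-physics researchers and students who
want an inspectable, testable implementation of a tangential auto-planning
algorithm.

## The algorithm

For a left-sided case with PTV = CTV + 5 mm cropped 4 mm from the skin:

1. Build posterior ring structures Ring_1/Ring_2 behind the PTV (dose-falloff
   control).
2. Isocenter at the PTV centroid.
3. **Tangential angle search**: for major field F1, every integer gantry in
   270–330° crossed with every integer collimator in 330–30° (61 × 61 = 3721
   pairs); for each pair, fit the X/Y jaws to the projected PTV and record
   the field area; keep the pair with the smallest area. Same for F2 over
   gantry 90–150°.
4. **Minor fields** F3/F4/F5 at F1 + 15/30/45°, F6 at F2 − 15°, collimators
   copied from the parent; jaws fit the PTV, then the inner X jaw opens
   1.5 cm beyond the isocenter.
5. Optimize beamlet fluence against a dose-volume objective template
   (quadratic penalties, projected gradient descent).
6. If the volume above 105% of prescription exceeds 0.5 cc, the 105% isodose
   region becomes a constraint structure, is appended to the template, and
   optimization repeats **exactly once**.

Plan quality is reported as PTV V95%, homogeneity index HI = D5%/D95%,
conformity index CI = BV95%/V_PTV (BV95% = body volume receiving ≥ 95% of
prescription), body V110%, organ-at-risk dose-volume points (lung V16Gy and
mean, heart V20Gy and mean, contralateral-breast V5Gy and max) and a
monitor-unit proxy, plus paired t-tests, one-way ANOVA across breast-size
classes (CTV < 300 / 300–600 / > 600 ml) and mean DVH bands for cohorts.

The dose engine is a deliberately simple divergent pencil-beam model
(inverse square × effective attenuation × Gaussian lateral spread) built for
transparency and analytic testability; plans are internally consistent but
not dosimetrically comparable to a commercial system. See the methods
vignette (`vignettes/autoplanning-methods.Rmd`) for every model, convention
and default.

## Worked example

```r
library(autotangent)
phantom <- generate_phantom("medium", seed = 1)   # 450 ml CTV class
plan <- autoplan(phantom, engine = dose_engine_config(beamlet_size_mm = 10,
                                                      lateral_sigma_mm = 6))
print(plan)
print(plan$metrics)
```

prints (a few seconds on one CPU):

```
breast_autoplan: 6 fields, 2 optimization pass(es), completed at step 7 -> 8
  F1 gantry/collimator 313/0, F2 133/0
  V105 pre 158.016 cc, post 67.584 cc; PTV V95 97.4%, HI 1.186, CI 1.415, MU proxy 2196
PTV V95 97.4%, HI 1.186, CI 1.415, body V110 5.72%
Lung V16 6.3% V4 13.4% mean 3.30 Gy | heart V20 0.00% mean 0.03 Gy | contra breast V5 0.00% max 0.00 Gy | MU 2196
```

Reading this: the search chose tangents at gantry 313°/133° (collimator 0°
both), i.e. near-opposed beams entering right-anterior and left-posterior.
The first optimization pass left 158 cc above the 105% isodose, so the
hotspot loop triggered and a single re-optimization cut it to 68 cc. After
coverage normalization 97.4% of the PTV receives ≥ 95% of prescription; the
HI and CI are looser than clinical values because of the simplified engine
(the vignette discusses this). Heart and contralateral breast are essentially
out of the beams.

`run_cohort()` repeats this across seeded phantoms in all three size classes
and emits per-plan metrics, mean ± SD summaries and the stratified ANOVA.
A thin CLI wraps the same functions:

```sh
Rscript inst/cli/autotangent plan --size medium --seed 1 --coarse --trace --out out/
Rscript inst/cli/autotangent cohort --n 2 --seed 1 --coarse --out out/
```

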