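# limbarch

Quantifying skeletal-muscle and deep-fascia structure from volumetric and
diffusion MRI.

`limbarch` is an R package for longitudinal limb-structure studies — for
example, quantifying what changes in a leg between a pre-injury scan and a
follow-up after weeks in an immobilization boot. It takes segmented image
data (labeled masks on the acquisition grid, diffusion-weighted stacks with
their gradient tables) and computes three families of quantities:

1. **Volumetry** — per-muscle and per-bone volumes by voxel summation
   (`labelVolume`), signed percent changes (`percentChange`), integer
   slice alignment of pre/post stacks on a bony landmark
   (`alignStacksByLandmark`), and anatomical compartment grouping
   (`groupCompartments`, with the standard calf/thigh compartment table in
   `defaultCompartments`).
2. **Fascia thickness** — the deep (crural) fascia is a ~1 mm collagenous
   tube imaged at ~0.3 mm resolution with dual-echo ultrashort-TE contrast
   (`dualEchoSubtract`). Its thickness distribution is mapped slice by
   slice: the binary sheet is thinned to its centerline
   (`sliceCenterline`), and at every centerline pixel the local thickness
   is twice the Euclidean distance transform of the foreground
   (`thicknessMap`). At a medial pixel the inner and outer boundary are
   equidistant, so *t(x) = 2 d(x)* is the local sheet thickness. An
   independent algebraic estimate, volume / (centerline length × slice
   coverage) (`meanThicknessAlgebraic`), cross-checks the map, and
   `compareThickness` reports the pre-to-post distribution shift.
3. **Muscle architecture from DTI** — per-voxel diffusion tensors by
   log-linear least squares (`fitTensors`), FA/MD maps (`faMD`),
   deterministic streamline tractography along the principal eigenvector
   (`trackFibers`), polynomial extrapolation of tracts to the muscle
   boundary (`extrapolateTracts`), the ≤1.3× / 5–200 mm inclusion filter
   (`filterTracts`), and per-muscle fascicle length, pennation angle
   (arccos of the fascicle–line-of-action dot product) and PCSA = V / L̄
   (`architectureMetrics`, or everything at once via
   `muscleArchitecture`).

Because subject data for such studies are rarely shareable, the package
ships analytic phantom generators with closed-form ground truth: an
irregular fascia tube (`makeFasciaPhantom`), labeled elliptic-cylinder limb
masks (`makeLimbPhantom`), a unipennate muscle with a constant tensor field
and simulated Rician-noise DWI (`makePennatePhantom`, `simulateDWI`), and a
matched pre/post pair with prescribed changes (`makePrePostPair`). Every
pipeline stage is validated against these truths.

## Worked example

```r
library(limbarch)

# fascia: constant-thickness tube, truth 1.2 mm, 0.3 mm pixels
ph <- makeFasciaPhantom(nSlices = 10)
thicknessMap(ph$mask)
#> ThicknessMap: 2380 samples over 10 slices
#>   mean 1.252 mm, sd 0.095 mm
meanThicknessAlgebraic(ph$mask)
#> [1] 1.213

# muscle architecture: unipennate phantom at 30 degrees
pp  <- makePennatePhantom(30)
dwi <- simulateDWI(pp$tensors, gradientTable(20), bValue = 500)
muscleArchitecture(dwi, pp$mask, seed = 42)$report
#> ArchitectureReport: muscle
#>   volume 80.00 cm^3, PCSA 40.51 cm^2
#>   fascicle length 1.97 +/- 0.13 cm, pennation 30.0 +/- 0.0 deg
#>   tracts: seeded=1002, tracked=1000, extrapolated=1000, accepted=1000

# pre/post comparison: fascia scaled by 1.09, femur volume -2.22%
pair <- makePrePostPair(seed = 1)
compareThickness(thicknessMap(pair$pre$fascia),
                 thicknessMap(pair$post$fascia))
#> ThicknessShift: mean +8.58%, median +11.80%
```

The thickness map recovers the 1.2 mm truth to a sixth of a pixel, the two
thickness estimators agree within ~3%, the recovered pennation equals the
phantom's 30° (truth fascicle length here is 10 mm / sin 30° = 20 mm, the
report's 1.97 cm), and the prescribed 9% fascia thickening is detected as an
8.6% mean shift.

`runComparison(runConfig(...))` chains the stages into a single reproducible
pre-vs-post report with provenance; see the methods vignette
(`vignettes/limbarch-methods.Rmd`) for the models, parameter defaults and
their rationale.

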