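# panicleCT

Nondestructive 3D phenotyping of rice panicles from X-ray micro-CT.

Grain number and grain size per panicle are central yield traits, but
measuring them traditionally means threshing — slow, destructive, and blind
to 3D quantities such as grain volume and thickness. panicleCT turns a CT
scan of an intact panicle (a DICOM slice stack, ~0.3 mm resolution, the
panicle fixed in a plastic holder) into per-grain measurements and a
22-trait panicle record:

1. **Holder clearance** — the holder's gray levels can overlap the grains'
   completely, so it is removed geometrically: per-slice inner-edge
   detection, size-based selection of the holder bore, 2D filling, 3D
   morphological closing, masking.
2. **Grain segmentation** — global Otsu thresholding (exact argmax of the
   between-class variance σ²ᵦ(t) = w₀w₁(μ₀ − μ₁)² over all 65,536
   thresholds), then an improved distance-transform watershed: chessboard
   distance map, regional maxima merged at the grain-radius scale (plus a
   ridge-connectivity criterion that distinguishes noise dips from true
   contact necks), and marker-based priority flooding. Touching grains are
   split only where they touch; single grains are never cut apart.
3. **Morphometry** — per grain: PCA-oriented length/width/thickness, voxel
   volume, watertight iso-surface area (marching tetrahedra on a
   PSF-smoothed mask), equivalent diameter (6V/π)^(1/3), convex-hull volume
   and solidity, mean grayscale.
4. **Aggregation** — the 22-trait record (GN, MGL, SGL, MGW, SGW, MGT,
   SGT, MLWR, SLWR, MWTR, SWTR, MED, MS, TGV, MGV, SGV, TGS, MGS, SGS,
   MCHV, SCHV, MGG) written as CSV.

It also ships the benchmark metrics (R², RMSE, MAPE), variety
classification (stepwise discriminant analysis, PSO-tuned RBF-SVM, random
forest) under leave-one-out cross-validation, and a phantom generator that
renders grains-in-holder scenes with analytic ground truth so the whole
pipeline is testable without scanner data.

## Worked example

Generate a 20-grain phantom (five touching pairs, 5% noise, holder
included), run the full pipeline, and compare against the analytic truth:

```r
library(panicleCT)

spec <- panicle_phantom_spec(n_grains = 20, n_touching_pairs = 5, seed = 1)
ph   <- generate_phantom(spec)
res  <- run_pipeline(pipeline_config(), volume = ph$volume,
                     panicle_id = "demo")
#> volume 128 x 128 x 128, spacing 0.3/0.3/0.3 mm
#> holder cleared: edge found in 128/128 slices
#> segmentation: Otsu threshold 13187, merge threshold 3.50 vox, 20 grains
#> traits: GN = 20, TGV = 434.94 mm^3

res$traits[, c("panicle","GN","MGL","MGW","MGT","TGV","TGS","MED","MS","MGG")]
#>  panicle GN   MGL   MGW  MGT     TGV     TGS  MED MS      MGG
#>     demo 20 6.996 3.227 2.22 434.943 888.141 3.46  1 30003.43

head(res$records[, c("label","length","width","thickness","volume",
                     "surface_area","solidity")], 3)
#>  label length width thickness volume surface_area solidity
#>      1  7.484 3.389     2.181 23.058       47.198    0.999
#>      2  6.570 3.205     2.102 19.089       40.665    1.000
#>      3  6.904 3.139     2.250 20.952       43.185    1.000
```

All 20 grains are recovered, including the five touching pairs. The
phantom's analytic truth for this scene is GN = 20, mean grain length
6.907 mm and total volume 435.54 mm³: the pipeline reads 6.996 mm
(+0.3 voxel) and 434.94 mm³ (−0.14%). Solidity is ~1, as it must be for
convex grains, and MGG recovers the rendered grain intensity (30,000).

With real data, point `pipeline_config(input = ...)` at the DICOM
directory instead of passing a volume. A thin command-line front end wraps
the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli","panicle-ct",package="panicleCT"))')
Rscript $CLI phantom  --output demo --grains 20 --pairs 5 --seed 1
Rscript $CLI process  --input demo/dicom --output demo/out
Rscript $CLI evaluate --input pairs.csv
Rscript $CLI classify --input traits.csv --model svm
```

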