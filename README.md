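# drusenmspr

Quantifies longitudinal change in drusen area in age-related macular
degeneration (AMD) from multimodal en face retinal imaging, and scores
its agreement with expert grading.

Drusen — lipid-rich deposits under the retinal pigment epithelium — are
the hallmark lesion of AMD, and growth or regression of their area is a
risk marker for progression to late disease. This package implements
*multispectral pattern recognition* for paired clinic visits: three
co-registered en face channels (fundus autofluorescence 488 nm,
infrared SLO 815 nm, green SLO 532 nm) are clustered per pixel into
spectral *theme classes*, the classes covering expert-annotated drusen
are pooled into a binary drusen mask, and the change in mask area
between visits is classified as progression (> +5%), stable (−5% to
+5%) or regression (< −5%).

The analysis chain per visit is

1. **Registration** — least-squares affine transform from 8 paired
   vessel-bifurcation landmarks onto the reference colour fundus
   photograph grid; bilinear resampling.
2. **Preprocessing** — grayscale normalisation, background correction
   by Gaussian-blur subtraction, 0.4%-saturation contrast stretch,
   circular macular mask.
3. **Clustering** — k-means from k = 16 with deterministic seeding;
   iterative merging of the least-separable class pair until every
   pairwise *transformed divergence*

   D_T = 2 (1 − e^(−D/8)),
   D = ½ tr[(Σa−Σb)(Σb⁻¹−Σa⁻¹)] + ½ tr[(Σa⁻¹+Σb⁻¹)(μa−μb)(μa−μb)ᵀ]

   reaches D_T ≥ 1.5.
4. **Quantification** — theme classes with majority overlap of the
   expert drusen annotation are pooled; drusen area is the pixel count
   of the pooled mask; percent change and category follow.

Evaluation utilities reproduce the comparative statistics used for this
kind of method: 3×3 expert-vs-method confusion matrices, overall
agreement, direction-aware sensitivity, specificity, per-subgroup
agreement, Bland–Altman limits of agreement and Pearson correlation.
Because no imaging dataset is publicly deposited for this workflow, the
package ships a first-class synthetic phantom generator
(`phantom_params()`, `phantom_pair()`, `phantom_cohort()`) producing
paired-visit eyes with exact ground truth, which the test suite and the
acceptance script use for end-to-end validation.

## Worked example

```r
library(drusenmspr)

# a synthetic eye whose drusen grow by 20% between visits
p    <- phantom_params(seed = 42, target_percent_change = 20)
pair <- phantom_pair(p)
pair$truth$true_percent_change
#> [1] 19.95541

cfg <- pipeline_config(image_width = 192,
                       preprocess = preprocess_config(blur_sigma = 61))
res <- analyze_pair(pair$visits[[1]], pair$visits[[2]], cfg)
res
#> Multispectral drusen-change analysis
#>   visit 1: k = 13 classes, 2 drusen, area 1764 px
#>   visit 2: k = 15 classes, 3 drusen, area 2123 px
#>   Drusen change: 1764 -> 2123 px (+20.4%) => progression
```

The analysis registered the three jittered channels, clustered them
into 13-15 spectral theme classes, pooled the 2-3 classes overlapping
the expert-style annotation, and measured +20.4% growth against the
planted +20.0% — within half a percentage point, classified correctly
as progression.

Agreement scoring against expert grading uses the bundled 33-eye
example table:

```r
g  <- read_gradings(system.file("extdata", "example_gradings.csv",
                                package = "drusenmspr"))
confusion_summary(g$expert, g$mspr_cat)
#> Expert vs method confusion (n = 33)
#>              method
#> expert        progression stable regression
#>   progression          11      0          0
#>   stable                3      8          0
#>   regression            0      0         11
#> agreement 90.9% | sensitivity 100.0% | specificity 72.7%
```

## Command line

A thin CLI wraps the same functions:

```sh
drusenmspr simulate --out cohort/ --seed 7 --eyes 11,11,11
drusenmspr register --landmarks lm.csv --image faf.png --out reg/
drusenmspr analyze  --visit1 eye01/visit1 --visit2 eye01/visit2 --out out/
drusenmspr evaluate --gradings gradings.csv --out report.json
```

Exit codes: 0 success, 2 input/validation error, 3 numeric failure.

See the methods vignette (`vignettes/drusen-change-methods.Rmd`) for
the model, its assumptions, parameter rationale, and what phantom-based
validation does and does not demonstrate.
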