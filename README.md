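# otsu2d

Robust two-dimensional Otsu thresholding for grayscale images, with
median-filter hardening against salt-and-pepper noise and an energy-based
splitting line for vertically uneven illumination.

Global thresholding is still the workhorse for binarizing cell, grain and
coin-like images, but the classical methods fail in two common regimes:
impulse (salt-and-pepper) corruption, and illumination gradients strong
enough that foreground in the shadowed region is *darker* than background
in the lit region — where no single threshold can be right. This package
implements a 2D Otsu variant that addresses both, for image-analysis users
who want a scriptable, dependency-light segmenter with built-in evaluation
and synthetic benchmarks.

## The method

**2D histogram.** Each pixel contributes a pair (i, j): its gray level and
a neighbourhood-smoothed gray level. Classical 2D Otsu uses
(I, avg(I)); the robust variant here uses the median image M = med(I) and
the median-average image avg(M), i.e. pairs (M, avg(M)), so isolated
impulses are removed from *both* coordinates before they reach the
histogram p_ij.

**Criterion.** A threshold pair (s, t) defines background
C0 = {i ≤ s, j ≤ t} and foreground C1 = {i > s, j > t} with occurrence
probabilities ω0, ω1 and mean vectors u0, u1. The fitted pair maximises
the trace of the between-class scatter matrix

    tr σ_B(s, t) = ω0 ‖u0 − u_T‖² + ω1 ‖u1 − u_T‖²,

searched exhaustively over all pairs in O(L²) via cumulative-sum tables
(verified in the tests against a naive O(L⁴) evaluator). Off-diagonal
histogram quadrants (edges/noise) are assigned by the smoothed coordinate
by default.

**Splitting line.** For unevenly lit images, a left-to-right 8-connected
path (one row per column) maximises the energy
E = W_position · (ω1 E_color − ω2 E_geometrical), where E_color is the
squared vertical intensity difference, E_geometrical the Sobel gradient
magnitude (a penalty for crossing real structure), and W_position a
Gaussian row weight centred at m/2. The optimum path is found by dynamic
programming and cuts the image into two evenly lit parts.

**Two schemes.** Scheme 1 thresholds the two parts independently; scheme 2
finds one pair maximising the product tr σ_B^p1 · tr σ_B^p2 of the per-part
criteria. With a ground-truth mask the fit selects the scheme with lower
misclassification error (ME); segmentation quality is reported as ME and
the Dice similarity coefficient (DSC).

## Worked example

```r
library(otsu2d)
scene <- synth_preset("uneven", seed = 1)   # contrast-inversion fixture
fit <- otsu2d(scene$image, truth = scene$mask)
fit
#> Robust 2D Otsu segmentation fit
#>   image: 96x96, L = 256, histogram strategy: med_medavg (k = 3)
#>   splitting line: rows 49..49, mean energy 6270.81
#>   split1: thresholds (91,176) (82,94)  [ME 0.0088, DSC 0.9837]
#>   split2: threshold (91,104)  [ME 0.5155, DSC 0.4718]
#>   selected: split1
coef(fit)
#>               s   t  criterion
#> split1.part1 91 176   600.7093
#> split1.part2 82  94   508.1428
#> split2       91 104 74643.3923
```

The splitting line locks onto the illumination boundary (row 49 of 96).
Scheme 1 then thresholds the bright part at (91, 176) and the shadowed
part at (82, 94) — two very different operating points no single pair
could provide — and reaches ME 0.0088 / DSC 0.984 against the ground
truth, while the single-pair scheme 2 (and likewise whole-image 2D Otsu,
ME ≈ 0.71 here) cannot separate both halves at once. `fitted(fit)`
returns the selected 0/1 mask, `plot(fit)` shows the image, line and
masks, and `predict(fit, newimage)` transfers the thresholds.

From a shell:

```sh
Rscript inst/cli/otsu2d.R synth --preset uneven --seed 1 -o data/
Rscript inst/cli/otsu2d.R segment --input data/image.png --gt data/mask.png -o out/
```

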