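# eospec

Spectral-residual localization of eosinophils in multispectral images of
H&E-stained esophagus tissue.

## The problem

Eosinophil infiltration of the esophagus is the histological hallmark of
eosinophilic esophagitis, and counting eosinophils in hematoxylin-and-eosin
(H&E) stained sections is the basis of its assessment. Automating that count
is hard with ordinary color imaging: eosinophils stain pink-to-red with eosin,
almost exactly like red blood cells (RBC) and other connective tissue, so RGB
pixel color cannot separate them. A multispectral microscope, which records a
narrowband transmittance spectrum at every pixel instead of three broadband
color values, can.

`eospec` implements the spectral-residual method for this problem, for image
analysts working with multispectral histopathology:

1. **Transmittance.** Each pixel's N-band spectrum is the ratio of the
   specimen signal to the blank-glass signal, `f = i_s / i_g`, per band.
   55 narrowband measurements (450-720 nm at 5 nm) are averaged in contiguous
   groups of four into 14 working bands.
2. **PCA on everything except the target.** From labeled training spectra of
   the ordinary tissue classes - nucleus, cytoplasm, RBC, fiber, and white
   (tissue-free) areas - but *excluding* eosinophils, compute the sample mean
   `f_bar`, the covariance `C`, and its eigenvectors `v_1, ..., v_n` sorted by
   descending eigenvalue. With 5 tissue classes, the first m = 5 eigenvectors
   explain essentially all (>= 99.99%) of the training variance.
3. **Spectral error.** Reconstruct each pixel from the first m eigenvectors,
   `f_hat = f_bar + sum_i (v_i' (f - f_bar)) v_i`, and take the residual
   `e = f - f_hat`. In-model tissue reconstructs almost perfectly; the
   held-out eosinophils leave a residual with a characteristic signature: a
   negative peak at band 7 (570-585 nm) and a positive peak at band 10
   (630-645 nm), on the flanks of the hematoxylin absorption peak.
4. **Band pair and segmentation.** With `r` the band of the highest positive
   mean residual and `s` the band of the largest-magnitude negative one,
   threshold the per-pixel difference `d = e_r - e_s` (Otsu by default),
   clean the mask with morphological closing and a small-object filter, and
   overlay the outlines on an RGB rendering.

Because no public multispectral H&E data exist, the package ships a
Beer-Lambert phantom generator (`generate_phantom()`,
`generate_training_set()`) that renders ground-truthed synthetic scenes from
Gaussian hematoxylin/eosin absorption curves, and a k-means (k = 6) RGB
clustering baseline (`kmeans_rgb()`) that documents why broadband color fails.
Every stage of the pipeline is validated end-to-end on these phantoms.

## Worked example

```r
library(eospec)

cfg      <- phantom_config()                       # 256x256, 14 bands, defaults
training <- generate_training_set(cfg, seed = 0)   # 600 spectra x 5 classes
basis    <- fit_spectral_pca(training)
basis
#> <spectral_pca> 14 bands, 3000 training samples (cytoplasm: 600, fiber: 600,
#>   nucleus: 600, rbc: 600, white: 600), default m = 5
#>   variance explained by first 5 PCs: 99.9906%

eos  <- generate_training_set(cfg, seed = 1, n_per_class = 300,
                              classes = "eosinophil")
pair <- select_band_pair(mean_class_error(basis, eos), cfg$band_edges)
pair
#> <band_pair> r = band 10 (630-645 nm) [e = +0.07132], s = band 7 (570-585 nm) [e = -0.03971]

scene <- generate_phantom(cfg, seed = 2)
mask  <- segment_cube(scene$cube, basis, pair)     # residuals -> d-map -> Otsu -> closing
evaluate_segmentation(mask, scene$truth)
#> # A tibble: 1 x 7
#>   positive      tp    fp    fn precision recall    f1
#> 1 eosinophil  2040     3     0     0.999      1 0.999

km <- kmeans_rgb(render_rgb(scene$cube), k = 6, seed = 2)
evaluate_clustering(km, scene$truth)
#> # A tibble: 1 x 6
#>   cluster precision recall    f1 confuser confuser_fraction
#> 1       5     0.383      1 0.554 rbc                      1
```

Reading the output: the five in-model classes span the spectral space almost
completely (99.99% in 5 PCs), the held-out eosinophil residual peaks exactly
at the construction bands 7 and 10, and thresholding `d = e10 - e7` recovers
the eosinophil pixels at F1 = 0.999 with 3 false-positive pixels. The RGB
baseline's best-matching cluster reaches only F1 = 0.55 because it absorbs
every RBC pixel (`confuser_fraction = 1`) - the color-ambiguity failure the
spectral method avoids.

`autoplot()` methods exist for the fitted basis (scree/cumulative variance),
the band pair (mean-error curve), residual maps, masks and RGB renderings;
`tidy()`/`glance()` return the eigenvalue table and fit summary as tibbles.

A thin command-line front end for the same pipeline is installed at
`inst/cli/eospec.R` (`simulate`, `train`, `select-bands`, `segment`,
`baseline`).

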