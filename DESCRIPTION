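Package: eospec
Title: Spectral-Residual Localization of Eosinophils in Multispectral H&E Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and segments eosinophils in multispectral images of
    hematoxylin-and-eosin stained esophagus tissue using the reconstruction
    residual of a principal component basis trained on all tissue classes
    except the target class. Provides readers and writers for multi-page TIFF
    spectral cubes with wavelength sidecars, transmittance computation against
    a glass reference, contiguous band averaging, PCA fitting with explained
    variance and per-band spectral error, residual band-pair selection,
    threshold-and-morphology segmentation with RGB overlays, a k-means RGB
    clustering baseline, and a Beer-Lambert phantom generator that produces
    ground-truthed synthetic H&E scenes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    generics,
    ggplot2,
    grDevices,
    png,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    dplyr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
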