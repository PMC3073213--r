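#' H&E dye absorption curves on a band grid
#'
#' Smooth Gaussian parameterizations of the hematoxylin and eosin absorption
#' spectra (optical density per unit concentration, unit peak height), sampled
#' at the band centers: hematoxylin peaks at 600 nm (sd 45 nm), loading the
#' 570-645 nm region, and eosin peaks at 525 nm (sd 40 nm). On the standard
#' 14-band grid the hematoxylin maximum falls in bands 7-10.
#'
#' @param band_edges N x 2 wavelength ranges; default [grid_14band()].
#' @return An object of class `dye_spectra`: list with `hematoxylin`, `eosin`
#'   (length-N absorbance vectors) and `band_edges`.
#' @export
he_dye_spectra <- function(band_edges = grid_14band()) {
  band_edges <- as_band_edges(band_edges)
  lambda <- band_centers(band_edges)
  structure(
    list(
      hematoxylin = gaussian_curve(lambda, 600, 45),
      eosin = gaussian_curve(lambda, 525, 40),
      band_edges = band_edges
    ),
    class = "dye_spectra"
  )
}

#' Tissue class models for the phantom generator
#'
#' Each model carries Beer-Lambert dye loadings (hematoxylin and eosin
#' concentrations), an optional spectral perturbation in absorbance units
#' (zero for every class except the eosinophil), a within-class coefficient of
#' variation, a shape family and size range for scene placement, and a target
#' area fraction. The defaults emulate strongly stained esophagus tissue:
#' hematoxylin-dense nuclei, eosin-stained cytoplasm, fiber and red blood
#' cells, and unstained white (glass) areas.
#'
#' The eosinophil shares the RBC dye loadings; its distinctiveness is a small
#' absorbance perturbation with a positive lobe at 577.5 nm (band 7) and a
#' negative lobe at 637.5 nm (band 10), i.e. slightly stronger absorption
#' around the short flank of the hematoxylin peak and slightly weaker on the
#' long flank. The lobe amplitudes are weighted 2:1 so that, after Beer-Lambert
#' conversion, the transmittance difference against RBC has comparable
#' magnitude at both bands, and its magnitude is set so that broadband RGB
#' renderings of eosinophil and RBC differ by under 5% in the green and blue
#' channels - the color ambiguity that defeats RGB-only segmentation.
#'
#' @param band_edges band grid for the perturbation vector.
#' @param eosinophil_delta perturbation amplitude in absorbance units.
#' @param lobe_sd Gaussian width of each perturbation lobe in nm.
#' @param lobe_ratio amplitude ratio of the 577.5 nm lobe over the 637.5 nm
#'   lobe.
#' @param within_class_cv lognormal coefficient of variation of the per-pixel
#'   brightness factor, applied to every class.
#' @return Named list of tissue class models.
#' @export
tissue_models <- function(band_edges = grid_14band(), eosinophil_delta = 0.05,
                          lobe_sd = 9, lobe_ratio = 2, within_class_cv = 0.02) {
  band_edges <- as_band_edges(band_edges)
  lambda <- band_centers(band_edges)
  zero <- numeric(length(lambda))
  pert <- eosinophil_delta * (
    lobe_ratio * gaussian_curve(lambda, 577.5, lobe_sd) -
      gaussian_curve(lambda, 637.5, lobe_sd)
  )
  model <- function(name, c_h, c_e, perturbation, shape, size_range, area_fraction) {
    list(
      name = name, dye_loadings = c(c_h = c_h, c_e = c_e),
      spectral_perturbation = perturbation, within_class_cv = within_class_cv,
      shape = shape, size_range = size_range, area_fraction = area_fraction
    )
  }
  list(
    nucleus    = model("nucleus", 1.80, 0.10, zero, "ellipse", c(4, 7), 0.08),
    cytoplasm  = model("cytoplasm", 0.18, 0.80, zero, "background", NULL, NA_real_),
    rbc        = model("rbc", 0.05, 1.00, zero, "ellipse", c(3, 5), 0.05),
    fiber      = model("fiber", 0.12, 1.30, zero, "fiber", c(12, 20), 0.08),
    white      = model("white", 0.00, 0.00, zero, "ellipse", c(8, 14), 0.10),
    eosinophil = model("eosinophil", 0.05, 1.00, pert, "ellipse", c(4, 7), 0.03)
  )
}

#' Noise-free endmember transmittance of a tissue class
#'
#' Beer-Lambert conversion of the class's total absorbance:
#' `T = 10^-(c_H * a_H + c_E * a_E + perturbation)`, per band. An unstained
#' class (zero loadings, zero perturbation) transmits 1 everywhere.
#'
#' @param model one element of [tissue_models()].
#' @param dyes a [he_dye_spectra()] object on the same grid.
#' @return Length-N transmittance vector in (0, 1] (up to the perturbation).
#' @export
endmember_transmittance <- function(model, dyes = he_dye_spectra()) {
  stopifnot(inherits(dyes, "dye_spectra"))
  if (any(model$dye_loadings < 0)) {
    abort_parameter("dye loadings must be nonnegative")
  }
  absorbance <- model$dye_loadings[["c_h"]] * dyes$hematoxylin +
    model$dye_loadings[["c_e"]] * dyes$eosin +
    model$spectral_perturbation
  10^(-absorbance)
}

#' Phantom generator configuration
#'
#' Bundles the scene size, band grid, tissue models and sensor noise level.
#' With `bands = 55` the phantom is produced on the 5 nm instrument grid
#' (exercising [band_average()] upstream); the default is the 14-band working
#' grid.
#'
#' @param width,height scene size in pixels (>= 64).
#' @param bands 14 or 55.
#' @param noise_sd standard deviation of the per-pixel, per-band multiplicative
#'   Gaussian sensor noise (default 0.5%).
#' @param models tissue class models; default [tissue_models()] on the chosen
#'   grid.
#' @param ... passed to [tissue_models()] when `models` is not supplied.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(width = 256L, height = 256L, bands = 14L,
                           noise_sd = 0.005, models = NULL, ...) {
  if (width < 64L || height < 64L) abort_parameter("scene must be at least 64 x 64")
  if (!bands %in% c(14L, 55L)) abort_parameter("`bands` must be 14 or 55")
  band_edges <- if (bands == 14L) grid_14band() else grid_55band()
  models <- models %||% tissue_models(band_edges, ...)
  structure(
    list(
      width = as.integer(width), height = as.integer(height),
      band_edges = band_edges, noise_sd = noise_sd, models = models
    ),
    class = "phantom_config"
  )
}

phantom_class_codes <- function(models) {
  stats::setNames(seq_along(models), names(models))
}

draw_shape <- function(model) {
  if (model$shape == "fiber") {
    long <- sample(seq(model$size_range[1L], model$size_range[2L]), 1L)
    short <- sample(2:4, 1L)
    if (stats::runif(1) < 0.5) list(ry = long, rx = short) else list(ry = short, rx = long)
  } else {
    list(
      ry = sample(seq(model$size_range[1L], model$size_range[2L]), 1L),
      rx = sample(seq(model$size_range[1L], model$size_range[2L]), 1L)
    )
  }
}

place_class <- function(labels, code, model, max_tries = 10000L) {
  h <- nrow(labels)
  w <- ncol(labels)
  target <- model$area_fraction * h * w
  tries <- 0L
  while (sum(labels == code) < target && tries < max_tries) {
    tries <- tries + 1L
    sh <- draw_shape(model)
    cy <- sample.int(h, 1L)
    cx <- sample.int(w, 1L)
    ys <- max(1L, cy - sh$ry):min(h, cy + sh$ry)
    xs <- max(1L, cx - sh$rx):min(w, cx + sh$rx)
    inside <- outer(((ys - cy) / sh$ry)^2, ((xs - cx) / sh$rx)^2, `+`) <= 1
    patch <- labels[ys, xs]
    if (any(patch[inside] != 0L)) next
    patch[inside] <- code
    labels[ys, xs] <- patch
  }
  if (sum(labels == code) < 0.9 * target) {
    abort_generation(sprintf(
      "could not place '%s' shapes without overlap (reached %d of %d target pixels)",
      model$name, sum(labels == code), round(target)
    ))
  }
  labels
}

#' Generate a ground-truthed multispectral H&E phantom
#'
#' Places non-overlapping elliptical shapes for each foreground class
#' (white areas, fibers, nuclei, red blood cells, eosinophils) on a cytoplasm
#' background, then renders each pixel as its class endmember times a
#' per-pixel lognormal brightness factor (within-class variation) times
#' multiplicative Gaussian sensor noise. Every pixel has exactly one true
#' class; the scene is deterministic given the seed.
#'
#' @param config a [phantom_config()].
#' @param seed integer RNG seed.
#' @return An object of class `phantom_scene`: `cube` (transmittance
#'   [spectral_cube()]), `truth` ([roi_mask()]), `params` (config plus seed).
#' @export
generate_phantom <- function(config = phantom_config(), seed = 0L) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(seed)
  models <- config$models
  codes <- phantom_class_codes(models)
  h <- config$height
  w <- config$width
  labels <- matrix(0L, h, w)
  # biggest shapes first so placement cannot paint itself into a corner
  for (nm in c("white", "fiber", "nucleus", "rbc", "eosinophil")) {
    labels <- place_class(labels, codes[[nm]], models[[nm]])
  }
  bg <- names(which(vapply(models, function(m) m$shape == "background", logical(1L))))
  labels[labels == 0L] <- codes[[bg]]
  dyes <- he_dye_spectra(config$band_edges)
  endmembers <- vapply(
    models, endmember_transmittance,
    numeric(nrow(config$band_edges)),
    dyes = dyes
  )
  cv_by_code <- vapply(models, function(m) m$within_class_cv, numeric(1L))
  brightness <- exp(stats::rnorm(h * w, 0, cv_by_code[labels]))
  nb <- nrow(config$band_edges)
  px <- array(0, c(h, w, nb))
  for (b in seq_len(nb)) {
    base <- matrix(endmembers[b, labels], h, w)
    px[, , b] <- base * brightness * (1 + stats::rnorm(h * w, 0, config$noise_sd))
  }
  px[px < 0] <- 0
  structure(
    list(
      cube = spectral_cube(px, config$band_edges, kind = "transmittance"),
      truth = roi_mask(labels, stats::setNames(names(codes), codes)),
      params = list(config = config, seed = seed)
    ),
    class = "phantom_scene"
  )
}

#' @export
print.phantom_scene <- function(x, ...) {
  counts <- table(factor(
    x$truth$class_names[as.character(x$truth$labels)],
    levels = x$truth$class_names
  ))
  cat(sprintf(
    "<phantom_scene> %d x %d x %d (seed %d)\n  pixels: %s\n",
    dim(x$cube$pixels)[1L], dim(x$cube$pixels)[2L], dim(x$cube$pixels)[3L],
    x$params$seed,
    paste(sprintf("%s %d", names(counts), counts), collapse = ", ")
  ))
  invisible(x)
}

#' Draw labeled training spectra from the class models
#'
#' Samples `n_per_class` spectra per requested class from the same generative
#' model as [generate_phantom()] (endmember x lognormal brightness x
#' multiplicative noise). The target class is drawn separately for band
#' selection and must not be mixed into an in-model training set, so requesting
#' `"eosinophil"` together with other classes is an error.
#'
#' @param config a [phantom_config()].
#' @param seed integer RNG seed.
#' @param n_per_class samples per class (>= 2).
#' @param classes class names to draw; default the five in-model tissue
#'   classes (nucleus, cytoplasm, rbc, fiber, white).
#' @return A [labeled_spectra()] set.
#' @export
generate_training_set <- function(config = phantom_config(), seed = 0L,
                                  n_per_class = 600L,
                                  classes = c(
                                    "nucleus", "cytoplasm", "rbc",
                                    "fiber", "white"
                                  )) {
  stopifnot(inherits(config, "phantom_config"))
  if (n_per_class < 2L) abort_parameter("`n_per_class` must be at least 2")
  unknown <- setdiff(classes, names(config$models))
  if (length(unknown)) {
    abort_parameter(sprintf("unknown class name(s): %s", paste(unknown, collapse = ", ")))
  }
  if ("eosinophil" %in% classes && length(classes) > 1L) {
    abort_parameter(
      "the held-out eosinophil class must be drawn separately, not mixed into a training set"
    )
  }
  set.seed(seed)
  dyes <- he_dye_spectra(config$band_edges)
  nb <- nrow(config$band_edges)
  blocks <- lapply(classes, function(cl) {
    model <- config$models[[cl]]
    endmember <- endmember_transmittance(model, dyes)
    brightness <- exp(stats::rnorm(n_per_class, 0, model$within_class_cv))
    m <- outer(endmember, brightness)
    m * (1 + matrix(stats::rnorm(nb * n_per_class, 0, config$noise_sd), nb, n_per_class))
  })
  labeled_spectra(
    do.call(cbind, blocks),
    rep(classes, each = n_per_class),
    config$band_edges
  )
}
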