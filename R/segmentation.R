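#' Per-pixel spectral residuals and the d-map
#'
#' Computes the spectral error of every pixel against the fitted basis, then
#' the scalar difference map `d = e_r - e_s` between the two selected residual
#' bands. Pixels of the held-out class sit high in `d`; in-model tissue sits
#' near zero.
#'
#' @param cube a transmittance [spectral_cube()] on the basis's band grid.
#' @param basis a [fit_spectral_pca()] result.
#' @param pair a [select_band_pair()] result.
#' @param m number of eigenvectors (default: the basis default).
#' @return An object of class `residual_map` with elements `errors`
#'   (H x W x N), `dmap` (H x W), `band_pair`, `m_used`, `band_edges`.
#' @export
residual_map <- function(cube, basis, pair, m = basis$m) {
  stopifnot(
    inherits(cube, "spectral_cube"), inherits(basis, "spectral_pca"),
    inherits(pair, "band_pair")
  )
  d <- dim(cube$pixels)
  if (d[3L] != length(basis$mean)) {
    abort_dimension(sprintf(
      "cube has %d bands but the basis has %d", d[3L], length(basis$mean)
    ))
  }
  flat <- t(matrix(cube$pixels, d[1L] * d[2L], d[3L])) # n x (H*W)
  err <- spectral_error(basis, flat, m)
  errors <- array(t(err), d)
  dmap <- errors[, , pair$r] - errors[, , pair$s]
  structure(
    list(
      errors = errors, dmap = dmap, band_pair = pair,
      m_used = as.integer(m), band_edges = cube$band_edges
    ),
    class = "residual_map"
  )
}

#' @export
print.residual_map <- function(x, ...) {
  cat(sprintf(
    "<residual_map> %d x %d x %d, d = e[band %d] - e[band %d], m = %d\n",
    dim(x$errors)[1L], dim(x$errors)[2L], dim(x$errors)[3L],
    x$band_pair$r, x$band_pair$s, x$m_used
  ))
  invisible(x)
}

#' Grey-level rendering of one residual band
#'
#' Min-max scales the error plane of one band to [0, 255] for visualization.
#' On the held-out class the plane at band `s` renders its pixels as the
#' darkest spots and the plane at band `r` as the brightest. A constant plane
#' maps to mid-grey.
#'
#' @param residual a [residual_map()].
#' @param band band index (1-based).
#' @return H x W numeric matrix of rounded grey levels in 0..255.
#' @export
grey_error_image <- function(residual, band) {
  stopifnot(inherits(residual, "residual_map"))
  nb <- dim(residual$errors)[3L]
  if (band < 1L || band > nb) {
    abort_parameter(sprintf("`band` must be between 1 and %d", nb))
  }
  plane <- residual$errors[, , band]
  rng <- range(plane)
  if (rng[1L] == rng[2L]) {
    return(matrix(128, nrow(plane), ncol(plane)))
  }
  round((plane - rng[1L]) / (rng[2L] - rng[1L]) * 255)
}

new_segmentation_mask <- function(binary, threshold_used, morphology = "none") {
  structure(
    list(binary = binary, threshold_used = threshold_used, morphology = morphology),
    class = "segmentation_mask"
  )
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf(
    "<segmentation_mask> %d x %d, %d foreground px, threshold %.5g, morphology: %s\n",
    nrow(x$binary), ncol(x$binary), sum(x$binary), x$threshold_used, x$morphology
  ))
  invisible(x)
}

#' Threshold the d-map into a binary mask
#'
#' Keeps pixels with `d >= T`. With `method = "otsu"` the threshold is chosen
#' by Otsu's criterion on a 256-bin histogram of the d-map (computed on the
#' min-max normalized map and mapped back to d units). A constant d-map cannot
#' be thresholded: an all-false mask is returned with a warning.
#'
#' @param residual a [residual_map()] (or a plain numeric matrix d-map).
#' @param method `"otsu"` or `"fixed"`.
#' @param t threshold value, required for `method = "fixed"`.
#' @return A `segmentation_mask` with the applied threshold recorded.
#' @export
threshold_dmap <- function(residual, method = c("otsu", "fixed"), t = NULL) {
  method <- match.arg(method)
  dmap <- if (inherits(residual, "residual_map")) residual$dmap else residual
  if (anyNA(dmap) || any(!is.finite(dmap))) abort_data("d-map contains non-finite values")
  if (method == "fixed") {
    if (is.null(t)) abort_parameter("`t` is required for method = 'fixed'")
    return(new_segmentation_mask(dmap >= t, t))
  }
  rng <- range(dmap)
  if (rng[1L] == rng[2L]) {
    warning("constant d-map: Otsu threshold undefined, returning empty mask")
    return(new_segmentation_mask(
      matrix(FALSE, nrow(dmap), ncol(dmap)), NA_real_
    ))
  }
  norm <- (dmap - rng[1L]) / (rng[2L] - rng[1L])
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1), levels = 256L)
  t <- rng[1L] + th * (rng[2L] - rng[1L])
  new_segmentation_mask(dmap >= t, t)
}

#' Morphological cleanup of a binary mask
#'
#' Morphological closing (dilation then erosion with a disk structuring
#' element) followed by removal of connected components smaller than
#' `min_size` pixels. Closing fills small holes and smooths boundaries; the
#' size filter drops isolated noise detections. The operation is idempotent.
#'
#' @param mask a `segmentation_mask` (or logical matrix).
#' @param radius disk radius of the structuring element; `0` skips closing.
#' @param min_size minimum component area in pixels kept (4-connectivity).
#' @return A cleaned `segmentation_mask`.
#' @export
morph_cleanup <- function(mask, radius = 1L, min_size = 20L) {
  binary <- if (inherits(mask, "segmentation_mask")) mask$binary else mask
  threshold <- if (inherits(mask, "segmentation_mask")) mask$threshold_used else NA_real_
  if (radius < 0) abort_parameter("`radius` must be >= 0")
  out <- binary
  if (radius > 0 && any(out)) {
    brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
    out <- EBImage::imageData(
      EBImage::closing(EBImage::Image(out * 1), brush)
    ) > 0.5
  }
  if (min_size > 0 && any(out)) {
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(out * 1)))
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_size)
    out <- matrix(lab %in% keep, nrow(out), ncol(out))
  }
  new_segmentation_mask(
    out, threshold,
    sprintf("closing(disk r=%d) + min_size=%d", as.integer(radius), as.integer(min_size))
  )
}

mask_outline <- function(binary) {
  # mask pixels with at least one 8-neighbor that is background or outside
  h <- nrow(binary)
  w <- ncol(binary)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- binary
  interior <- matrix(TRUE, h, w)
  for (di in -1:1) {
    for (dj in -1:1) {
      if (di == 0L && dj == 0L) next
      interior <- interior & pad[(2:(h + 1L)) + di, (2:(w + 1L)) + dj]
    }
  }
  binary & !interior
}

#' Overlay mask boundaries on an RGB image
#'
#' Paints the 8-connected outline of the binary mask (mask pixels adjacent to
#' background or to the image border) in a fixed color on a copy of the RGB
#' rendering. The outline is parameter-free and deterministic.
#'
#' @param mask a `segmentation_mask` (or logical matrix).
#' @param rgb_image H x W x 3 array in [0, 1] (or an `rgb_rendering`).
#' @param color length-3 RGB color of the outline, default green.
#' @return H x W x 3 array with the outline painted.
#' @export
overlay_boundaries <- function(mask, rgb_image, color = c(0, 1, 0)) {
  binary <- if (inherits(mask, "segmentation_mask")) mask$binary else mask
  if (inherits(rgb_image, "rgb_rendering")) rgb_image <- rgb_image$image
  if (length(dim(rgb_image)) != 3L || dim(rgb_image)[3L] != 3L ||
    !all(dim(rgb_image)[1:2] == dim(binary))) {
    abort_dimension("rgb_image must be H x W x 3 and match the mask")
  }
  outline <- mask_outline(binary)
  out <- rgb_image
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[outline] <- color[ch]
    out[, , ch] <- plane
  }
  out
}

#' End-to-end segmentation of a cube
#'
#' Convenience wrapper chaining [residual_map()], [threshold_dmap()] and
#' [morph_cleanup()] with the package defaults.
#'
#' @inheritParams residual_map
#' @param method threshold method, see [threshold_dmap()].
#' @param t fixed threshold (when `method = "fixed"`).
#' @param radius,min_size morphology parameters, see [morph_cleanup()].
#' @return A `segmentation_mask`; the residual map is attached as attribute
#'   `"residual_map"`.
#' @export
segment_cube <- function(cube, basis, pair, m = basis$m,
                         method = c("otsu", "fixed"), t = NULL,
                         radius = 1L, min_size = 20L) {
  rmap <- residual_map(cube, basis, pair, m)
  mask <- threshold_dmap(rmap, method = method, t = t)
  mask <- morph_cleanup(mask, radius = radius, min_size = min_size)
  attr(mask, "residual_map") <- rmap
  mask
}

#' Pixelwise segmentation metrics against a ground-truth mask
#'
#' @param mask a `segmentation_mask` (or logical matrix).
#' @param truth a [roi_mask()] ground truth, or a logical matrix of
#'   positive-class pixels.
#' @param positive class name treated as positive when `truth` is a
#'   `roi_mask`.
#' @return One-row tibble with tp/fp/fn counts, precision, recall and F1.
#' @export
evaluate_segmentation <- function(mask, truth, positive = "eosinophil") {
  pred <- if (inherits(mask, "segmentation_mask")) mask$binary else mask
  if (inherits(truth, "roi_mask")) {
    code <- mask_label_of(truth, positive)
    if (is.na(code)) abort_parameter(sprintf("class '%s' not in truth mask", positive))
    truth <- truth$labels == code
  }
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  tibble::tibble(
    positive = positive,
    tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  )
}

#' Fraction of each true class captured by a mask
#'
#' Reports, per ground-truth class, how many of its pixels fall inside the
#' segmentation mask. Used e.g. to verify that red blood cells are not picked
#' up by the eosinophil segmentation.
#'
#' @inheritParams evaluate_segmentation
#' @return Tibble with class, pixel count, captured count, and fraction.
#' @export
class_capture <- function(mask, truth) {
  pred <- if (inherits(mask, "segmentation_mask")) mask$binary else mask
  stopifnot(inherits(truth, "roi_mask"))
  codes <- sort(unique(truth$labels[truth$labels != 0L]))
  rows <- lapply(codes, function(code) {
    sel <- truth$labels == code
    tibble::tibble(
      class = unname(truth$class_names[as.character(code)]),
      n_pixels = sum(sel),
      n_captured = sum(pred & sel),
      fraction = sum(pred & sel) / sum(sel)
    )
  })
  do.call(rbind, rows)
}
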