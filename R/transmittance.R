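#' Convert raw signals to spectral transmittance
#'
#' The transmittance of a pixel at each band is the ratio between the specimen
#' signal and the glass (blank) signal at that band. The reference is floored
#' at `1e-6 * max(reference)` before division, since the ratio is undefined at
#' zero glass signal. Values above 1 occur where noise pushes blank areas above
#' the reference; they are kept by default because clipping silently biases
#' downstream PCA. Set `clip = TRUE` to clamp to [0, 1.05].
#'
#' @param specimen a raw [spectral_cube()].
#' @param reference the glass signal: either a length-N positive vector (one
#'   value per band) or a raw `spectral_cube` of the same dimensions.
#' @param clip clamp output to [0, 1.05]? Default `FALSE`.
#' @return A transmittance `spectral_cube` with the specimen's band edges.
#' @export
compute_transmittance <- function(specimen, reference, clip = FALSE) {
  stopifnot(inherits(specimen, "spectral_cube"))
  d <- dim(specimen$pixels)
  if (inherits(reference, "spectral_cube")) reference <- reference$pixels
  if (is.array(reference) && length(dim(reference)) == 3L) {
    if (!all(dim(reference) == d)) {
      abort_dimension("reference cube dimensions do not match the specimen")
    }
    ref <- pmax(reference, 1e-6 * max(reference))
    tr <- specimen$pixels / ref
  } else {
    reference <- as.numeric(reference)
    if (length(reference) != d[3L]) {
      abort_dimension(sprintf(
        "reference has %d bands but specimen has %d", length(reference), d[3L]
      ))
    }
    ref <- pmax(reference, 1e-6 * max(reference))
    tr <- specimen$pixels / rep(ref, each = d[1L] * d[2L])
  }
  if (clip) tr <- pmin(pmax(tr, 0), 1.05)
  spectral_cube(tr, specimen$band_edges, kind = "transmittance")
}

#' Average contiguous spectral bands
#'
#' Reduces the band count by averaging `group_size` contiguous bands, grouping
#' sequentially from band 1. A final partial group is averaged over its actual
#' members; with the 55-band instrument grid and `group_size = 4` the last
#' output band averages the remaining three samples. The output wavelength
#' range of a group spans from the first member's lambda_lo to the last
#' member's lambda_hi, which reproduces the standard 14-band table (450-465,
#' 470-485, ..., 710-720 nm).
#'
#' @param cube a [spectral_cube()].
#' @param group_size number of contiguous input bands per output band (>= 1).
#' @return A `spectral_cube` with `ceiling(N / group_size)` bands.
#' @export
band_average <- function(cube, group_size) {
  stopifnot(inherits(cube, "spectral_cube"))
  group_size <- as.integer(group_size)
  n <- n_bands(cube)
  if (is.na(group_size) || group_size < 1L) {
    abort_parameter("`group_size` must be a positive integer")
  }
  if (group_size > n) {
    abort_parameter(sprintf(
      "`group_size` (%d) exceeds the number of bands (%d)", group_size, n
    ))
  }
  groups <- split(seq_len(n), ceiling(seq_len(n) / group_size))
  d <- dim(cube$pixels)
  out <- array(0, c(d[1L], d[2L], length(groups)))
  edges <- matrix(0, length(groups), 2L)
  for (k in seq_along(groups)) {
    idx <- groups[[k]]
    out[, , k] <- rowMeans(cube$pixels[, , idx, drop = FALSE], dims = 2L)
    edges[k, ] <- c(cube$band_edges[idx[1L], 1L], cube$band_edges[idx[length(idx)], 2L])
  }
  spectral_cube(out, edges, kind = cube$kind)
}

#' Labeled training spectra
#'
#' A `labeled_spectra` object holds an n x q matrix of q sample spectra
#' (columns) over n bands, one class label per column, and the band grid.
#'
#' @param spectra n x q numeric matrix, columns are samples.
#' @param labels character vector of length q.
#' @param band_edges N x 2 wavelength ranges (N == n).
#' @return An object of class `labeled_spectra`.
#' @export
labeled_spectra <- function(spectra, labels, band_edges) {
  spectra <- as.matrix(spectra)
  if (ncol(spectra) < 1L) abort_data("at least one sample spectrum is required")
  if (anyNA(spectra) || any(!is.finite(spectra))) {
    abort_data("spectra contain non-finite values")
  }
  labels <- as.character(labels)
  if (length(labels) != ncol(spectra)) {
    abort_dimension("one label per sample column is required")
  }
  band_edges <- as_band_edges(band_edges)
  if (nrow(band_edges) != nrow(spectra)) {
    abort_dimension("band_edges row count must equal the number of bands")
  }
  structure(
    list(spectra = spectra, labels = labels, band_edges = band_edges),
    class = "labeled_spectra"
  )
}

#' @export
print.labeled_spectra <- function(x, ...) {
  counts <- table(x$labels)
  cat(sprintf(
    "<labeled_spectra> %d bands x %d samples (%s)\n",
    nrow(x$spectra), ncol(x$spectra),
    paste(sprintf("%s: %d", names(counts), counts), collapse = ", ")
  ))
  invisible(x)
}

#' @method as_tibble labeled_spectra
#' @export
as_tibble.labeled_spectra <- function(x, ...) {
  tibble::tibble(
    sample = rep(seq_len(ncol(x$spectra)), each = nrow(x$spectra)),
    class = rep(x$labels, each = nrow(x$spectra)),
    band = rep(seq_len(nrow(x$spectra)), ncol(x$spectra)),
    lambda_lo = rep(x$band_edges[, 1L], ncol(x$spectra)),
    lambda_hi = rep(x$band_edges[, 2L], ncol(x$spectra)),
    value = as.vector(x$spectra)
  )
}

#' Extract labeled pixel spectra from a cube
#'
#' Collects the spectrum of every pixel carrying one of the requested class
#' labels. Pixels are scanned in row-major order (across columns within each
#' row) so training matrices are reproducible.
#'
#' @param cube a transmittance [spectral_cube()].
#' @param mask a [roi_mask()] with the same spatial dimensions.
#' @param classes class names to extract (must appear in the mask's
#'   `class_names`). A class with no labeled pixels yields a warning and zero
#'   samples; an error is raised only if all requested classes are empty.
#' @return A [labeled_spectra()] with one column per labeled pixel.
#' @export
extract_labeled_spectra <- function(cube, mask, classes) {
  stopifnot(inherits(cube, "spectral_cube"), inherits(mask, "roi_mask"))
  d <- dim(cube$pixels)
  if (!all(dim(mask$labels) == d[1:2])) {
    abort_dimension("mask dimensions do not match the cube")
  }
  unknown <- setdiff(classes, mask$class_names)
  if (length(unknown)) {
    abort_parameter(sprintf(
      "classes not present in mask: %s", paste(unknown, collapse = ", ")
    ))
  }
  flat <- matrix(cube$pixels, d[1L] * d[2L], d[3L]) # column-major pixel index
  # row-major scan order: row varies slowest
  rm_order <- order(row(mask$labels), col(mask$labels))
  cols <- list()
  labs <- character(0)
  for (cl in classes) {
    code <- mask_label_of(mask, cl)
    sel <- rm_order[mask$labels[rm_order] == code]
    if (!length(sel)) {
      warning(sprintf("class '%s' has no labeled pixels", cl))
      next
    }
    cols[[cl]] <- t(flat[sel, , drop = FALSE])
    labs <- c(labs, rep(cl, length(sel)))
  }
  if (!length(labs)) abort_data("all requested classes are empty")
  labeled_spectra(do.call(cbind, cols), labs, cube$band_edges)
}
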