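#' Multispectral image cube
#'
#' A `spectral_cube` holds an H x W x N stack of band images together with the
#' wavelength interval of each band. `kind` records whether the values are raw
#' camera counts or unitless transmittance (specimen signal divided by the
#' glass reference). Transmittance values may slightly exceed 1 where sensor
#' noise pushes blank areas above the reference; they are deliberately not
#' clipped (see [compute_transmittance()]).
#'
#' @param pixels numeric H x W x N array (an H x W matrix is promoted to a
#'   single-band cube). Values must be finite and non-negative.
#' @param band_edges N x 2 numeric matrix of (lambda_lo, lambda_hi) in nm, one
#'   row per band, sorted ascending and non-overlapping. Point-sampled grids
#'   (lambda_lo == lambda_hi) are allowed; that is how 5 nm instrument
#'   wavelength samples are represented before band averaging.
#' @param kind `"raw"` or `"transmittance"`.
#'
#' @return An object of class `spectral_cube`.
#' @seealso [read_cube()], [compute_transmittance()], [band_average()]
#' @export
spectral_cube <- function(pixels, band_edges, kind = c("raw", "transmittance")) {
  kind <- match.arg(kind)
  if (is.matrix(pixels)) {
    pixels <- array(pixels, c(dim(pixels), 1L))
  }
  if (!is.array(pixels) || length(dim(pixels)) != 3L) {
    abort_format("`pixels` must be an H x W x N array")
  }
  band_edges <- as_band_edges(band_edges)
  if (nrow(band_edges) != dim(pixels)[3L]) {
    abort_format(sprintf(
      "band count mismatch: %d image planes but %d wavelength ranges",
      dim(pixels)[3L], nrow(band_edges)
    ))
  }
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    abort_data("cube contains non-finite pixel values")
  }
  if (any(pixels < 0)) {
    abort_data("cube contains negative pixel values")
  }
  structure(
    list(pixels = pixels, band_edges = band_edges, kind = kind),
    class = "spectral_cube"
  )
}

as_band_edges <- function(band_edges) {
  if (is.list(band_edges)) {
    band_edges <- do.call(rbind, lapply(band_edges, as.numeric))
  }
  if (is.vector(band_edges)) band_edges <- matrix(band_edges, ncol = 2L)
  band_edges <- as.matrix(band_edges)
  if (ncol(band_edges) != 2L || anyNA(band_edges)) {
    abort_format("`band_edges` must be an N x 2 numeric matrix of (lo, hi) nm")
  }
  storage.mode(band_edges) <- "double"
  dimnames(band_edges) <- list(NULL, c("lambda_lo", "lambda_hi"))
  if (any(band_edges[, 1L] > band_edges[, 2L])) {
    abort_format("each band must satisfy lambda_lo <= lambda_hi")
  }
  if (nrow(band_edges) > 1L) {
    if (any(diff(band_edges[, 1L]) <= 0)) {
      abort_format("bands must be sorted ascending by lambda_lo")
    }
    if (any(band_edges[-nrow(band_edges), 2L] > band_edges[-1L, 1L])) {
      abort_format("band wavelength ranges must not overlap")
    }
  }
  band_edges
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<spectral_cube> %d x %d pixels, %d bands (%g-%g nm), kind: %s\n",
    d[1L], d[2L], d[3L], x$band_edges[1L, 1L], x$band_edges[d[3L], 2L], x$kind
  ))
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) dim(x$pixels)

n_bands <- function(cube) dim(cube$pixels)[3L]

#' Band centers of a wavelength grid
#'
#' @param band_edges N x 2 matrix of wavelength ranges, or a `spectral_cube`.
#' @return Numeric vector of interval midpoints in nm.
#' @export
band_centers <- function(band_edges) {
  if (inherits(band_edges, "spectral_cube")) band_edges <- band_edges$band_edges
  rowMeans(as_band_edges(band_edges))
}

#' Standard wavelength grids
#'
#' `grid_55band()` is the instrument sampling grid: 55 measurements at 5 nm
#' spacing from 450 to 720 nm, represented as point samples
#' (lambda_lo == lambda_hi). `grid_14band()` is the reduced working grid
#' obtained by averaging the 55 bands in contiguous groups of four (the last
#' group keeps the remaining three): band 1 spans 450-465 nm, band 7 570-585
#' nm, band 10 630-645 nm and band 14 710-720 nm.
#'
#' @return N x 2 numeric matrix of wavelength ranges in nm.
#' @export
grid_55band <- function() {
  lambda <- seq(450, 720, by = 5)
  cbind(lambda_lo = lambda, lambda_hi = lambda)
}

#' @rdname grid_55band
#' @export
grid_14band <- function() {
  lo <- seq(450, 710, by = 20)
  hi <- c(seq(465, 705, by = 20), 720)
  cbind(lambda_lo = lo, lambda_hi = hi)
}

#' Labeled region-of-interest mask
#'
#' Pairs an H x W integer label image with a mapping from label codes to class
#' names. Label 0 conventionally means unlabeled/background and needs no entry
#' in `class_names`.
#'
#' @param labels H x W integer matrix.
#' @param class_names named character vector mapping label codes (names) to
#'   class names (values), e.g. `c("1" = "nucleus", "2" = "cytoplasm")`.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(labels, class_names) {
  if (!is.matrix(labels)) abort_format("`labels` must be an H x W matrix")
  storage.mode(labels) <- "integer"
  codes <- sort(unique(labels[labels != 0L]))
  known <- suppressWarnings(as.integer(names(class_names)))
  if (anyNA(known)) abort_format("names of `class_names` must be label codes")
  missing <- setdiff(codes, known)
  if (length(missing)) {
    abort_format(sprintf(
      "labels present in mask but absent from class_names: %s",
      paste(missing, collapse = ", ")
    ))
  }
  structure(
    list(labels = labels, class_names = class_names),
    class = "roi_mask"
  )
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf(
    "<roi_mask> %d x %d, classes: %s\n",
    nrow(x$labels), ncol(x$labels),
    paste(x$class_names, collapse = ", ")
  ))
  invisible(x)
}

mask_label_of <- function(mask, class) {
  hit <- names(mask$class_names)[mask$class_names == class]
  if (!length(hit)) return(NA_integer_)
  as.integer(hit[1L])
}
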