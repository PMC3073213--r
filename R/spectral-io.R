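#' Read and write wavelength sidecar files
#'
#' A sidecar is a plain-text file with one wavelength range per TIFF page, in
#' page order: either "lo_nm hi_nm" or a single wavelength for point-sampled
#' grids. Comment lines starting with `#` are ignored, except for an optional
#' header of the form `# kind <raw|transmittance> scale <s>` written by
#' [write_cube()] for floating-point cubes.
#'
#' @param path sidecar file path.
#' @return `read_wavelength_sidecar()` returns a list with `band_edges`,
#'   `kind`, and `scale`.
#' @export
read_wavelength_sidecar <- function(path) {
  lines <- readLines(path)
  kind <- "raw"
  scale <- 1
  format <- "u16"
  header <- grep("^#", lines, value = TRUE)
  for (h in header) {
    toks <- strsplit(trimws(sub("^#", "", h)), "\\s+")[[1L]]
    if (length(toks) >= 2L && toks[1L] == "kind") kind <- toks[2L]
    i <- match("scale", toks)
    if (!is.na(i) && length(toks) > i) scale <- as.numeric(toks[i + 1L])
    i <- match("format", toks)
    if (!is.na(i) && length(toks) > i) format <- toks[i + 1L]
  }
  lines <- trimws(grep("^#", lines, value = TRUE, invert = TRUE))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort_format("sidecar lists no wavelength ranges")
  rows <- lapply(lines, function(l) {
    v <- suppressWarnings(as.numeric(strsplit(l, "[,;[:space:]]+")[[1L]]))
    if (anyNA(v) || !length(v) %in% 1:2) {
      abort_format(sprintf("cannot parse sidecar line: '%s'", l))
    }
    if (length(v) == 1L) c(v, v) else v
  })
  list(
    band_edges = as_band_edges(do.call(rbind, rows)),
    kind = kind, scale = scale, format = format
  )
}

#' @rdname read_wavelength_sidecar
#' @param band_edges N x 2 matrix of wavelength ranges.
#' @param kind cube kind recorded in the header.
#' @param scale value scale recorded in the header (floating-point cubes).
#' @param format TIFF sample format recorded in the header: `"u16"` (16-bit
#'   unsigned integer) or `"f32"` (32-bit float).
#' @export
write_wavelength_sidecar <- function(path, band_edges, kind = "raw", scale = 1,
                                     format = "u16") {
  band_edges <- as_band_edges(band_edges)
  lines <- sprintf("%.10g %.10g", band_edges[, 1L], band_edges[, 2L])
  if (kind != "raw" || scale != 1 || format != "u16") {
    lines <- c(sprintf("# kind %s scale %.10g format %s", kind, scale, format), lines)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a multispectral cube from a multi-page TIFF
#'
#' One TIFF page per band; the sidecar lists the wavelength range of each page
#' in the same order. 16-bit pages are read as integer counts without
#' rescaling. Floating-point pages written by [write_cube()] are rescaled by
#' the scale factor recorded in the sidecar header.
#'
#' @param path multi-page TIFF file.
#' @param sidecar_path wavelength sidecar (default: `path` + ".wl").
#' @return A [spectral_cube()].
#' @export
read_cube <- function(path, sidecar_path = paste0(path, ".wl")) {
  side <- read_wavelength_sidecar(sidecar_path)
  # u16 pages are read as raw integer counts; f32 pages as floats in [0, 1]
  pages <- tiff::readTIFF(path, all = TRUE, as.is = side$format == "u16")
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != nrow(side$band_edges)) {
    abort_format(sprintf(
      "TIFF has %d pages but sidecar lists %d wavelength ranges",
      length(pages), nrow(side$band_edges)
    ))
  }
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L])) {
    abort_format("TIFF pages have non-uniform dimensions")
  }
  px <- array(0, c(dims[1L, 1L], dims[2L, 1L], length(pages)))
  for (b in seq_along(pages)) px[, , b] <- pages[[b]] * side$scale
  spectral_cube(px, side$band_edges, kind = side$kind)
}

#' Write a multispectral cube to a multi-page TIFF
#'
#' Raw cubes with integer values in 0..65535 are written as 16-bit unsigned
#' pages (bit-exact round trip). Other cubes are written as 32-bit float pages;
#' because float TIFF storage is only defined on [0, 1], values are divided by
#' a power-of-two scale (recorded in the sidecar header) before writing and
#' multiplied back by [read_cube()].
#'
#' @param cube a [spectral_cube()].
#' @param path output TIFF file.
#' @param sidecar_path output sidecar path (default: `path` + ".wl").
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, sidecar_path = paste0(path, ".wl")) {
  stopifnot(inherits(cube, "spectral_cube"))
  px <- cube$pixels
  is_u16 <- cube$kind == "raw" && all(px == round(px)) && max(px) <= 65535
  if (is_u16) {
    pages <- lapply(seq_len(n_bands(cube)), function(b) px[, , b] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    write_wavelength_sidecar(sidecar_path, cube$band_edges, kind = cube$kind)
  } else {
    scale <- max(1, 2^ceiling(log2(max(px, 1e-12))))
    pages <- lapply(seq_len(n_bands(cube)), function(b) px[, , b] / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    write_wavelength_sidecar(sidecar_path, cube$band_edges,
      kind = cube$kind, scale = scale, format = "f32"
    )
  }
  invisible(path)
}

#' Read and write label masks as PNG
#'
#' Label images are stored as 8-bit grayscale PNG with the label code as the
#' pixel value (up to 255 classes). Class names are not stored in the PNG; pass
#' them when reading.
#'
#' @param path PNG file path.
#' @param class_names named character vector mapping label codes to class
#'   names (see [roi_mask()]).
#' @return `read_label_mask()` returns a [roi_mask()].
#' @export
read_label_mask <- function(path, class_names) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  roi_mask(matrix(as.integer(round(img * 255)), nrow(img), ncol(img)), class_names)
}

#' @rdname read_label_mask
#' @param mask a [roi_mask()] (or plain integer matrix) to write.
#' @export
write_label_mask <- function(mask, path) {
  labels <- if (inherits(mask, "roi_mask")) mask$labels else mask
  if (max(labels) > 255L) abort_parameter("more than 255 label codes")
  png::writePNG(labels / 255, path)
  invisible(path)
}
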