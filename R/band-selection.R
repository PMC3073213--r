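#' Mean spectral error of a held-out class
#'
#' Arithmetic mean, over all target samples, of the per-band spectral error at
#' `m` eigenvectors. For the class excluded from the PCA fit this curve shows a
#' distinct positive and negative peak; for in-model classes it is almost zero.
#'
#' @param basis a [fit_spectral_pca()] result.
#' @param target a [labeled_spectra()] set of held-out class samples.
#' @param m number of eigenvectors (default: the basis default).
#' @return Length-n numeric vector of mean per-band errors.
#' @export
mean_class_error <- function(basis, target, m = basis$m) {
  stopifnot(inherits(basis, "spectral_pca"), inherits(target, "labeled_spectra"))
  if (ncol(target$spectra) == 0L) abort_data("target spectrum set is empty")
  err <- spectral_error(basis, target$spectra, m)
  rowMeans(err)
}

new_band_pair <- function(r, s, mean_error, band_edges = NULL) {
  structure(
    list(r = r, s = s, mean_error = mean_error, band_edges = band_edges),
    class = "band_pair"
  )
}

#' Select the residual band pair (r, s)
#'
#' From the mean spectral error of the held-out class, picks band `r` where the
#' error has its highest positive peak and band `s` where the negative error
#' has the largest magnitude. Peaks are the global extrema of the curve; ties
#' are broken toward the lowest band index. The segmentation statistic is then
#' `d = e_r - e_s`, large for pixels of the held-out class.
#'
#' @param mean_error length-n vector from [mean_class_error()].
#' @param band_edges optional wavelength ranges attached for reporting.
#' @return An object of class `band_pair` with 1-based indices `r` and `s`.
#' @export
select_band_pair <- function(mean_error, band_edges = NULL) {
  mean_error <- as.numeric(mean_error)
  if (anyNA(mean_error)) abort_data("mean error contains missing values")
  if (!any(mean_error > 0) || !any(mean_error < 0)) {
    abort_selection(paste0(
      "mean error has no sign change (all non-negative or all non-positive); ",
      "the residual band-pair method is inapplicable to this class"
    ))
  }
  r <- which.max(mean_error) # ties -> lowest index
  s <- which.min(mean_error)
  new_band_pair(r, s, mean_error, if (!is.null(band_edges)) as_band_edges(band_edges))
}

#' @export
print.band_pair <- function(x, ...) {
  fmt <- function(b) {
    if (is.null(x$band_edges)) {
      sprintf("band %d", b)
    } else {
      sprintf("band %d (%g-%g nm)", b, x$band_edges[b, 1L], x$band_edges[b, 2L])
    }
  }
  cat(sprintf(
    "<band_pair> r = %s [e = %+.4g], s = %s [e = %+.4g]\n",
    fmt(x$r), x$mean_error[x$r], fmt(x$s), x$mean_error[x$s]
  ))
  invisible(x)
}

#' Tabulate a mean-error curve
#'
#' @param x a `band_pair` or a plain mean-error vector.
#' @param band_edges wavelength ranges (required when `x` is a vector and
#'   carries none).
#' @return A tibble with band number (1-based), wavelength range, mean error,
#'   and the role of the band in the selected pair (`"r"`, `"s"`, or `NA`).
#' @export
band_error_table <- function(x, band_edges = NULL) {
  if (inherits(x, "band_pair")) {
    me <- x$mean_error
    band_edges <- band_edges %||% x$band_edges
    role <- rep(NA_character_, length(me))
    role[x$r] <- "r"
    role[x$s] <- "s"
  } else {
    me <- as.numeric(x)
    role <- rep(NA_character_, length(me))
  }
  if (is.null(band_edges)) {
    band_edges <- matrix(NA_real_, length(me), 2L)
  } else {
    band_edges <- as_band_edges(band_edges)
  }
  tibble::tibble(
    band = seq_along(me),
    lambda_lo = band_edges[, 1L],
    lambda_hi = band_edges[, 2L],
    mean_error = me,
    role = role
  )
}
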