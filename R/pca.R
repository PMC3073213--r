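#' Fit a principal component basis on in-model tissue spectra
#'
#' Computes the sample mean and covariance (1/(q-1) normalization) of the
#' training spectra after dropping `exclude_classes`, then eigendecomposes the
#' symmetric covariance. Eigenvectors are sorted by descending eigenvalue and
#' sign-fixed so each vector's largest-magnitude entry is positive, which makes
#' bases reproducible across eigensolvers. The target class to be localized is
#' the one excluded here: its spectra are deliberately not represented in the
#' basis, so its reconstruction residual stays large.
#'
#' @param training a [labeled_spectra()] set.
#' @param exclude_classes class names to hold out of the fit (e.g.
#'   `"eosinophil"`). May be `NULL`.
#' @param m default number of eigenvectors for reconstruction; defaults to the
#'   number of distinct in-model classes remaining after exclusion.
#' @return An object of class `spectral_pca` with elements `mean`,
#'   `eigenvectors` (n x n, columns), `eigenvalues` (descending, clamped at 0),
#'   `band_edges`, `class_counts`, `m`.
#' @export
fit_spectral_pca <- function(training, exclude_classes = NULL, m = NULL) {
  stopifnot(inherits(training, "labeled_spectra"))
  keep <- !(training$labels %in% exclude_classes)
  X <- training$spectra[, keep, drop = FALSE]
  labs <- training$labels[keep]
  if (ncol(X) < 2L) {
    abort_data("fewer than 2 training samples remain after class exclusion")
  }
  if (anyNA(X) || any(!is.finite(X))) abort_data("training spectra contain non-finite values")
  mu <- rowMeans(X)
  C <- stats::cov(t(X))
  eg <- eigen(C, symmetric = TRUE) # descending eigenvalues
  V <- eg$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  m <- m %||% length(unique(labs))
  structure(
    list(
      mean = mu,
      eigenvectors = V,
      eigenvalues = pmax(eg$values, 0),
      band_edges = training$band_edges,
      class_counts = table(labs),
      excluded = exclude_classes %||% character(0),
      m = as.integer(m)
    ),
    class = "spectral_pca"
  )
}

#' @export
print.spectral_pca <- function(x, ...) {
  cat(sprintf(
    "<spectral_pca> %d bands, %d training samples (%s), default m = %d\n",
    length(x$mean), sum(x$class_counts),
    paste(sprintf("%s: %d", names(x$class_counts), x$class_counts), collapse = ", "),
    x$m
  ))
  if (length(x$excluded)) {
    cat("  excluded class(es):", paste(x$excluded, collapse = ", "), "\n")
  }
  cat(sprintf(
    "  variance explained by first %d PCs: %.4f%%\n",
    x$m, 100 * explained_variance(x, x$m)
  ))
  invisible(x)
}

check_m <- function(basis, m) {
  n <- length(basis$mean)
  if (length(m) != 1L || is.na(m) || m < 0 || m > n) {
    abort_parameter(sprintf("`m` must be between 0 and %d", n))
  }
  as.integer(m)
}

#' Accumulated fraction of variance explained
#'
#' Ratio between the sum of the first `m` eigenvalues and the sum of all `n`
#' eigenvalues of the training covariance.
#'
#' @param basis a [fit_spectral_pca()] result.
#' @param m number of leading eigenvectors, `0 <= m <= n`.
#' @return Fraction in [0, 1]; 0 at `m = 0`, 1 at `m = n`.
#' @export
explained_variance <- function(basis, m) {
  stopifnot(inherits(basis, "spectral_pca"))
  m <- check_m(basis, m)
  if (m == 0L) return(0)
  sum(basis$eigenvalues[seq_len(m)]) / sum(basis$eigenvalues)
}

as_spectrum_matrix <- function(basis, spectrum) {
  n <- length(basis$mean)
  if (is.vector(spectrum)) spectrum <- matrix(spectrum, ncol = 1L)
  if (nrow(spectrum) != n) {
    abort_dimension(sprintf(
      "spectrum has %d bands but the basis has %d", nrow(spectrum), n
    ))
  }
  spectrum
}

#' Reconstruct spectra from the leading eigenvectors
#'
#' Orthogonal projection onto the span of the first `m` eigenvectors about the
#' training mean: `f_hat = mean + V_m t(V_m) (f - mean)`.
#'
#' @param basis a [fit_spectral_pca()] result.
#' @param spectrum length-n vector, or an n x k matrix of column spectra.
#' @param m number of eigenvectors used (default: the basis default).
#' @return Reconstruction with the same shape as `spectrum`.
#' @export
reconstruct_spectrum <- function(basis, spectrum, m = basis$m) {
  stopifnot(inherits(basis, "spectral_pca"))
  m <- check_m(basis, m)
  was_vec <- is.vector(spectrum)
  f <- as_spectrum_matrix(basis, spectrum)
  centered <- f - basis$mean
  if (m == 0L) {
    out <- matrix(basis$mean, nrow(f), ncol(f))
  } else {
    V <- basis$eigenvectors[, seq_len(m), drop = FALSE]
    out <- basis$mean + V %*% (t(V) %*% centered)
  }
  if (was_vec) drop(out) else out
}

#' Per-band spectral error of a reconstruction
#'
#' Difference between a spectrum and its reconstruction from the first `m`
#' eigenvectors. For spectra belonging to the classes represented in the
#' training set the error is near zero once `m` reaches the number of classes;
#' for the excluded class it remains large and peaks at characteristic bands.
#'
#' @inheritParams reconstruct_spectrum
#' @return Error vector (or n x k matrix), with attribute `m_used`.
#' @export
spectral_error <- function(basis, spectrum, m = basis$m) {
  err <- spectrum - reconstruct_spectrum(basis, spectrum, m)
  attr(err, "m_used") <- as.integer(m)
  err
}

#' @method tidy spectral_pca
#' @export
tidy.spectral_pca <- function(x, ...) {
  ev <- x$eigenvalues
  tibble::tibble(
    component = seq_along(ev),
    eigenvalue = ev,
    variance_prop = ev / sum(ev),
    cumulative = cumsum(ev) / sum(ev)
  )
}

#' @method glance spectral_pca
#' @export
glance.spectral_pca <- function(x, ...) {
  tibble::tibble(
    n_bands = length(x$mean),
    n_samples = as.integer(sum(x$class_counts)),
    n_classes = length(x$class_counts),
    m = x$m,
    total_variance = sum(x$eigenvalues),
    explained_at_m = explained_variance(x, x$m)
  )
}

#' Persist and restore a fitted spectral model
#'
#' Stores the PCA basis (mean, eigenvalues, eigenvectors, band grid, class
#' counts, default m) and, optionally, the selected residual band pair in a
#' plain-text YAML file loadable by the command-line `segment` tool.
#'
#' @param basis a [fit_spectral_pca()] result.
#' @param path output YAML file.
#' @param pair optional [select_band_pair()] result stored with the model.
#' @return `read_spectral_model()` returns a list with elements `basis` and
#'   `pair` (`NULL` when no pair was stored).
#' @export
write_spectral_model <- function(basis, path, pair = NULL) {
  stopifnot(inherits(basis, "spectral_pca"))
  obj <- list(
    mean = as.numeric(basis$mean),
    eigenvalues = as.numeric(basis$eigenvalues),
    eigenvectors = lapply(seq_len(ncol(basis$eigenvectors)), function(j) {
      as.numeric(basis$eigenvectors[, j])
    }),
    band_edges = lapply(seq_len(nrow(basis$band_edges)), function(i) {
      as.numeric(basis$band_edges[i, ])
    }),
    class_counts = as.list(stats::setNames(
      as.integer(basis$class_counts), names(basis$class_counts)
    )),
    excluded = as.character(basis$excluded),
    m = basis$m
  )
  if (!is.null(pair)) {
    obj$band_pair <- list(
      r = pair$r, s = pair$s, mean_error = as.numeric(pair$mean_error)
    )
  }
  yaml::write_yaml(obj, path, precision = 17L)
  invisible(path)
}

#' @rdname write_spectral_model
#' @export
read_spectral_model <- function(path) {
  obj <- yaml::read_yaml(path)
  basis <- structure(
    list(
      mean = as.numeric(obj$mean),
      eigenvectors = do.call(cbind, lapply(obj$eigenvectors, as.numeric)),
      eigenvalues = as.numeric(obj$eigenvalues),
      band_edges = as_band_edges(do.call(rbind, lapply(obj$band_edges, as.numeric))),
      class_counts = do.call(
        structure,
        c(list(as.integer(unlist(obj$class_counts))),
          list(dim = length(obj$class_counts),
               dimnames = list(labs = names(obj$class_counts)),
               class = "table")
        )
      ),
      excluded = as.character(obj$excluded %||% character(0)),
      m = as.integer(obj$m)
    ),
    class = "spectral_pca"
  )
  pair <- NULL
  if (!is.null(obj$band_pair)) {
    pair <- new_band_pair(
      as.integer(obj$band_pair$r), as.integer(obj$band_pair$s),
      as.numeric(obj$band_pair$mean_error), basis$band_edges
    )
  }
  list(basis = basis, pair = pair)
}
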