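#' Broadband RGB camera sensitivities on a band grid
#'
#' Three Gaussian broadband curves centered at 610 (red), 550 (green) and 470
#' nm (blue) with a 35 nm standard deviation, sampled at the band centers and
#' row-normalized to sum to 1. These emulate a conventional RGB camera whose
#' wide filters blur narrow spectral differences between similarly stained
#' tissue.
#'
#' @param band_edges N x 2 wavelength ranges (or a `spectral_cube`).
#' @param centers,sds channel centers and widths in nm (red, green, blue).
#' @return 3 x N nonnegative matrix with rows summing to 1.
#' @export
rgb_sensitivity <- function(band_edges, centers = c(610, 550, 470),
                            sds = c(35, 35, 35)) {
  lambda <- band_centers(band_edges)
  w <- rbind(
    gaussian_curve(lambda, centers[1L], sds[1L]),
    gaussian_curve(lambda, centers[2L], sds[2L]),
    gaussian_curve(lambda, centers[3L], sds[3L])
  )
  rownames(w) <- c("red", "green", "blue")
  w / rowSums(w)
}

#' Render an RGB image from a transmittance cube
#'
#' Each channel is the sensitivity-weighted average of the band images,
#' clipped to [0, 1].
#'
#' @param cube a transmittance [spectral_cube()].
#' @param sensitivity 3 x N nonnegative weight matrix with rows summing to 1;
#'   default [rgb_sensitivity()] on the cube's grid.
#' @return An object of class `rgb_rendering` with elements `image`
#'   (H x W x 3 in [0, 1]) and `sensitivity`.
#' @export
render_rgb <- function(cube, sensitivity = NULL) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$pixels)
  sensitivity <- sensitivity %||% rgb_sensitivity(cube$band_edges)
  sensitivity <- as.matrix(sensitivity)
  if (ncol(sensitivity) != d[3L] || nrow(sensitivity) != 3L) {
    abort_dimension(sprintf(
      "sensitivity must be 3 x %d to match the cube's bands", d[3L]
    ))
  }
  if (any(sensitivity < 0)) abort_parameter("sensitivity weights must be nonnegative")
  sensitivity <- sensitivity / rowSums(sensitivity)
  flat <- matrix(cube$pixels, d[1L] * d[2L], d[3L])
  img <- array(pmin(pmax(flat %*% t(sensitivity), 0), 1), c(d[1L], d[2L], 3L))
  structure(
    list(image = img, sensitivity = sensitivity),
    class = "rgb_rendering"
  )
}

#' @export
print.rgb_rendering <- function(x, ...) {
  cat(sprintf(
    "<rgb_rendering> %d x %d, %d source bands\n",
    dim(x$image)[1L], dim(x$image)[2L], ncol(x$sensitivity)
  ))
  invisible(x)
}

#' k-means clustering of RGB pixel colors
#'
#' The conventional color-only segmentation baseline: Lloyd's algorithm on the
#' H*W x 3 pixel color matrix, with a deterministic farthest-point
#' initialization (first center drawn with the supplied seed, each further
#' center the pixel farthest from all chosen centers). With broadband RGB the
#' eosinophil and red-blood-cell colors are nearly identical, so a cluster
#' cannot separate them - the failure mode this baseline documents.
#'
#' @param rendering an [render_rgb()] result (or H x W x 3 array).
#' @param k number of clusters (>= 2); default 6, one per tissue class.
#' @param seed integer seed for the initialization.
#' @param max_iter Lloyd iteration cap.
#' @return An object of class `rgb_kmeans`: `labels` (H x W integer matrix),
#'   `centers` (k x 3), `tot_withinss`, `k`, `seed`.
#' @export
kmeans_rgb <- function(rendering, k = 6L, seed = 0L, max_iter = 300L) {
  img <- if (inherits(rendering, "rgb_rendering")) rendering$image else rendering
  d <- dim(img)
  if (length(d) != 3L || d[3L] != 3L) abort_dimension("rendering must be H x W x 3")
  k <- as.integer(k)
  if (k < 2L) abort_parameter("`k` must be at least 2")
  px <- matrix(img, d[1L] * d[2L], 3L)
  n_colors <- nrow(unique(px))
  if (k > n_colors) {
    abort_parameter(sprintf(
      "k = %d exceeds the number of distinct pixel colors (%d)", k, n_colors
    ))
  }
  set.seed(seed)
  centers <- matrix(0, k, 3L)
  centers[1L, ] <- px[sample.int(nrow(px), 1L), ]
  dmin <- rowSums((px - matrix(centers[1L, ], nrow(px), 3L, byrow = TRUE))^2)
  for (j in 2:k) {
    centers[j, ] <- px[which.max(dmin), ]
    dmin <- pmin(dmin, rowSums((px - matrix(centers[j, ], nrow(px), 3L, byrow = TRUE))^2))
  }
  km <- suppressWarnings(
    stats::kmeans(px, centers, iter.max = max_iter, algorithm = "Lloyd")
  )
  structure(
    list(
      labels = matrix(km$cluster, d[1L], d[2L]),
      centers = km$centers,
      tot_withinss = km$tot.withinss,
      k = k, seed = seed
    ),
    class = "rgb_kmeans"
  )
}

#' @export
print.rgb_kmeans <- function(x, ...) {
  cat(sprintf(
    "<rgb_kmeans> k = %d, %d x %d labels, total within-SS %.5g\n",
    x$k, nrow(x$labels), ncol(x$labels), x$tot_withinss
  ))
  invisible(x)
}

#' Score a k-means clustering against a ground-truth class
#'
#' k-means labels are arbitrary, so the cluster with maximal overlap with the
#' ground-truth positive class is taken as that class's segmentation and scored
#' pixelwise. Also reports the fraction of a confuser class (default RBC)
#' absorbed into the same cluster.
#'
#' @param clustering an [kmeans_rgb()] result.
#' @param truth a [roi_mask()] ground truth.
#' @param positive positive class name.
#' @param confuser class whose absorption into the positive cluster is
#'   reported.
#' @return One-row tibble: matched cluster, precision, recall, F1, and the
#'   captured fraction of the confuser class.
#' @export
evaluate_clustering <- function(clustering, truth, positive = "eosinophil",
                                confuser = "rbc") {
  stopifnot(inherits(clustering, "rgb_kmeans"), inherits(truth, "roi_mask"))
  pos <- truth$labels == mask_label_of(truth, positive)
  if (!any(pos)) abort_data(sprintf("no '%s' pixels in truth", positive))
  counts <- tabulate(clustering$labels[pos], nbins = clustering$k)
  best <- which.max(counts)
  pred <- clustering$labels == best
  m <- evaluate_segmentation(pred, pos, positive = positive)
  conf_code <- mask_label_of(truth, confuser)
  conf_frac <- if (is.na(conf_code)) {
    NA_real_
  } else {
    sel <- truth$labels == conf_code
    sum(pred & sel) / sum(sel)
  }
  tibble::tibble(
    cluster = best,
    precision = m$precision, recall = m$recall, f1 = m$f1,
    confuser = confuser, confuser_fraction = conf_frac
  )
}
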