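# Independent brute-force oracles. These deliberately avoid the code paths
# they check: plain loops and direct formulas only.

# Otsu criterion on a 256-bin histogram of the min-max normalized map,
# recomputed per candidate bin from raw sums (class 1 = bins 1..k, class 2 =
# bins k..levels, i.e. the candidate bin contributes to both classes), the
# threshold being the midpoint of the best bin mapped back to data units.
oracle_otsu <- function(dmap, levels = 256L) {
  rng <- range(dmap)
  x <- (dmap - rng[1L]) / (rng[2L] - rng[1L])
  breaks <- seq(0, 1, length.out = levels + 1L)
  counts <- hist(x, breaks = breaks, plot = FALSE)$counts
  mids <- (breaks[-1L] + breaks[-(levels + 1L)]) / 2
  best <- -Inf
  best_k <- integer(0)
  for (k in seq_len(levels)) {
    i1 <- 1:k
    i2 <- k:levels
    w1 <- sum(counts[i1])
    w2 <- sum(counts[i2])
    if (w1 == 0 || w2 == 0) next
    m1 <- sum(counts[i1] * mids[i1]) / w1
    m2 <- sum(counts[i2] * mids[i2]) / w2
    v <- w1 * w2 * (m2 - m1)^2
    if (v > best + 1e-12) {
      best <- v
      best_k <- k
    } else if (abs(v - best) <= 1e-12) {
      best_k <- c(best_k, k)
    }
  }
  th <- (mids[best_k[1L]] + mids[best_k[length(best_k)]]) / 2
  rng[1L] + th * (rng[2L] - rng[1L])
}

# binary dilation/erosion by explicit structuring-element sweep;
# out-of-image neighbors are ignored (background for dilation, foreground
# for erosion)
oracle_dilate <- function(mask, brush) {
  h <- nrow(mask)
  w <- ncol(mask)
  ci <- (nrow(brush) + 1L) %/% 2L
  cj <- (ncol(brush) + 1L) %/% 2L
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      hit <- FALSE
      for (bi in seq_len(nrow(brush))) {
        for (bj in seq_len(ncol(brush))) {
          if (brush[bi, bj] == 0) next
          ii <- i + bi - ci
          jj <- j + bj - cj
          if (ii >= 1 && ii <= h && jj >= 1 && jj <= w && mask[ii, jj]) hit <- TRUE
        }
      }
      out[i, j] <- hit
    }
  }
  out
}

oracle_erode <- function(mask, brush) {
  h <- nrow(mask)
  w <- ncol(mask)
  ci <- (nrow(brush) + 1L) %/% 2L
  cj <- (ncol(brush) + 1L) %/% 2L
  out <- matrix(TRUE, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      all_in <- TRUE
      for (bi in seq_len(nrow(brush))) {
        for (bj in seq_len(ncol(brush))) {
          if (brush[bi, bj] == 0) next
          ii <- i + bi - ci
          jj <- j + bj - cj
          if (ii >= 1 && ii <= h && jj >= 1 && jj <= w && !mask[ii, jj]) all_in <- FALSE
        }
      }
      out[i, j] <- all_in
    }
  }
  out & mask
}

oracle_closing <- function(mask, brush) oracle_erode(oracle_dilate(mask, brush), brush)

# connected components by flood fill (4-connectivity), small-object removal
oracle_remove_small <- function(mask, min_size) {
  h <- nrow(mask)
  w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  out <- matrix(FALSE, h, w)
  for (i0 in seq_len(h)) {
    for (j0 in seq_len(w)) {
      if (!mask[i0, j0] || seen[i0, j0]) next
      comp <- matrix(c(i0, j0), 1L, 2L)
      seen[i0, j0] <- TRUE
      head <- 1L
      while (head <= nrow(comp)) {
        ci <- comp[head, 1L]
        cj <- comp[head, 2L]
        head <- head + 1L
        for (step in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
          ii <- ci + step[1L]
          jj <- cj + step[2L]
          if (ii >= 1 && ii <= h && jj >= 1 && jj <= w &&
            mask[ii, jj] && !seen[ii, jj]) {
            seen[ii, jj] <- TRUE
            comp <- rbind(comp, c(ii, jj))
          }
        }
      }
      if (nrow(comp) >= min_size) out[comp] <- TRUE
    }
  }
  out
}

# least-squares projection onto the first m basis columns via the explicit
# Gram system (independent of the V %*% t(V) fast path)
oracle_project <- function(mean_vec, V, spectrum, m) {
  if (m == 0L) return(mean_vec)
  Vm <- V[, seq_len(m), drop = FALSE]
  coef <- solve(t(Vm) %*% Vm, t(Vm) %*% (spectrum - mean_vec))
  as.numeric(mean_vec + Vm %*% coef)
}

# eigenpairs of the sample covariance via SVD of the centered data matrix
oracle_pca_svd <- function(X) {
  mu <- rowMeans(X)
  Xc <- X - mu
  sv <- svd(Xc / sqrt(ncol(X) - 1))
  V <- sv$u
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  list(mean = mu, values = sv$d^2, vectors = V)
}

# exhaustive scan for the residual band pair with the stated tie rule
oracle_band_pair <- function(v) {
  r <- 1L
  s <- 1L
  for (i in seq_along(v)) {
    if (v[i] > v[r]) r <- i
    if (v[i] < v[s]) s <- i
  }
  c(r = r, s = s)
}
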