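# Small image-processing helpers shared by the pipeline stages.

# Discrete Gaussian (derivative) kernel. Derivative kernels are calibrated on
# polynomial ramps: sum(k0) = 1, sum(t * k1) = 1, sum(t^2 * k2) = 2 with
# sum(k1) = sum(k2) = 0, so discrete derivatives are exact for quadratics.
gaussian_kernel <- function(sigma_vox, order = 0L) {
  r <- max(1L, ceiling(3 * sigma_vox))
  t <- seq(-r, r)
  g <- exp(-t^2 / (2 * sigma_vox^2))
  if (order == 0L) return(g / sum(g))
  if (order == 1L) {
    k <- -t / sigma_vox^2 * g
    k <- k - mean(k)
    return(k / sum(t * k))
  }
  if (order == 2L) {
    k <- (t^2 - sigma_vox^2) / sigma_vox^4 * g
    k <- k - mean(k)
    return(k * (2 / sum(t^2 * k)))
  }
  stop_pulmo("kernel order must be 0, 1 or 2", "validation_error")
}

# Separable Gaussian smoothing; sigma_vox may differ per axis (z, y, x).
gaussian_blur <- function(vol, sigma_vox) {
  if (length(sigma_vox) == 1) sigma_vox <- rep(sigma_vox, 3)
  out <- vol
  for (axis in 1:3) {
    if (sigma_vox[axis] <= 0) next
    out <- .convolve_axis(out, gaussian_kernel(sigma_vox[axis]), axis - 1L)
  }
  out
}

# Global Otsu threshold (maximum between-class variance) on a numeric sample.
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) < 2 || diff(range(x)) == 0)
    stop_pulmo("cannot threshold a constant sample", "validation_error")
  h <- hist(x, breaks = seq(min(x), max(x), length.out = nbins + 1L),
            plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# Grey-value maximum filter (26-neighborhood), `iter` passes.
max_filter3 <- function(x, iter = 1L) {
  d <- dim(x)
  for (it in seq_len(iter)) {
    out <- x
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dz == 0 && dy == 0 && dx == 0) next
      zs <- pmin(pmax(seq_len(d[1]) + dz, 1L), d[1])
      ys <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
      xs <- pmin(pmax(seq_len(d[3]) + dx, 1L), d[3])
      out <- pmax(out, x[zs, ys, xs])
    }
    x <- out
  }
  x
}

# Connected components as an integer array plus voxel counts.
label_components <- function(mask, connectivity = 26L) {
  lab <- .cc_label(mask, as.integer(connectivity))
  n <- attr(lab, "ncomp")
  counts <- if (n > 0) tabulate(lab[lab > 0L], nbins = n) else integer(0)
  list(labels = lab, n = n, sizes = counts)
}

# Surface voxels: mask voxels with at least one face-adjacent background
# neighbor (voxels beyond the grid count as background).
surface_voxels <- function(mask) {
  mask & !.bin_erode(mask, 6L, 1L)
}

# Largest connected component of a mask (26-connectivity).
largest_component <- function(mask) {
  cc <- label_components(mask, 26L)
  if (cc$n == 0) return(mask)
  array(cc$labels == which.max(cc$sizes), dim = dim(mask))
}

# 0-based (z,y,x) voxel coordinates of TRUE voxels, as an n x 3 matrix.
which_voxels <- function(mask) {
  idx <- which(mask) - 1L
  d <- dim(mask)
  z <- idx %% d[1]
  r <- idx %/% d[1]
  cbind(z = z, y = r %% d[2], x = r %/% d[2])
}

# linear 1-based index from 0-based (z,y,x) coordinates
voxel_index <- function(coords, d) {
  1L + coords[, 1] + d[1] * (coords[, 2] + d[2] * coords[, 3])
}
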