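#' Gaussian kernel density surface of survey effort
#'
#' Each cell receives the sum over points of the isotropic bivariate
#' Gaussian kernel `exp(-d^2 / (2*sigma^2)) / (2*pi*sigma^2)` of the
#' point-to-cell-center distance `d`. The kernel is separable on the
#' regular grid, so each point contributes a rank-1 (row x column) outer
#' product; contributions beyond 6 sigma are truncated (relative error
#' < 1e-8). Nodata cells in the template stay nodata.
#'
#' @param points an `occ_set`; at least one point required.
#' @param grid template `hs_raster` defining the output grid and mask.
#' @param bandwidth Gaussian sigma in meters.
#' @return `hs_raster` of densities (points per m^2).
#' @export
kernel_density <- function(points, grid, bandwidth) {
  stopifnot(bandwidth > 0)
  if (nrow(points) == 0)
    stop("kernel_density needs at least one point (no effort information)",
         call. = FALSE)
  nr <- nrow(grid$values); nc <- ncol(grid$values); cs <- grid$cellsize
  cx <- grid$xll + (seq_len(nc) - 0.5) * cs          # column centers, W->E
  cy <- grid$yll + (nr - seq_len(nr) + 0.5) * cs     # row centers, N->S
  sig2 <- bandwidth^2
  norm <- 1 / (2 * pi * sig2)
  cutoff <- 6 * bandwidth
  acc <- matrix(0, nr, nc)
  for (p in seq_len(nrow(points))) {
    px <- points$x[p]; py <- points$y[p]
    jc <- which(abs(cx - px) <= cutoff)
    jr <- which(abs(cy - py) <= cutoff)
    if (length(jc) == 0L || length(jr) == 0L) next
    gx <- exp(-(cx[jc] - px)^2 / (2 * sig2))
    gy <- exp(-(cy[jr] - py)^2 / (2 * sig2))
    acc[jr, jc] <- acc[jr, jc] + norm * (gy %o% gx)
  }
  acc[is.na(grid$values)] <- NA_real_
  hs_raster(acc, grid$xll, grid$yll, cs)
}

#' Rescale a density field to the 1-30 effort range
#'
#' Affine map sending the field minimum to 1 and maximum to 30 over
#' non-nodata cells. A constant field (no effort gradient) maps to all 1,
#' i.e. uniform minimal effort.
#'
#' @param density `hs_raster` of non-negative densities.
#' @param lo,hi target range endpoints (defaults 1 and 30).
#' @return `hs_raster` of effort weights in `[lo, hi]`.
#' @export
rescale_bias <- function(density, lo = 1, hi = 30) {
  v <- density$values
  rng <- range(v, na.rm = TRUE)
  if (any(v < 0, na.rm = TRUE))
    stop("density must be non-negative", call. = FALSE)
  out <- if (rng[2] > rng[1]) {
    lo + (v - rng[1]) * (hi - lo) / (rng[2] - rng[1])
  } else {
    v * 0 + lo
  }
  hs_raster(out, density$xll, density$yll, density$cellsize)
}

#' Build a sampling-effort bias surface from target-group records
#'
#' Convenience wrapper: kernel density of the pooled focal plus
#' target-group records, rescaled to 1-30. The target group (here,
#' arboreal mammal occurrences sharing the focal species' detectability)
#' proxies where observers actually looked.
#'
#' @param points pooled `occ_set` of focal + target-group records.
#' @param grid template `hs_raster`.
#' @param bandwidth Gaussian sigma in meters; default 2 cell widths.
#' @return `hs_raster` of weights in `[1, 30]` with attribute
#'   `"bandwidth"`.
#' @export
bias_surface <- function(points, grid, bandwidth = 2 * grid$cellsize) {
  b <- rescale_bias(kernel_density(points, grid, bandwidth))
  attr(b, "bandwidth") <- bandwidth
  b
}
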