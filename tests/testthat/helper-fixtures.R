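# shared toy fixtures; everything is built in code, nothing on disk

# n x n raster with given values (recycled), 100-m cells at origin
toy_raster <- function(values, n = 5, cellsize = 100) {
  hs_raster(matrix(values, n, n), xll = 0, yll = 0, cellsize = cellsize)
}

# clustered point set: k clusters of spread `spread` m on a w x w field
clustered_points <- function(n, k = 5, w = 20000, spread = 800, seed = 1) {
  set.seed(seed)
  cx <- runif(k, 0, w); cy <- runif(k, 0, w)
  g <- sample.int(k, n, replace = TRUE)
  occurrence_set(x = cx[g] + rnorm(n, 0, spread),
                 y = cy[g] + rnorm(n, 0, spread))
}

# brute-force O(n^2) min-distance check
min_pair_dist <- function(occ) {
  if (nrow(occ) < 2) return(Inf)
  d <- stats::dist(cbind(occ$x, occ$y))
  min(d)
}

# tiny detection-history fixture
toy_history <- function(y, ...) detection_history(as.matrix(y), ...)

# intercept-only occupancy neg2LL on a (psi, p) grid, vectorized closed form
occu_grid_oracle <- function(y, step = 1e-3) {
  det <- rowSums(y == 1, na.rm = TRUE)
  tot <- rowSums(!is.na(y))
  psis <- seq(step, 1 - step, by = step)
  ps <- seq(step, 1 - step, by = step)
  best <- c(NA, NA, Inf)
  for (psi in psis) {
    # for fixed psi, neg2LL over all p at once
    ll <- rep(0, length(ps))
    for (i in seq_along(det)) {
      Li <- psi * ps^det[i] * (1 - ps)^(tot[i] - det[i]) +
        (1 - psi) * (det[i] == 0)
      ll <- ll - 2 * log(Li)
    }
    j <- which.min(ll)
    if (ll[j] < best[3]) best <- c(psi, ps[j], ll[j])
  }
  names(best) <- c("psi", "p", "neg2LL")
  best
}
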