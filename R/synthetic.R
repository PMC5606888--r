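#' Synthetic landscape generator
#'
#' Builds a predictor stack with the statistical structure the analysis
#' assumes: continuous layers are standardized Gaussian random fields
#' (white noise smoothed by circular convolution with a Gaussian kernel
#' of scale `correlation_length` cells), categorical layers are
#' quantile-thresholded independent fields (a soil-like layer with
#' `soil_levels` codes and a fire-like layer with codes 0..3). True
#' suitability is the inverse logit of a sparse linear-plus-hinge
#' combination of the first three continuous layers:
#' `eta = -2.5 + 1.5 z1 + 2 max(z2, 0) - z3`. The negative intercept
#' right-skews the suitability field so that high-suitability cells are
#' rare pockets rather than half the map — the regime a regional
#' presence-only model actually faces, where most of the region is poor
#' habitat and records concentrate in a small high-suitability fraction.
#'
#' @param size grid edge in cells (default 200; nominal 250-m cells).
#' @param n_continuous number of continuous layers (>= 3; default 4 —
#'   layer 4 onward is pure noise, i.e. uninformative).
#' @param n_categorical number of categorical layers (default 2).
#' @param correlation_length smoothing scale in cells (default 16; 0
#'   gives white noise).
#' @param soil_levels categories for the first categorical layer
#'   (default 8).
#' @param cellsize cell size in meters (default 250).
#' @param seed integer RNG seed; output is bit-reproducible given it.
#' @return list: `stack` (`hs_stack`), `truth` (true suitability raster,
#'   generating coefficients, seed).
#' @export
gen_landscape <- function(size = 200, n_continuous = 4, n_categorical = 2,
                          correlation_length = 16, soil_levels = 8,
                          cellsize = 250, seed = 1L) {
  stopifnot(n_continuous >= 3)
  with_seed(seed, {
    grf <- function() grf_field(size, correlation_length)
    layers <- list()
    kinds <- character(0)
    for (i in seq_len(n_continuous)) {
      layers[[paste0("cont", i)]] <- hs_raster(grf(), cellsize = cellsize)
      kinds[paste0("cont", i)] <- "continuous"
    }
    for (i in seq_len(n_categorical)) {
      nlev <- if (i == 1) soil_levels else 4L
      f <- grf()
      codes <- cut(f, stats::quantile(f, probs = seq(0, 1,
                                                     length.out = nlev + 1)),
                   include.lowest = TRUE, labels = FALSE)
      if (i == 2) codes <- codes - 1L   # fire-like: classes 0..3
      layers[[paste0("cat", i)]] <-
        hs_raster(matrix(as.numeric(codes), size, size),
                  cellsize = cellsize)
      kinds[paste0("cat", i)] <- "categorical"
    }
    coefs <- c(intercept = -2.5, cont1 = 1.5, cont2_hinge = 2, cont3 = -1)
    eta <- coefs[["intercept"]] +
      coefs[["cont1"]] * layers$cont1$values +
      coefs[["cont2_hinge"]] * pmax(layers$cont2$values, 0) +
      coefs[["cont3"]] * layers$cont3$values
    suit <- hs_raster(stats::plogis(eta), cellsize = cellsize)
    list(stack = predictor_stack(layers, kinds),
         truth = list(suitability = suit, coefficients = coefs,
                      correlation_length = correlation_length, seed = seed))
  })
}

## standardized Gaussian random field on a size x size torus
grf_field <- function(size, len) {
  noise <- matrix(stats::rnorm(size * size), size, size)
  if (len <= 0) return(noise)
  d <- pmin(0:(size - 1), size:1)          # torus distance along one axis
  k <- exp(-outer(d^2, d^2, `+`) / (2 * len^2))
  sm <- Re(stats::fft(stats::fft(noise) * stats::fft(k), inverse = TRUE)) /
    size^2
  (sm - mean(sm)) / stats::sd(sm)
}

#' Sample observer-biased presence records from a known truth
#'
#' Presence cells are drawn with replacement with probability
#' proportional to `true suitability x observer bias`, then jittered
#' uniformly within the cell (emulating record clustering near heavily
#' surveyed areas).
#'
#' @param truth truth list from [gen_landscape()] (needs
#'   `$suitability`).
#' @param n_presence number of records.
#' @param observer_bias optional `hs_raster` of relative survey effort;
#'   `NULL` for unbiased sampling.
#' @param seed integer RNG seed.
#' @param accuracy_range range (m) for per-record uniform positional
#'   accuracy (default 5-95 m, all passing the 100-m filter).
#' @return an `occ_set` with source `"synthetic"`.
#' @export
gen_occurrences <- function(truth, n_presence = 500, observer_bias = NULL,
                            seed = 1L, accuracy_range = c(5, 95)) {
  suit <- truth$suitability
  w <- as.vector(suit$values)
  if (!is.null(observer_bias)) {
    assert_same_grid(suit, observer_bias, "observer bias")
    w <- w * as.vector(observer_bias$values)
  }
  valid <- which(!is.na(w))
  with_seed(seed, {
    cells <- sample(valid, n_presence, replace = TRUE, prob = w[valid])
    cc <- cell_centers(suit)
    cs <- suit$cellsize
    occurrence_set(
      x = cc$x[cells] + stats::runif(n_presence, -cs / 2, cs / 2),
      y = cc$y[cells] + stats::runif(n_presence, -cs / 2, cs / 2),
      accuracy = stats::runif(n_presence, accuracy_range[1],
                              accuracy_range[2]),
      source = rep("synthetic", n_presence))
  })
}

#' Simulate acoustic detection histories at stratified sites
#'
#' Sites are stratified across four suitability quantile strata (the
#' very-high/high/moderate/low design), occupancy is Bernoulli with
#' `logit(psi) = psi_coef[1] + psi_coef[2] * suitability`, and nightly
#' detections at occupied sites are Bernoulli with a per-trip detection
#' probability (sites are split into three survey trips). Failed
#' recorders (all-missing rows) can be injected and are dropped from the
#' returned history, mirroring a real deployment.
#'
#' @param truth truth list from [gen_landscape()].
#' @param n_sites number of deployed recorders (default 65).
#' @param occasions survey nights per site (default 7).
#' @param p_by_trip per-trip nightly detection probabilities (default
#'   `c(0.43, 0.36, 0.30)`); a single value gives constant detection.
#' @param psi_coef intercept and slope of true occupancy on the logit
#'   scale (default `c(-2, 4)`).
#' @param n_failed recorders that fail entirely (default 0).
#' @param seed integer RNG seed.
#' @return list: `history` (`det_history` of working sites with site
#'   covariates `suitability`, `trip`, `topo`, `elevation` and occasion
#'   covariate `rainfall`), `sites` (all deployments incl. `failed`
#'   flag), `truth` (psi/p parameters and latent occupancy states `z`).
#' @export
gen_histories <- function(truth, n_sites = 65, occasions = 7,
                          p_by_trip = c(0.43, 0.36, 0.30),
                          psi_coef = c(-2, 4), n_failed = 0, seed = 1L) {
  suit <- truth$suitability
  v <- as.vector(suit$values)
  valid <- which(!is.na(v))
  with_seed(seed, {
    strata <- cut(v[valid], stats::quantile(v[valid], probs = 0:4 / 4),
                  include.lowest = TRUE, labels = FALSE)
    per <- diff(round(seq(0, n_sites, length.out = 5)))
    cells <- unlist(lapply(1:4, function(s)
      sample(valid[strata == s], per[s])))
    cells <- sample(cells)                       # shuffle stratum order
    cc <- cell_centers(suit)
    s_val <- v[cells]
    n_trip <- length(p_by_trip)
    trip <- factor(rep(seq_len(n_trip), length.out = n_sites))
    psi <- stats::plogis(psi_coef[1] + psi_coef[2] * s_val)
    z <- stats::rbinom(n_sites, 1, psi)
    p_site <- p_by_trip[as.integer(trip)]
    y <- matrix(stats::rbinom(n_sites * occasions, 1,
                              rep(p_site, occasions)),
                nrow = n_sites) * z
    rain <- matrix(stats::rlnorm(n_sites * occasions, 0, 1),
                   nrow = n_sites)
    sites <- data.frame(site = seq_len(n_sites),
                        x = cc$x[cells], y = cc$y[cells],
                        suitability = s_val, trip = trip,
                        topo = stats::rnorm(n_sites),
                        elevation = stats::runif(n_sites, 0, 1000),
                        failed = FALSE)
    if (n_failed > 0) {
      failed <- sample.int(n_sites, n_failed)
      sites$failed[failed] <- TRUE
    }
    ok <- !sites$failed
    hist <- detection_history(y[ok, , drop = FALSE],
                              sites[ok, c("suitability", "trip", "topo",
                                          "elevation")],
                              list(rainfall = rain[ok, , drop = FALSE]))
    list(history = hist, sites = sites,
         truth = list(psi_coef = psi_coef, p_by_trip = p_by_trip, z = z,
                      occasions = occasions, seed = seed))
  })
}

default_species_pool <- function() {
  data.frame(
    species = c("E_tereticornis", "E_microcorys", "E_robusta",
                "E_punctata", "C_variegata", "Rainforest_sp"),
    class = c(1L, 1L, 2L, 3L, 4L, 4L))
}

#' Simulate Point-Quarter transects over Poisson forests
#'
#' Per site: a homogeneous Poisson pattern of qualifying trees
#' (dbh > 20 cm) at `stems_per_ha` over a window buffering the 200-m
#' transect by 60 m; ten stations at 20-m spacing measure the nearest
#' tree in each quadrant geometrically. Species are multinomial with the
#' class-1/2 share increasing in true site suitability; dbh is lognormal
#' (median 35 cm, log-sd 0.3) truncated above 20 cm.
#'
#' @param sites data.frame with columns `site` and `suitability`.
#' @param stems_per_ha true intensity of qualifying trees (default 300).
#' @param species_pool data.frame `species`, `class` (1..4); default six
#'   species spanning the four browse classes.
#' @param seed integer RNG seed.
#' @return a `transect_sample` covering all sites, with attribute
#'   `"truth"` (intensity, pool, seed).
#' @export
gen_transects <- function(sites, stems_per_ha = 300,
                          species_pool = default_species_pool(),
                          seed = 1L) {
  xmin <- -60; xmax <- 240; ymin <- -60; ymax <- 60
  area_m2 <- (xmax - xmin) * (ymax - ymin)
  lambda <- stems_per_ha / 1e4
  stations_x <- seq(0, 180, by = 20)
  with_seed(seed, {
    rows <- vector("list", nrow(sites))
    for (i in seq_len(nrow(sites))) {
      n_tree <- stats::rpois(1, lambda * area_m2)
      tx <- stats::runif(n_tree, xmin, xmax)
      ty <- stats::runif(n_tree, ymin, ymax)
      sp <- sample(species_pool$species, n_tree, replace = TRUE,
                   prob = species_weights(species_pool,
                                          sites$suitability[i]))
      dbh <- 35 * exp(stats::rnorm(n_tree, 0, 0.3))
      while (any(dbh <= 20))
        dbh[dbh <= 20] <- 35 * exp(stats::rnorm(sum(dbh <= 20), 0, 0.3))
      per_station <- lapply(seq_along(stations_x), function(k) {
        dx <- tx - stations_x[k]; dy <- ty
        quad <- 1L + (dx < 0) + 2L * (dy < 0)  # 1:NE 2:NW 3:SE 4:SW
        dd <- sqrt(dx^2 + dy^2)
        found <- lapply(1:4, function(q) {
          in_q <- which(quad == q)
          if (!length(in_q))
            return(data.frame(quadrant = q, distance_m = NA_real_,
                              species = NA_character_,
                              dbh_cm = NA_real_))
          j <- in_q[which.min(dd[in_q])]
          data.frame(quadrant = q, distance_m = dd[j], species = sp[j],
                     dbh_cm = dbh[j])
        })
        cbind(station = k, do.call(rbind, found))
      })
      rows[[i]] <- cbind(site = sites$site[i],
                         do.call(rbind, per_station))
    }
    out <- do.call(rbind, rows)
    out$height_m <- 0.6 * out$dbh_cm / 2 + stats::rnorm(nrow(out), 0, 2)
    out <- transect_sample(out)
    attr(out, "truth") <- list(stems_per_ha = stems_per_ha,
                               species_pool = species_pool, seed = seed)
    out
  })
}

## class shares shift toward primary browse with suitability
species_weights <- function(pool, s) {
  share <- c(0.05 + 0.5 * s, 0.15 + 0.1 * s, 0.25 - 0.15 * s, 0)
  share[4] <- 1 - sum(share[1:3])
  counts <- tabulate(pool$class, 4L)
  as.numeric(share[pool$class] / pmax(counts[pool$class], 1L))
}
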