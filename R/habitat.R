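#' Point-Quarter transect data
#'
#' One row per measured tree: at each of 10 stations spaced 20 m along a
#' 200-m transect, the nearest tree with dbh > 20 cm is recorded in each
#' of four quadrants (40 trees per complete transect). An empty quadrant
#' (no qualifying tree within the search limit) is a row with `NA`
#' distance.
#'
#' @param df data.frame with columns `site`, `station`, `quadrant`,
#'   `distance_m`, `species`, `dbh_cm` and optionally `height_m`.
#' @return data.frame of class `transect_sample`.
#' @export
transect_sample <- function(df) {
  need <- c("site", "station", "quadrant", "distance_m", "species", "dbh_cm")
  stopifnot(all(need %in% names(df)))
  if (any(df$distance_m <= 0, na.rm = TRUE))
    stop("distances must be positive", call. = FALSE)
  if (!"height_m" %in% names(df)) df$height_m <- NA_real_
  class(df) <- c("transect_sample", "data.frame")
  df
}

#' @rdname transect_sample
#' @param path CSV path (`site,station,quadrant,distance_m,species,dbh_cm,height_m`).
#' @export
read_transects <- function(path) {
  transect_sample(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Pollard's Point-Quarter density estimator
#'
#' The unbiased plotless estimator
#' `lambda_hat = 4 * (4n - 1) / (pi * sum(r^2))` with `n` the number of
#' stations and `r` the quadrant distances in meters, converted to stems
#' per hectare. Empty quadrants (`NA` distance) are substituted with the
#' truncation distance (default 50 m) rather than dropped, which would
#' bias density upward; the substitution count is returned.
#'
#' @param transect a `transect_sample` for a single site (or any subset).
#' @param truncation substitution distance in m for empty quadrants.
#' @return list: `density_ha` (stems/ha), `n_stations`, `n_empty`.
#' @export
point_quarter_density <- function(transect, truncation = 50) {
  stopifnot(nrow(transect) >= 4)
  n <- length(unique(transect$station))
  r <- transect$distance_m
  n_empty <- sum(is.na(r))
  r[is.na(r)] <- truncation
  lambda_m2 <- 4 * (4 * n - 1) / (pi * sum(r^2))
  list(density_ha = lambda_m2 * 1e4, n_stations = n, n_empty = n_empty)
}

#' Species composition of a transect
#'
#' Percent occurrence, mean dbh, and mean per-stem basal area
#' (`pi * (dbh/2)^2`, m^2) by species. Empty quadrants are excluded.
#'
#' @param transect a `transect_sample`.
#' @return data.frame: `species`, `n`, `pct_occurrence`, `mean_dbh_cm`,
#'   `mean_stem_ba_m2`.
#' @export
species_composition <- function(transect) {
  tr <- transect[!is.na(transect$distance_m), , drop = FALSE]
  stopifnot(all(nzchar(tr$species)))
  ba <- pi * (tr$dbh_cm / 200)^2          # dbh cm -> radius m
  agg <- stats::aggregate(cbind(dbh = tr$dbh_cm, ba = ba),
                          by = list(species = tr$species), FUN = mean)
  cnt <- as.data.frame(table(species = tr$species), stringsAsFactors = FALSE)
  out <- merge(cnt, agg, by = "species")
  data.frame(species = out$species, n = out$Freq,
             pct_occurrence = 100 * out$Freq / sum(out$Freq),
             mean_dbh_cm = out$dbh, mean_stem_ba_m2 = out$ba)
}

#' Per-species basal area from density and composition
#'
#' `BA_s = density * occurrence_s * mean per-stem basal area_s`, in
#' m^2/ha.
#'
#' @param density_ha stand density in stems/ha (from
#'   [point_quarter_density()]).
#' @param composition output of [species_composition()].
#' @return data.frame `species`, `basal_area_m2_ha`.
#' @export
species_basal_area <- function(density_ha, composition) {
  data.frame(species = composition$species,
             basal_area_m2_ha = density_ha *
               (composition$pct_occurrence / 100) *
               composition$mean_stem_ba_m2)
}

#' Browse-weighted habitat-quality index
#'
#' Weights each species' basal area by its browse class (1 = primary
#' browse ... 4 = unsuitable; default weights 3, 2, 1, 0) and applies a
#' diversity multiplier `1 + diversity_bonus * (richness of class-1/2
#' species - 1)`, capped at `cap`. The exact published index formula
#' lives in unavailable supplementary material, so every knob here is
#' exposed and documented rather than hard-coded. Zero when no class
#' 1-3 trees are present.
#'
#' @param basal_area data.frame from [species_basal_area()].
#' @param browse_classes named integer vector mapping species to class
#'   1..4; unmapped species fall to class 4 with a warning.
#' @param weights per-class weights, class 1 first (default `c(3,2,1,0)`);
#'   must be non-negative.
#' @param diversity_bonus per extra class-1/2 species (default 0.1).
#' @param cap maximum diversity multiplier (default 1.5).
#' @return list: `index`, `class_ba` (basal area by class), `multiplier`,
#'   `weights`.
#' @export
habitat_quality_index <- function(basal_area, browse_classes,
                                  weights = c(3, 2, 1, 0),
                                  diversity_bonus = 0.1, cap = 1.5) {
  if (any(weights < 0)) stop("browse weights must be non-negative",
                             call. = FALSE)
  stopifnot(length(weights) == 4)
  cls <- browse_classes[basal_area$species]
  if (any(is.na(cls))) {
    warning("unmapped species assigned to class 4: ",
            paste(basal_area$species[is.na(cls)], collapse = ", "),
            call. = FALSE)
    cls[is.na(cls)] <- 4L
  }
  class_ba <- vapply(1:4, function(k)
    sum(basal_area$basal_area_m2_ha[cls == k]), numeric(1))
  rich12 <- sum(cls %in% c(1L, 2L) & basal_area$basal_area_m2_ha > 0)
  mult <- min(1 + diversity_bonus * max(rich12 - 1, 0), cap)
  list(index = sum(weights * class_ba) * mult,
       class_ba = stats::setNames(class_ba, paste0("class", 1:4)),
       multiplier = mult, weights = weights)
}

#' Per-site habitat-quality indices from pooled transect data
#'
#' Convenience wrapper chaining density, composition, basal area and the
#' index for every site in a multi-site transect table.
#'
#' @param transects a `transect_sample` covering several sites.
#' @param browse_classes,weights,diversity_bonus,cap as in
#'   [habitat_quality_index()].
#' @return data.frame `site`, `density_ha`, `index`.
#' @export
site_quality_indices <- function(transects, browse_classes,
                                 weights = c(3, 2, 1, 0),
                                 diversity_bonus = 0.1, cap = 1.5) {
  sites <- unique(transects$site)
  rows <- lapply(sites, function(s) {
    tr <- transects[transects$site == s, , drop = FALSE]
    dens <- point_quarter_density(tr)
    comp <- species_composition(tr)
    ba <- species_basal_area(dens$density_ha, comp)
    hq <- habitat_quality_index(ba, browse_classes, weights,
                                diversity_bonus, cap)
    data.frame(site = s, density_ha = dens$density_ha, index = hq$index)
  })
  do.call(rbind, rows)
}

#' Regress the habitat-quality index on modelled suitability
#'
#' Ordinary least squares per subregion with a two-sided test on the
#' slope.
#'
#' @param index per-site habitat-quality index.
#' @param suitability per-site modelled suitability.
#' @param subregion optional per-site labels; `NULL` fits one pooled
#'   regression labelled `"all"`.
#' @return data.frame per subregion: `subregion`, `n`, `slope`,
#'   `r_squared`, `p_value`.
#' @export
regress_index <- function(index, suitability, subregion = NULL) {
  stopifnot(length(index) == length(suitability))
  if (is.null(subregion)) subregion <- rep("all", length(index))
  rows <- lapply(unique(subregion), function(s) {
    i <- subregion == s
    fit <- stats::lm(index[i] ~ suitability[i])
    sm <- summary(fit)
    data.frame(subregion = s, n = sum(i),
               slope = unname(stats::coef(fit)[2]),
               r_squared = sm$r.squared,
               p_value = sm$coefficients[2, 4])
  })
  do.call(rbind, rows)
}
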