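#' Occurrence records
#'
#' Presence-only records in projected coordinates (meters). Stored as a
#' data.frame with columns `x`, `y`, `accuracy` (m), `date`, `source`; an
#' empty set is legal. Coordinates must be finite and accuracy positive —
#' geodetic (lon/lat) input is the caller's error: all distances here are
#' planar Euclidean.
#'
#' @param x,y numeric coordinates in meters (projected CRS).
#' @param accuracy positional accuracy in meters, `> 0`.
#' @param date ISO date strings (free-form, not parsed).
#' @param source free-text provenance tag.
#' @return data.frame of class `occ_set`.
#' @export
occurrence_set <- function(x = numeric(), y = numeric(),
                           accuracy = rep(100, length(x)),
                           date = rep(NA_character_, length(x)),
                           source = rep(NA_character_, length(x))) {
  stopifnot(length(y) == length(x), all(is.finite(x)), all(is.finite(y)),
            all(is.finite(accuracy)), all(accuracy > 0))
  out <- data.frame(x = as.numeric(x), y = as.numeric(y),
                    accuracy = as.numeric(accuracy),
                    date = as.character(date), source = as.character(source),
                    stringsAsFactors = FALSE)
  class(out) <- c("occ_set", "data.frame")
  out
}

as_occ_set <- function(df) {
  occurrence_set(df$x, df$y, df$accuracy, df$date, df$source)
}

#' Read / write occurrence CSV
#'
#' Column layout: `x,y,accuracy_m,date,source`, one header row, UTF-8.
#' @param path CSV path.
#' @return `read_occurrences`: an `occ_set`.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "accuracy_m")
  if (!all(need %in% names(df)))
    stop("occurrence CSV must have columns x,y,accuracy_m[,date,source]",
         call. = FALSE)
  occurrence_set(df$x, df$y, df$accuracy_m,
                 if ("date" %in% names(df)) df$date else rep(NA, nrow(df)),
                 if ("source" %in% names(df)) df$source else rep(NA, nrow(df)))
}

#' @rdname read_occurrences
#' @param occ an `occ_set`.
#' @export
write_occurrences <- function(occ, path) {
  df <- data.frame(x = occ$x, y = occ$y, accuracy_m = occ$accuracy,
                   date = occ$date, source = occ$source)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## run code under a seed without clobbering the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Clean occurrence records against a clearing mask and accuracy cutoff
#'
#' Drops records with positional accuracy worse than `max_accuracy` and
#' records whose containing cell is cleared (mask value truthy). Records
#' falling outside the mask extent are rejected and counted, not raised.
#'
#' @param records an `occ_set`.
#' @param cleared_mask `hs_raster` of 0/1 (1 = cleared); co-registered with
#'   the analysis grid.
#' @param max_accuracy accuracy cutoff in meters (default 100 m).
#' @return filtered `occ_set`, input order preserved; attribute
#'   `"n_outside"` counts out-of-extent rejections (also warned).
#' @export
clean_records <- function(records, cleared_mask, max_accuracy = 100) {
  stopifnot(max_accuracy > 0)
  if (nrow(records) == 0) return(records)
  v <- extract_values(cleared_mask, records$x, records$y)
  in_ext <- attr(v, "in_extent")
  n_out <- sum(!in_ext)
  if (n_out > 0)
    warning(sprintf("%d record(s) outside raster extent rejected", n_out),
            call. = FALSE)
  keep <- in_ext & !is.na(v) & v == 0 & records$accuracy <= max_accuracy
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_outside") <- n_out
  out
}

#' Split records into elevational subregions
#'
#' Subregion 1 holds records strictly below `threshold` m ASL; ties at the
#' threshold go to subregion 2. Records on nodata DEM cells or outside the
#' extent belong to neither and are counted.
#'
#' @param records an `occ_set`.
#' @param dem `hs_raster` of elevations in meters.
#' @param threshold elevation split in meters (default 500).
#' @return list with `low` (below), `high` (at/above), and `n_unassigned`.
#' @export
split_subregions <- function(records, dem, threshold = 500) {
  if (nrow(records) == 0)
    return(list(low = records, high = records, n_unassigned = 0L))
  z <- extract_values(dem, records$x, records$y)
  low <- !is.na(z) & z < threshold
  high <- !is.na(z) & z >= threshold
  n_un <- sum(is.na(z))
  if (n_un > 0)
    message(sprintf("%d record(s) on nodata DEM cells left unassigned", n_un))
  res <- list(low = records[low, , drop = FALSE],
              high = records[high, , drop = FALSE],
              n_unassigned = n_un)
  rownames(res$low) <- rownames(res$high) <- NULL
  res
}

#' Spatially thin records to a minimum pairwise distance
#'
#' Random-order greedy thinning: records are shuffled under `seed`, then
#' each is accepted iff it lies at least `min_dist` (inclusive) from every
#' previously accepted record. The result is maximal — every rejected
#' record is within `min_dist` of some retained one — and deterministic
#' given the seed.
#'
#' @param records an `occ_set`.
#' @param min_dist minimum separation in meters (default 2000).
#' @param seed integer RNG seed for the shuffle.
#' @return thinned `occ_set` (retains original row order among survivors);
#'   attribute `"kept"` gives the retained row indices of the input.
#' @export
thin_occurrences <- function(records, min_dist = 2000, seed = 1L) {
  stopifnot(min_dist > 0)
  n <- nrow(records)
  if (n <= 1) {
    attr(records, "kept") <- seq_len(n)
    return(records)
  }
  ord <- with_seed(seed, sample.int(n))
  xs <- records$x[ord]; ys <- records$y[ord]
  acc <- logical(n)
  ax <- numeric(0); ay <- numeric(0)
  d2 <- min_dist^2
  for (i in seq_len(n)) {
    if (length(ax) == 0L ||
        all((ax - xs[i])^2 + (ay - ys[i])^2 >= d2)) {
      acc[i] <- TRUE
      ax <- c(ax, xs[i]); ay <- c(ay, ys[i])
    }
  }
  kept <- sort(ord[acc])
  out <- records[kept, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "kept") <- kept
  out
}

#' Replicated thinning with a holdout set
#'
#' Runs `thin_occurrences` once per seed; the holdout is every record that
#' appears in none of the replicates (the model-evaluation set).
#'
#' @param records an `occ_set`.
#' @param n_rep number of replicates (default 5).
#' @param min_dist minimum separation in meters.
#' @param seeds integer vector of length `n_rep`; must be distinct.
#' @return list with `replicates` (list of `occ_set`), `holdout`,
#'   `min_dist`, `seeds`.
#' @export
make_replicates <- function(records, n_rep = 5, min_dist = 2000,
                            seeds = seq_len(n_rep)) {
  stopifnot(length(seeds) == n_rep)
  if (anyDuplicated(seeds))
    stop("duplicate seeds would produce coinciding replicates", call. = FALSE)
  reps <- lapply(seeds, function(s) thin_occurrences(records, min_dist, s))
  used <- sort(unique(unlist(lapply(reps, attr, "kept"))))
  hold_idx <- setdiff(seq_len(nrow(records)), used)
  holdout <- records[hold_idx, , drop = FALSE]
  rownames(holdout) <- NULL
  list(replicates = reps, holdout = holdout, min_dist = min_dist,
       seeds = seeds)
}

#' Screen continuous predictors for collinearity
#'
#' Greedy elimination in priority order: walking down `priority`, a layer is
#' retained iff its absolute Pearson correlation with every
#' already-retained continuous layer is at or below `threshold`.
#' Correlations use all cells valid in both layers. Categorical layers are
#' always retained; zero-variance layers are dropped with a warning.
#'
#' @param stack an `hs_stack`.
#' @param threshold absolute correlation cutoff (default 0.75; elimination
#'   applies when |r| exceeds it).
#' @param priority character vector ordering all continuous layer names,
#'   most biologically interpretable first.
#' @return character vector of retained layer names (continuous in priority
#'   order, then categorical).
#' @export
screen_predictors <- function(stack, threshold = 0.75, priority = NULL) {
  cont <- names(stack$kinds)[stack$kinds == "continuous"]
  cat_ <- sort(names(stack$kinds)[stack$kinds == "categorical"])
  if (is.null(priority)) priority <- sort(cont)
  if (!setequal(priority, cont))
    stop("priority must cover exactly the continuous layers", call. = FALSE)
  vals <- lapply(stack$layers[priority], function(l) as.vector(l$values))
  keep <- character(0)
  for (nm in priority) {
    v <- vals[[nm]]
    if (stats::sd(v, na.rm = TRUE) == 0 || all(is.na(v))) {
      warning("dropping constant layer '", nm, "'", call. = FALSE)
      next
    }
    ok <- TRUE
    for (k in keep) {
      r <- suppressWarnings(stats::cor(v, vals[[k]],
                                       use = "pairwise.complete.obs"))
      if (is.finite(r) && abs(r) > threshold) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, nm)
  }
  c(keep, cat_)
}
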