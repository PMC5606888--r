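#' Default pipeline configuration
#'
#' Every stochastic stage consumes a named seed derived from
#' `seed`, so two runs with equal configs produce equal outputs. Scale
#' knobs default to the published design (5 sets x 20 replicates, 10,000
#' background points, 65 sites x 7 nights); desk-scale runs override
#' them.
#'
#' @param input_dir directory holding the input bundle (see
#'   [simulate_bundle()]).
#' @param output_dir where stage outputs and manifests are written.
#' @param seed master integer seed.
#' @param ... overrides for any default entry.
#' @return a named list (class `run_config`).
#' @export
run_config <- function(input_dir, output_dir, seed = 1L, ...) {
  cfg <- list(
    input_dir = input_dir, output_dir = output_dir, seed = as.integer(seed),
    max_accuracy = 100, elevation_threshold = 500, min_dist = 2000,
    n_sets = 5, n_rep = 20, train_frac = 0.75,
    n_background = 10000, knots = 50, reg_multiplier = 2,
    max_iter = 1000, tol = 1e-5,
    bias_bandwidth = NULL,            # NULL -> 2 x cell size
    browse_weights = c(3, 2, 1, 0), diversity_bonus = 0.1,
    p_specs = c("psi(.),p(.)", "psi(.),p(trip)", "psi(.),p(rainfall)",
                "psi(.),p(topo)"),
    psi_covariates = c("suitability_250m", "habitat_quality", "topo",
                       "elevation"))
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  if (length(cfg$seed) != 1 || !is.finite(cfg$seed))
    stop("config must carry an integer seed", call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  s <- paste(deparse(unclass(cfg)), collapse = "")
  h <- 5381
  for (v in utf8ToInt(s)) h <- (h * 33 + v) %% 2147483647
  sprintf("%08x", h)
}

#' Simulate a complete input bundle
#'
#' Emits everything the pipeline reads, generated from a known truth:
#' predictor rasters (ESRI ASCII) including a DEM and a cleared-area
#' mask, focal and target-group occurrence CSVs sampled under an
#' urban-clustered observer bias, detection histories with covariates,
#' Point-Quarter transects with a browse-class map, and `truth.json`
#' plus the true suitability raster for recovery tests (pipeline code
#' never reads the truth files).
#'
#' @param dir output directory (created).
#' @param size landscape edge in cells (default 200).
#' @param n_presence focal records (default 800).
#' @param n_target target-group records for the bias surface (default
#'   800).
#' @param n_sites recorder deployments (default 65, 2 of which fail).
#' @param seed master integer seed.
#' @return `dir`, invisibly.
#' @export
simulate_bundle <- function(dir, size = 200, n_presence = 800,
                            n_target = 800, n_sites = 65, seed = 1L) {
  dir.create(file.path(dir, "stack"), recursive = TRUE, showWarnings = FALSE)
  land <- gen_landscape(size = size, seed = seed)
  stack <- land$stack
  truth <- land$truth
  cs <- truth$suitability$cellsize

  # DEM: smooth field scaled to 0-1000 m, added as a predictor
  dem_f <- with_seed(seed + 11L, grf_field(size, 16))
  dem <- hs_raster(1000 * (dem_f - min(dem_f)) / diff(range(dem_f)),
                   cellsize = cs)
  stack <- predictor_stack(c(stack$layers, list(dem = dem)),
                           c(stack$kinds, dem = "continuous"))

  # cleared areas: top decile of an independent smooth field
  clr_f <- with_seed(seed + 12L, grf_field(size, 8))
  cleared <- hs_raster(matrix(as.numeric(clr_f >= stats::quantile(clr_f,
                                                                  0.9)),
                              size, size), cellsize = cs)

  # observer bias: effort decays from an "urban" corner
  cc <- cell_centers(truth$suitability)
  ux <- 0.25 * size * cs; uy <- 0.25 * size * cs
  eff <- 1 + 29 * exp(-((cc$x - ux)^2 + (cc$y - uy)^2) /
                        (2 * (0.15 * size * cs)^2))
  observer <- hs_raster(matrix(eff, size, size), cellsize = cs)

  occ <- gen_occurrences(truth, n_presence, observer, seed = seed + 1L)
  flat <- truth; flat$suitability <- hs_raster(matrix(1, size, size),
                                               cellsize = cs)
  target <- gen_occurrences(flat, n_target, observer, seed = seed + 2L)

  hh <- gen_histories(truth, n_sites = n_sites, n_failed = 2L,
                      seed = seed + 3L)
  tr <- gen_transects(hh$sites[!hh$sites$failed,
                               c("site", "suitability")],
                      seed = seed + 4L)

  for (nm in names(stack$layers))
    write_raster(stack$layers[[nm]], file.path(dir, "stack",
                                               paste0(nm, ".asc")))
  jsonlite::write_json(as.list(stack$kinds),
                       file.path(dir, "stack", "kinds.json"),
                       auto_unbox = TRUE)
  write_raster(cleared, file.path(dir, "cleared.asc"))
  write_occurrences(occ, file.path(dir, "occurrences.csv"))
  write_occurrences(target, file.path(dir, "target_group.csv"))

  ok <- !hh$sites$failed
  y <- hh$history$y
  det <- data.frame(site = hh$sites$site[ok], y)
  names(det)[-1] <- paste0("night_", seq_len(ncol(y)))
  utils::write.csv(det, file.path(dir, "detections.csv"),
                   row.names = FALSE)
  utils::write.csv(cbind(site = hh$sites$site[ok],
                         hh$history$site_covariates,
                         x = hh$sites$x[ok], y = hh$sites$y[ok]),
                   file.path(dir, "site_covariates.csv"),
                   row.names = FALSE)
  rain <- data.frame(site = hh$sites$site[ok],
                     hh$history$occasion_covariates$rainfall)
  names(rain)[-1] <- paste0("night_", seq_len(ncol(y)))
  utils::write.csv(rain, file.path(dir, "rainfall.csv"), row.names = FALSE)
  utils::write.csv(tr, file.path(dir, "transects.csv"), row.names = FALSE)
  utils::write.csv(default_species_pool(),
                   file.path(dir, "browse_classes.csv"), row.names = FALSE)

  write_raster(truth$suitability, file.path(dir, "truth_suitability.asc"))
  jsonlite::write_json(list(coefficients = as.list(truth$coefficients),
                            psi_coef = hh$truth$psi_coef,
                            p_by_trip = hh$truth$p_by_trip,
                            stems_per_ha = attr(tr, "truth")$stems_per_ha,
                            seed = seed),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

read_bundle_stack <- function(dir) {
  kinds <- unlist(jsonlite::read_json(file.path(dir, "stack",
                                                "kinds.json"),
                                      simplifyVector = TRUE))
  layers <- lapply(names(kinds), function(nm)
    read_raster(file.path(dir, "stack", paste0(nm, ".asc"))))
  names(layers) <- names(kinds)
  predictor_stack(layers, kinds)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Sequencing: record cleaning -> elevational subregion split ->
#' replicated spatial thinning -> bias surface -> per-subregion maxent
#' (sets x replicates, averaged, mosaicked at the elevation threshold)
#' -> suitability-class frequency vs the holdout -> staged occupancy
#' model selection (detection structure first, then occupancy
#' covariates with the best detection structure) -> habitat-quality
#' index and its regression on suitability -> fitted-psi validation.
#' Every output directory carries a manifest with the config, its hash,
#' and per-stage record counts.
#'
#' @param cfg a `run_config`.
#' @return list of in-memory results (also written under
#'   `cfg$output_dir`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()

  stack <- stage("read", read_bundle_stack(cfg$input_dir))
  occ <- stage("read", read_occurrences(file.path(cfg$input_dir,
                                                  "occurrences.csv")))
  target <- stage("read", read_occurrences(file.path(cfg$input_dir,
                                                     "target_group.csv")))
  cleared <- stage("read", read_raster(file.path(cfg$input_dir,
                                                 "cleared.asc")))
  dem <- stack$layers$dem
  if (is.null(dem)) stop("pipeline stage 'read' failed: no dem layer",
                         call. = FALSE)

  clean <- stage("prep", clean_records(occ, cleared, cfg$max_accuracy))
  counts$n_raw <- nrow(occ); counts$n_clean <- nrow(clean)
  sub <- stage("prep", split_subregions(clean, dem,
                                        cfg$elevation_threshold))
  counts$n_sub1 <- nrow(sub$low); counts$n_sub2 <- nrow(sub$high)

  template <- hs_raster(ifelse(stack$mask, NA_real_, 1), stack$grid$xll,
                        stack$grid$yll, stack$grid$cellsize)
  bw <- if (is.null(cfg$bias_bandwidth)) 2 * template$cellsize else
    cfg$bias_bandwidth
  bias <- stage("bias",
                bias_surface(as_occ_set(rbind(as.data.frame(clean),
                                              as.data.frame(target))),
                             template, bw))
  write_raster(bias, file.path(cfg$output_dir, "bias.asc"))

  fit_subregion <- function(recs, label) {
    reps <- make_replicates(recs, cfg$n_sets, cfg$min_dist,
                            seeds = cfg$seed + seq_len(cfg$n_sets))
    maps <- list(); aucs <- c()
    for (s in seq_len(cfg$n_sets)) {
      rr <- run_replicates(reps$replicates[[s]], stack, bias,
                           n_rep = cfg$n_rep, train_frac = cfg$train_frac,
                           seed = cfg$seed + 100L * s,
                           n_background = cfg$n_background,
                           knots = cfg$knots,
                           reg_multiplier = cfg$reg_multiplier,
                           max_iter = cfg$max_iter, tol = cfg$tol)
      maps[[s]] <- rr$mean_map; aucs <- c(aucs, rr$auc)
    }
    list(map = average_sets(maps), auc = aucs, holdout = reps$holdout,
         sizes = vapply(reps$replicates, nrow, integer(1)))
  }
  r1 <- stage("maxent", fit_subregion(sub$low, "subregion1"))
  r2 <- stage("maxent", fit_subregion(sub$high, "subregion2"))
  counts$thinned_sub1 <- r1$sizes; counts$thinned_sub2 <- r2$sizes

  mosaic <- r1$map
  hi <- !is.na(dem$values) & dem$values >= cfg$elevation_threshold
  mosaic$values[hi] <- r2$map$values[hi]
  write_raster(mosaic, file.path(cfg$output_dir, "suitability.asc"))

  holdout <- as_occ_set(rbind(as.data.frame(r1$holdout),
                              as.data.frame(r2$holdout)))
  cf <- stage("classify", class_frequency(mosaic, holdout))
  utils::write.csv(cf, file.path(cfg$output_dir, "class_frequency.csv"),
                   row.names = FALSE)

  # -- field data ---------------------------------------------------------
  sites <- utils::read.csv(file.path(cfg$input_dir, "site_covariates.csv"),
                           stringsAsFactors = FALSE)
  det <- utils::read.csv(file.path(cfg$input_dir, "detections.csv"))
  rain <- utils::read.csv(file.path(cfg$input_dir, "rainfall.csv"))
  y <- as.matrix(det[, grep("^night_", names(det)), drop = FALSE])
  tr <- read_transects(file.path(cfg$input_dir, "transects.csv"))
  pool <- utils::read.csv(file.path(cfg$input_dir, "browse_classes.csv"),
                          stringsAsFactors = FALSE)
  browse <- stats::setNames(pool$class, pool$species)

  hq <- stage("hq-index",
              site_quality_indices(tr, browse, cfg$browse_weights,
                                   cfg$diversity_bonus))
  sites$habitat_quality <- hq$index[match(sites$site, hq$site)]
  sites$suitability_250m <- extract_values(mosaic, sites$x, sites$y)
  sites$trip <- factor(sites$trip)
  sc <- sites[, c("suitability_250m", "habitat_quality", "topo",
                  "elevation", "trip")]
  dh <- detection_history(y, sc,
                          list(rainfall = as.matrix(rain[, -1])))

  # stage 1: detection structure against a null, occupancy constant
  p_models <- lapply(cfg$p_specs, function(s) {
    f <- parse_model_spec(s); occu_fit(dh, f$psi, f$p)
  })
  t_p <- stage("fit-occupancy", selection_table(p_models, cfg$p_specs))
  best_p <- parse_model_spec(t_p$model[1])$p
  # stage 2: occupancy covariates with the selected detection structure
  psi_specs <- c("psi(.)", paste0("psi(", cfg$psi_covariates, ")"))
  psi_models <- lapply(c("~1", paste("~", cfg$psi_covariates)),
                       function(f) occu_fit(dh, stats::as.formula(f),
                                            best_p))
  t_psi <- stage("fit-occupancy",
                 selection_table(psi_models,
                                 paste0(psi_specs, ",p(",
                                        deparse(best_p[[2]]), ")")))
  utils::write.csv(t_p, file.path(cfg$output_dir,
                                  "selection_detection.csv"),
                   row.names = FALSE)
  utils::write.csv(t_psi, file.path(cfg$output_dir,
                                    "selection_occupancy.csv"),
                   row.names = FALSE)

  suit_mod <- occu_fit(dh, ~suitability_250m, best_p)
  fp <- fitted_psi(suit_mod)
  val <- stage("validate",
               correlate_validation(fp$psi, sc$suitability_250m))
  subreg <- ifelse(extract_values(dem, sites$x, sites$y) <
                     cfg$elevation_threshold, "subregion1", "subregion2")
  reg <- stage("validate",
               regress_index(sites$habitat_quality,
                             sites$suitability_250m, subreg))
  utils::write.csv(reg, file.path(cfg$output_dir, "hq_regression.csv"),
                   row.names = FALSE)

  manifest <- list(config = unclass(cfg), config_hash = config_hash(cfg),
                   counts = counts,
                   auc = list(subregion1 = r1$auc, subregion2 = r2$auc),
                   validation = val)
  jsonlite::write_json(manifest, file.path(cfg$output_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(map = mosaic, auc1 = r1$auc, auc2 = r2$auc,
                 class_frequency = cf, detection_table = t_p,
                 occupancy_table = t_psi, fitted = fp, validation = val,
                 hq = hq, hq_regression = reg, counts = counts,
                 manifest = manifest))
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (emit a synthetic input bundle), `run-all`
#' (full pipeline), and the single stages `prep`, `bias`, `fit-maxent`,
#' `classify`, `fit-occupancy`, `hq-index`, `validate` (each runs the
#' pipeline up to and including that stage on the bundle; staging is
#' cheap at desk scale). Options are `--key value` pairs matching
#' [run_config()] / [simulate_bundle()] arguments.
#'
#' @param args character vector (default `commandArgs(TRUE)`).
#' @return exit status, invisibly.
#' @export
habsuit_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: habsuit <simulate|run-all|prep|bias|fit-maxent|classify|",
        "fit-occupancy|hq-index|validate> [--key value ...]\n", sep = "")
    return(invisible(1L))
  }
  cmd <- args[1]
  kv <- list()
  i <- 2
  while (i < length(args) + 1) {
    if (startsWith(args[i], "--") && i < length(args)) {
      key <- sub("^--", "", args[i])
      val <- utils::type.convert(args[i + 1], as.is = TRUE)
      kv[[key]] <- val
      i <- i + 2
    } else i <- i + 1
  }
  if (cmd == "simulate") {
    if (is.null(kv$out)) stop("simulate needs --out DIR", call. = FALSE)
    do.call(simulate_bundle,
            c(list(dir = kv$out), kv[setdiff(names(kv), "out")]))
    message("bundle written to ", kv$out)
    return(invisible(0L))
  }
  if (cmd %in% c("run-all", "prep", "bias", "fit-maxent", "classify",
                 "fit-occupancy", "hq-index", "validate")) {
    if (is.null(kv$input) || is.null(kv$out))
      stop(cmd, " needs --input DIR --out DIR", call. = FALSE)
    cfg <- do.call(run_config,
                   c(list(input_dir = kv$input, output_dir = kv$out),
                     kv[setdiff(names(kv), c("input", "out"))]))
    run_pipeline(cfg)
    message("outputs written to ", kv$out)
    return(invisible(0L))
  }
  stop("unknown subcommand: ", cmd, call. = FALSE)
}
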