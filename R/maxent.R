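#' Hinge-feature basis for maximum-entropy modelling
#'
#' For each continuous variable, knots are placed at equally spaced
#' quantiles of the background sample (probabilities `(1:k)/(k+1)`, so one
#' knot sits at the median) and both hinge directions are emitted:
#' forward `max(0, (x - knot) / (x_max - knot))` and reverse
#' `max(0, (knot - x) / (knot - x_min))`, with `x_min`/`x_max` the
#' background range, so every feature is scaled to `[0, 1]` over the
#' background. Categorical variables contribute one 0/1 indicator per
#' level observed in the background. Variables constant over the
#' background emit no features (with a warning).
#'
#' @param background data.frame of predictor values at background points,
#'   one column per variable.
#' @param kinds named character vector (`"continuous"`/`"categorical"`)
#'   covering the columns of `background`.
#' @param knots knots per variable per hinge direction (default 50),
#'   capped by the number of distinct values.
#' @return object of class `hinge_basis`: a data.frame of feature
#'   descriptors (`var`, `type`, `knot`, `xmin`, `xmax`).
#' @export
build_features <- function(background, kinds = NULL, knots = 50) {
  stopifnot(knots >= 1, nrow(background) >= 2)
  if (is.null(kinds))
    kinds <- stats::setNames(rep("continuous", ncol(background)),
                             names(background))
  feats <- list()
  for (nm in names(background)) {
    x <- background[[nm]]
    x <- x[!is.na(x)]
    if (length(unique(x)) < 2) {
      warning("variable '", nm, "' constant over background; no features",
              call. = FALSE)
      next
    }
    if (kinds[[nm]] == "categorical") {
      for (lev in sort(unique(x)))
        feats[[length(feats) + 1L]] <-
          data.frame(var = nm, type = "cat", knot = lev,
                     xmin = NA_real_, xmax = NA_real_)
    } else {
      xmin <- min(x); xmax <- max(x)
      ks <- unique(stats::quantile(x, probs = seq_len(knots) / (knots + 1),
                                   names = FALSE, type = 7))
      fwd <- ks[ks < xmax]
      rev_ <- ks[ks > xmin]
      if (length(fwd))
        feats[[length(feats) + 1L]] <-
          data.frame(var = nm, type = "fwd", knot = fwd, xmin = xmin,
                     xmax = xmax)
      if (length(rev_))
        feats[[length(feats) + 1L]] <-
          data.frame(var = nm, type = "rev", knot = rev_, xmin = xmin,
                     xmax = xmax)
    }
  }
  if (!length(feats)) stop("no usable features", call. = FALSE)
  out <- do.call(rbind, feats)
  rownames(out) <- NULL
  class(out) <- c("hinge_basis", "data.frame")
  out
}

#' Evaluate a hinge basis at predictor rows
#' @param basis a `hinge_basis`.
#' @param data data.frame holding every variable the basis references.
#' @return numeric matrix, rows of `data` x features.
#' @export
eval_features <- function(basis, data) {
  n <- nrow(data)
  m <- matrix(0, n, nrow(basis))
  for (j in seq_len(nrow(basis))) {
    b <- basis[j, ]
    x <- data[[b$var]]
    m[, j] <- switch(b$type,
      fwd = pmax(0, (x - b$knot) / (b$xmax - b$knot)),
      rev = pmax(0, (b$knot - x) / (b$knot - b$xmin)),
      cat = as.numeric(x == b$knot))
  }
  colnames(m) <- paste(basis$var, basis$type, signif(basis$knot, 8), sep = ":")
  m
}

log_sum_exp <- function(x) {
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

#' Fit a regularized maximum-entropy presence-background model
#'
#' Minimizes the L1-regularized maxent log loss
#' `-(mean over presences of lambda . f) + log Z(lambda) +
#' sum_j beta_j |lambda_j|`, with `Z` the normalizer over the background
#' sample, by cyclic coordinate descent: each coordinate takes a
#' soft-thresholded proximal Newton step, halved (backtracking) until the
#' objective does not increase, so the objective is non-increasing at
#' every accepted step. Iteration stops when a full cycle improves the
#' objective by less than `tol`, or after `max_iter` cycles.
#'
#' Per-feature penalties follow the hinge default schedule
#' `beta_j = reg_multiplier * (0.5 / sqrt(m)) * s_j` with `m` the presence
#' count and `s_j` the feature's background standard deviation. Features
#' with zero background variance are frozen at zero weight.
#'
#' @param presence_feat,background_feat feature matrices from
#'   [eval_features()] for presence and background rows.
#' @param reg_multiplier L1 penalty multiplier (default 2).
#' @param max_iter maximum coordinate-descent cycles (default 1000).
#' @param tol convergence threshold on the per-cycle objective decrease
#'   (default 1e-5).
#' @param basis optional `hinge_basis` stored for later prediction.
#' @param feature_vars character vector mapping features to source
#'   variables (defaults to `basis$var`); used for percent contribution.
#' @return object of class `maxent_model`: weights `lambda`, penalties
#'   `beta`, log-normalizer `logZ`, entropy `H` of the raw background
#'   distribution, per-variable gain credits, objective trace.
#' @export
fit_maxent <- function(presence_feat, background_feat, reg_multiplier = 2,
                       max_iter = 1000, tol = 1e-5, basis = NULL,
                       feature_vars = NULL) {
  Fp <- as.matrix(presence_feat); Fb <- as.matrix(background_feat)
  if (nrow(Fp) < 1 || nrow(Fb) < 2)
    stop("need >= 1 presence and >= 2 background rows", call. = FALSE)
  if (!all(is.finite(Fp)) || !all(is.finite(Fb)))
    stop("non-finite feature values", call. = FALSE)
  stopifnot(ncol(Fp) == ncol(Fb))
  p <- ncol(Fb); m <- nrow(Fp); nb <- nrow(Fb)
  if (is.null(feature_vars))
    feature_vars <- if (!is.null(basis)) basis$var else rep("all", p)
  sj <- apply(Fb, 2, stats::sd)
  beta <- reg_multiplier * (0.5 / sqrt(m)) * sj
  active <- sj > 0
  pmean <- colMeans(Fp)
  lambda <- numeric(p)
  eta_b <- numeric(nb)
  logZ <- log(nb)
  w <- rep(1 / nb, nb)
  obj <- function(lz, lam, pm_dot) -pm_dot + lz + sum(beta * abs(lam))
  pm_dot <- 0
  cur <- obj(logZ, lambda, pm_dot)
  gain_credit <- stats::setNames(numeric(length(unique(feature_vars))),
                                 unique(feature_vars))
  trace_obj <- cur
  for (cycle in seq_len(max_iter)) {
    start <- cur
    for (j in which(active)) {
      fj <- Fb[, j]
      Ef <- sum(w * fj)
      g <- -pmean[j] + Ef
      if (lambda[j] == 0 && abs(g) <= beta[j]) next
      h <- sum(w * fj * fj) - Ef^2
      if (h < 1e-12) h <- 1e-12
      z <- lambda[j] - g / h
      lam_new <- sign(z) * max(abs(z) - beta[j] / h, 0)
      d <- lam_new - lambda[j]
      if (abs(d) < 1e-12) next
      accepted <- FALSE
      for (bt in 1:30) {
        lam_try <- lambda[j] + d
        eta_try <- eta_b + d * fj
        logZ_try <- log_sum_exp(eta_try)
        pm_try <- pm_dot + d * pmean[j]
        lam_vec <- lambda; lam_vec[j] <- lam_try
        new <- obj(logZ_try, lam_vec, pm_try)
        if (new <= cur + 1e-12) { accepted <- TRUE; break }
        d <- d / 2
      }
      if (!accepted) next
      gain_credit[feature_vars[j]] <-
        gain_credit[feature_vars[j]] + max(cur - new, 0)
      lambda[j] <- lambda[j] + d
      eta_b <- eta_b + d * fj
      logZ <- log_sum_exp(eta_b)
      w <- exp(eta_b - logZ)
      pm_dot <- pm_dot + d * pmean[j]
      cur <- obj(logZ, lambda, pm_dot)
    }
    trace_obj <- c(trace_obj, cur)
    if (start - cur < tol) break
  }
  q <- w
  H <- -sum(q * ifelse(q > 0, log(q), 0))
  structure(list(lambda = lambda, beta = beta, logZ = logZ, H = H,
                 pmean = pmean, basis = basis, feature_vars = feature_vars,
                 gain_credit = gain_credit, objective = trace_obj,
                 n_presence = m, n_background = nb,
                 reg_multiplier = reg_multiplier),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(paste0("<maxent_model: %d features (%d nonzero), %d presences,",
                     " %d background, H = %.4f>\n"),
              length(x$lambda), sum(x$lambda != 0), x$n_presence,
              x$n_background, x$H))
  invisible(x)
}

#' Raw and logistic maxent output
#'
#' The raw output is the normalized density
#' `q(x) = exp(lambda . f(x)) / Z`; the logistic transform is
#' `exp(H) q / (1 + exp(H) q)` with `H` the entropy of the raw
#' distribution over the background, so a cell with "typical" presence
#' environment scores about 0.5. Strictly increasing in `q`.
#'
#' @param model a `maxent_model`.
#' @param features feature matrix (or single row) from [eval_features()].
#' @return numeric vector of suitabilities in `[0, 1]`.
#' @export
logistic_output <- function(model, features) {
  q <- raw_output(model, features)
  eq <- exp(model$H) * q
  eq / (1 + eq)
}

#' @rdname logistic_output
#' @export
raw_output <- function(model, features) {
  features <- matrix(as.numeric(features), ncol = length(model$lambda))
  eta <- drop(features %*% model$lambda)
  exp(eta - model$logZ)
}

#' Predict suitability from predictor values
#' @param object a `maxent_model` fitted with a stored basis.
#' @param newdata data.frame of predictor values.
#' @param type `"logistic"` (default) or `"raw"`.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.maxent_model <- function(object, newdata,
                                 type = c("logistic", "raw"), ...) {
  type <- match.arg(type)
  if (is.null(object$basis))
    stop("model carries no feature basis; predict from feature rows instead",
         call. = FALSE)
  f <- eval_features(object$basis, newdata)
  if (type == "raw") raw_output(object, f) else logistic_output(object, f)
}

#' Sample background points weighted by survey effort
#'
#' Draws `n` cells with replacement from the template's non-nodata cells
#' with probability proportional to the bias weight, then returns their
#' cell-center coordinates. Deterministic given `seed`.
#'
#' @param grid template `hs_raster` (defines valid cells).
#' @param bias optional `hs_raster` of effort weights on the same grid;
#'   `NULL` for uniform sampling.
#' @param n number of background points (default 10000).
#' @param seed integer RNG seed.
#' @return data.frame with `x`, `y`, `cell` (column-major cell index).
#' @export
sample_background <- function(grid, bias = NULL, n = 10000, seed = 1L) {
  stopifnot(n >= 1)
  valid <- which(!is.na(as.vector(grid$values)))
  if (!length(valid)) stop("all-nodata grid", call. = FALSE)
  wt <- if (is.null(bias)) NULL else {
    assert_same_grid(grid, bias, "bias surface")
    as.vector(bias$values)[valid]
  }
  cells <- with_seed(seed, sample(valid, n, replace = TRUE, prob = wt))
  cc <- cell_centers(grid)
  data.frame(x = cc$x[cells], y = cc$y[cells], cell = cells)
}

#' Presence-background AUC with midrank tie handling
#'
#' Probability that a random presence score outranks a random background
#' score (ties counted half), i.e. the Mann-Whitney statistic scaled to
#' `[0, 1]`.
#'
#' @param pos,neg numeric score vectors for presences and background.
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(pos, neg) {
  stopifnot(length(pos) >= 1, length(neg) >= 1)
  r <- rank(c(pos, neg))
  np <- length(pos)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(neg))
}

#' Replicated train/test maxent runs
#'
#' For each replicate: a random 75/25 presence split, background sampled
#' under the bias surface, a maxent fit on the training presences, AUC of
#' the test presences against the background, and a logistic suitability
#' surface over the full grid. Returns the cellwise mean surface and the
#' per-replicate AUCs.
#'
#' @param records presence `occ_set` (records on masked cells are dropped).
#' @param stack predictor `hs_stack`.
#' @param bias optional bias `hs_raster` for background weighting.
#' @param n_rep replicates (default 20).
#' @param train_frac training fraction of presences (default 0.75).
#' @param seed integer; replicate r uses `seed + r` for its partition and
#'   background draw.
#' @param n_background background points per replicate (default 10000).
#' @param knots hinge knots per variable per direction (default 50).
#' @param reg_multiplier,max_iter,tol passed to [fit_maxent()].
#' @return list: `mean_map` (`hs_raster` in `[0,1]`), `auc` (length
#'   `n_rep`), `contribution` (mean percent contribution), `n_used`.
#' @export
run_replicates <- function(records, stack, bias = NULL, n_rep = 20,
                           train_frac = 0.75, seed = 1L,
                           n_background = 10000, knots = 50,
                           reg_multiplier = 2, max_iter = 1000, tol = 1e-5) {
  pv <- extract_stack(stack, records$x, records$y)
  ok <- stats::complete.cases(pv)
  pv <- pv[ok, , drop = FALSE]
  if (nrow(pv) < 4) stop("fewer than 4 usable presence records",
                         call. = FALSE)
  grid <- stack$layers[[1]]
  grid_mask <- hs_raster(ifelse(stack$mask, NA_real_, 1),
                         grid$xll, grid$yll, grid$cellsize)
  sm <- stack_matrix(stack)
  keep <- attr(sm, "cell_keep")
  cell_df <- as.data.frame(sm)
  n <- nrow(pv)
  n_train <- max(1L, floor(train_frac * n))
  if (n_train >= n) n_train <- n - 1L
  acc <- matrix(0, nrow(grid$values), ncol(grid$values))
  aucs <- numeric(n_rep)
  contribs <- NULL
  for (r in seq_len(n_rep)) {
    idx <- with_seed(seed + r, sample.int(n))
    tr <- idx[seq_len(n_train)]; te <- idx[-seq_len(n_train)]
    bg <- sample_background(grid_mask, bias, n_background,
                            seed = seed + 1000L + r)
    bg_df <- extract_stack(stack, bg$x, bg$y)
    basis <- build_features(bg_df, stack$kinds, knots)
    Fb <- eval_features(basis, bg_df)
    Fp <- eval_features(basis, pv[tr, , drop = FALSE])
    mod <- fit_maxent(Fp, Fb, reg_multiplier, max_iter, tol, basis = basis)
    Fte <- eval_features(basis, pv[te, , drop = FALSE])
    aucs[r] <- auc_mw(raw_output(mod, Fte), raw_output(mod, Fb))
    surf <- logistic_output(mod, eval_features(basis, cell_df))
    full <- rep(NA_real_, length(keep)); full[keep] <- surf
    acc <- acc + matrix(full, nrow(grid$values))
    pc <- percent_contribution(mod)
    contribs <- if (is.null(contribs)) pc else contribs + pc
  }
  list(mean_map = hs_raster(acc / n_rep, grid$xll, grid$yll, grid$cellsize),
       auc = aucs, contribution = contribs / n_rep, n_used = n)
}

#' Average suitability maps cellwise
#' @param maps list of co-registered `hs_raster` maps in `[0, 1]`.
#' @return `hs_raster`; nodata in any input propagates.
#' @export
average_sets <- function(maps) {
  stopifnot(length(maps) >= 1)
  ref <- maps[[1]]
  for (m in maps[-1]) assert_same_grid(ref, m, "suitability map")
  acc <- Reduce(`+`, lapply(maps, `[[`, "values")) / length(maps)
  hs_raster(acc, ref$xll, ref$yll, ref$cellsize)
}

#' Percent contribution of each predictor variable
#'
#' Credits every accepted coordinate-descent step's objective improvement
#' to the stepped feature's source variable and normalizes the totals to
#' sum to 100. If no step improved the objective the credit is split
#' evenly.
#'
#' @param model a `maxent_model`.
#' @return named numeric vector of percentages summing to 100.
#' @export
percent_contribution <- function(model) {
  g <- model$gain_credit
  if (sum(g) <= 0) return(stats::setNames(rep(100 / length(g), length(g)),
                                          names(g)))
  100 * g / sum(g)
}

#' Univariate response curve
#'
#' Fits a maxent model using only one variable's features and evaluates
#' the logistic output across a grid of its values — how suitability
#' responds when all other predictors are ignored.
#'
#' @param variable layer name.
#' @param records presence `occ_set`.
#' @param stack predictor `hs_stack`.
#' @param bias optional bias raster for the background draw.
#' @param values evaluation grid; default 100 points over the background
#'   range (or the observed levels for a categorical variable).
#' @param n_background,knots,reg_multiplier,seed as in [run_replicates()].
#' @return data.frame with `value` and `suitability`.
#' @export
response_curve <- function(variable, records, stack, bias = NULL,
                           values = NULL, n_background = 2000, knots = 50,
                           reg_multiplier = 2, seed = 1L) {
  stopifnot(variable %in% names(stack$layers))
  grid <- stack$layers[[1]]
  grid_mask <- hs_raster(ifelse(stack$mask, NA_real_, 1),
                         grid$xll, grid$yll, grid$cellsize)
  bg <- sample_background(grid_mask, bias, n_background, seed = seed)
  bg_df <- extract_stack(stack, bg$x, bg$y)[variable]
  pv <- extract_stack(stack, records$x, records$y)[variable]
  pv <- pv[stats::complete.cases(pv), , drop = FALSE]
  kinds <- stack$kinds[variable]
  basis <- build_features(bg_df, kinds, knots)
  mod <- fit_maxent(eval_features(basis, pv), eval_features(basis, bg_df),
                    reg_multiplier, basis = basis)
  if (is.null(values)) {
    values <- if (kinds[[variable]] == "categorical") {
      sort(unique(bg_df[[variable]]))
    } else {
      seq(min(bg_df[[variable]]), max(bg_df[[variable]]), length.out = 100)
    }
  }
  nd <- stats::setNames(data.frame(values), variable)
  data.frame(value = values, suitability = predict(mod, nd))
}

#' Suitability-class frequency of area and holdout records
#'
#' Classifies a suitability map into nine 0.1-wide classes
#' (`[0,0.1), ..., [0.8, max]` — the top class absorbs everything at or
#' above 0.8) and tabulates the percentage of non-nodata area and of
#' in-extent holdout records per class. Both columns sum to 100.
#'
#' @param map suitability `hs_raster` in `[0, 1]`.
#' @param holdout evaluation `occ_set` (records excluded from modelling).
#' @param bin_width class width (default 0.1; nine classes).
#' @return data.frame `class`, `lower`, `upper`, `pct_area`,
#'   `pct_records`, plus attribute `"n_excluded"` (records off-grid or on
#'   nodata).
#' @export
class_frequency <- function(map, holdout, bin_width = 0.1) {
  n_class <- 9L
  breaks <- c(seq(0, by = bin_width, length.out = n_class), Inf)
  v <- as.vector(map$values)
  v <- v[!is.na(v)]
  area_cl <- cut(v, breaks, right = FALSE, labels = FALSE)
  rv <- extract_values(map, holdout$x, holdout$y)
  n_excl <- sum(is.na(rv))
  rv <- rv[!is.na(rv)]
  rec_cl <- cut(rv, breaks, right = FALSE, labels = FALSE)
  pct <- function(cl, n) if (n == 0) rep(0, n_class) else
    100 * tabulate(cl, nbins = n_class) / n
  out <- data.frame(class = seq_len(n_class),
                    lower = breaks[seq_len(n_class)],
                    upper = c(breaks[2:n_class], 1),
                    pct_area = pct(area_cl, length(v)),
                    pct_records = pct(rec_cl, length(rv)))
  attr(out, "n_excluded") <- n_excl
  out
}

#' Serialize / restore a fitted maxent model as JSON
#'
#' Stores weights, penalties, basis, normalizer and entropy with full
#' precision so re-prediction is bit-identical.
#'
#' @param model a `maxent_model`.
#' @param path JSON path.
#' @return `read_maxent_model`: a `maxent_model`.
#' @export
write_maxent_model <- function(model, path) {
  obj <- model
  class(obj) <- NULL
  obj$basis <- if (!is.null(model$basis)) as.data.frame(model$basis) else NULL
  # doubles as 17-significant-digit strings: guarantees IEEE round-trip
  obj <- rapply(obj, function(x)
    if (is.double(x)) sprintf("%.17g", x) else x, how = "replace")
  jsonlite::write_json(obj, path, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_maxent_model
#' @export
read_maxent_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  num_fields <- c("lambda", "beta", "logZ", "H", "pmean", "gain_credit",
                  "objective")
  for (nm in intersect(num_fields, names(obj))) {
    nms <- names(obj[[nm]])
    obj[[nm]] <- stats::setNames(as.numeric(obj[[nm]]), nms)
  }
  if (!is.null(obj$basis)) {
    obj$basis <- as.data.frame(obj$basis)
    for (cl in c("knot", "xmin", "xmax"))
      obj$basis[[cl]] <- as.numeric(obj$basis[[cl]])
    class(obj$basis) <- c("hinge_basis", "data.frame")
  }
  class(obj) <- "maxent_model"
  obj
}
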