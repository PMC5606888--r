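#' Detection history container
#'
#' Binary site x occasion detection data with covariates, the sufficient
#' data for a single-season occupancy model. Missing occasions (`NA` in
#' `y`) contribute no factor to the likelihood.
#'
#' @param y integer matrix over `{0, 1, NA}`, sites x occasions; every
#'   site needs at least one non-missing occasion.
#' @param site_covariates data.frame of per-site covariates (one row per
#'   site); may include a categorical trip label used on the detection
#'   side.
#' @param occasion_covariates named list of site x occasion matrices
#'   (e.g. nightly rainfall).
#' @return object of class `det_history`.
#' @export
detection_history <- function(y, site_covariates = NULL,
                              occasion_covariates = NULL) {
  y <- as.matrix(y)
  stopifnot(all(y %in% c(0, 1) | is.na(y)))
  if (any(rowSums(!is.na(y)) == 0))
    stop("every site needs >= 1 non-missing occasion", call. = FALSE)
  if (is.null(site_covariates))
    site_covariates <- data.frame(row.names = seq_len(nrow(y)))
  stopifnot(nrow(site_covariates) == nrow(y))
  if (!is.null(occasion_covariates)) {
    for (nm in names(occasion_covariates))
      stopifnot(identical(dim(occasion_covariates[[nm]]), dim(y)))
  }
  structure(list(y = y, site_covariates = site_covariates,
                 occasion_covariates = occasion_covariates),
            class = "det_history")
}

#' @export
print.det_history <- function(x, ...) {
  cat(sprintf("<det_history: %d sites x %d occasions, naive occupancy %.3f>\n",
              nrow(x$y), ncol(x$y), naive_occupancy(x)))
  invisible(x)
}

#' Naive occupancy: fraction of sites with at least one detection
#' @param data a `det_history`.
#' @return proportion in `[0, 1]`.
#' @export
naive_occupancy <- function(data) {
  mean(rowSums(data$y == 1, na.rm = TRUE) > 0)
}

#' Read a detection-history CSV (`site,night_1..night_T`, 0/1/NA)
#' @param path CSV path.
#' @param site_covariates optional data.frame joined by row order.
#' @return a `det_history`.
#' @export
read_detection_history <- function(path, site_covariates = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  y <- as.matrix(df[, grep("^night_", names(df)), drop = FALSE])
  rownames(y) <- df$site
  detection_history(y, site_covariates)
}

## design matrices for the two linear predictors
occu_designs <- function(data, psi = ~1, p = ~1) {
  n <- nrow(data$y); t_ <- ncol(data$y)
  Xpsi <- stats::model.matrix(psi, data$site_covariates)
  long <- data$site_covariates[rep(seq_len(n), times = t_), , drop = FALSE]
  if (!is.null(data$occasion_covariates)) {
    for (nm in names(data$occasion_covariates))
      long[[nm]] <- as.vector(data$occasion_covariates[[nm]])
  }
  Xp <- stats::model.matrix(p, long)
  if (nrow(Xpsi) != n || nrow(Xp) != n * t_)
    stop("design covariates missing for some sites", call. = FALSE)
  list(Xpsi = Xpsi, Xp = Xp, n = n, t = t_)
}

#' Single-season occupancy likelihood with imperfect detection
#'
#' Site likelihood
#' `L_i = psi_i * prod_t p_it^y (1-p_it)^(1-y)  +  (1 - psi_i) * I[no
#' detections at i]`, with logit links on both occupancy `psi` and
#' per-occasion detection `p`; missing occasions are skipped. Returns
#' `-2 * sum(log L_i)`.
#'
#' @param params coefficient vector: psi block then p block, logit scale.
#' @param data a `det_history`.
#' @param psi,p model formulas over site / site-occasion covariates
#'   (default intercept-only `~1`).
#' @return scalar neg2LL.
#' @export
occu_likelihood <- function(params, data, psi = ~1, p = ~1) {
  d <- occu_designs(data, psi, p)
  occu_neg2ll_raw(params, data$y, d$Xpsi, d$Xp)
}

occu_neg2ll_raw <- function(params, y, Xpsi, Xp) {
  if (any(!is.finite(params))) return(Inf)
  kpsi <- ncol(Xpsi)
  psi_i <- stats::plogis(drop(Xpsi %*% params[seq_len(kpsi)]))
  p_it <- matrix(stats::plogis(drop(Xp %*% params[-seq_len(kpsi)])),
                 nrow = nrow(y))
  obs <- !is.na(y)
  lp_hist <- rowSums(ifelse(obs, log(ifelse(!obs | is.na(y), 1,
                                            ifelse(y == 1, p_it, 1 - p_it))),
                            0), na.rm = TRUE)
  detected <- rowSums(y == 1, na.rm = TRUE) > 0
  L <- psi_i * exp(lp_hist) + (1 - psi_i) * as.numeric(!detected)
  if (any(L <= 0)) return(Inf)
  -2 * sum(log(L))
}

## deterministic dispersed starting values (multimodal small-sample NLL)
default_starts <- function(npar, n_starts = 5) {
  offs <- c(0, -1, 1, -2, 2)[seq_len(n_starts)]
  t(vapply(offs, function(o) rep(o, npar), numeric(npar)))
}

#' Fit a single-season occupancy model by maximum likelihood
#'
#' Minimizes the neg2LL by quasi-Newton (BFGS) from several dispersed
#' deterministic starts and keeps the best optimum. The coefficient
#' covariance is the inverse observed information (numeric Hessian); a
#' non-invertible Hessian is flagged, not fatal.
#'
#' @param data a `det_history`.
#' @param psi,p model formulas (logit scale), e.g. `~ suitability`.
#' @param starts optional matrix of starting vectors (rows).
#' @param control passed to [stats::optim()].
#' @return object of class `occu_model`: `coef`, `neg2LL`, `k`, `AIC`,
#'   `vcov`, `vcov_ok`, the designs, and the data.
#' @export
occu_fit <- function(data, psi = ~1, p = ~1, starts = NULL,
                     control = list(maxit = 500, reltol = 1e-10)) {
  d <- occu_designs(data, psi, p)
  npar <- ncol(d$Xpsi) + ncol(d$Xp)
  if (is.null(starts)) starts <- default_starts(npar)
  fn <- function(par) occu_neg2ll_raw(par, data$y, d$Xpsi, d$Xp)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- try(stats::optim(starts[s, ], fn, method = "BFGS",
                            control = control), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all starts failed", call. = FALSE)
  hess <- stats::optimHess(best$par, fn)
  vc <- try(solve(hess / 2), silent = TRUE)   # I_obs = Hessian(neg2LL)/2
  vcov_ok <- !inherits(vc, "try-error") && all(is.finite(vc)) &&
    all(diag(vc) > 0)
  if (!vcov_ok) vc <- matrix(NA_real_, npar, npar)
  nm <- c(paste0("psi:", colnames(d$Xpsi)), paste0("p:", colnames(d$Xp)))
  structure(list(coef = stats::setNames(best$par, nm),
                 neg2LL = best$value, k = npar, AIC = best$value + 2 * npar,
                 vcov = vc, vcov_ok = vcov_ok, psi = psi, p = p,
                 k_psi = ncol(d$Xpsi), designs = d, data = data),
            class = "occu_model")
}

#' @export
print.occu_model <- function(x, ...) {
  cat(sprintf("<occu_model: psi(%s), p(%s); k = %d, neg2LL = %.3f, AIC = %.3f>\n",
              deparse(x$psi[[2]]), deparse(x$p[[2]]), x$k, x$neg2LL, x$AIC))
  print(round(x$coef, 4))
  invisible(x)
}

#' Parse a compact model-spec string like `psi(suitability),p(trip)`
#' @param spec string; `.` means intercept-only.
#' @return list of formulas `psi` and `p`.
#' @export
parse_model_spec <- function(spec) {
  m <- regmatches(spec, regexec("psi\\(([^)]*)\\)\\s*,\\s*p\\(([^)]*)\\)",
                                spec))[[1]]
  if (length(m) != 3) stop("cannot parse model spec: ", spec, call. = FALSE)
  to_f <- function(s) {
    s <- trimws(s)
    if (s == "." || s == "") ~1 else stats::as.formula(paste("~", s))
  }
  list(psi = to_f(m[2]), p = to_f(m[3]))
}

#' AIC model-selection table
#'
#' Ranks models by `AIC = neg2LL + 2k`; reports delta AIC, the model
#' likelihood `exp(-delta/2)`, normalized Akaike weights, and whether the
#' model falls within 2 AIC of the best (substantial support).
#'
#' @param models list of `occu_model` objects fitted to the same data, or
#'   a data.frame with columns `neg2LL` and `k` (e.g. transcribed from a
#'   published table).
#' @param labels model labels (defaults to `psi(...),p(...)` strings).
#' @return data.frame sorted by AIC with columns `model`, `AIC`,
#'   `delta_AIC`, `weight`, `model_likelihood`, `k`, `neg2LL`,
#'   `supported`.
#' @export
selection_table <- function(models, labels = NULL) {
  if (is.data.frame(models)) {
    neg2 <- models$neg2LL; k <- models$k
    if (is.null(labels)) labels <- models$model
  } else {
    fp <- lapply(models, function(m) m$data$y)
    if (!all(vapply(fp, identical, logical(1), fp[[1]])))
      stop("models were fitted to different data", call. = FALSE)
    neg2 <- vapply(models, `[[`, numeric(1), "neg2LL")
    k <- vapply(models, `[[`, numeric(1), "k")
    if (is.null(labels))
      labels <- vapply(models, function(m)
        sprintf("psi(%s),p(%s)", deparse(m$psi[[2]]), deparse(m$p[[2]])),
        character(1))
  }
  aic <- neg2 + 2 * k
  delta <- aic - min(aic)
  lik <- exp(-delta / 2)
  out <- data.frame(model = labels, AIC = aic, delta_AIC = delta,
                    weight = lik / sum(lik), model_likelihood = lik,
                    k = k, neg2LL = neg2, supported = delta < 2)
  out <- out[order(out$AIC), ]
  rownames(out) <- NULL
  out
}

## probability of every possible history for one cohort (psi, p vector)
history_probs <- function(psi, p) {
  t_ <- length(p)
  hist_mat <- as.matrix(expand.grid(rep(list(c(0, 1)), t_)))
  pr <- apply(hist_mat, 1, function(h) {
    cond <- prod(ifelse(h == 1, p, 1 - p))
    psi * cond + (1 - psi) * as.numeric(sum(h) == 0)
  })
  list(histories = hist_mat, prob = pr)
}

## Pearson chi-square over detection-history frequencies, cohorts pooled
## by identical (covariate row, missingness pattern)
occu_chi2 <- function(model, data = model$data) {
  d <- occu_designs(data, model$psi, model$p)
  kpsi <- model$k_psi
  psi_i <- stats::plogis(drop(d$Xpsi %*% model$coef[seq_len(kpsi)]))
  p_it <- matrix(stats::plogis(drop(d$Xp %*% model$coef[-seq_len(kpsi)])),
                 nrow = d$n)
  key <- apply(cbind(round(psi_i, 12), round(p_it, 12), is.na(data$y)), 1,
               paste, collapse = "|")
  chi2 <- 0
  for (k in unique(key)) {
    sites <- which(key == k)
    obs_idx <- which(!is.na(data$y[sites[1], ]))
    hp <- history_probs(psi_i[sites[1]], p_it[sites[1], obs_idx])
    obs_h <- apply(data$y[sites, obs_idx, drop = FALSE], 1, paste,
                   collapse = "")
    all_h <- apply(hp$histories, 1, paste, collapse = "")
    O <- as.numeric(table(factor(obs_h, levels = all_h)))
    E <- length(sites) * hp$prob
    chi2 <- chi2 + sum((O - E)^2 / E)
  }
  chi2
}

#' Parametric-bootstrap goodness of fit (MacKenzie-Bailey style)
#'
#' Computes the Pearson chi-squared statistic over observed vs expected
#' detection-history frequencies (sites pooled into cohorts sharing a
#' covariate and missingness pattern; with continuous covariates each
#' site is its own cohort), then simulates `n_boot` datasets from the
#' fitted model, refits, and recomputes the statistic. The p-value is the
#' bootstrap fraction at or above the observed statistic and the
#' overdispersion factor is `c_hat = observed / mean(bootstrap)`.
#'
#' @param model a fitted `occu_model`.
#' @param data the `det_history` (defaults to the model's data).
#' @param n_boot bootstrap replicates (>= 2).
#' @param seed integer RNG seed; results are deterministic given it.
#' @return list: `chi2`, `p_value`, `c_hat`, `boot` (the bootstrap
#'   statistics).
#' @export
gof_bootstrap <- function(model, data = model$data, n_boot = 100,
                          seed = 1L) {
  if (n_boot < 2) stop("n_boot must be >= 2", call. = FALSE)
  obs <- occu_chi2(model, data)
  d <- model$designs
  kpsi <- model$k_psi
  psi_i <- stats::plogis(drop(d$Xpsi %*% model$coef[seq_len(kpsi)]))
  p_it <- matrix(stats::plogis(drop(d$Xp %*% model$coef[-seq_len(kpsi)])),
                 nrow = d$n)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      z <- stats::rbinom(d$n, 1, psi_i)
      ysim <- matrix(stats::rbinom(d$n * d$t, 1, as.vector(p_it)),
                     nrow = d$n) * z
      ysim[is.na(data$y)] <- NA
      ok <- rowSums(!is.na(ysim)) > 0
      sim <- detection_history(ysim[ok, , drop = FALSE],
                               data$site_covariates[ok, , drop = FALSE],
                               lapply(data$occasion_covariates,
                                      function(m) m[ok, , drop = FALSE]))
      refit <- occu_fit(sim, model$psi, model$p,
                        starts = matrix(model$coef, nrow = 1))
      occu_chi2(refit, sim)
    }, numeric(1))
  })
  list(chi2 = obs, p_value = mean(boot >= obs), c_hat = obs / mean(boot),
       boot = boot)
}

#' Fitted occupancy probabilities with delta-method intervals
#'
#' Evaluates the occupancy linear predictor at new covariate values and
#' back-transforms; 95% intervals are computed on the logit scale from
#' the coefficient covariance and then inverse-logit transformed.
#'
#' @param model a fitted `occu_model`.
#' @param covariate_values data.frame of site covariates (defaults to the
#'   model's own sites).
#' @return data.frame `psi`, `lower`, `upper`, `se_logit`.
#' @export
fitted_psi <- function(model, covariate_values = NULL) {
  if (is.null(covariate_values))
    covariate_values <- model$data$site_covariates
  X <- stats::model.matrix(model$psi, covariate_values)
  if (nrow(X) != nrow(covariate_values))
    stop("missing covariate values for some rows", call. = FALSE)
  b <- model$coef[seq_len(model$k_psi)]
  eta <- drop(X %*% b)
  V <- model$vcov[seq_len(model$k_psi), seq_len(model$k_psi), drop = FALSE]
  se <- sqrt(pmax(rowSums((X %*% V) * X), 0))
  zc <- stats::qnorm(0.975)
  data.frame(psi = stats::plogis(eta),
             lower = stats::plogis(eta - zc * se),
             upper = stats::plogis(eta + zc * se),
             se_logit = se)
}

#' Pearson correlation between fitted occupancy and modelled suitability
#'
#' @param fitted per-site fitted psi values.
#' @param suitability per-site suitability values.
#' @return list: `r`, `p_value`, `df` (= n - 2), `n`.
#' @export
correlate_validation <- function(fitted, suitability) {
  stopifnot(length(fitted) == length(suitability), length(fitted) >= 3)
  if (stats::sd(fitted) == 0 || stats::sd(suitability) == 0)
    stop("zero variance in fitted or suitability values", call. = FALSE)
  ct <- stats::cor.test(fitted, suitability)
  list(r = unname(ct$estimate), p_value = ct$p.value,
       df = unname(ct$parameter), n = length(fitted))
}
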