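test_that("site likelihood matches closed-form hand arithmetic", {
  # 1 site, 1 occasion, y = 1, psi = p = 0.5 -> L = 0.25
  d1 <- toy_history(matrix(1, 1, 1))
  expect_equal(occu_likelihood(c(0, 0), d1), -2 * log(0.25))
  # 1 site, 2 occasions, y = (0,0) -> L = 0.5 * 0.25 + 0.5 = 0.625
  d2 <- toy_history(matrix(0, 1, 2))
  expect_equal(occu_likelihood(c(0, 0), d2), -2 * log(0.625))
  # missing occasions contribute no factor: y = (1, NA) equals y = (1)
  d3 <- toy_history(matrix(c(1, NA), 1, 2))
  expect_equal(occu_likelihood(c(0.3, -0.2), d3),
               occu_likelihood(c(0.3, -0.2), toy_history(matrix(1, 1, 1))))
})

test_that("history probabilities over all 2^7 outcomes sum to one", {
  set.seed(10)
  for (i in 1:20) {
    psi <- runif(1, 0.05, 0.95); p <- runif(7, 0.05, 0.95)
    hp <- habsuit:::history_probs(psi, p)
    expect_equal(sum(hp$prob), 1, tolerance = 1e-10)
  }
})

test_that("intercept-only MLE matches the 2-D grid-search oracle", {
  set.seed(21)
  y <- matrix(rbinom(12 * 5, 1, 0.4), 12, 5) *
    rbinom(12, 1, 0.6)
  fit <- occu_fit(toy_history(y))
  oracle <- occu_grid_oracle(y, step = 1e-3)
  expect_equal(plogis(fit$coef[[1]]), oracle[["psi"]], tolerance = 2e-3)
  expect_equal(plogis(fit$coef[[2]]), oracle[["p"]], tolerance = 2e-3)
  expect_lte(fit$neg2LL, oracle[["neg2LL"]] + 1e-6)
})

test_that("perfect detection collapses to naive occupancy", {
  y <- rbind(matrix(1, 6, 4), matrix(0, 4, 4))
  fit <- occu_fit(toy_history(y))
  expect_equal(plogis(fit$coef[[1]]), 0.6, tolerance = 1e-3)
  expect_gt(plogis(fit$coef[[2]]), 0.99)
})

test_that("simulation recovery at the published design scale", {
  # psi = 0.5, p = 0.32, 1000 sites x 7 nights
  set.seed(33)
  z <- rbinom(1000, 1, 0.5)
  y <- matrix(rbinom(7000, 1, 0.32), 1000, 7) * z
  fit <- occu_fit(toy_history(y))
  expect_lt(abs(plogis(fit$coef[[1]]) - 0.5), 0.05)
  expect_lt(abs(plogis(fit$coef[[2]]) - 0.32), 0.05)
})

test_that("selection table reproduces the published arithmetic", {
  # printed (-2LL, k) cells are inputs; AIC/delta/likelihood recomputed
  tab2 <- data.frame(model = c("psi(.),p(.)", "psi(.),p(trip)",
                               "psi(.),p(rainfall)", "psi(.),p(topo)"),
                     neg2LL = c(234.74, 236.22, 242.12, 249.2),
                     k = c(2, 2, 2, 2))
  st <- selection_table(tab2)
  expect_equal(st$AIC, c(238.74, 240.22, 246.12, 253.2))
  expect_equal(st$delta_AIC, c(0, 1.48, 7.38, 14.46))
  expect_equal(round(st$model_likelihood, 4), c(1, 0.4771, 0.025, 7e-04))
  expect_equal(st$supported, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sum(st$weight), 1, tolerance = 1e-9)
  # symmetric case: identical models split the weight
  two <- selection_table(data.frame(neg2LL = c(10, 10), k = c(1, 1),
                                    model = c("a", "b")))
  expect_equal(two$weight, c(0.5, 0.5))
})

test_that("selection table refuses models fitted to different data", {
  set.seed(3)
  y1 <- matrix(rbinom(40, 1, 0.5), 10, 4)
  y2 <- matrix(rbinom(40, 1, 0.5), 10, 4)
  m1 <- occu_fit(toy_history(y1))
  m2 <- occu_fit(toy_history(y2))
  expect_error(selection_table(list(m1, m2)), "different data")
  expect_s3_class(selection_table(list(m1, occu_fit(toy_history(y1)))),
                  "data.frame")
})

test_that("covariate models run through formulas and model-spec strings", {
  set.seed(14)
  land_s <- runif(40)
  z <- rbinom(40, 1, plogis(-1 + 3 * land_s))
  y <- matrix(rbinom(40 * 5, 1, 0.5), 40, 5) * z
  dh <- toy_history(y, site_covariates = data.frame(suit = land_s))
  spec <- parse_model_spec("psi(suit),p(.)")
  fit <- occu_fit(dh, spec$psi, spec$p)
  expect_equal(fit$k, 3)
  expect_gt(fit$coef[["psi:suit"]], 0)
  expect_error(parse_model_spec("nonsense"), "cannot parse")
})

test_that("gof bootstrap is deterministic and zero for a perfect fit", {
  set.seed(55)
  z <- rbinom(40, 1, 0.6)
  y <- matrix(rbinom(40 * 5, 1, 0.45), 40, 5) * z
  dh <- toy_history(y)
  fit <- occu_fit(dh)
  g1 <- gof_bootstrap(fit, n_boot = 20, seed = 7)
  g2 <- gof_bootstrap(fit, n_boot = 20, seed = 7)
  expect_identical(g1[c("chi2", "p_value", "c_hat")],
                   g2[c("chi2", "p_value", "c_hat")])
  expect_gt(g1$chi2, 0)
  expect_true(g1$p_value >= 0 && g1$p_value <= 1)
  expect_error(gof_bootstrap(fit, n_boot = 1), "n_boot")
})

test_that("fitted_psi applies the logit link and the delta method", {
  # zero coefficients -> psi = 0.5 everywhere
  mod0 <- structure(list(coef = c("psi:(Intercept)" = 0,
                                  "psi:x" = 0, "p:(Intercept)" = 0),
                         vcov = diag(3) * 0.04, k_psi = 2, psi = ~x,
                         data = list(site_covariates =
                                       data.frame(x = c(-1, 0, 2)))),
                    class = "occu_model")
  fp <- fitted_psi(mod0)
  expect_equal(fp$psi, rep(0.5, 3))
  # beta = (0, 1): covariate 0 -> 0.5; large covariate -> 1
  mod1 <- mod0; mod1$coef[1:2] <- c(0, 1)
  expect_equal(fitted_psi(mod1, data.frame(x = 0))$psi, 0.5)
  expect_gt(fitted_psi(mod1, data.frame(x = 50))$psi, 0.999)
  # delta method by hand: se = sqrt(x' V x) on the logit scale
  X <- c(1, 2)
  V <- matrix(c(0.04, 0.01, 0.01, 0.09), 2)
  mod2 <- mod0; mod2$coef[1:2] <- c(-0.5, 0.8)
  mod2$vcov[1:2, 1:2] <- V
  fp2 <- fitted_psi(mod2, data.frame(x = 2))
  se <- sqrt(drop(t(X) %*% V %*% X))
  eta <- -0.5 + 0.8 * 2
  expect_equal(fp2$se_logit, se)
  expect_equal(fp2$lower, plogis(eta - qnorm(0.975) * se))
  expect_equal(fp2$upper, plogis(eta + qnorm(0.975) * se))
})

test_that("validation correlation matches the manual formula", {
  x <- c(0.1, 0.3, 0.4, 0.8, 0.9)
  y <- c(0.2, 0.2, 0.5, 0.7, 1.0)
  v <- correlate_validation(y, x)
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(v$r, r_manual)
  expect_equal(v$df, 3)
  expect_equal(correlate_validation(x, x)$r, 1)
  set.seed(6)
  big <- correlate_validation(rnorm(1000), rnorm(1000))
  expect_lt(abs(big$r), 0.1)
  expect_error(correlate_validation(rep(1, 5), 1:5), "zero variance")
})
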