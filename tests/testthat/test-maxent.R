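# small presence/background fixture with a known 1-D signal
signal_fixture <- function(n_bg = 400, n_pres = 80, seed = 1) {
  set.seed(seed)
  bg <- data.frame(v = runif(n_bg), w = runif(n_bg))
  pres <- data.frame(v = rbeta(n_pres, 5, 1.2), w = runif(n_pres))
  list(bg = bg, pres = pres)
}

test_that("hinge knots sit at background quantiles and scale to [0,1]", {
  bg <- data.frame(v = seq(0, 1, length.out = 101))
  basis <- build_features(bg, knots = 1)
  expect_equal(nrow(basis), 2)          # one forward + one reverse hinge
  expect_equal(basis$knot, c(0.5, 0.5))
  f <- eval_features(basis, data.frame(v = 0.75))
  expect_equal(f[1, basis$type == "fwd"], 0.5, ignore_attr = TRUE)
  expect_equal(f[1, basis$type == "rev"], 0, ignore_attr = TRUE)
  # feature values over the background live in [0,1]
  fb <- eval_features(basis, bg)
  expect_true(all(fb >= 0 & fb <= 1))
})

test_that("hinge features match hand-computed values at probe points", {
  bg <- data.frame(v = c(0, 1, 2, 3, 4, 5, 6, 7, 8, 10))
  basis <- build_features(bg, knots = 3)
  # type-7 quantiles of bg at probs .25/.5/.75: 2.25, 4.5, 6.75
  expect_equal(sort(unique(basis$knot)), c(2.25, 4.5, 6.75))
  probe <- data.frame(v = c(0, 3, 7, 10))
  f <- eval_features(basis, probe)
  fwd <- function(x, k) pmax(0, (x - k) / (10 - k))
  rev_ <- function(x, k) pmax(0, (k - x) / (k - 0))
  for (j in seq_len(nrow(basis))) {
    expected <- if (basis$type[j] == "fwd") fwd(probe$v, basis$knot[j])
    else rev_(probe$v, basis$knot[j])
    expect_equal(f[, j], expected, ignore_attr = TRUE)
  }
})

test_that("categorical variables emit one indicator per observed level", {
  bg <- data.frame(soil = c(1, 2, 2, 5, 5, 5))
  basis <- build_features(bg, kinds = c(soil = "categorical"))
  expect_equal(nrow(basis), 3)
  f <- eval_features(basis, data.frame(soil = c(5, 1)))
  expect_equal(rowSums(f), c(1, 1))
  expect_equal(f[1, basis$knot == 5], 1, ignore_attr = TRUE)
})

test_that("constant variables emit no features, with a warning", {
  bg <- data.frame(a = runif(50), b = rep(2, 50))
  expect_warning(basis <- build_features(bg, knots = 3), "constant")
  expect_true(all(basis$var == "a"))
})

test_that("full shrinkage yields the uniform raw distribution", {
  fx <- signal_fixture()
  basis <- build_features(fx$bg, knots = 5)
  mod <- fit_maxent(eval_features(basis, fx$pres),
                    eval_features(basis, fx$bg), reg_multiplier = 1e6)
  expect_true(all(mod$lambda == 0))
  expect_equal(mod$H, log(nrow(fx$bg)))
  q <- raw_output(mod, eval_features(basis, fx$bg))
  expect_equal(q, rep(1 / nrow(fx$bg), nrow(fx$bg)))
})

test_that("single-feature fit matches a 1-D brute-force grid search", {
  # single binary feature: presences all 1, background half 1
  Fp <- matrix(1, 40, 1)
  Fb <- matrix(rep(c(0, 1), 100), ncol = 1)
  mod <- fit_maxent(Fp, Fb, reg_multiplier = 2)
  beta <- mod$beta[1]
  obj <- function(l) -l + log(sum(exp(l * Fb[, 1]))) + beta * abs(l)
  grid <- seq(0, 6, by = 1e-4)
  l_star <- grid[which.min(vapply(grid, obj, numeric(1)))]
  expect_equal(mod$lambda[1], l_star, tolerance = 1e-3)
})

test_that("objective is non-increasing and raw probabilities sum to 1", {
  fx <- signal_fixture(seed = 3)
  basis <- build_features(fx$bg, knots = 10)
  Fb <- eval_features(basis, fx$bg)
  mod <- fit_maxent(eval_features(basis, fx$pres[1:50, , drop = FALSE]),
                    Fb, basis = basis)
  expect_true(all(diff(mod$objective) <= 1e-12))
  expect_equal(sum(raw_output(mod, Fb)), 1, tolerance = 1e-8)
  expect_gte(mod$H, 0)
})

test_that("logistic output follows the entropy calibration exactly", {
  # hand-built model: 1 feature, lambda = 1, 3 background values
  f_bg <- matrix(c(0, 0.5, 1), ncol = 1)
  Z <- sum(exp(f_bg))
  q <- exp(f_bg) / Z
  H <- -sum(q * log(q))
  mod <- structure(list(lambda = 1, logZ = log(Z), H = H),
                   class = "maxent_model")
  got <- logistic_output(mod, matrix(0.5))
  qx <- exp(0.5) / Z
  expect_equal(got, exp(H) * qx / (1 + exp(H) * qx))
  # q -> 0 gives 0; q = exp(-H) gives exactly 0.5
  expect_equal(logistic_output(mod, matrix(-1e6)), 0)
  f_half <- log(exp(-H)) + log(Z)       # feature value with q = exp(-H)
  expect_equal(logistic_output(mod, matrix(f_half)), 0.5)
  # strictly increasing in the raw density
  vals <- logistic_output(mod, matrix(seq(0, 1, 0.1)))
  expect_true(all(diff(vals) > 0))
})

test_that("background sampling follows the bias weights", {
  g <- hs_raster(matrix(1, 1, 2), cellsize = 100)
  b <- hs_raster(matrix(c(30, 1), 1, 2), cellsize = 100)
  bg <- sample_background(g, b, n = 10000, seed = 4)
  frac <- mean(bg$cell == 1)
  p <- 30 / 31
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 10000))
  # determinism and uniform fallback
  expect_identical(sample_background(g, b, 100, seed = 9),
                   sample_background(g, b, 100, seed = 9))
  u <- sample_background(g, NULL, 10000, seed = 5)
  expect_lt(abs(mean(u$cell == 1) - 0.5), 0.02)
  expect_error(sample_background(hs_raster(matrix(NA_real_, 2, 2)), NULL, 5),
               "all-nodata")
})

test_that("AUC uses midranks and degenerate scores give 0.5", {
  expect_equal(auc_mw(c(2, 3), c(1, 1)), 1)
  expect_equal(auc_mw(c(1, 1), c(1, 1)), 0.5)
  # hand value: pairs (3,2)=1, (3,1)=1, (1,2)=0, (1,1)=0.5 -> 2.5/4
  expect_equal(auc_mw(c(3, 1), c(2, 1)), 0.625)
})

test_that("average_sets is the cellwise mean with nodata propagation", {
  a <- toy_raster(0.2, 3); b <- toy_raster(0.6, 3)
  expect_equal(average_sets(list(a, b))$values, matrix(0.4, 3, 3))
  expect_equal(average_sets(list(a, a))$values, a$values)
  set.seed(8)
  maps <- lapply(1:5, function(i) toy_raster(runif(9), 3))
  manual <- Reduce(`+`, lapply(maps, `[[`, "values")) / 5
  expect_equal(average_sets(maps)$values, manual)
  a$values[1, 1] <- NA
  expect_true(is.na(average_sets(list(a, b))$values[1, 1]))
})

test_that("percent contribution is normalized and credits the signal", {
  fx <- signal_fixture(seed = 5)
  basis <- build_features(fx$bg, knots = 8)
  mod <- fit_maxent(eval_features(basis, fx$pres),
                    eval_features(basis, fx$bg), basis = basis)
  pc <- percent_contribution(mod)
  expect_equal(sum(pc), 100, tolerance = 1e-9)
  # v carries all the signal, w none
  expect_gt(pc[["v"]], 90)
  # single-variable model: everything on that variable
  b1 <- build_features(fx$bg["v"], knots = 8)
  m1 <- fit_maxent(eval_features(b1, fx$pres["v"]),
                   eval_features(b1, fx$bg["v"]), basis = b1)
  expect_equal(unname(percent_contribution(m1)), 100)
})

test_that("class_frequency matches a hand tally and sums to 100", {
  m <- hs_raster(matrix(c(0.05, 0.15, 0.65, 0.65, 0.85, 0.95,
                          0.41, 0.49, 0.85, NA), 2, 5), cellsize = 100)
  # 9 valid cells: classes 1,2,7,7,9,9,5,5,9
  occ <- occurrence_set(x = c(50, 50, 150, 450, 1950),
                        y = c(150, 50, 150, 150, 150))
  # in-extent records hit cells 0.05, 0.15, 0.65, 0.85 (classes 1,2,7,9);
  # the last point lies off-grid and is excluded
  cf <- class_frequency(m, occ)
  expect_equal(sum(cf$pct_area), 100, tolerance = 1e-9)
  expect_equal(sum(cf$pct_records), 100, tolerance = 1e-9)
  expect_equal(cf$pct_records[c(1, 2, 7, 9)], rep(25, 4))
  expect_equal(attr(cf, "n_excluded"), 1)
  expect_equal(cf$pct_area[c(1, 2, 5, 7, 9)],
               100 * c(1, 1, 2, 2, 3) / 9)
  # uniform map: all area and records in class 7
  u <- toy_raster(0.65, 3)
  cfu <- class_frequency(u, occurrence_set(x = c(50, 150), y = c(50, 50)))
  expect_equal(cfu$pct_area[7], 100)
  expect_equal(cfu$pct_records[7], 100)
  # top bin is closed: value 1.0 lands in class 9
  t9 <- class_frequency(toy_raster(1, 3), occurrence_set(x = 50, y = 50))
  expect_equal(t9$pct_area[9], 100)
})

test_that("model JSON serialization re-predicts bit-identically", {
  fx <- signal_fixture(seed = 7)
  basis <- build_features(fx$bg, knots = 6)
  mod <- fit_maxent(eval_features(basis, fx$pres),
                    eval_features(basis, fx$bg), basis = basis)
  path <- withr::local_tempfile(fileext = ".json")
  write_maxent_model(mod, path)
  back <- read_maxent_model(path)
  nd <- data.frame(v = seq(0, 1, 0.05), w = seq(1, 0, -0.05))
  expect_identical(predict(mod, nd), predict(back, nd))
})

test_that("non-finite features are rejected before optimization", {
  expect_error(fit_maxent(matrix(NA_real_, 2, 1), matrix(0, 4, 1)),
               "non-finite")
})
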