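test_that("clean_records applies the clearing mask and accuracy filter", {
  # 5x5 toy mask, 100-m cells: cleared cells chosen by hand
  mask <- toy_raster(0, n = 5)
  mask$values[cbind(c(1, 3, 5), c(2, 3, 1))] <- 1
  # 10 records: 3 land in cleared cells, 1 has accuracy 250 m -> 6 retained
  occ <- occurrence_set(
    x = c(150, 250, 50, 350, 450, 150, 250, 350, 50, 450),
    y = c(450, 250, 50, 350, 150, 250, 450, 50, 350, 450),
    accuracy = c(50, 50, 50, 50, 50, 250, 50, 50, 50, 50))
  # cleared: (150,450)->row1 col2; (250,250)->row3 col3; (50,50)->row5 col1
  out <- clean_records(occ, mask)
  expect_equal(nrow(out), 6)
  expect_true(all(out$accuracy <= 100))
  # order preserved
  expect_equal(out$x, c(350, 450, 250, 350, 50, 450))

  expect_equal(nrow(clean_records(occurrence_set(), mask)), 0)
})

test_that("out-of-extent records are rejected with a warning, not an error", {
  mask <- toy_raster(0, n = 5)
  occ <- occurrence_set(x = c(50, 5000), y = c(50, 50))
  expect_warning(out <- clean_records(occ, mask), "1 record")
  expect_equal(nrow(out), 1)
  expect_equal(attr(out, "n_outside"), 1)
})

test_that("subregion split is exhaustive with ties going upslope", {
  dem <- toy_raster(rep(c(499, 500, 510, 100, 900), 5), n = 5)
  cc <- cell_centers(dem)
  occ <- occurrence_set(x = cc$x, y = cc$y)
  sp <- split_subregions(occ, dem, 500)
  z <- extract_values(dem, occ$x, occ$y)
  expect_equal(nrow(sp$low), sum(z < 500))
  expect_equal(nrow(sp$high), sum(z >= 500))
  expect_equal(nrow(sp$low) + nrow(sp$high) + sp$n_unassigned, nrow(occ))
  # boundary convention: 499 below, 500 at/above
  one <- split_subregions(occurrence_set(x = c(50, 50), y = c(450, 350)),
                          dem)  # DEM 499 vs exactly 500
  expect_equal(c(nrow(one$low), nrow(one$high)), c(1, 1))
})

test_that("records on nodata DEM cells are assigned to neither", {
  dem <- toy_raster(600, n = 3)
  dem$values[1, 1] <- NA
  occ <- occurrence_set(x = c(50, 150), y = c(250, 250))
  expect_message(sp <- split_subregions(occ, dem), "1 record")
  expect_equal(sp$n_unassigned, 1)
  expect_equal(nrow(sp$high), 1)
})

test_that("thinning boundary is inclusive and small cases pass through", {
  two_near <- occurrence_set(x = c(0, 1500), y = c(0, 0))
  expect_equal(nrow(thin_occurrences(two_near, 2000, seed = 1)), 1)
  two_at <- occurrence_set(x = c(0, 2000), y = c(0, 0))
  expect_equal(nrow(thin_occurrences(two_at, 2000, seed = 1)), 2)
  one <- occurrence_set(x = 1, y = 1)
  expect_equal(nrow(thin_occurrences(one, 2000, seed = 1)), 1)
  expect_equal(nrow(thin_occurrences(occurrence_set(), 2000, seed = 1)), 0)
})

test_that("thinning satisfies the distance constraint and maximality", {
  occ <- clustered_points(50, k = 4, w = 8000, spread = 900, seed = 7)
  for (seed in c(1, 2, 3)) {
    th <- thin_occurrences(occ, 2000, seed = seed)
    # O(n^2) verification: no retained pair below min_dist
    expect_gte(min_pair_dist(th), 2000)
    # maximality: every rejected record is < min_dist from a retained one
    kept <- attr(th, "kept")
    rej <- setdiff(seq_len(nrow(occ)), kept)
    for (i in rej) {
      d <- sqrt((th$x - occ$x[i])^2 + (th$y - occ$y[i])^2)
      expect_lt(min(d), 2000)
    }
  }
})

test_that("thinning is deterministic given the seed", {
  occ <- clustered_points(80, seed = 3)
  expect_identical(thin_occurrences(occ, 2000, seed = 11),
                   thin_occurrences(occ, 2000, seed = 11))
})

test_that("make_replicates holdout equals the independent set difference", {
  occ <- clustered_points(200, k = 6, w = 10000, spread = 700, seed = 5)
  mr <- make_replicates(occ, n_rep = 5, min_dist = 2000, seeds = 11:15)
  used <- unique(unlist(lapply(mr$replicates, attr, "kept")))
  expect_setequal(setdiff(seq_len(nrow(occ)), used),
                  which(paste(occ$x, occ$y) %in%
                          paste(mr$holdout$x, mr$holdout$y)))
  # bit-reproducible
  mr2 <- make_replicates(occ, n_rep = 5, min_dist = 2000, seeds = 11:15)
  expect_identical(mr, mr2)
  expect_error(make_replicates(occ, 2, 2000, seeds = c(3, 3)), "duplicate")
})

test_that("widely spaced records give full replicates and empty holdout", {
  occ <- occurrence_set(x = c(0, 5000, 10000), y = c(0, 0, 0))
  mr <- make_replicates(occ, n_rep = 2, min_dist = 2000, seeds = 1:2)
  expect_equal(vapply(mr$replicates, nrow, integer(1)), c(3L, 3L))
  expect_equal(nrow(mr$holdout), 0)
})

test_that("screen_predictors keeps the priority layer among correlated ones", {
  set.seed(42)
  n <- 100
  a <- rnorm(n * n)
  b <- 0.9 * a + sqrt(1 - 0.9^2) * rnorm(n * n)   # r(A,B) ~ 0.9
  c_ <- rnorm(n * n)                              # independent
  stopifnot(abs(cor(a, b)) > 0.85, abs(cor(a, c_)) < 0.1)
  st <- predictor_stack(list(A = toy_raster(a, n), B = toy_raster(b, n),
                             C = toy_raster(c_, n)))
  expect_equal(screen_predictors(st, 0.75, priority = c("A", "B", "C")),
               c("A", "C"))
  # identical layers: priority one retained
  st2 <- predictor_stack(list(A = toy_raster(a, n), B = toy_raster(a, n)))
  expect_equal(screen_predictors(st2, 0.75, c("A", "B")), "A")
  expect_equal(screen_predictors(st2, 0.75, c("B", "A")), "B")
  # independent white-noise layers both retained
  st3 <- predictor_stack(list(A = toy_raster(a, n), C = toy_raster(c_, n)))
  expect_setequal(screen_predictors(st3, 0.75, c("A", "C")), c("A", "C"))
})

test_that("screening drops constant layers and keeps categoricals", {
  set.seed(1)
  a <- toy_raster(rnorm(25), 5)
  k <- toy_raster(rep(1:5, 5), 5)
  flat <- toy_raster(3, 5)
  st <- predictor_stack(list(A = a, flat = flat, K = k),
                        c(A = "continuous", flat = "continuous",
                          K = "categorical"))
  expect_warning(keep <- screen_predictors(st, 0.75, c("A", "flat")),
                 "constant")
  expect_equal(keep, c("A", "K"))
})

test_that("occurrence CSV round-trips", {
  occ <- occurrence_set(x = c(1.5, 2), y = c(3, 4.25),
                        accuracy = c(10, 99), date = c("2015-10-01", NA),
                        source = c("atlas", NA))
  path <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(occ, path)
  back <- read_occurrences(path)
  expect_equal(back$x, occ$x)
  expect_equal(back$accuracy, occ$accuracy)
})
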