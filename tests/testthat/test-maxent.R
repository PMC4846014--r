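test_that("thinning keeps one point per occupied stand", {
  occ <- thinning_fixture()
  ids <- grid_layer(matrix(1:54, 6, 9), cellsize = 30)
  stands <- stands_from_ids(ids)
  thin <- thin_by_polygon(occ, stands, seed = 4)
  expect_equal(nrow(thin), 54)
  expect_equal(sort(unique(thin$stand_id)), 1:54)
  # already one-per-polygon input is returned unchanged
  again <- thin_by_polygon(thin, stands, seed = 99)
  expect_equal(again$x, thin$x)
  # deterministic for a seed
  expect_identical(thin_by_polygon(occ, stands, seed = 4), thin)
  t2 <- thin_by_polygon(occ, stands, seed = 5)
  expect_equal(nrow(t2), 54)
  # a point outside every polygon is an error naming it
  bad <- occurrence_set(c(10, 1e6), c(10, 1e6))
  expect_error(thin_by_polygon(bad, stands, seed = 1), "row\\(s\\) 2")
})

test_that("train/test split reproduces the documented sizes", {
  occ <- occurrence_set(runif(54), runif(54))
  sp <- train_test_split(occ, 0.8, seed = 2)
  expect_equal(sum(sp$partition == "train"), 43)
  expect_equal(sum(sp$partition == "test"), 11)
  sp10 <- train_test_split(occurrence_set(runif(10), runif(10)), 0.8, 1)
  expect_equal(table(sp10$partition)[["train"]], 8)
  expect_equal(table(sp10$partition)[["test"]], 2)
  expect_true(all(sp$partition %in% c("train", "test")))
  expect_error(train_test_split(occurrence_set(1, 1), 0.8, 1), "at least 2")
  expect_identical(train_test_split(occ, 0.8, seed = 2), sp)
})

test_that("background sampling is valid, capped, and seeded", {
  sc <- small_scenario()
  bg <- sample_background(sc$stack, n = 500, seed = 6)
  expect_equal(length(bg$cells), 500)
  expect_false(any(duplicated(bg$cells)))
  valid <- !is.na(sc$stack$E$values)
  expect_true(all(valid[bg$cells]))
  expect_identical(sample_background(sc$stack, n = 500, seed = 6), bg)
  # requesting more cells than exist returns them all
  all_bg <- sample_background(sc$stack, n = 1e7, seed = 1)
  nvalid <- sum(Reduce(`&`, lapply(sc$stack, function(g) !is.na(g$values))))
  expect_equal(length(all_bg$cells), nvalid)
  # presence cells appended and flagged
  bgp <- sample_background(sc$stack, n = 500, seed = 6,
                           presences = sc$presences)
  pidx <- cell_index_at(sc$dem, sc$presences$x, sc$presences$y)
  expect_true(all(pidx %in% bgp$cells))
  expect_true(all(bgp$is_presence[match(pidx, bgp$cells)]))
})

test_that("features are min-max scaled with quadratic and indicator terms", {
  sc <- small_scenario()
  bg <- sample_background(sc$stack, n = 2000, seed = 3)
  spec <- feature_spec(sc$stack, c("E", "FT"), bg)
  M <- feature_matrix(spec, sc$stack, bg$cells)
  expect_true(all(M >= 0 & M <= 1))
  expect_equal(unname(M[, "E^2"]), unname(M[, "E"]^2))
  # endpoints map to 0 and 1
  e <- sc$stack$E$values[bg$cells]
  expect_equal(unname(M[which.min(e), "E"]), 0)
  expect_equal(unname(M[which.max(e), "E"]), 1)
  # a synthetic midpoint cell scores (0.5, 0.25)
  lo <- spec$info$E$min; hi <- spec$info$E$max
  z <- ((lo + hi) / 2 - lo) / (hi - lo)
  expect_equal(z, 0.5)
  # indicators partition: each row sums to one over FT levels
  ftcols <- grep("^\\(FT=", colnames(M))
  expect_true(all(rowSums(M[, ftcols, drop = FALSE]) == 1))
  # constant variable dropped with a warning
  const <- sc$stack
  const$Z <- grid_layer(matrix(1, 60, 60), cellsize = 30)
  expect_warning(sp2 <- feature_spec(const, c("E", "Z"), bg), "constant")
  expect_false("Z" %in% sp2$variables)
})

test_that("the featureless model is uniform with maximal entropy", {
  sc <- small_scenario()
  occ <- train_test_split(sc$presences, 0.8, seed = 1)
  bg <- sample_background(sc$stack, n = 1000, seed = 2, presences = occ)
  f <- fit_maxent(sc$stack, occ, character(0), background = bg)
  N <- length(bg$cells)
  expect_equal(f$entropy, log(N))
  r <- raw_map(f, sc$stack)
  vals <- r$values[!is.na(r$values)]
  expect_true(all(abs(vals - 1 / N) < 1e-12))
})

test_that("a diagnostic binary feature gets a positive lambda", {
  # feature = 1 at all presences but only half the background
  n <- 40
  ind <- grid_layer(matrix(rep(c(12, 7), each = n * n / 2), n, n),
                    cellsize = 30)
  flat <- grid_layer(matrix(0, n, n), cellsize = 30)
  stack <- predictor_stack(list(FT = ind, E = flat))
  set.seed(15)
  rows <- sample(1:n, 30, replace = TRUE)
  cols <- sample(1:(n / 2), 30, replace = TRUE)  # west half: FT = 12
  ctr <- cell_center(ind, rows, cols)
  occ <- occurrence_set(ctr$x, ctr$y)
  f <- fit_maxent(stack, occ, "FT", beta = 1e-6, bg_n = 1500, seed = 1,
                  max_iter = 5000)
  expect_gt(f$lambdas[["(FT=12)"]] - f$lambdas[["(FT=7)"]], 0)
})

test_that("raw maps normalize over the background for fitted models", {
  sc <- small_scenario()
  occ <- train_test_split(sc$presences, 0.8, seed = 3)
  bg <- sample_background(sc$stack, n = 2000, seed = 4, presences = occ)
  f <- fit_maxent(sc$stack, occ, c("FT", "NS", "EW", "E", "R"),
                  background = bg, beta = 1, max_iter = 2000)
  r <- raw_map(f, sc$stack)
  expect_equal(sum(r$values[bg$cells]), 1, tolerance = 1e-9)
  # the exponent never exceeds zero on the background (normalizer property)
  M <- feature_matrix(f$spec, sc$stack, bg$cells)
  expect_lte(max(drop(M %*% f$lambdas) - f$lpn), 0)
  # entropy within its theoretical bounds
  expect_gte(f$entropy, 0)
  expect_lte(f$entropy, log(length(bg$cells)))
})

test_that("the fit objective is convex: restarts agree", {
  sc <- small_scenario()
  occ <- train_test_split(sc$presences, 0.8, seed = 3)
  bg <- sample_background(sc$stack, n = 1000, seed = 4, presences = occ)
  tol <- 1e-10
  f0 <- fit_maxent(sc$stack, occ, c("E", "NS"), background = bg, beta = 1,
                   tol = tol, max_iter = 20000)
  set.seed(77)
  objs <- replicate(5, {
    l0 <- rnorm(length(f0$lambdas), sd = 0.5)
    fit_maxent(sc$stack, occ, c("E", "NS"), background = bg, beta = 1,
               tol = tol, max_iter = 20000, lambda0 = l0)$objective
  })
  expect_true(all(abs(objs - f0$objective) <= 10 * tol * max(1, abs(f0$objective))))
})

test_that("non-convergence raises an informative error", {
  sc <- small_scenario()
  occ <- train_test_split(sc$presences, 0.8, seed = 3)
  expect_error(
    fit_maxent(sc$stack, occ, c("FT", "E"), bg_n = 1000, seed = 1,
               tol = 1e-14, max_iter = 2),
    "did not converge")
})

test_that("the logistic transform follows the entropy calibration", {
  for (H in c(0, 7.90, 8.12)) {
    expect_equal(logistic_transform(exp(-H), H), 0.5)
  }
  expect_equal(logistic_transform(0, 5), 0)
  expect_equal(logistic_transform(2 * exp(-7.90), 7.90), 2 / 3)
  # strictly increasing, bounded in [0, 1)
  raw <- seq(0, 1, length.out = 200)
  out <- logistic_transform(raw, 3)
  expect_true(all(diff(out) > 0))
  expect_true(all(out >= 0 & out < 1))
  # grid input keeps georeference
  g <- grid_layer(matrix(exp(-2), 2, 2), cellsize = 30)
  lg <- logistic_transform(g, 2)
  expect_equal(lg$values, matrix(0.5, 2, 2))
  expect_equal(lg$cellsize, 30)
})

test_that("AUC is the concordance probability with half ties", {
  expect_equal(auc(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
  expect_equal(auc(rep(0.3, 5), rep(0.3, 7)), 0.5)
  expect_equal(auc(c(5, 6), c(1, 2)), 1.0)
  expect_equal(auc(c(1, 2), c(5, 6)), 0.0)
})
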