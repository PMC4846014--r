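test_that("the default registry is the balanced 26-model set", {
  reg <- default_registry()
  expect_equal(nrow(reg), 26)
  expect_false(anyDuplicated(reg$name) > 0)
  counts <- table(unlist(reg$variables))
  expect_equal(sort(names(counts)),
               sort(c("FT", "NS", "EW", "S", "E", "W", "TR", "MR", "R", "C")))
  expect_true(all(counts == 8))
  expect_setequal(reg$variables[[which(reg$name == "Pine 2")]],
                  c("FT", "NS", "EW", "E", "R"))
  expect_equal(length(reg$variables[[which(reg$name == "Global")]]), 10)
  expect_true(all(lengths(reg$variables) >= 1))
})

test_that("registry config files round-trip, including alternate encodings", {
  f <- withr::local_tempfile(fileext = ".txt")
  reg <- default_registry()
  writeLines(c("# candidate set",
               sprintf("%s: %s", reg$name,
                       vapply(reg$variables, paste, "", collapse = "+"))), f)
  back <- read_registry(f)
  expect_equal(back$name, reg$name)
  expect_equal(back$variables, reg$variables)
  # the narrower printed encoding of the foraging hypothesis is expressible
  writeLines(c("Foraging 1: W", "Global: FT,NS,EW,S,E,W,TR,MR,R,C"), f)
  alt <- read_registry(f)
  expect_equal(alt$variables[[1]], "W")
  expect_equal(length(alt$variables[[2]]), 10)
})

test_that("occurrence log-likelihood uses map-wide standardization", {
  u <- grid_layer(matrix(1, 10, 10), cellsize = 30)
  pts <- occurrence_set(c(15, 45, 75), c(15, 45, 75))
  expect_equal(occurrence_log_likelihood(u, pts), 3 * log(1 / 100))
  r2 <- grid_layer(matrix(c(0.75, 0.25), 1, 2), cellsize = 1)
  toy <- occurrence_set(c(0.5, 0.5, 1.5), rep(0.5, 3))
  expect_equal(occurrence_log_likelihood(r2, toy), 2 * log(0.75) + log(0.25))
  # moving a point from a low to a high cell strictly increases lnL
  lo <- occurrence_set(c(1.5, 1.5), rep(0.5, 2))
  hi <- occurrence_set(c(0.5, 1.5), rep(0.5, 2))
  expect_gt(occurrence_log_likelihood(r2, hi),
            occurrence_log_likelihood(r2, lo))
  out <- occurrence_set(1e6, 1e6)
  expect_error(occurrence_log_likelihood(r2, out), "outside")
})

test_that("parameter counting respects the zero tolerance", {
  m <- list(lambdas = c(0.5, 0, -1.2))
  class(m) <- "maxent_model"
  expect_equal(count_parameters(m), 2)
  expect_equal(count_parameters(list(lambdas = c(0, 0))), 0)
  expect_equal(count_parameters(list(lambdas = c(0.05, 0.5)), tol = 0.1), 1)
})

test_that("AICc follows the small-sample correction formula", {
  expect_equal(aicc(-100, 5, 43), 210 + 60 / 37)
  expect_equal(aicc(-50, 0, 20), 100)
  expect_equal(aicc(-100, 5, 1e9), 2 * 5 + 200, tolerance = 1e-6)
  expect_error(aicc(-10, 5, 6), "unscoreable")
  # strictly increasing in k at fixed lnL and n
  ks <- 1:8
  scores <- vapply(ks, function(k) aicc(-40, k, 30), 0)
  expect_true(all(diff(scores) > 0))
})

test_that("Akaike weights normalize, shift-invariantly", {
  expect_equal(akaike_weights(c(100, 100)), c(0.5, 0.5))
  expect_equal(akaike_weights(42), 1)
  sc <- example_ranking()$aicc
  w <- akaike_weights(sc)
  expect_equal(sum(w), 1)
  expect_equal(w, akaike_weights(sc + 1234.5))
  expect_equal(round(w[1:4], 2), c(0.78, 0.15, 0.05, 0.02))
})

test_that("the plausible set applies the strict delta cutoff", {
  rk <- example_ranking()
  tab <- data.frame(model = rk$model, delta = rk$aicc - min(rk$aicc))
  expect_equal(plausible_set(tab, 7),
               c("Pine 2", "Pine 1", "Topography 1"))  # 7.53 excluded
  expect_equal(plausible_set(tab, 0.1), "Pine 2")
  expect_equal(length(plausible_set(tab, Inf)), nrow(tab))
})

test_that("weight-sum importance reproduces the published arithmetic", {
  rk <- example_ranking()
  tab <- data.frame(model = rk$model, weight = akaike_weights(rk$aicc))
  imp <- variable_importance(tab)
  get <- function(v) imp$importance[imp$variable == v]
  expect_equal(round(get("NS"), 2), 0.85)
  expect_equal(round(get("R"), 2), 0.83)
  expect_equal(round(get("EW"), 2), 0.85)
  expect_equal(round(get("FT"), 2), 0.93)
  expect_equal(round(get("E"), 2), 1.00)
  expect_true(all(imp$importance >= 0 & imp$importance <= 1))
  # complement identity: importance = 1 - weight of models excluding it
  reg <- default_registry()
  w <- stats::setNames(rep(0, nrow(reg)), reg$name)
  w[tab$model] <- tab$weight
  for (v in c("NS", "E", "W", "C")) {
    excl <- !vapply(reg$variables, function(vs) v %in% vs, TRUE)
    expect_equal(get(v), 1 - sum(w[excl]), tolerance = 1e-12)
  }
  # a variable in every model has importance 1
  tiny <- data.frame(name = c("a", "b"), hypothesis = "")
  tiny$variables <- list(c("E", "W"), "E")
  imp2 <- variable_importance(data.frame(model = c("a", "b"),
                                         weight = c(0.4, 0.6)), tiny)
  expect_equal(imp2$importance[imp2$variable == "E"], 1)
})

test_that("run_comparison produces a coherent, reproducible table", {
  sc <- small_scenario()
  occ <- thin_by_polygon(sc$presences, sc$stands, seed = 21)
  occ <- train_test_split(occ, 0.8, seed = 22)
  reg <- default_registry()
  reg <- reg[reg$name %in% c("Pine 2", "Pine 1", "Elevation", "Corridor 3",
                             "Sunny Ridgetop"), ]
  cmp <- run_comparison(sc$stack, occ, registry = reg, bg_n = 1500,
                        seed = 23)
  expect_s3_class(cmp, "comparison_table")
  expect_equal(nrow(cmp), 5)
  expect_equal(sum(cmp$weight), 1, tolerance = 1e-9)
  expect_equal(cmp$delta[cmp$rank == 1], 0)
  expect_true(all(cmp$k < cmp$n - 1, na.rm = TRUE))
  expect_true(all(diff(cmp$aicc) >= 0))
  # the same sample size for every model (shared split)
  expect_equal(unique(cmp$n), round(0.8 * nrow(occ)))
  # bit-for-bit reproducible
  cmp2 <- run_comparison(sc$stack, occ, registry = reg, bg_n = 1500,
                         seed = 23)
  expect_identical(as.data.frame(cmp), as.data.frame(cmp2))
  # fitted models travel with the table
  expect_s3_class(attr(cmp, "models")[["Pine 2"]], "maxent_model")
})
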