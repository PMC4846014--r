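test_that("focal-mean smoothing has the expected fixed points", {
  g <- grid_layer(matrix(7, 5, 5), cellsize = 1)
  expect_equal(smooth_dem(g, 10)$values, g$values)
  center9 <- grid_layer(matrix(c(0, 0, 0, 0, 9, 0, 0, 0, 0), 3, 3),
                        cellsize = 1)
  expect_equal(smooth_dem(center9, 1)$values[2, 2], 1.0)
  ramp <- plane_grid(7, "east")
  expect_equal(smooth_dem(ramp, 1)$values[2:6, 2:6], ramp$values[2:6, 2:6])
})

test_that("Horn slope matches hand-computed values", {
  expect_equal(slope(grid_layer(matrix(3, 4, 4), cellsize = 1))$values,
               matrix(0, 4, 4))
  expect_equal(slope(plane_grid(5, "east"))$values[3, 3], 45)
  # irregular 3x3 fixture: dz/dx = 0.35, dz/dy = -1.0 at cellsize 5
  z <- matrix(c(10, 11, 13, 14, 16, 17, 19, 21, 24), 3, 3, byrow = TRUE)
  expected <- atan(sqrt(0.35^2 + 1^2)) * 180 / pi
  expect_equal(slope(grid_layer(z, cellsize = 5))$values[2, 2], expected)
})

test_that("aspect is the downslope azimuth with a flat code", {
  expect_equal(aspect(plane_grid(5, "north"))$values[3, 3], 180)
  west_rising <- grid_layer(matrix(rep(5:1, each = 5), 5, 5), cellsize = 1)
  expect_equal(aspect(west_rising)$values[3, 3], 90)
  flat <- aspect(grid_layer(matrix(2, 4, 4), cellsize = 1))
  expect_true(all(flat$values == -1))
})

test_that("aspect components are cosine/sine with unit norm off-flat", {
  mk <- function(deg) grid_layer(matrix(deg, 2, 2), cellsize = 1)
  comp <- aspect_components(mk(180))
  expect_equal(comp$ns$values[1, 1], -1)
  expect_equal(comp$ew$values[1, 1], 0)
  comp <- aspect_components(mk(90))
  expect_equal(comp$ns$values[1, 1], 0, tolerance = 1e-12)
  expect_equal(comp$ew$values[1, 1], 1)
  comp <- aspect_components(mk(0))
  expect_equal(comp$ns$values[1, 1], 1)
  comp <- aspect_components(mk(-1))          # flat code
  expect_equal(comp$ns$values[1, 1], 0)
  expect_equal(comp$ew$values[1, 1], 0)
  asp <- aspect(small_scenario()$dem)
  comp <- aspect_components(asp)
  offflat <- asp$values >= 0
  expect_equal(max(abs(comp$ns$values[offflat]^2 +
                         comp$ew$values[offflat]^2 - 1)), 0,
               tolerance = 1e-12)
})

test_that("curvature matches the quadratic-fit oracle and sign convention", {
  expect_equal(curvature(plane_grid(5, "east"))$values[2:4, 2:4],
               matrix(0, 3, 3))
  # dome: apex upwardly convex -> positive
  x <- matrix(rep(-2:2, each = 5), 5, 5)
  dome <- grid_layer(-(x^2 + t(x)^2), cellsize = 1)
  expect_gt(curvature(dome)$values[3, 3], 0)
  # hand-computed Zevenbergen-Thorne on an irregular 3x3 at cellsize 5:
  # D = ((14+17)/2 - 16)/25, E = ((11+21)/2 - 16)/25, curv = -200(D+E) = 4
  z <- matrix(c(10, 11, 13, 14, 16, 17, 19, 21, 24), 3, 3, byrow = TRUE)
  expect_equal(curvature(grid_layer(z, cellsize = 5))$values[2, 2], 4)
})

test_that("sink filling raises pits to spill level and is idempotent", {
  ramp <- plane_grid(6, "east")
  expect_equal(fill_sinks(ramp)$values, ramp$values)
  pit <- grid_layer(matrix(c(10, 10, 10, 10, 2, 10, 10, 10, 10), 3, 3),
                    cellsize = 1)
  expect_equal(fill_sinks(pit)$values[2, 2], 10, tolerance = 1e-4)
  sc <- small_scenario()
  once <- fill_sinks(sc$dem)
  expect_identical(fill_sinks(once)$values, once$values)
  # non-sink cells unchanged
  expect_true(all(once$values >= sc$dem$values))
})

test_that("D8 directions point down the steepest drop with documented ties", {
  east <- flow_direction(plane_grid(5, "east"))
  expect_true(all(east$values[2:4, 2:4] == 16))  # rises east -> flows west
  # plane falling to the east flows east (code 1)
  fall_e <- grid_layer(matrix(rep(5:1, each = 5), 5, 5), cellsize = 1)
  expect_true(all(flow_direction(fall_e)$values[2:4, 2:4] == 1))
  # southwest-falling plane -> code 8
  swp <- grid_layer(outer(1:5, 1:5, function(r, c) -r + c + 10), cellsize = 1)
  expect_true(all(flow_direction(swp)$values[2:4, 2:4] == 8))
  # tie between E and S resolves to the smaller code (E = 1)
  tie <- grid_layer(matrix(c(5, 5, 5, 5, 5, 4, 5, 4, 4), 3, 3, byrow = TRUE),
                    cellsize = 1)
  expect_equal(flow_direction(tie)$values[2, 2], 1)
})

test_that("flow accumulation counts upstream cells and conserves flow", {
  # 1 x 5 chain draining east
  chain <- grid_layer(matrix(5:1, 1, 5), cellsize = 1)
  acc <- flow_accumulation(flow_direction(chain))
  expect_equal(as.vector(acc$values), 0:4)
  # hand-traced 4x4 southeast-sloping fixture
  d4 <- grid_layer(matrix(c(9, 8, 7, 6, 8, 7, 6, 5, 7, 6, 5, 4, 6, 5, 4, 3),
                          4, 4, byrow = TRUE), cellsize = 1)
  acc4 <- flow_accumulation(flow_direction(d4))
  expect_equal(acc4$values,
               matrix(c(0, 0, 0, 0, 0, 1, 1, 2, 0, 1, 2, 5, 0, 2, 5, 15),
                      4, 4, byrow = TRUE))
  expect_equal(acc4$values[4, 4], 15)        # outlet drains ncells - 1
  # conservation on random filled DEMs: outlets account for every valid cell
  for (s in 1:5) {
    set.seed(100 + s)
    dem <- grid_layer(matrix(runif(400), 20, 20), cellsize = 1)
    filled <- fill_sinks(dem)
    fd <- flow_direction(filled)
    a <- flow_accumulation(fd)
    outlets <- fd$values == 0
    expect_equal(sum(a$values[outlets] + 1), 400)
  }
})

test_that("cyclic flow directions are detected as an error", {
  fd <- grid_layer(matrix(c(1, 16), 1, 2), cellsize = 1)  # A -> B -> A
  expect_error(flow_accumulation(fd), "cycle")
})

test_that("Strahler ordering follows the junction rules", {
  # unbranched channel: order 1 everywhere on it
  chain <- grid_layer(matrix(9:1, 1, 9), cellsize = 1)
  fd <- flow_direction(chain)
  acc <- flow_accumulation(fd)
  so <- stream_order(fd, acc, threshold = 2)
  expect_true(all(so$values[!is.na(so$values)] == 1))
  # two order-1 tributaries joining -> order 2 downstream; an order-1 joining
  # the order-2 trunk leaves it at 2
  z <- matrix(c(9, 9, 9, 9, 9,
                5, 9, 5, 9, 9,
                9, 4, 9, 9, 9,
                9, 3, 9, 2, 9,
                9, 2.5, 2, 1, 0), 5, 5, byrow = TRUE)
  dem <- grid_layer(z, cellsize = 1)
  fd <- flow_direction(fill_sinks(dem))
  acc <- flow_accumulation(fd)
  so <- stream_order(fd, acc, threshold = 1)
  ord <- so$values
  expect_equal(ord[3, 2], 2)   # below the first junction
  expect_equal(ord[4, 2], 2)
  expect_true(all(ord[2, c(1, 3)] == 1, na.rm = TRUE))
})

test_that("ridge extraction is the stream mask of the inverted DEM", {
  sc <- small_scenario()
  thr <- 20
  ridges <- extract_ridges(sc$dem, threshold = thr)
  inv <- grid_layer(-sc$dem$values, cellsize = sc$dem$cellsize)
  fd <- flow_direction(fill_sinks(inv))
  so <- stream_order(fd, flow_accumulation(fd), thr)
  expect_equal(ridges$values, ifelse(is.na(so$values), 0, 1))
  # ridge cells sit high: their mean elevation exceeds the grid mean
  expect_gt(mean(sc$dem$values[ridges$values == 1]), mean(sc$dem$values))
})

test_that("tent-shaped DEM yields a crest-line ridge mask", {
  # symmetric tent: crest along the middle row
  n <- 15
  z <- outer(seq_len(n), seq_len(n), function(r, c) 100 - 10 * abs(r - 8))
  # tilt along the crest so drainage concentrates without flats
  z <- z + outer(seq_len(n), seq_len(n), function(r, c) 0.01 * c)
  # threshold above the largest hillslope accumulation (6 cells per column
  # flank) isolates the crest line itself
  ridges <- extract_ridges(grid_layer(z, cellsize = 1), threshold = 8)
  crest <- which(ridges$values == 1, arr.ind = TRUE)
  expect_true(nrow(crest) > 0)
  expect_true(all(crest[, "row"] == 8))
})

test_that("Euclidean distance is exact and 1-Lipschitz per cell", {
  m <- matrix(0, 5, 5); m[3, 3] <- 1
  d <- euclidean_distance(grid_layer(m, cellsize = 30))
  expect_equal(d$values[3, 3], 0)
  expect_equal(d$values[3, 4], 30)
  expect_equal(d$values[2, 2], 30 * sqrt(2))
  expect_equal(d$values[1, 1], 30 * sqrt(8))
  # random masks agree with brute force and neighbor differences are bounded
  set.seed(11)
  for (rep in 1:3) {
    m <- matrix(rbinom(100, 1, 0.08), 10, 10)
    if (!any(m == 1)) m[5, 5] <- 1
    g <- grid_layer(m, cellsize = 30)
    d <- euclidean_distance(g)$values
    src <- which(m == 1, arr.ind = TRUE)
    brute <- matrix(NA_real_, 10, 10)
    for (r in 1:10) for (c in 1:10)
      brute[r, c] <- 30 * sqrt(min((r - src[, 1])^2 + (c - src[, 2])^2))
    expect_equal(d, brute)
    expect_true(all(abs(d[, -1] - d[, -10]) <= 30 + 1e-9))
    expect_true(all(abs(d[-1, ] - d[-10, ]) <= 30 + 1e-9))
  }
  expect_error(euclidean_distance(grid_layer(matrix(0, 3, 3))), "no source")
})

test_that("band statistics give a valid correlation matrix", {
  set.seed(21)
  a <- grid_layer(matrix(rnorm(2500), 50, 50), cellsize = 30)
  b <- grid_layer(-a$values, cellsize = 30)
  e <- grid_layer(matrix(rnorm(2500), 50, 50), cellsize = 30)
  ctr <- c(mean(grid_extent(a)[1:2]), mean(grid_extent(a)[3:4]))
  cm <- band_statistics(list(a = a, neg = b, noise = e), ctr, radius = 600)
  expect_equal(unname(diag(cm)), rep(1, 3))
  expect_equal(cm["a", "neg"], -1)
  expect_lt(abs(cm["a", "noise"]), 0.1)
  expect_equal(cm, t(cm))
  expect_error(band_statistics(list(a = a, b = b), c(-1e6, -1e6), 100),
               "fewer than 3")
})

test_that("ruggedness centers find high- and low-relief windows", {
  flat <- grid_layer(matrix(1, 30, 30), cellsize = 30)
  rc <- ruggedness_centers(flat, radius = 90)
  expect_equal(rc$most_rugged$sd, 0, tolerance = 1e-6)
  expect_equal(rc$least_rugged$sd, 0, tolerance = 1e-6)
  # flat west half, rugged east half
  set.seed(3)
  z <- matrix(0, 30, 30)
  z[, 16:30] <- matrix(rnorm(30 * 15, sd = 50), 30, 15)
  g <- grid_layer(z, cellsize = 30)
  rc <- ruggedness_centers(g, radius = 90)
  expect_gt(rc$most_rugged$x, grid_extent(g)["xmax"] / 2)
  expect_lt(rc$least_rugged$x, grid_extent(g)["xmax"] / 2)
  rc2 <- ruggedness_centers(g, radius = 90)
  expect_identical(rc, rc2)
})
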