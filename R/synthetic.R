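# Synthetic ridge-valley landscapes with a known maximum-entropy truth.
# The generator emulates the statistical structure the analysis assumes --
# rugged terrain, a forest-type mosaic correlated with elevation and aspect,
# streams in valleys, random road/trail lines, and presences drawn from a
# Gibbs distribution over the landscape -- so that fitting, model selection
# and mapping can be validated end to end with no external data.

#' Scenario configuration
#'
#' Defaults describe the study conditions the pipeline targets: a 30 m grid,
#' elevation spanning 260-2025 m, 13 forest-type codes, 76 presences across a
#' 54-stand partition, and true coefficients concentrating suitability on
#' south-facing cells near ridge tops in a low-to-mid elevation band.
#'
#' @param nrows,ncols grid size (>= 16).
#' @param cellsize cell size in map units (default 30).
#' @param seed integer run seed; every stochastic stage derives its own
#'   stream from it via [stage_seed()].
#' @param n_ridges number of elongated ridge crests summed into the DEM.
#' @param ridge_orientation mean crest orientation, degrees counterclockwise
#'   from east.
#' @param elev_range elevation range (m), min < max.
#' @param noise_amplitude smooth-noise amplitude relative to ridge relief.
#' @param n_forest_types number of forest-type codes.
#' @param pine_codes codes treated as pine-component classes (concentrated at
#'   low elevation on south-facing cells).
#' @param true_lambdas named list of generating coefficients on scaled
#'   features: per continuous variable `c(linear, quadratic)`, for `FT` one
#'   value per code. See [default_true_lambdas()].
#' @param n_presences number of presence points drawn from the truth surface.
#' @param n_stands number of Voronoi stands (<= n_presences).
#' @param smoothing_passes DEM smoothing passes for the terrain stage.
#' @param ridge_threshold channel threshold for ridge extraction (NULL =
#'   0.5\% of valid cells).
#' @param water_threshold flow-accumulation threshold defining streams
#'   (NULL = 1\% of cells).
#' @param n_major_roads,n_trails number of random polylines per mask.
#' @return a list of class `"scenario_config"`.
#' @export
scenario_config <- function(nrows = 200, ncols = 200, cellsize = 30,
                            seed = 1, n_ridges = 5, ridge_orientation = 30,
                            elev_range = c(260, 2025),
                            noise_amplitude = 0.15,
                            n_forest_types = 13,
                            pine_codes = c(2, 3, 5, 9, 13),
                            true_lambdas = default_true_lambdas(),
                            n_presences = 76, n_stands = 54,
                            smoothing_passes = 10, ridge_threshold = NULL,
                            water_threshold = NULL,
                            n_major_roads = 2, n_trails = 4) {
  if (elev_range[1] >= elev_range[2]) stop("elevation range min must be < max")
  if (n_stands > n_presences) stop("n_stands must be <= n_presences")
  structure(as.list(environment()), class = "scenario_config")
}

#' Default generating coefficients
#'
#' Coefficients on [0, 1]-scaled features. The elevation pair (+4, -13)
#' puts the suitability optimum near 530 m of a 260-2025 m landscape (a
#' low-to-mid elevation band); northness -2.1 favors south-facing cells;
#' distance-to-ridge -3 concentrates points near crests; eastness is weak. The
#' forest-type block is centered to mean zero because a full indicator block
#' is identified only up to an additive shift. Variables absent from the list
#' (S, W, TR, MR, C) do not influence the truth.
#'
#' @return named list of coefficient vectors.
#' @export
default_true_lambdas <- function() {
  ft <- c(0.81, 3.31, 2.39, -0.12, 2.23, 1.17, 1.54, 1.68, 2.77, 1.00,
          1.72, 1.22, 1.50)
  list(FT = ft - mean(ft),
       NS = c(-2.1, 0),
       EW = c(0.35, 0.22),
       E = c(4, -13),
       R = c(-3, 0))
}

#' Generate a synthetic DEM
#'
#' A sum of elongated Gaussian ridge crests (random centers, orientations
#' near `ridge_orientation`, random lengths/widths/amplitudes) plus
#' low-amplitude smooth noise, rescaled exactly to the configured elevation
#' range. Deterministic for the configuration seed.
#'
#' @param config a [scenario_config()].
#' @return elevation [grid_layer()].
#' @export
make_dem <- function(config) {
  nr <- config$nrows; nc <- config$ncols
  if (nr < 16L || nc < 16L) stop("grid must be at least 16 x 16")
  rng <- local_rng(stage_seed(config$seed, "dem"))
  rr <- matrix(rep(seq_len(nr), nc), nr, nc)
  cc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  z <- matrix(0, nr, nc)
  L <- max(nr, nc)
  for (i in seq_len(config$n_ridges)) {
    r0 <- if (config$n_ridges == 1L) (nr + 1) / 2 else rng$runif(1, 1, nr)
    c0 <- if (config$n_ridges == 1L) (nc + 1) / 2 else rng$runif(1, 1, nc)
    theta <- (config$ridge_orientation +
                if (config$n_ridges == 1L) 0 else rng$rnorm(1, 0, 20)) *
      pi / 180
    sig_par <- rng$runif(1, 0.25, 0.55) * L
    sig_perp <- rng$runif(1, 0.02, 0.06) * L
    amp <- rng$runif(1, 0.6, 1)
    # rotated coordinates: u along the crest, v across it; x = east (col),
    # y = north (-row)
    dx <- cc - c0; dy <- -(rr - r0)
    u <- dx * cos(theta) + dy * sin(theta)
    v <- -dx * sin(theta) + dy * cos(theta)
    z <- z + amp * exp(-(u^2 / (2 * sig_par^2) + v^2 / (2 * sig_perp^2)))
  }
  if (config$noise_amplitude > 0) {
    noise <- matrix(rng$rnorm(nr * nc), nr, nc)
    ng <- smooth_dem(grid_layer(noise, cellsize = config$cellsize),
                     passes = 5)$values
    ng <- (ng - min(ng)) / (max(ng) - min(ng))
    z <- z + config$noise_amplitude * ng * max(z)
  }
  z <- (z - min(z)) / (max(z) - min(z))
  z <- config$elev_range[1] + z * diff(config$elev_range)
  grid_layer(z, 0, 0, config$cellsize)
}

#' Generate a categorical forest-type layer
#'
#' Each cell's type is a multinomial draw whose logits depend on scaled
#' elevation and northness: pine-component codes load negatively on elevation
#' and northness (lower, south-facing cells), the remaining codes mildly the
#' other way. Forest type is therefore correlated with, but not determined
#' by, topography. With all logit weights zero the classes are uniform.
#'
#' @param dem elevation [grid_layer()].
#' @param config a [scenario_config()].
#' @param logit_elev,logit_ns optional per-code logit weights (default built
#'   from `pine_codes`); `logit_base` per-code intercepts.
#' @return integer-coded [grid_layer()].
#' @export
make_forest_types <- function(dem, config, logit_elev = NULL,
                              logit_ns = NULL, logit_base = NULL) {
  K <- config$n_forest_types
  pine <- seq_len(K) %in% config$pine_codes
  if (is.null(logit_elev)) logit_elev <- ifelse(pine, -2.5, 0.5)
  if (is.null(logit_ns)) logit_ns <- ifelse(pine, -1.5, 0.3)
  if (is.null(logit_base)) logit_base <- rep(0, K)
  z <- dem$values
  ez <- (z - min(z, na.rm = TRUE)) /
    (max(z, na.rm = TRUE) - min(z, na.rm = TRUE))
  ns <- aspect_components(aspect(dem))$ns$values
  eta <- outer(as.vector(ez), logit_elev) + outer(as.vector(ns), logit_ns)
  eta <- sweep(eta, 2L, logit_base, "+")
  eta <- eta - apply(eta, 1L, max)
  p <- exp(eta); p <- p / rowSums(p)
  rng <- local_rng(stage_seed(config$seed, "forest"))
  u <- rng$runif(length(ez))
  cum <- t(apply(p, 1L, cumsum))
  cls <- rowSums(u > cum) + 1L
  out <- matrix(as.numeric(cls), nrow(z), ncol(z))
  out[is.na(z)] <- NA_real_
  grid_layer(out, dem$xllcorner, dem$yllcorner, dem$cellsize,
             nodata = dem$nodata)
}

#' Generate hydrography and road/trail masks
#'
#' Streams are cells whose D8 flow accumulation (on the sink-filled DEM)
#' exceeds a channel threshold, so water follows the valleys; roads and
#' trails are random smooth polylines walked across the grid and rasterized
#' to 0/1 cell masks.
#'
#' @param dem elevation [grid_layer()].
#' @param config a [scenario_config()].
#' @return list with `water_mask`, `major_road_mask`, `trail_mask`.
#' @export
make_linear_features <- function(dem, config) {
  thr <- config$water_threshold
  if (is.null(thr))
    thr <- max(10, ceiling(0.01 * sum(!is.na(dem$values))))
  facc <- flow_accumulation(flow_direction(fill_sinks(dem)))
  water <- ifelse(!is.na(facc$values) & facc$values >= thr, 1, 0)
  water[is.na(dem$values)] <- NA_real_
  rng <- local_rng(stage_seed(config$seed, "lines"))
  walk_line <- function() {
    nr <- nrow(dem$values); nc <- ncol(dem$values)
    mask <- matrix(0, nr, nc)
    # enter on a random edge, head across with small angular noise
    side <- rng$int(4L)
    pos <- switch(side,
                  c(1, rng$runif(1, 1, nc)),            # north edge, head S
                  c(nr, rng$runif(1, 1, nc)),           # south edge, head N
                  c(rng$runif(1, 1, nr), 1),            # west edge, head E
                  c(rng$runif(1, 1, nr), nc))           # east edge, head W
    ang <- switch(side, pi / 2, -pi / 2, 0, pi)         # direction of travel
    ang <- ang + rng$runif(1, -0.4, 0.4)
    for (step in seq_len(4L * (nr + nc))) {
      r <- round(pos[1]); c <- round(pos[2])
      if (r < 1 || r > nr || c < 1 || c > nc) break
      mask[r, c] <- 1
      ang <- ang + rng$rnorm(1, 0, 0.15)
      pos <- pos + 0.7 * c(sin(ang), cos(ang))   # (row, col) step
    }
    mask
  }
  roads <- matrix(0, nrow(dem$values), ncol(dem$values))
  for (i in seq_len(config$n_major_roads)) roads <- pmax(roads, walk_line())
  trails <- matrix(0, nrow(dem$values), ncol(dem$values))
  for (i in seq_len(config$n_trails)) trails <- pmax(trails, walk_line())
  roads[is.na(dem$values)] <- NA_real_
  trails[is.na(dem$values)] <- NA_real_
  mk <- function(v) grid_layer(v, dem$xllcorner, dem$yllcorner, dem$cellsize,
                               nodata = dem$nodata)
  list(water_mask = mk(water), major_road_mask = mk(roads),
       trail_mask = mk(trails))
}

#' Truth model from generating coefficients
#'
#' Builds a `"maxent_model"` over the whole landscape (background = every
#' valid cell) with the configured coefficients, so the truth has the same
#' functional form the fitter estimates and parameter recovery is
#' well-posed.
#'
#' @param stack a [predictor_stack()].
#' @param true_lambdas named coefficient list (see [default_true_lambdas()]).
#' @return a `"maxent_model"` whose raw map is the generating distribution.
#' @export
make_truth_model <- function(stack, true_lambdas = default_true_lambdas()) {
  cells <- which(stack_valid(stack))
  bg <- list(cells = cells, is_presence = rep(FALSE, length(cells)))
  spec <- feature_spec(stack, names(true_lambdas), bg)
  lam <- numeric(0)
  for (v in spec$variables) {
    fi <- spec$info[[v]]
    tl <- true_lambdas[[v]]
    if (fi$type == "categorical") {
      lv <- stats::setNames(rep(0, length(fi$levels)),
                            sprintf("(%s=%g)", v, fi$levels))
      idx <- match(fi$levels, seq_along(tl))
      lv[!is.na(idx)] <- tl[idx[!is.na(idx)]]
      lam <- c(lam, lv)
    } else {
      lam <- c(lam, stats::setNames(tl[1:2], c(v, paste0(v, "^2"))))
    }
  }
  Fb <- feature_matrix(spec, stack, cells)
  eta <- drop(Fb %*% lam[colnames(Fb)])
  lpn <- max(eta)
  w <- exp(eta - lpn); dn <- sum(w)
  raw <- w / dn
  H <- -sum(raw * log(raw))
  new_maxent_model(lambdas = lam[colnames(Fb)], spec = spec, lpn = lpn,
                   dn = dn, entropy = H)
}

#' Sample presence points from an intensity surface
#'
#' Cells are drawn without replacement with probability proportional to the
#' (raw) intensity; each presence sits at its cell's center, so point-in-cell
#' lookups are unambiguous.
#'
#' @param truth_raw intensity [grid_layer()] (non-negative; need not be
#'   pre-normalized).
#' @param n number of points; must not exceed the cells with positive
#'   intensity.
#' @param seed integer RNG seed.
#' @return an [occurrence_set()].
#' @export
sample_presences <- function(truth_raw, n, seed = 1) {
  v <- as.vector(truth_raw$values)
  cand <- which(!is.na(v) & v > 0)
  if (n > length(cand))
    stop(sprintf("n (%d) exceeds cells with positive intensity (%d)",
                 n, length(cand)))
  rng <- local_rng(seed)
  pick <- cand[rng$sample_int(length(cand), n, prob = v[cand])]
  nr <- grid_nrow(truth_raw)
  rows <- ((pick - 1L) %% nr) + 1L
  cols <- ((pick - 1L) %/% nr) + 1L
  ctr <- cell_center(truth_raw, rows, cols)
  occurrence_set(ctr$x, ctr$y)
}

#' Simulate a complete scenario
#'
#' Runs the generator end to end: DEM, forest types, hydrography and road
#' masks, the full predictor stack, the truth model and its raw surface,
#' presences, and a stand partition. Reproducible bit-for-bit from the
#' configuration (all stage seeds derive from `config$seed`).
#'
#' @param config a [scenario_config()].
#' @return list of class `"scenario_bundle"` with elements `dem`,
#'   `forest_type`, `water_mask`, `major_road_mask`, `trail_mask`, `stack`,
#'   `truth`, `truth_raw`, `presences`, `stands`, `config`.
#' @export
simulate_scenario <- function(config = scenario_config()) {
  dem <- make_dem(config)
  forest <- make_forest_types(dem, config)
  lines <- make_linear_features(dem, config)
  stack <- build_predictors(dem, forest, lines$water_mask,
                            lines$major_road_mask, lines$trail_mask,
                            passes = config$smoothing_passes,
                            ridge_threshold = config$ridge_threshold)
  truth <- make_truth_model(stack, config$true_lambdas)
  truth_raw <- raw_map(truth, stack)
  presences <- sample_presences(truth_raw, config$n_presences,
                                seed = stage_seed(config$seed, "presences"))
  stands <- make_stands(dem, config$n_stands,
                        seed = stage_seed(config$seed, "stands"))
  structure(list(dem = dem, forest_type = forest,
                 water_mask = lines$water_mask,
                 major_road_mask = lines$major_road_mask,
                 trail_mask = lines$trail_mask, stack = stack, truth = truth,
                 truth_raw = truth_raw, presences = presences,
                 stands = stands, config = config),
            class = "scenario_bundle")
}
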