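# Shared fixtures, all built in code.

# small deterministic scenario, memoized so several test files can reuse it
.fixture_env <- new.env(parent = emptyenv())

small_scenario <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- simulate_scenario(
      scenario_config(nrows = 60, ncols = 60, seed = 42,
                      n_presences = 60, n_stands = 30))
  }
  .fixture_env$small
}

# a 76-point / 54-stand thinning fixture: 54 single-cell stands (6 x 9 id
# grid), one point at every stand's cell center plus 22 duplicates
thinning_fixture <- function() {
  ids <- grid_layer(matrix(1:54, 6, 9), cellsize = 30)
  stands <- stands_from_ids(ids)
  ctr <- cell_center(ids, rep(1:6, 9), rep(1:9, each = 6))
  extra <- 1:22
  occurrence_set(c(ctr$x, ctr$x[extra] + 5), c(ctr$y, ctr$y[extra] - 5))
}

# plane DEMs (row 1 = north): "east" rises eastward, "north" rises northward
plane_grid <- function(n = 5, slope_dir = c("east", "north"), cellsize = 1) {
  slope_dir <- match.arg(slope_dir)
  v <- if (slope_dir == "east")
    matrix(rep(seq_len(n), each = n), n, n)   # column j has value j
  else
    matrix(rep(rev(seq_len(n)), n), n, n)     # row 1 (north) is highest
  grid_layer(v, cellsize = cellsize)
}
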