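#' Stand partition of a grid extent
#'
#' Stands are the forest-management polygons used as spatial-thinning units.
#' The package represents a partition either as the Voronoi diagram of a set
#' of generator points (every location belongs to its nearest generator) or,
#' through [stands_from_ids()], as an arbitrary integer-coded id grid
#' rasterized from real stand polygons. Both forms answer the only query the
#' pipeline needs: which stand contains a point.
#'
#' @param seeds data.frame with columns `x`, `y` of generator points (one per
#'   stand).
#' @param extent extent vector as returned by [grid_extent()].
#' @param id_grid optional [grid_layer()] of integer stand ids (overrides the
#'   Voronoi rule where supplied).
#' @return object of class `"stand_partition"`.
#' @export
stand_partition <- function(seeds = NULL, extent = NULL, id_grid = NULL) {
  if (is.null(seeds) && is.null(id_grid))
    stop("supply generator points or an id grid")
  structure(list(seeds = seeds, extent = extent, id_grid = id_grid),
            class = "stand_partition")
}

#' Stand partition from a rasterized id grid
#'
#' Adapter for real stand maps: any integer-coded grid (e.g. polygons burned
#' onto the analysis grid) defines the partition.
#'
#' @param id_grid a [grid_layer()] of integer stand ids.
#' @return a [stand_partition()].
#' @export
stands_from_ids <- function(id_grid) {
  stand_partition(id_grid = id_grid, extent = grid_extent(id_grid))
}

#' Number of stands in a partition
#' @param stands a [stand_partition()].
#' @return integer count.
#' @export
n_stands <- function(stands) {
  if (!is.null(stands$seeds)) nrow(stands$seeds)
  else length(unique(stats::na.omit(as.vector(stands$id_grid$values))))
}

#' Stand membership of points
#'
#' @param stands a [stand_partition()].
#' @param x,y point coordinates.
#' @return integer stand id per point (`NA` outside the partition).
#' @export
stand_of <- function(stands, x, y) {
  if (!is.null(stands$id_grid)) {
    idx <- cell_index_at(stands$id_grid, x, y)
    out <- rep(NA_integer_, length(x))
    ok <- !is.na(idx)
    out[ok] <- as.integer(stands$id_grid$values[idx[ok]])
    return(out)
  }
  ext <- stands$extent
  inside <- x >= ext["xmin"] & x <= ext["xmax"] &
    y >= ext["ymin"] & y <= ext["ymax"]
  d2 <- outer(x, stands$seeds$x, "-")^2 + outer(y, stands$seeds$y, "-")^2
  out <- max.col(-d2, ties.method = "first")
  out[!inside] <- NA_integer_
  as.integer(out)
}

#' Generate a Voronoi stand partition
#'
#' Partitions a grid extent into `n` contiguous polygons as the Voronoi cells
#' of uniformly placed generator points. Every location in the extent belongs
#' to exactly one stand, so the cells tile the extent.
#'
#' @param grid a [grid_layer()] supplying the extent.
#' @param n number of stands (>= 1, at most the cell count).
#' @param seed integer RNG seed.
#' @return a [stand_partition()].
#' @export
make_stands <- function(grid, n, seed = 1) {
  stopifnot(n >= 1L)
  ncell <- grid_nrow(grid) * grid_ncol(grid)
  if (n > ncell) stop("more stands than grid cells")
  ext <- grid_extent(grid)
  rng <- local_rng(seed)
  # generators at distinct cell centers, so n stands are always non-empty
  cells <- rng$sample_int(ncell, n)
  nr <- grid_nrow(grid)
  rows <- ((cells - 1L) %% nr) + 1L
  cols <- ((cells - 1L) %/% nr) + 1L
  ctr <- cell_center(grid, rows, cols)
  stand_partition(seeds = data.frame(x = ctr$x, y = ctr$y), extent = ext)
}
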