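#' Single-band georeferenced raster grid
#'
#' `grid_layer()` is the universal carrier for predictor and output layers:
#' a numeric matrix (row 1 = northernmost row) with an ESRI-ASCII-style
#' georeference (lower-left corner, square cells, nodata sentinel). Nodata
#' cells are held as `NA` internally and only rendered as the sentinel on
#' write, so ordinary arithmetic propagates nodata automatically.
#'
#' Cell centers follow the ESRI ASCII convention:
#' `x = xllcorner + (col - 0.5) * cellsize`,
#' `y = yllcorner + (nrows - row + 0.5) * cellsize` (1-based row/col).
#'
#' @param values numeric matrix, row 1 = north. Cells equal to `nodata` are
#'   converted to `NA`.
#' @param xllcorner,yllcorner map coordinates of the lower-left corner of the
#'   lower-left cell.
#' @param cellsize cell edge length in map units (must be > 0).
#' @param nodata sentinel written for missing cells (default -9999).
#' @return an object of class `"grid_layer"`.
#' @export
grid_layer <- function(values, xllcorner = 0, yllcorner = 0, cellsize = 30,
                       nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0)
    stop("cellsize must be a single positive number")
  values[!is.na(values) & values == nodata] <- NA_real_
  structure(
    list(values = values, xllcorner = as.numeric(xllcorner),
         yllcorner = as.numeric(yllcorner), cellsize = as.numeric(cellsize),
         nodata = as.numeric(nodata)),
    class = "grid_layer")
}

#' @export
print.grid_layer <- function(x, ...) {
  v <- x$values
  cat(sprintf("<grid_layer> %d rows x %d cols, cellsize %g\n",
              nrow(v), ncol(v), x$cellsize))
  cat(sprintf("  origin (xll, yll): (%g, %g); %d nodata cell(s)\n",
              x$xllcorner, x$yllcorner, sum(is.na(v))))
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  if (all(is.finite(rng)))
    cat(sprintf("  value range: [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

is_grid_layer <- function(x) inherits(x, "grid_layer")

grid_nrow <- function(g) nrow(g$values)
grid_ncol <- function(g) ncol(g$values)

#' Extent of a grid
#'
#' @param g a `grid_layer`.
#' @return named numeric vector `c(xmin, xmax, ymin, ymax)`.
#' @export
grid_extent <- function(g) {
  c(xmin = g$xllcorner,
    xmax = g$xllcorner + grid_ncol(g) * g$cellsize,
    ymin = g$yllcorner,
    ymax = g$yllcorner + grid_nrow(g) * g$cellsize)
}

# same extent / cellsize (co-registration) check
grids_compatible <- function(a, b, tol = 1e-9) {
  isTRUE(all.equal(grid_extent(a), grid_extent(b), tolerance = tol)) &&
    abs(a$cellsize - b$cellsize) < tol &&
    grid_nrow(a) == grid_nrow(b) && grid_ncol(a) == grid_ncol(b)
}

#' Map coordinates of cell centers
#'
#' @param g a `grid_layer`.
#' @param row,col 1-based row (from north) and column (from west) indices.
#' @return data.frame with columns `x`, `y`.
#' @export
cell_center <- function(g, row, col) {
  data.frame(x = g$xllcorner + (col - 0.5) * g$cellsize,
             y = g$yllcorner + (grid_nrow(g) - row + 0.5) * g$cellsize)
}

#' Locate points on a grid
#'
#' @param g a `grid_layer`.
#' @param x,y point coordinates (map units).
#' @return data.frame with columns `row`, `col` (NA for points outside the
#'   extent).
#' @export
cell_at <- function(g, x, y) {
  col <- floor((x - g$xllcorner) / g$cellsize) + 1L
  row <- grid_nrow(g) - floor((y - g$yllcorner) / g$cellsize)
  bad <- col < 1L | col > grid_ncol(g) | row < 1L | row > grid_nrow(g)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

# linear (column-major) cell index of points; NA outside extent
cell_index_at <- function(g, x, y) {
  rc <- cell_at(g, x, y)
  rc$row + (rc$col - 1L) * grid_nrow(g)
}

#' Read an ESRI ASCII grid
#'
#' Parses the 6-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`) followed by `nrows` whitespace-separated rows in
#' north-to-south order. Malformed input raises an error naming the offending
#' line.
#'
#' @param path path to a `.asc` file.
#' @return a [grid_layer()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  keys <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (length(lines) < 6L)
    stop(sprintf("'%s': fewer than 6 header lines", path))
  hdr <- numeric(6)
  for (i in seq_len(6L)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2L || tolower(parts[1]) != keys[i])
      stop(sprintf("'%s' line %d: expected '%s <value>', got '%s'",
                   path, i, keys[i], lines[i]))
    val <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(val))
      stop(sprintf("'%s' line %d: non-numeric %s", path, i, keys[i]))
    hdr[i] <- val
  }
  ncols <- as.integer(hdr[1]); nrows <- as.integer(hdr[2])
  if (ncols < 1L || nrows < 1L)
    stop(sprintf("'%s': ncols/nrows must be positive", path))
  body <- lines[-seq_len(6L)]
  if (length(body) != nrows)
    stop(sprintf("'%s': expected %d data rows, found %d",
                 path, nrows, length(body)))
  vals <- matrix(NA_real_, nrows, ncols)
  for (r in seq_len(nrows)) {
    row <- suppressWarnings(as.numeric(strsplit(trimws(body[r]), "\\s+")[[1]]))
    if (length(row) != ncols)
      stop(sprintf("'%s' line %d: expected %d values, found %d",
                   path, r + 6L, ncols, length(row)))
    if (anyNA(row))
      stop(sprintf("'%s' line %d: non-numeric cell value", path, r + 6L))
    vals[r, ] <- row
  }
  grid_layer(vals, hdr[3], hdr[4], hdr[5], nodata = hdr[6])
}

#' Write an ESRI ASCII grid
#'
#' Values are written with 17 significant digits so that
#' `read_ascii_grid(write_ascii_grid(g))` round-trips losslessly; `NA` cells
#' are written as the grid's nodata sentinel.
#'
#' @param g a [grid_layer()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(g, path) {
  stopifnot(is_grid_layer(g))
  num <- function(x) {
    out <- trimws(formatC(x, format = "g", digits = 17))
    # keep integers compact
    int <- !is.na(x) & x == round(x) & abs(x) < 1e15
    out[int] <- formatC(x[int], format = "d")
    out
  }
  hdr <- c(paste("ncols", grid_ncol(g)),
           paste("nrows", grid_nrow(g)),
           paste("xllcorner", num(g$xllcorner)),
           paste("yllcorner", num(g$yllcorner)),
           paste("cellsize", num(g$cellsize)),
           paste("NODATA_value", num(g$nodata)))
  v <- g$values
  v[is.na(v)] <- g$nodata
  rows <- apply(v, 1L, function(r) paste(num(r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Resample a grid to a coarser resolution
#'
#' Aggregates whole blocks of cells into one target cell covering the same
#' extent. `method = "mean"` takes the block mean over non-nodata cells
#' (continuous layers); `method = "nearest"` takes the value of the source
#' cell containing the target cell's center, ties at block boundaries falling
#' to the south-east cell (categorical layers). Upsampling is not supported.
#'
#' @param g a [grid_layer()].
#' @param target_cellsize new cell size; must be an integer multiple of
#'   `g$cellsize`.
#' @param method `"mean"` or `"nearest"`.
#' @return a [grid_layer()] at the new resolution.
#' @export
resample_grid <- function(g, target_cellsize, method = c("mean", "nearest")) {
  method <- match.arg(method)
  stopifnot(is_grid_layer(g))
  f <- target_cellsize / g$cellsize
  if (f < 1)
    stop("upsampling (target cellsize smaller than source) is not supported")
  if (abs(f - round(f)) > 1e-9)
    stop("target_cellsize must be an integer multiple of the source cellsize")
  f <- as.integer(round(f))
  if (f == 1L) return(g)
  nr <- grid_nrow(g); nc <- grid_ncol(g)
  if (nr %% f != 0L || nc %% f != 0L)
    stop("grid dimensions must be divisible by the aggregation factor ",
         "so the resampled grid covers the same extent")
  nr2 <- nr %/% f; nc2 <- nc %/% f
  ri <- ceiling(seq_len(nr) / f); ci <- ceiling(seq_len(nc) / f)
  if (method == "mean") {
    vals <- g$values
    ok <- !is.na(vals)
    vals[!ok] <- 0
    s <- t(rowsum(t(rowsum(vals, ri)), ci))          # block sums
    n <- t(rowsum(t(rowsum(ok * 1, ri)), ci))        # valid-cell counts
    out <- s / n
    out[n == 0] <- NA_real_
    dimnames(out) <- NULL
  } else {
    # source cell containing the target center: offset floor(f/2) + 1 within
    # the block (for even f the center lies on a cell boundary and falls
    # south-east)
    off <- floor(f / 2) + 1L
    src_r <- pmin((seq_len(nr2) - 1L) * f + off, nr)
    src_c <- pmin((seq_len(nc2) - 1L) * f + off, nc)
    out <- g$values[src_r, src_c, drop = FALSE]
  }
  grid_layer(out, g$xllcorner, g$yllcorner, target_cellsize, nodata = g$nodata)
}
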