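# DEM-derived predictor layers: smoothing, Horn slope, aspect decomposition,
# Zevenbergen-Thorne curvature, D8 hydrology on the inverted surface for ridge
# extraction, exact Euclidean distance transforms, and the collinearity check.

# shifted copy: out[r, c] = m[r + dr, c + dc]; off-grid cells become `fill`
shift_mat <- function(m, dr, dc, fill = NA_real_) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
  rok <- rs >= 1L & rs <= nr; cok <- cs >= 1L & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

# mirror-pad by one cell on every side (edge rows/cols duplicated)
pad_mirror <- function(m) {
  m2 <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
  cbind(m2[, 1, drop = FALSE], m2, m2[, ncol(m2), drop = FALSE])
}

# 3x3 neighborhood of the padded matrix as a list a..i (a = NW of center)
neigh3 <- function(mp) {
  nr <- nrow(mp) - 2L; nc <- ncol(mp) - 2L
  pick <- function(dr, dc) mp[(1 + dr):(nr + dr), (1 + dc):(nc + dc)]
  list(a = pick(0, 0), b = pick(0, 1), c = pick(0, 2),
       d = pick(1, 0), e = pick(1, 1), f = pick(1, 2),
       g = pick(2, 0), h = pick(2, 1), i = pick(2, 2))
}

# replace NA neighbors by the center value (ArcGIS-like treatment at nodata)
center_fill <- function(n) {
  for (k in setdiff(names(n), "e")) {
    miss <- is.na(n[[k]])
    n[[k]][miss] <- n$e[miss]
  }
  n
}

#' Smooth a DEM with repeated 3x3 focal means
#'
#' Removes production artifacts before slope/curvature/ridge derivation. Each
#' pass replaces every cell with the mean of its 3x3 neighborhood; at grid
#' edges and next to nodata cells the mean uses only in-grid, non-nodata
#' cells. Nodata cells stay nodata.
#'
#' @param dem a [grid_layer()].
#' @param passes number of filter passes (default 10).
#' @return smoothed [grid_layer()].
#' @export
smooth_dem <- function(dem, passes = 10) {
  stopifnot(is_grid_layer(dem), passes >= 0)
  z <- dem$values
  valid <- !is.na(z)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  for (p in seq_len(passes)) {
    zs <- z; zs[!valid] <- 0
    s <- matrix(0, nrow(z), ncol(z)); n <- s
    for (k in seq_len(nrow(offs))) {
      s <- s + shift_mat(zs, offs$dr[k], offs$dc[k], fill = 0)
      n <- n + shift_mat(valid * 1, offs$dr[k], offs$dc[k], fill = 0)
    }
    z <- s / n
    z[!valid] <- NA_real_
  }
  grid_layer(z, dem$xllcorner, dem$yllcorner, dem$cellsize,
             nodata = dem$nodata)
}

# Horn (1981) third-order finite-difference gradient; returns east- and
# north-pointing components (p = dz/dx, q = dz/dy with y increasing north)
horn_gradient <- function(dem) {
  n <- center_fill(neigh3(pad_mirror(dem$values)))
  L8 <- 8 * dem$cellsize
  p <- ((n$c + 2 * n$f + n$i) - (n$a + 2 * n$d + n$g)) / L8
  q <- ((n$a + 2 * n$b + n$c) - (n$g + 2 * n$h + n$i)) / L8
  list(p = p, q = q)
}

#' Slope in degrees (Horn's method)
#'
#' 3x3 third-order finite difference; edges use mirrored padding and nodata
#' neighbors take the center value.
#'
#' @param dem a [grid_layer()].
#' @return [grid_layer()] of slope in degrees.
#' @export
slope <- function(dem) {
  g <- horn_gradient(dem)
  s <- atan(sqrt(g$p^2 + g$q^2)) * 180 / pi
  s[is.na(dem$values)] <- NA_real_
  grid_layer(s, dem$xllcorner, dem$yllcorner, dem$cellsize,
             nodata = dem$nodata)
}

#' Aspect: downslope azimuth in degrees
#'
#' Clockwise from north in [0, 360); flat cells (zero gradient) are coded with
#' the reserved value -1.
#'
#' @param dem a [grid_layer()].
#' @return [grid_layer()] of aspect; flat cells -1.
#' @export
aspect <- function(dem) {
  g <- horn_gradient(dem)
  az <- atan2(-g$p, -g$q) * 180 / pi       # downslope vector (east, north)
  az <- (az + 360) %% 360
  flat <- g$p == 0 & g$q == 0
  az[flat] <- -1
  az[is.na(dem$values)] <- NA_real_
  grid_layer(az, dem$xllcorner, dem$yllcorner, dem$cellsize,
             nodata = dem$nodata)
}

#' Decompose aspect into northness and eastness
#'
#' Aspect is circular, so it enters the models as two components:
#' northness = cos(aspect), eastness = sin(aspect). South-facing cells have
#' northness near -1. Flat-coded cells (-1) map to (0, 0).
#'
#' @param asp aspect [grid_layer()] in degrees (or -1 for flat).
#' @return list with grids `ns` (northness) and `ew` (eastness).
#' @export
aspect_components <- function(asp) {
  a <- asp$values
  rad <- a * pi / 180
  ns <- cos(rad); ew <- sin(rad)
  flat <- !is.na(a) & a < 0
  ns[flat] <- 0; ew[flat] <- 0
  mk <- function(v) grid_layer(v, asp$xllcorner, asp$yllcorner, asp$cellsize,
                               nodata = asp$nodata)
  list(ns = mk(ns), ew = mk(ew))
}

#' Curvature (Zevenbergen-Thorne)
#'
#' Second derivative of the 3x3 quadratic surface fit, scaled by 100 per the
#' common GIS convention (units 1/(100 m)); positive values are upwardly
#' convex (ridges), negative concave (valleys).
#'
#' @param dem a [grid_layer()].
#' @return curvature [grid_layer()].
#' @export
curvature <- function(dem) {
  n <- center_fill(neigh3(pad_mirror(dem$values)))
  L2 <- dem$cellsize^2
  D <- ((n$d + n$f) / 2 - n$e) / L2
  E <- ((n$b + n$h) / 2 - n$e) / L2
  cv <- -2 * (D + E) * 100
  cv[is.na(dem$values)] <- NA_real_
  grid_layer(cv, dem$xllcorner, dem$yllcorner, dem$cellsize,
             nodata = dem$nodata)
}

#' Fill sinks in a DEM
#'
#' Raises cells the minimal amount (plus a tiny epsilon gradient that resolves
#' flats deterministically) so that every cell has a non-ascending D8 path to
#' the grid edge or to a nodata cell, using the iterative algorithm of
#' Planchon & Darboux (2001). Cells not in sinks are unchanged.
#'
#' @param dem a [grid_layer()].
#' @param eps drainage-enforcing increment (default `1e-6 * cellsize`).
#' @return filled [grid_layer()].
#' @export
fill_sinks <- function(dem, eps = 1e-6 * dem$cellsize) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  valid <- !is.na(z)
  # border cells: on the grid edge or 8-adjacent to nodata; they drain freely
  edge <- matrix(FALSE, nr, nc)
  edge[1, ] <- TRUE; edge[nr, ] <- TRUE; edge[, 1] <- TRUE; edge[, nc] <- TRUE
  near_na <- matrix(FALSE, nr, nc)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  if (any(!valid)) {
    for (k in seq_len(nrow(offs)))
      near_na <- near_na |
        shift_mat((!valid) * 1, offs$dr[k], offs$dc[k], fill = 0) > 0
  }
  border <- (edge | near_na) & valid
  w <- matrix(Inf, nr, nc)
  w[border] <- z[border]
  w[!valid] <- -Inf                     # nodata acts as an unconditional drain
  interior <- valid & !border
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > nr * nc + 1L) stop("sink filling failed to converge")
    nmin <- matrix(Inf, nr, nc)
    for (k in seq_len(nrow(offs)))
      nmin <- pmin(nmin, shift_mat(w, offs$dr[k], offs$dc[k], fill = Inf))
    wnew <- pmax(z, pmin(w, nmin + eps))
    wnew[!interior] <- w[!interior]
    if (all(wnew[interior] == w[interior])) break
    w <- wnew
  }
  w[!valid] <- NA_real_
  grid_layer(w, dem$xllcorner, dem$yllcorner, dem$cellsize,
             nodata = dem$nodata)
}

# D8 neighbor table in ArcGIS code order (tie-break = smallest code)
d8_table <- function() {
  data.frame(code = c(1, 2, 4, 8, 16, 32, 64, 128),
             dr = c(0, 1, 1, 1, 0, -1, -1, -1),
             dc = c(1, 1, 0, -1, -1, -1, 0, 1))
}

#' D8 flow direction
#'
#' Steepest-descent direction among the 8 neighbors (drop divided by
#' center-to-center distance), ArcGIS codes 1 = E, 2 = SE, 4 = S, 8 = SW,
#' 16 = W, 32 = NW, 64 = N, 128 = NE. Ties take the smallest code. Cells with
#' no lower in-grid neighbor (outlets at the grid or nodata edge, or sinks in
#' an unfilled DEM) get code 0.
#'
#' @param dem a sink-filled [grid_layer()].
#' @return [grid_layer()] of direction codes.
#' @export
flow_direction <- function(dem) {
  z <- dem$values
  tab <- d8_table()
  best <- matrix(0, nrow(z), ncol(z))
  code <- matrix(0, nrow(z), ncol(z))
  for (k in seq_len(nrow(tab))) {
    zn <- shift_mat(z, tab$dr[k], tab$dc[k], fill = NA_real_)
    dist <- dem$cellsize * if (tab$dr[k] != 0 && tab$dc[k] != 0) sqrt(2) else 1
    drop <- (z - zn) / dist
    upd <- !is.na(drop) & drop > best   # strict: earlier (smaller) code wins
    best[upd] <- drop[upd]
    code[upd] <- tab$code[k]
  }
  code[is.na(z)] <- NA_real_
  grid_layer(code, dem$xllcorner, dem$yllcorner, dem$cellsize,
             nodata = dem$nodata)
}

# receiver linear index (column-major) per cell, 0 = outlet, NA = nodata
d8_receiver <- function(fdir) {
  v <- fdir$values
  nr <- nrow(v); nc <- ncol(v)
  tab <- d8_table()
  recv <- matrix(0L, nr, nc)
  rows <- row(v); cols <- col(v)
  for (k in seq_len(nrow(tab))) {
    sel <- !is.na(v) & v == tab$code[k]
    rr <- rows[sel] + tab$dr[k]; cc <- cols[sel] + tab$dc[k]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    ri <- integer(sum(sel)); ri[ok] <- rr[ok] + (cc[ok] - 1L) * nr
    recv[sel] <- ri                      # 0 for receivers off-grid
  }
  recv[is.na(v)] <- NA_integer_
  # receivers that are nodata cells count as off-grid outlets
  flat_na <- which(!is.na(recv) & recv > 0L)
  tgt <- recv[flat_na]
  recv[flat_na][is.na(v[tgt])] <- 0L
  recv
}

# Kahn topological order over the D8 graph; errors on a cycle
d8_topo_order <- function(recv) {
  n <- length(recv)
  cells <- which(!is.na(recv))
  indeg <- integer(n)
  tgt <- recv[cells]
  tgt <- tgt[tgt > 0L]
  tb <- tabulate(tgt, nbins = n)
  indeg <- tb
  queue <- cells[indeg[cells] == 0L]
  order <- integer(length(cells)); head <- 1L; tail <- length(queue)
  order[seq_len(tail)] <- queue
  while (head <= tail) {
    c0 <- order[head]; head <- head + 1L
    r <- recv[c0]
    if (!is.na(r) && r > 0L) {
      indeg[r] <- indeg[r] - 1L
      if (indeg[r] == 0L) { tail <- tail + 1L; order[tail] <- r }
    }
  }
  if (tail != length(cells))
    stop("cycle detected in flow directions; input DEM was not sink-filled")
  order
}

#' D8 flow accumulation
#'
#' Number of upstream cells draining through each cell, excluding the cell
#' itself (so headwater cells are 0). Errors if the direction grid contains a
#' cycle, which signals an unfilled DEM.
#'
#' @param fdir direction codes from [flow_direction()].
#' @return accumulation [grid_layer()].
#' @export
flow_accumulation <- function(fdir) {
  recv <- d8_receiver(fdir)
  ord <- d8_topo_order(recv)
  acc <- numeric(length(recv))
  for (c0 in ord) {
    r <- recv[c0]
    if (r > 0L) acc[r] <- acc[r] + acc[c0] + 1
  }
  out <- matrix(acc, nrow(fdir$values), ncol(fdir$values))
  out[is.na(fdir$values)] <- NA_real_
  grid_layer(out, fdir$xllcorner, fdir$yllcorner, fdir$cellsize,
             nodata = fdir$nodata)
}

#' Strahler stream order on the channel network
#'
#' Channels are cells whose flow accumulation meets the threshold. Headwater
#' channel cells are order 1; where two donors of equal order meet the order
#' increments, otherwise the maximum donor order carries through (Strahler's
#' rule). Non-channel cells are nodata.
#'
#' @param fdir direction codes from [flow_direction()].
#' @param faccum accumulation from [flow_accumulation()].
#' @param threshold minimum accumulation (upstream cell count) defining a
#'   channel; must be >= 1.
#' @return [grid_layer()] of Strahler orders (nodata off-channel).
#' @export
stream_order <- function(fdir, faccum, threshold) {
  stopifnot(threshold >= 1)
  recv <- d8_receiver(fdir)
  ord <- d8_topo_order(recv)
  chan <- !is.na(faccum$values) & faccum$values >= threshold
  n <- length(recv)
  maxo <- integer(n); cntmax <- integer(n)
  so <- rep(NA_real_, n)
  for (c0 in ord) {
    if (!chan[c0]) next
    o <- if (maxo[c0] == 0L) 1L else maxo[c0] + (cntmax[c0] >= 2L)
    so[c0] <- o
    r <- recv[c0]
    if (r > 0L && chan[r]) {
      if (o > maxo[r]) { maxo[r] <- o; cntmax[r] <- 1L }
      else if (o == maxo[r]) cntmax[r] <- cntmax[r] + 1L
    }
  }
  out <- matrix(so, nrow(fdir$values), ncol(fdir$values))
  grid_layer(out, fdir$xllcorner, fdir$yllcorner, fdir$cellsize,
             nodata = fdir$nodata)
}

#' Extract ridge lines from a DEM
#'
#' Runs the fill / flow-direction / flow-accumulation / stream-order chain on
#' the inverted DEM (elevation times -1), so that drainage concentration picks
#' out crests instead of channels. The result is a 0/1 mask of ridge cells.
#'
#' @param dem a [grid_layer()].
#' @param threshold channel threshold on the inverted surface; default 0.5%
#'   of the valid cell count (scale-free).
#' @return 0/1 ridge-mask [grid_layer()].
#' @export
extract_ridges <- function(dem, threshold = NULL) {
  if (is.null(threshold))
    threshold <- max(1, ceiling(0.005 * sum(!is.na(dem$values))))
  inv <- grid_layer(-dem$values, dem$xllcorner, dem$yllcorner, dem$cellsize,
                    nodata = dem$nodata)
  filled <- fill_sinks(inv)
  fdir <- flow_direction(filled)
  acc <- flow_accumulation(fdir)
  so <- stream_order(fdir, acc, threshold)
  mask <- ifelse(is.na(so$values), 0, 1)
  mask[is.na(dem$values)] <- NA_real_
  grid_layer(mask, dem$xllcorner, dem$yllcorner, dem$cellsize,
             nodata = dem$nodata)
}

# exact 1-D squared-distance transform (lower envelope of parabolas);
# f may contain Inf (columns with no source)
dt1d <- function(f) {
  n <- length(f)
  fin <- which(is.finite(f))
  if (length(fin) == 0L) return(rep(Inf, n))
  v <- integer(n); zz <- numeric(n + 1L)
  k <- 1L; v[1L] <- fin[1L]; zz[1L] <- -Inf; zz[2L] <- Inf
  for (q in fin[-1L]) {
    repeat {
      vk <- v[k]
      s <- ((f[q] + q * q) - (f[vk] + vk * vk)) / (2 * q - 2 * vk)
      if (s <= zz[k]) k <- k - 1L else break
    }
    k <- k + 1L; v[k] <- q; zz[k] <- s; zz[k + 1L] <- Inf
  }
  d <- numeric(n); k <- 1L
  for (q in seq_len(n)) {
    while (zz[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Euclidean distance to the nearest source cell
#'
#' Exact center-to-center Euclidean distance (map units) from every cell to
#' the nearest cell where `mask` equals 1, computed with the separable
#' squared-distance transform of Felzenszwalb & Huttenlocher. Nodata cells in
#' the mask stay nodata in the output (but valid cells measure distance to
#' sources across them).
#'
#' @param mask 0/1 source-mask [grid_layer()] with at least one source cell.
#' @return distance [grid_layer()] (0 exactly on source cells).
#' @export
euclidean_distance <- function(mask) {
  m <- mask$values
  src <- !is.na(m) & m == 1
  if (!any(src)) stop("mask contains no source cells")
  f <- matrix(Inf, nrow(m), ncol(m))
  f[src] <- 0
  # pass 1: down columns; pass 2: across rows
  for (j in seq_len(ncol(f))) f[, j] <- dt1d(f[, j])
  for (i in seq_len(nrow(f))) f[i, ] <- dt1d(f[i, ])
  d <- mask$cellsize * sqrt(f)
  d[is.na(m)] <- NA_real_
  grid_layer(d, mask$xllcorner, mask$yllcorner, mask$cellsize,
             nodata = mask$nodata)
}

#' Pearson correlations among layers inside a circular region
#'
#' The collinearity check: correlations are computed over cells whose centers
#' lie within `radius` of `center` and that are non-nodata in every layer.
#'
#' @param layers named list of co-registered [grid_layer()]s (>= 2).
#' @param center numeric `c(x, y)` of the circle center (map units).
#' @param radius circle radius in map units (default 1000).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
band_statistics <- function(layers, center, radius = 1000) {
  stopifnot(length(layers) >= 2L)
  g1 <- layers[[1L]]
  for (g in layers[-1L])
    if (!grids_compatible(g1, g)) stop("layers are not co-registered")
  rc <- expand.grid(row = seq_len(grid_nrow(g1)), col = seq_len(grid_ncol(g1)))
  ctr <- cell_center(g1, rc$row, rc$col)
  inside <- (ctr$x - center[1])^2 + (ctr$y - center[2])^2 <= radius^2
  if (sum(inside) < 3L)
    stop("fewer than 3 valid cells inside the region")
  vals <- vapply(layers, function(g) as.vector(g$values)[inside],
                 numeric(sum(inside)))
  vals <- vals[stats::complete.cases(vals), , drop = FALSE]
  if (nrow(vals) < 3L)
    stop("fewer than 3 valid cells inside the region")
  stats::cor(vals)
}

# zero-padded FFT cross-correlation of `m` with a centered 0/1 circular kernel
focal_circle_sum <- function(m, rad_cells) {
  nr <- nrow(m); nc <- ncol(m)
  kr <- -rad_cells:rad_cells
  kern <- outer(kr, kr, function(a, b) (a * a + b * b) <= rad_cells^2) * 1
  P <- nr + 2 * rad_cells; Q <- nc + 2 * rad_cells
  A <- matrix(0, P, Q); A[seq_len(nr), seq_len(nc)] <- m
  K <- matrix(0, P, Q)
  K[seq_len(2 * rad_cells + 1L), seq_len(2 * rad_cells + 1L)] <- kern
  conv <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) /
    (P * Q)
  conv[rad_cells + seq_len(nr), rad_cells + seq_len(nc)]
}

#' Locate the most and least rugged portions of a DEM
#'
#' Ruggedness is the standard deviation of elevation within a circular window;
#' the centers of the windows maximizing and minimizing it anchor the
#' collinearity-check regions. Ties break in row-major (north-to-south,
#' west-to-east) order.
#'
#' @param dem a [grid_layer()].
#' @param radius window radius in map units.
#' @return list with `most_rugged` and `least_rugged`, each a list holding the
#'   center point (`x`, `y`) and the window `sd`.
#' @export
ruggedness_centers <- function(dem, radius) {
  rad_cells <- floor(radius / dem$cellsize)
  if (2 * rad_cells + 1 > min(dim(dem$values)))
    stop("window larger than the DEM")
  z <- dem$values
  valid <- !is.na(z)
  z0 <- z; z0[!valid] <- 0
  s1 <- focal_circle_sum(z0, rad_cells)
  s2 <- focal_circle_sum(z0^2, rad_cells)
  n <- focal_circle_sum(valid * 1, rad_cells)
  n <- round(n)
  varv <- (s2 - s1^2 / pmax(n, 1)) / pmax(n - 1, 1)
  sdv <- sqrt(pmax(varv, 0))
  sdv[!valid | n < 2] <- NA_real_
  # row-major tie-break: scan the transpose
  st <- t(sdv)
  imax <- which(st == max(st, na.rm = TRUE))[1L]
  imin <- which(st == min(st, na.rm = TRUE))[1L]
  to_rc <- function(i) {
    col <- ((i - 1L) %/% nrow(st)) + 1L   # row of t() = col of sdv
    row <- ((i - 1L) %% nrow(st)) + 1L
    c(row = col, col = row)
  }
  mk <- function(i) {
    rc <- to_rc(i)
    ctr <- cell_center(dem, rc["row"], rc["col"])
    list(x = ctr$x, y = ctr$y, sd = sdv[rc["row"], rc["col"]])
  }
  list(most_rugged = mk(imax), least_rugged = mk(imin))
}

#' Assemble the full predictor stack from base layers
#'
#' Derives every model variable from the DEM and the vector-feature masks:
#' elevation (E), Horn slope (S) and Zevenbergen-Thorne curvature (C) from the
#' smoothed DEM, northness/eastness (NS/EW) from aspect, distance-to-ridge (R)
#' via D8 ridge extraction on the inverted smoothed DEM, Euclidean distances
#' to water (W), major roads (MR) and trails/minor roads (TR), and the
#' categorical forest-type layer (FT).
#'
#' @param dem elevation [grid_layer()] (m).
#' @param forest_type integer-coded categorical [grid_layer()].
#' @param water_mask,major_road_mask,trail_mask 0/1 source masks.
#' @param passes smoothing passes before slope/curvature/ridge derivation.
#' @param ridge_threshold channel threshold for [extract_ridges()] (default
#'   0.5% of valid cells).
#' @return named list of co-registered grids (class `"predictor_stack"`) with
#'   elements `E`, `S`, `NS`, `EW`, `C`, `R`, `W`, `MR`, `TR`, `FT`.
#' @export
build_predictors <- function(dem, forest_type, water_mask, major_road_mask,
                             trail_mask, passes = 10, ridge_threshold = NULL) {
  sm <- smooth_dem(dem, passes = passes)
  comps <- aspect_components(aspect(dem))
  ridge <- extract_ridges(sm, threshold = ridge_threshold)
  stack <- list(E = dem,
                S = slope(sm),
                NS = comps$ns,
                EW = comps$ew,
                C = curvature(sm),
                R = euclidean_distance(ridge),
                W = euclidean_distance(water_mask),
                MR = euclidean_distance(major_road_mask),
                TR = euclidean_distance(trail_mask),
                FT = forest_type)
  predictor_stack(stack)
}

#' Construct a predictor stack from named grids
#'
#' @param layers named list of co-registered [grid_layer()]s.
#' @return the list with class `"predictor_stack"`.
#' @export
predictor_stack <- function(layers) {
  stopifnot(length(layers) >= 1L, !is.null(names(layers)))
  g1 <- layers[[1L]]
  for (g in layers[-1L])
    if (!grids_compatible(g1, g))
      stop("all stack layers must share extent and cellsize")
  structure(layers, class = "predictor_stack")
}

# logical matrix: cells valid (non-nodata) in every layer of the stack
stack_valid <- function(stack) {
  v <- !is.na(stack[[1L]]$values)
  for (g in stack[-1L]) v <- v & !is.na(g$values)
  v
}
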