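# Model-averaged suitability mapping and habitat classification.

#' AICc-weighted average of logistic maps
#'
#' Cellwise weighted mean with the supplied weights renormalized over the
#' averaged set; nodata wherever any input map is nodata. With a single map
#' (or identical maps) the output equals the input regardless of weights.
#'
#' @param logistic_maps list of co-registered [grid_layer()]s on the logistic
#'   scale.
#' @param weights non-negative weights, at least one positive.
#' @return averaged [grid_layer()].
#' @export
average_map <- function(logistic_maps, weights) {
  stopifnot(length(logistic_maps) >= 1L,
            length(weights) == length(logistic_maps))
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative with a positive sum")
  g1 <- logistic_maps[[1L]]
  for (g in logistic_maps[-1L])
    if (!grids_compatible(g1, g)) stop("maps are not co-registered")
  w <- weights / sum(weights)
  acc <- matrix(0, grid_nrow(g1), grid_ncol(g1))
  for (i in seq_along(logistic_maps))
    acc <- acc + w[i] * logistic_maps[[i]]$values
  grid_layer(acc, g1$xllcorner, g1$yllcorner, g1$cellsize, nodata = g1$nodata)
}

#' Classify a probability map into habitat classes
#'
#' Codes 0 (unsuitable), 1 (suitable, `>= suitable` and `< optimal`) and 2
#' (optimal, `>= optimal`); both thresholds are inclusive.
#'
#' @param map probability [grid_layer()] with values in [0, 1].
#' @param suitable,optimal thresholds (defaults 0.5 and 0.75);
#'   `suitable <= optimal` required.
#' @return [grid_layer()] of class codes.
#' @export
classify_habitat <- function(map, suitable = 0.5, optimal = 0.75) {
  if (suitable > optimal) stop("suitable threshold must be <= optimal")
  v <- map$values
  cls <- ifelse(v >= optimal, 2, ifelse(v >= suitable, 1, 0))
  out <- grid_layer(cls, map$xllcorner, map$yllcorner, map$cellsize,
                    nodata = map$nodata)
  attr(out, "thresholds") <- c(suitable = suitable, optimal = optimal)
  out
}

#' Summarize a classified habitat map
#'
#' Area fractions (over valid cells) of suitable and optimal habitat --
#' suitable is reported as class >= 1, i.e. it includes optimal cells -- and
#' the number of occurrence points falling in each.
#'
#' @param classified classified [grid_layer()] from [classify_habitat()].
#' @param points optional [occurrence_set()].
#' @return list of class `"suitability_summary"`: `fraction_suitable`,
#'   `fraction_optimal`, `n_points`, `n_points_in_suitable`,
#'   `n_points_in_optimal`, `thresholds`.
#' @export
summarize_habitat <- function(classified, points = NULL) {
  v <- classified$values
  nvalid <- sum(!is.na(v))
  fs <- sum(v >= 1, na.rm = TRUE) / nvalid
  fo <- sum(v >= 2, na.rm = TRUE) / nvalid
  np <- ns <- no <- 0L
  if (!is.null(points) && nrow(points) > 0L) {
    idx <- cell_index_at(classified, points$x, points$y)
    if (anyNA(idx)) stop("point(s) outside the classified map extent")
    cls <- v[idx]
    np <- nrow(points)
    ns <- sum(cls >= 1, na.rm = TRUE)
    no <- sum(cls >= 2, na.rm = TRUE)
  }
  structure(list(fraction_suitable = fs, fraction_optimal = fo,
                 n_points = np, n_points_in_suitable = ns,
                 n_points_in_optimal = no,
                 thresholds = attr(classified, "thresholds")),
            class = "suitability_summary")
}

#' @export
print.suitability_summary <- function(x, ...) {
  cat(sprintf("suitable habitat: %.1f%% of area", 100 * x$fraction_suitable))
  if (x$n_points > 0)
    cat(sprintf(" (%d/%d points)", x$n_points_in_suitable, x$n_points))
  cat(sprintf("\noptimal habitat:  %.1f%% of area", 100 * x$fraction_optimal))
  if (x$n_points > 0)
    cat(sprintf(" (%d/%d points)", x$n_points_in_optimal, x$n_points))
  cat("\n")
  invisible(x)
}

#' Model-averaged suitability map from a comparison run
#'
#' Builds each plausible model's logistic map (raw map transformed with its
#' own entropy), averages them with renormalized Akaike weights, and
#' classifies the result. The averaging set defaults to the `delta < 7`
#' plausible set; pass `models` to override.
#'
#' @param comparison a `"comparison_table"` from [run_comparison()].
#' @param stack the [predictor_stack()].
#' @param delta_max support cutoff for the averaging set (default 7).
#' @param models optional character vector of model names overriding the
#'   plausible-set rule.
#' @param suitable,optimal classification thresholds.
#' @return list: `average` (logistic [grid_layer()]), `classified`,
#'   `models` (names averaged), `weights` (renormalized).
#' @export
suitability_map <- function(comparison, stack, delta_max = 7, models = NULL,
                            suitable = 0.5, optimal = 0.75) {
  if (is.null(models)) models <- plausible_set(comparison, delta_max)
  if (length(models) == 0L) stop("no models selected for averaging")
  fits <- attr(comparison, "models")[models]
  if (any(vapply(fits, is.null, TRUE)))
    stop("model(s) not present in the comparison: ",
         paste(models[vapply(fits, is.null, TRUE)], collapse = ", "))
  w <- comparison$weight[match(models, comparison$model)]
  maps <- lapply(fits, function(f)
    logistic_transform(raw_map(f, stack), f$entropy))
  avg <- average_map(maps, w)
  list(average = avg,
       classified = classify_habitat(avg, suitable, optimal),
       models = models, weights = w / sum(w))
}
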