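# Information-theoretic engine: the balanced candidate-model registry,
# AICc scoring of fitted maxent models, Akaike weights, the plausible set,
# and weight-sum variable importance.

#' The default candidate-model registry
#'
#' Twenty-six named a-priori hypotheses about roost-habitat selection, each a
#' subset of the ten predictor variables (FT, NS, EW, S, E, W, TR, MR, R, C),
#' including a global model. The set is balanced: every variable appears in
#' exactly eight models. (Foraging 1 carries W + TR + MR per its hypothesis,
#' "closer to water, trails, and major roads for foraging", which is what
#' makes the set balance.)
#'
#' @return data.frame with columns `name`, `variables` (list column of
#'   character vectors), `hypothesis`.
#' @export
default_registry <- function() {
  m <- function(name, vars, hyp)
    list(name = name, variables = strsplit(vars, "\\+")[[1]], hypothesis = hyp)
  models <- list(
    m("Corridor 1", "TR", "Closer to trails"),
    m("Corridor 2", "MR+C", "On shallow ridges and closer to major roads"),
    m("Corridor 3", "W", "Closer to water"),
    m("Elevation", "E", "At lower elevations"),
    m("Foraging 1", "W+TR+MR",
      "Closer to water, trails, and major roads for foraging"),
    m("Foraging 2", "S+W+TR", "Lower slope, and closer to water and trails"),
    m("Forest Type", "FT", "Uses forests with a pine-hardwood component"),
    m("Global", "FT+NS+EW+S+E+W+TR+MR+R+C",
      "All variables are important to roost selection"),
    m("Humans", "TR+MR", "Near human made corridors"),
    m("Major Roads", "MR", "Near major roads"),
    m("Needs 1", "E+W", "At lower elevations near water"),
    m("Needs 2", "FT+W", "In pine-hardwood forests near water"),
    m("Needs 3", "FT+W+TR+MR",
      "Near water, travel corridors, and pine-hardwood"),
    m("Pine 1", "FT+E", "In conditions that promote pines"),
    m("Pine 2", "FT+NS+EW+E+R",
      "In conditions that promote pines based on ridge location"),
    m("Research Bias 1", "FT+TR+MR",
      "Near easy access trails/roads in forest types we targeted"),
    m("Research Bias 2", "TR+MR+R",
      "Near easy access trails/roads and ridgetop telemetry points"),
    m("Ridge 1", "NS+EW+S+R", "South-facing, low slope, and near ridgetop"),
    m("Ridge 2", "S+E+C", "Low slope, shallow ridges at lower elevation"),
    m("Ridge 3", "FT+R+C",
      "Near the ridgetop of shallow ridges in pine-hardwood forests"),
    m("Sun 1", "NS+EW+R+C",
      "Near ridgetop of shallow ridges with south-facing"),
    m("Sun 2", "NS+EW+S+C",
      "On gentle slopes of shallow ridges with south-facing"),
    m("Sunny Ridgetop", "NS+EW+R", "Near the ridgetop and south-facing"),
    m("Topography 1", "NS+EW+S+E+R+C",
      "Near the ridgetop on shallow, gentle slopes with south facing"),
    m("Topography 2", "NS+EW+S+E", "Gentle south-facing slopes at lower elevations"),
    m("Water flow", "S+W+C",
      "Shallow ridges at low elevations where water flows seasonally"))
  out <- data.frame(name = vapply(models, `[[`, "", "name"),
                    hypothesis = vapply(models, `[[`, "", "hypothesis"),
                    stringsAsFactors = FALSE)
  out$variables <- lapply(models, `[[`, "variables")
  if (anyDuplicated(out$name)) stop("duplicate model names in registry")
  out[, c("name", "variables", "hypothesis")]
}

#' Read a candidate-model registry from a config file
#'
#' One record per line: `name: VAR1+VAR2+...` (or comma-separated codes).
#' Lines starting with `#` are ignored.
#'
#' @param path path to the registry file.
#' @return registry data.frame as in [default_registry()].
#' @export
read_registry <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  name <- sub(":.*$", "", lines)
  vars <- trimws(sub("^[^:]*:", "", lines))
  out <- data.frame(name = trimws(name), hypothesis = "",
                    stringsAsFactors = FALSE)
  out$variables <- lapply(strsplit(vars, "[+,]"), trimws)
  if (anyDuplicated(out$name)) stop("duplicate model names in registry file")
  if (any(lengths(out$variables) == 0L)) stop("model with empty variable set")
  out[, c("name", "variables", "hypothesis")]
}

#' Published ranking of the default candidate set
#'
#' The printed AICc ranking for the default registry from the original
#' Indiana bat roosting-habitat analysis (ranks 1-11 and the two last ranks;
#' intermediate models were not printed, but at these deltas their Akaike
#' weights are < 1e-12 and do not affect weight or importance arithmetic).
#' Useful as a worked example for [akaike_weights()] and
#' [variable_importance()].
#'
#' @return data.frame with columns `rank`, `model`, `aicc`.
#' @export
example_ranking <- function() {
  data.frame(
    rank = c(1:11, 25L, 26L),
    model = c("Pine 2", "Pine 1", "Topography 1", "Topography 2",
              "Elevation", "Needs 1", "Global", "Research Bias 1",
              "Needs 3", "Ridge 1", "Sun 2", "Corridor 1", "Corridor 3"),
    aicc = c(1540.54, 1543.81, 1546.09, 1548.07, 1559.21, 1561.90, 1570.12,
             1583.07, 1586.23, 1593.89, 1595.68, 1613.98, 1614.95),
    stringsAsFactors = FALSE)
}

#' Log-likelihood of occurrence points under a raw surface
#'
#' Standardizes the raw surface to sum to one over all valid map cells (the
#' ENMTools convention) and sums the log of the standardized value at each
#' point's cell.
#'
#' @param raw raw-output [grid_layer()].
#' @param points an [occurrence_set()].
#' @return log-likelihood (scalar).
#' @export
occurrence_log_likelihood <- function(raw, points) {
  tot <- sum(raw$values, na.rm = TRUE)
  idx <- cell_index_at(raw, points$x, points$y)
  if (anyNA(idx)) stop("point(s) outside the raw surface extent")
  v <- raw$values[idx]
  if (anyNA(v)) stop("point(s) on nodata cells of the raw surface")
  sum(log(v / tot))
}

#' Number of model parameters
#'
#' The parameter count used in AICc: the number of features whose lambda
#' exceeds `tol` in absolute value (the L1 penalty produces exact zeros, so
#' the default `tol = 0` counts the retained features).
#'
#' @param model a `"maxent_model"`.
#' @param tol zero threshold (default 0).
#' @return integer count.
#' @export
count_parameters <- function(model, tol = 0) {
  sum(abs(model$lambdas) > tol)
}

#' Small-sample-corrected AIC
#'
#' `AICc = 2k - 2 lnL + 2k(k + 1) / (n - k - 1)`; requires `n > k + 1`.
#'
#' @param lnL log-likelihood.
#' @param k parameter count.
#' @param n sample size (occurrence count).
#' @return AICc (scalar).
#' @export
aicc <- function(lnL, k, n) {
  if (n - k - 1 <= 0)
    stop(sprintf("model unscoreable: n (%d) must exceed k + 1 (%d)",
                 n, k + 1L))
  2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` with
#' `delta_i = AICc_i - min(AICc)`; invariant to adding a constant to all
#' scores, and sums to one.
#'
#' @param aicc_scores numeric vector of AICc scores.
#' @return numeric vector of weights.
#' @export
akaike_weights <- function(aicc_scores) {
  stopifnot(length(aicc_scores) >= 1L)
  d <- aicc_scores - min(aicc_scores)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Models with some support
#'
#' The plausible set: models whose AICc lies within `delta_max` of the best
#' (strictly `delta < delta_max`).
#'
#' @param table a comparison table with columns `model` and `delta` (as from
#'   [run_comparison()]).
#' @param delta_max support cutoff (default 7).
#' @return character vector of model names, best first.
#' @export
plausible_set <- function(table, delta_max = 7) {
  tab <- table[!is.na(table$delta) & table$delta < delta_max, , drop = FALSE]
  tab$model[order(tab$delta)]
}

#' Weight-sum variable importance
#'
#' The importance of a variable is the summed Akaike weight of every
#' candidate model whose variable set contains it; because weights sum to
#' one, each importance lies in [0, 1], and equals one minus the total weight
#' of the models excluding the variable.
#'
#' @param table comparison table with columns `model` and `weight`.
#' @param registry candidate registry (default [default_registry()]).
#' @return data.frame with columns `variable`, `importance`, sorted
#'   decreasing.
#' @export
variable_importance <- function(table, registry = default_registry()) {
  vars <- sort(unique(unlist(registry$variables)))
  w <- stats::setNames(rep(0, nrow(registry)), registry$name)
  hit <- table$model %in% registry$name
  w[table$model[hit]] <- ifelse(is.na(table$weight[hit]), 0,
                                table$weight[hit])
  imp <- vapply(vars, function(v) {
    inset <- vapply(registry$variables, function(vs) v %in% vs, TRUE)
    sum(w[registry$name[inset]])
  }, 0)
  if (any(imp == 0 & !vars %in% unlist(registry$variables)))
    warning("variable absent from every model")
  out <- data.frame(variable = vars, importance = unname(imp),
                    stringsAsFactors = FALSE)
  out[order(-out$importance), , drop = FALSE]
}

#' Fit and rank the full candidate set
#'
#' For each candidate model: fit on the shared training presences (the same
#' background sample and train/test split for every model), record train and
#' test AUC, compute the occurrence log-likelihood of the configured point
#' set under the raw map, count retained parameters, and score AICc. Then
#' rank by AICc, attach deltas and Akaike weights, and report. A model whose
#' parameter count reaches `n - 1` cannot be scored at this sample size; it
#' is reported with `NA` scores and weight 0 rather than silently dropped.
#'
#' @param stack a [predictor_stack()].
#' @param occurrences thinned, split [occurrence_set()] (see
#'   [thin_by_polygon()], [train_test_split()]).
#' @param registry candidate registry (default [default_registry()]).
#' @param background optional shared background (built from `bg_n`/`seed`
#'   when `NULL`).
#' @param beta regularization multiplier passed to [fit_maxent()].
#' @param aicc_points which points enter the log-likelihood and n:
#'   `"train"` (default) or `"all"`.
#' @param bg_n,seed background size and seed.
#' @param tol,max_iter optimizer controls passed to [fit_maxent()].
#' @return data.frame of class `"comparison_table"` with one row per
#'   candidate: `model`, `k`, `n`, `lnL`, `aicc`, `delta`, `weight`, `rank`,
#'   `train_auc`, `test_auc`. Fitted models are attached as attribute
#'   `"models"`.
#' @export
run_comparison <- function(stack, occurrences, registry = default_registry(),
                           background = NULL, beta = 1.0,
                           aicc_points = c("train", "all"),
                           bg_n = 10000, seed = 1, tol = 1e-8,
                           max_iter = 2000) {
  aicc_points <- match.arg(aicc_points)
  if (is.null(background))
    background <- sample_background(stack, n = bg_n, seed = seed,
                                    presences = occurrences)
  pts <- if (aicc_points == "train")
    occurrences[occurrences$partition != "test", , drop = FALSE]
  else occurrences
  n <- nrow(pts)
  rows <- vector("list", nrow(registry))
  fits <- vector("list", nrow(registry))
  names(fits) <- registry$name
  for (i in seq_len(nrow(registry))) {
    fit <- fit_maxent(stack, occurrences, registry$variables[[i]],
                      background = background, beta = beta, tol = tol,
                      max_iter = max_iter)
    fits[[i]] <- fit
    k <- count_parameters(fit)
    lnL <- occurrence_log_likelihood(raw_map(fit, stack), pts)
    score <- if (n - k - 1 > 0) aicc(lnL, k, n) else NA_real_
    if (is.na(score))
      warning(sprintf("model '%s' unscoreable (k = %d, n = %d); weight 0",
                      registry$name[i], k, n))
    rows[[i]] <- data.frame(model = registry$name[i], k = k, n = n,
                            lnL = lnL, aicc = score,
                            train_auc = fit$train_auc,
                            test_auc = fit$test_auc,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$aicc)
  tab$delta <- NA_real_; tab$weight <- 0; tab$rank <- NA_integer_
  tab$delta[ok] <- tab$aicc[ok] - min(tab$aicc[ok])
  tab$weight[ok] <- akaike_weights(tab$aicc[ok])
  tab$rank[ok] <- rank(tab$aicc[ok], ties.method = "first")
  tab <- tab[order(!ok, tab$aicc), , drop = FALSE]
  rownames(tab) <- NULL
  tab <- tab[, c("model", "k", "n", "lnL", "aicc", "delta", "weight",
                 "rank", "train_auc", "test_auc")]
  attr(tab, "models") <- fits
  attr(tab, "registry") <- registry
  class(tab) <- c("comparison_table", "data.frame")
  tab
}

#' @export
print.comparison_table <- function(x, digits = 2, ...) {
  df <- as.data.frame(x)
  num <- c("lnL", "aicc", "delta", "weight", "train_auc", "test_auc")
  df[num] <- lapply(df[num], round, digits)
  print(df, ...)
  invisible(x)
}
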