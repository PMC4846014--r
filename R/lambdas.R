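#' Write fitted model parameters to a lambdas-style text file
#'
#' The plain-text parameter format: one record per feature giving
#' `name, lambda, min, max` (the min/max are the background scaling bounds of
#' the underlying variable; 0/1 for categorical indicators), followed by the
#' three labeled constants `linearPredictorNormalizer`, `densityNormalizer`
#' and `entropy`. Feature names encode their kind: `E` (linear), `E^2`
#' (quadratic, sharing the linear bounds), `(FT=3)` (categorical indicator).
#' Numbers are written with 17 significant digits so the file round-trips to
#' full precision.
#'
#' @param model a fitted model as returned by [fit_maxent()].
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [read_model_params()]
#' @export
write_model_params <- function(model, path) {
  stopifnot(inherits(model, "maxent_model"))
  num <- function(x) trimws(formatC(x, format = "g", digits = 17))
  fn <- names(model$lambdas)
  lines <- character(0)
  for (j in seq_along(fn)) {
    b <- feature_bounds(model$spec, fn[j])
    lines <- c(lines, paste(fn[j], num(model$lambdas[[j]]), num(b[1]),
                            num(b[2]), sep = ", "))
  }
  lines <- c(lines,
             paste("linearPredictorNormalizer", num(model$lpn), sep = ", "),
             paste("densityNormalizer", num(model$dn), sep = ", "),
             paste("entropy", num(model$entropy), sep = ", "))
  writeLines(lines, path)
  invisible(path)
}

#' Read model parameters from a lambdas-style text file
#'
#' Inverse of [write_model_params()]. The reconstructed model carries the
#' lambdas, scaling bounds and normalizing constants needed for prediction;
#' AUC fields (not part of the file) are `NA`. An unrecognized record label
#' raises an error.
#'
#' @param path path to a file written by [write_model_params()].
#' @return a `"maxent_model"` object.
#' @export
read_model_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lambdas <- numeric(0)
  info <- list()
  vars <- character(0)
  consts <- c(linearPredictorNormalizer = NA_real_,
              densityNormalizer = NA_real_, entropy = NA_real_)
  for (i in seq_along(lines)) {
    parts <- trimws(strsplit(lines[i], ",")[[1]])
    if (length(parts) == 2L) {
      if (!parts[1] %in% names(consts))
        stop(sprintf("'%s' line %d: unknown record label '%s'",
                     path, i, parts[1]))
      consts[[parts[1]]] <- as.numeric(parts[2])
    } else if (length(parts) == 4L) {
      name <- parts[1]
      lam <- as.numeric(parts[2]); lo <- as.numeric(parts[3])
      hi <- as.numeric(parts[4])
      if (anyNA(c(lam, lo, hi)))
        stop(sprintf("'%s' line %d: non-numeric value", path, i))
      lambdas[name] <- lam
      if (grepl("^\\(.+=.+\\)$", name)) {
        m <- regmatches(name, regexec("^\\((.+)=(.+)\\)$", name))[[1]]
        v <- m[2]; lvl <- as.numeric(m[3])
        if (is.null(info[[v]])) {
          info[[v]] <- list(type = "categorical", levels = numeric(0))
          vars <- c(vars, v)
        }
        info[[v]]$levels <- c(info[[v]]$levels, lvl)
      } else {
        v <- sub("\\^2$", "", name)
        if (is.null(info[[v]])) {
          info[[v]] <- list(type = "continuous", min = lo, max = hi)
          vars <- c(vars, v)
        }
      }
    } else {
      stop(sprintf("'%s' line %d: expected 2 or 4 comma-separated fields",
                   path, i))
    }
  }
  spec <- structure(list(variables = vars, info = info),
                    class = "feature_spec")
  new_maxent_model(lambdas = lambdas, spec = spec,
                   lpn = consts[["linearPredictorNormalizer"]],
                   dn = consts[["densityNormalizer"]],
                   entropy = consts[["entropy"]])
}
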