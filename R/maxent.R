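# Presence-only maximum-entropy model: linear + quadratic features for
# continuous variables, indicator features for forest type, fitted by
# L1-regularized convex optimisation (FISTA proximal gradient).

#' Thin occurrences to one point per stand
#'
#' Reduces spatial autocorrelation by keeping exactly one uniformly chosen
#' point in each occupied stand polygon.
#'
#' @param points an [occurrence_set()].
#' @param stands a [stand_partition()] (or any object with an id grid).
#' @param seed integer RNG seed; the selection is deterministic for a seed.
#' @return thinned [occurrence_set()] with `stand_id` filled in.
#' @export
thin_by_polygon <- function(points, stands, seed = 1) {
  ids <- stand_of(stands, points$x, points$y)
  if (anyNA(ids)) {
    bad <- which(is.na(ids))
    stop("point(s) outside all stand polygons: row(s) ",
         paste(bad, collapse = ", "))
  }
  rng <- local_rng(seed)
  keep <- integer(0)
  for (s in sort(unique(ids))) {
    idx <- which(ids == s)
    keep <- c(keep, if (length(idx) == 1L) idx else idx[rng$int(length(idx))])
  }
  keep <- sort(keep)
  out <- points[keep, , drop = FALSE]
  out$stand_id <- ids[keep]
  class(out) <- c("occurrence_set", "data.frame")
  out
}

#' Assign a train/test partition to occurrences
#'
#' One split, fixed up front and reused for every candidate model so all
#' models are built and tested on identical point sets.
#'
#' @param points an [occurrence_set()].
#' @param train_fraction fraction of points used for training (default 0.8);
#'   `n_train = round(train_fraction * n)`.
#' @param seed integer RNG seed.
#' @return the [occurrence_set()] with `partition` set to `"train"`/`"test"`.
#' @export
train_test_split <- function(points, train_fraction = 0.8, seed = 1) {
  n <- nrow(points)
  if (n < 2L) stop("need at least 2 points to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  n_train <- round(train_fraction * n)
  rng <- local_rng(seed)
  tr <- rng$sample_int(n, n_train)
  points$partition <- "test"
  points$partition[tr] <- "train"
  points
}

#' Sample background cells from a predictor stack
#'
#' Uniform sample without replacement from cells valid in every layer; if
#' fewer valid cells exist than requested, all are used. Presence cells are
#' appended to the background (the usual maxent convention), flagged so the
#' uniform part can be recovered.
#'
#' @param stack a [predictor_stack()].
#' @param n background size (default 10000).
#' @param seed integer RNG seed.
#' @param presences optional [occurrence_set()] whose cells are appended.
#' @return list with `cells` (linear indices into the grid matrices) and
#'   `is_presence` (logical, same length).
#' @export
sample_background <- function(stack, n = 10000, seed = 1, presences = NULL) {
  valid <- stack_valid(stack)
  cand <- which(valid)
  if (length(cand) == 0L) stop("no valid cells in stack")
  rng <- local_rng(seed)
  cells <- if (length(cand) <= n) cand else
    cand[rng$sample_int(length(cand), n)]
  isp <- rep(FALSE, length(cells))
  if (!is.null(presences) && nrow(presences) > 0L) {
    pc <- cell_index_at(stack[[1L]], presences$x, presences$y)
    if (anyNA(pc)) stop("presence point(s) outside the stack extent")
    if (any(!valid[pc])) stop("presence point(s) on nodata cells")
    add <- setdiff(pc, cells)
    cells <- c(cells, add)
    isp <- c(isp, rep(TRUE, length(add)))
    isp[match(unique(pc), cells)] <- TRUE
  }
  list(cells = cells, is_presence = isp)
}

#' Build the feature specification for a variable subset
#'
#' Continuous variables are min-max scaled to [0, 1] over the background and
#' contribute a linear and a quadratic feature (the quadratic is the square of
#' the scaled linear feature). Categorical variables contribute one 0/1
#' indicator per level observed in the background. A continuous variable that
#' is constant on the background carries no information and is dropped with a
#' warning.
#'
#' @param stack a [predictor_stack()].
#' @param variables character vector of layer names.
#' @param background background sample from [sample_background()].
#' @param categorical names of categorical layers (default `"FT"`).
#' @return an object of class `"feature_spec"`.
#' @export
feature_spec <- function(stack, variables, background,
                         categorical = "FT") {
  stopifnot(length(variables) >= 1L)
  missing <- setdiff(variables, names(stack))
  if (length(missing))
    stop("variable(s) missing from stack: ", paste(missing, collapse = ", "))
  info <- list()
  vars <- character(0)
  for (v in variables) {
    x <- stack[[v]]$values[background$cells]
    if (v %in% categorical) {
      info[[v]] <- list(type = "categorical", levels = sort(unique(x)))
      vars <- c(vars, v)
    } else {
      lo <- min(x); hi <- max(x)
      if (hi - lo <= 0) {
        warning("variable '", v, "' is constant on the background; dropped")
        next
      }
      info[[v]] <- list(type = "continuous", min = lo, max = hi)
      vars <- c(vars, v)
    }
  }
  structure(list(variables = vars, info = info), class = "feature_spec")
}

feature_names <- function(spec) {
  out <- character(0)
  for (v in spec$variables) {
    fi <- spec$info[[v]]
    out <- c(out, if (fi$type == "categorical")
      sprintf("(%s=%g)", v, fi$levels) else c(v, paste0(v, "^2")))
  }
  out
}

feature_bounds <- function(spec, name) {
  if (grepl("^\\(", name)) return(c(0, 1))
  v <- sub("\\^2$", "", name)
  fi <- spec$info[[v]]
  c(fi$min, fi$max)
}

#' Evaluate the feature matrix at a set of cells
#'
#' @param spec a [feature_spec()].
#' @param stack the [predictor_stack()].
#' @param cells linear cell indices.
#' @return numeric matrix (cells x features) with named columns.
#' @export
feature_matrix <- function(spec, stack, cells) {
  cols <- list()
  for (v in spec$variables) {
    fi <- spec$info[[v]]
    x <- stack[[v]]$values[cells]
    if (fi$type == "categorical") {
      for (lvl in fi$levels)
        cols[[sprintf("(%s=%g)", v, lvl)]] <- as.numeric(x == lvl)
    } else {
      z <- (x - fi$min) / (fi$max - fi$min)
      cols[[v]] <- z
      cols[[paste0(v, "^2")]] <- z * z
    }
  }
  if (length(cols) == 0L)
    return(matrix(0, length(cells), 0L))
  do.call(cbind, cols)
}

# fitted-model constructor (also used for synthetic truth models)
new_maxent_model <- function(lambdas, spec, lpn, dn, entropy,
                             train_auc = NA_real_, test_auc = NA_real_,
                             n_train = NA_integer_, objective = NA_real_,
                             n_iter = NA_integer_, beta = NA_real_) {
  structure(list(lambdas = lambdas, spec = spec, lpn = lpn, dn = dn,
                 entropy = entropy, train_auc = train_auc,
                 test_auc = test_auc, n_train = n_train,
                 objective = objective, n_iter = n_iter, beta = beta),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model> %d feature(s), %d nonzero lambda(s)\n",
              length(x$lambdas), sum(x$lambdas != 0)))
  cat(sprintf("  entropy %.4f | linear predictor normalizer %.4f\n",
              x$entropy, x$lpn))
  if (!is.na(x$train_auc))
    cat(sprintf("  train AUC %.3f | test AUC %s | n_train %d\n", x$train_auc,
                ifelse(is.na(x$test_auc), "NA", sprintf("%.3f", x$test_auc)),
                x$n_train))
  invisible(x)
}

# smooth part of the objective and its gradient at lambda
# g(l) = -mean(Fp l) + logSumExp(Fb l)
maxent_objective <- function(lambda, Fp, Fb) {
  eta <- drop(Fb %*% lambda)
  M <- max(eta)
  lse <- M + log(sum(exp(eta - M)))
  -mean(drop(Fp %*% lambda)) + lse
}

maxent_gradient <- function(lambda, Fp, Fb, mean_fp) {
  eta <- drop(Fb %*% lambda)
  q <- exp(eta - max(eta)); q <- q / sum(q)
  -mean_fp + drop(crossprod(Fb, q))
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Fit a maximum-entropy presence-only model
#'
#' Minimizes the L1-regularized negative presence log-likelihood
#' \deqn{-\frac{1}{m}\sum_i \lambda^\top f(x_i) +
#'       \ln \sum_{x \in bg} e^{\lambda^\top f(x)} +
#'       \sum_j \beta_j |\lambda_j|,}
#' with \eqn{\beta_j = \beta \, s_j / \sqrt{m}} (where \eqn{s_j} is the
#' background standard deviation of feature j and m the presence count), by
#' accelerated proximal gradient descent (FISTA with backtracking and adaptive
#' restart) from `lambda0`. The problem is convex, so the solution does not
#' depend on the start. After fitting, the linear-predictor normalizer `lpn`
#' is set to the maximum background linear predictor, the density normalizer
#' `dn` makes the raw distribution sum to one over the background, and the
#' entropy is that of the raw distribution. Training (and, when a test
#' partition exists, test) AUC is computed against the background sample.
#'
#' @param stack a [predictor_stack()].
#' @param presences an [occurrence_set()]; if partitions were assigned, only
#'   `"train"` points are fitted and `"test"` points feed the test AUC,
#'   otherwise all points train.
#' @param variables character vector of predictor names; `character(0)` gives
#'   the featureless (uniform) model.
#' @param background from [sample_background()]; built automatically (with
#'   `bg_n`, `seed`) when `NULL`.
#' @param beta regularization multiplier (default 1).
#' @param tol relative convergence tolerance on the objective (default 1e-8).
#' @param max_iter iteration budget; non-convergence is an error reporting the
#'   last objective value.
#' @param bg_n,seed background size and seed when `background` is `NULL`.
#' @param lambda0 optional start (default all zero).
#' @return a `"maxent_model"`.
#' @export
fit_maxent <- function(stack, presences, variables, background = NULL,
                       beta = 1.0, tol = 1e-8, max_iter = 500,
                       bg_n = 10000, seed = 1, lambda0 = NULL) {
  train <- presences[presences$partition != "test", , drop = FALSE]
  test <- presences[presences$partition == "test", , drop = FALSE]
  if (nrow(train) == 0L) stop("no training presences")
  if (is.null(background))
    background <- sample_background(stack, n = bg_n, seed = seed,
                                    presences = presences)
  N <- length(background$cells)
  if (length(variables) == 0L) {
    spec <- structure(list(variables = character(0), info = list()),
                      class = "feature_spec")
    H <- log(N)
    return(new_maxent_model(lambdas = numeric(0), spec = spec, lpn = 0,
                            dn = N, entropy = H, train_auc = 0.5,
                            test_auc = if (nrow(test)) 0.5 else NA_real_,
                            n_train = nrow(train), objective = log(N),
                            n_iter = 0L, beta = beta))
  }
  spec <- feature_spec(stack, variables, background)
  Fb <- feature_matrix(spec, stack, background$cells)
  pc <- cell_index_at(stack[[1L]], train$x, train$y)
  if (anyNA(pc)) stop("training presence outside stack extent")
  Fp <- feature_matrix(spec, stack, pc)
  m <- nrow(Fp)
  J <- ncol(Fb)
  sj <- apply(Fb, 2L, stats::sd)
  bj <- beta * sj / sqrt(m)
  mean_fp <- colMeans(Fp)
  lambda <- if (is.null(lambda0)) numeric(J) else {
    stopifnot(length(lambda0) == J); as.numeric(lambda0)
  }
  pen <- function(l) sum(bj * abs(l))
  obj <- maxent_objective(lambda, Fp, Fb) + pen(lambda)
  y <- lambda; tpar <- 1; L <- 1
  converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    gy <- maxent_objective(y, Fp, Fb)
    grad <- maxent_gradient(y, Fp, Fb, mean_fp)
    repeat {
      cand <- soft_threshold(y - grad / L, bj / L)
      d <- cand - y
      g_cand <- maxent_objective(cand, Fp, Fb)
      if (g_cand <= gy + sum(grad * d) + 0.5 * L * sum(d * d) + 1e-12) break
      L <- 2 * L
    }
    obj_new <- g_cand + pen(cand)
    if (obj_new > obj) {               # adaptive restart: drop momentum
      y <- lambda; tpar <- 1
      next
    }
    t_new <- (1 + sqrt(1 + 4 * tpar^2)) / 2
    y <- cand + ((tpar - 1) / t_new) * (cand - lambda)
    conv <- abs(obj - obj_new) <= tol * max(1, abs(obj_new))
    lambda <- cand; obj <- obj_new; tpar <- t_new
    if (conv) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf(
      "maxent fit did not converge in %d iterations (objective %.10g)",
      max_iter, obj))
  names(lambda) <- colnames(Fb)
  eta_b <- drop(Fb %*% lambda)
  lpn <- max(eta_b)
  w <- exp(eta_b - lpn)
  dn <- sum(w)
  raw_b <- w / dn
  H <- -sum(ifelse(raw_b > 0, raw_b * log(raw_b), 0))
  eta_p <- drop(Fp %*% lambda)
  train_auc <- auc(eta_p, eta_b)
  test_auc <- NA_real_
  if (nrow(test) > 0L) {
    tc <- cell_index_at(stack[[1L]], test$x, test$y)
    if (anyNA(tc)) stop("test presence outside stack extent")
    eta_t <- drop(feature_matrix(spec, stack, tc) %*% lambda)
    test_auc <- auc(eta_t, eta_b)
  }
  new_maxent_model(lambdas = lambda, spec = spec, lpn = lpn, dn = dn,
                   entropy = H, train_auc = train_auc, test_auc = test_auc,
                   n_train = m, objective = obj, n_iter = it, beta = beta)
}

#' Raw (relative occurrence rate) map of a fitted model
#'
#' `raw(x) = exp(lambda . f(x) - lpn) / dn` at every valid cell; by
#' construction the raw values sum to 1 over the background cells the model
#' was normalized on. Categorical levels unseen in the background score as
#' all-zero indicators.
#'
#' @param model a `"maxent_model"`.
#' @param stack a [predictor_stack()] holding every model variable.
#' @return raw-output [grid_layer()].
#' @export
raw_map <- function(model, stack) {
  missing <- setdiff(model$spec$variables, names(stack))
  if (length(missing))
    stop("variable(s) missing from stack: ", paste(missing, collapse = ", "))
  g1 <- stack[[1L]]
  valid <- stack_valid(stack)
  cells <- which(valid)
  raw <- matrix(NA_real_, grid_nrow(g1), grid_ncol(g1))
  if (length(model$lambdas) == 0L) {
    raw[cells] <- 1 / model$dn
  } else {
    Fm <- feature_matrix(model$spec, stack, cells)
    raw[cells] <- exp(drop(Fm %*% model$lambdas) - model$lpn) / model$dn
  }
  grid_layer(raw, g1$xllcorner, g1$yllcorner, g1$cellsize, nodata = g1$nodata)
}

#' Logistic transform of raw output
#'
#' Converts the raw distribution into a probability-of-presence scale using
#' the model entropy H:
#' `logistic = raw * exp(H) / (1 + raw * exp(H))`, in [0, 1). A cell whose raw
#' value equals `exp(-H)` (a "typical" cell) maps to exactly 0.5.
#'
#' @param raw a [grid_layer()] or numeric vector of raw values (>= 0).
#' @param entropy model entropy H (>= 0).
#' @return object of the same shape on the logistic scale.
#' @export
logistic_transform <- function(raw, entropy) {
  stopifnot(entropy >= 0)
  tr <- function(v) {
    s <- v * exp(entropy)
    s / (1 + s)
  }
  if (is_grid_layer(raw)) {
    grid_layer(tr(raw$values), raw$xllcorner, raw$yllcorner, raw$cellsize,
               nodata = raw$nodata)
  } else tr(raw)
}

#' Area under the ROC curve (rank-sum form)
#'
#' Probability that a randomly chosen presence outscores a randomly chosen
#' background point, ties counted one half.
#'
#' @param presence_scores,background_scores numeric score vectors (any
#'   monotone scale).
#' @return AUC in [0, 1].
#' @export
auc <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  stopifnot(np > 0L, nb > 0L)
  r <- rank(c(presence_scores, background_scores), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}
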