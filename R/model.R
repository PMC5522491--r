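#' Fit the class-balanced random-forest suitability model
#'
#' Fits a probability forest on the presence / pseudo-absence design.
#' Class imbalance (1 presence per `ratio` absences) is countered with
#' balanced class weights `w_c = N / (2 * N_c)`, realized as a
#' class-balanced bootstrap: every tree draws the same expected number of
#' presences and absences (sampling weight of a row proportional to
#' `N / (2 * N_class)`), so out-of-bag (OOB) predictions exist for every
#' row and predicted probabilities are calibrated to a balanced prior.
#'
#' @param design `training_design` from [assemble_design()].
#' @param n_trees number of trees (default 1,000).
#' @param seed RNG seed; refits are bit-identical per seed.
#' @return object of class `suitability_model` with the fitted forest,
#'   class weights, feature names, per-row OOB presence probability and
#'   the training design reference.
#' @export
fit_suitability <- function(design, n_trees = 1000, seed = 1) {
  stopifnot(inherits(design, "training_design"))
  y <- design$labels
  if (length(unique(y)) < 2) stop("design must contain both classes")
  zero_var <- vapply(design$features, function(v) stats::var(v) == 0, TRUE)
  if (any(zero_var))
    warning("zero-variance feature(s): ",
            paste(names(zero_var)[zero_var], collapse = ", "))
  n <- length(y); n1 <- sum(y == 1); n0 <- sum(y == 0)
  class_weights <- c(`0` = n / (2 * n0), `1` = n / (2 * n1))
  dat <- design$features
  dat$.y <- factor(y, levels = c(0, 1))
  # per-tree draw: n1 rows from each class, with replacement
  frac <- n1 / n
  rf <- ranger::ranger(
    dependent.variable.name = ".y", data = dat,
    num.trees = n_trees, probability = TRUE,
    sample.fraction = c(frac, frac), replace = TRUE,
    importance = "impurity", seed = seed, num.threads = 1)
  oob <- rf$predictions[, "1"]
  if (anyNA(oob) || any(is.nan(oob)))
    stop(sum(is.na(oob) | is.nan(oob)),
         " training row(s) have no OOB estimate; increase n_trees")
  structure(list(forest = rf, n_trees = n_trees, class_weights = class_weights,
                 feature_names = names(design$features),
                 categorical_levels = design$categorical_levels,
                 oob = as.numeric(oob), labels = y, seed = seed,
                 train_features = design$features),
            class = "suitability_model")
}

#' @export
print.suitability_model <- function(x, ...) {
  cat(sprintf("suitability_model: %d trees, %d features, %d training rows\n",
              x$n_trees, length(x$feature_names), length(x$labels)))
  cat(sprintf("  class weights: absence %.3g, presence %.3g; OOB AUC %.3f\n",
              x$class_weights["0"], x$class_weights["1"],
              roc_auc(x$labels, x$oob)))
  invisible(x)
}

#' Score points with the fitted model (relative index of occurrence)
#'
#' Appends an `rio` column: the forest's presence-class probability in
#' [0, 1] (0 = predicted absence, 1 = predicted presence).  Flagged rows
#' get `NA`.
#'
#' @param model `suitability_model`.
#' @param points covariate-extracted `point_table`.
#' @return the point table with `rio` filled.
#' @export
score_points <- function(model, points) {
  stopifnot(inherits(model, "suitability_model"))
  out <- as.data.frame(points)
  ok <- if ("flagged" %in% names(out)) !out$flagged else rep(TRUE, nrow(out))
  feats <- encode_features(out[ok, , drop = FALSE], model$feature_names,
                           model$categorical_levels)
  rio <- rep(NA_real_, nrow(out))
  if (any(ok))
    rio[ok] <- stats::predict(model$forest, data = feats,
                              num.threads = 1)$predictions[, "1"]
  out$rio <- rio
  class(out) <- c("point_table", "data.frame")
  out
}

#' Score every cell of a covariate stack
#'
#' Convenience wrapper: extracts the stack at all cell centres, scores
#' them, and returns the RIO raster.
#'
#' @param model `suitability_model`.
#' @param stack `raster_stack`.
#' @return `raster_grid` named `"RIO"`.
#' @export
score_grid <- function(model, stack) {
  tmpl <- stack[[1]]
  nr <- nrow(tmpl$values); nc <- ncol(tmpl$values)
  idx <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  ctr <- cell_centre(tmpl, idx$row, idx$col)
  pts <- extract_covariates(point_table(ctr$x, ctr$y, "background"), stack)
  scored <- score_points(model, pts)
  out <- raster_grid(matrix(NA_real_, nr, nc), origin_x = tmpl$origin_x,
                     origin_y = tmpl$origin_y, cell_size = tmpl$cell_size,
                     name = "RIO")
  out$values[cbind(idx$row, idx$col)] <- scored$rio
  out
}

#' Variable importance ranking
#'
#' Impurity-based importances rescaled so the top variable scores exactly
#' 100.0, in non-increasing rank order (the convention of the field's
#' reporting, e.g. Altitude 100.0).
#'
#' @param model `suitability_model`.
#' @return data.frame with columns `variable`, `score`, `rank`.
#' @export
variable_importance <- function(model) {
  raw <- model$forest$variable.importance
  raw <- pmax(raw, 0)
  sc <- 100 * raw / max(raw)
  ord <- order(sc, decreasing = TRUE)
  data.frame(variable = names(sc)[ord], score = as.numeric(sc[ord]),
             rank = seq_along(sc), row.names = NULL)
}

#' Partial-dependence response curve
#'
#' For each value `v` of an evaluation grid spanning the (trimmed)
#' training range of `variable`, the curve records the mean prediction
#' over training rows with that variable clamped to `v` (all other
#' covariates held at their observed values).
#'
#' Two averaging scales are offered.  `"probability"` (default) averages
#' the predicted RIO, matching the usual presentation of response curves;
#' values are in [0, 1].  `"odds"` averages the per-row odds
#' `rio / (1 - rio)` instead.  For a presence-background classifier with
#' balanced classes the predicted probability is a saturating transform
#' `s / (s + m)` of relative suitability `s` (`m` = mean landscape
#' suitability), so probability-scale curves flatten well below the true
#' response midpoint when suitable habitat is rare; the per-row odds are
#' proportional to `s` itself, which makes the odds-scale curve the right
#' input for locating response inflections (see [half_max_crossing()]).
#'
#' The evaluation grid is quantile-spaced over the training values of the
#' variable (including the minimum and maximum, so the full training
#' range is spanned): grid points concentrate where the forest actually
#' has support, which stabilizes the curve in sparse tails.
#'
#' @param model `suitability_model`.
#' @param variable feature name.
#' @param grid_size number of evaluation points (default 25).
#' @param max_rows cap on training rows used (evenly thinned,
#'   deterministic; default 1500).
#' @param scale `"probability"` or `"odds"`.
#' @return object of class `response_curve`: data.frame with columns
#'   `value` and `rio`, plus `variable` and `scale` attributes.
#' @export
response_curve <- function(model, variable, grid_size = 25, max_rows = 1500,
                           scale = c("probability", "odds")) {
  scale <- match.arg(scale)
  if (!variable %in% model$feature_names)
    stop("unknown feature: ", variable)
  X <- model$train_features
  if (nrow(X) > max_rows)
    X <- X[round(seq(1, nrow(X), length.out = max_rows)), , drop = FALSE]
  if (diff(range(X[[variable]])) == 0) {
    warning("constant variable '", variable, "': flat response curve")
    grid <- rep(X[[variable]][1], 2)
  } else {
    grid <- unique(as.numeric(stats::quantile(
      X[[variable]], seq(0, 1, length.out = grid_size))))
  }
  big <- X[rep(seq_len(nrow(X)), times = length(grid)), , drop = FALSE]
  big[[variable]] <- rep(grid, each = nrow(X))
  pred <- stats::predict(model$forest, data = big,
                         num.threads = 1)$predictions[, "1"]
  if (scale == "odds") {
    pred <- pmin(pmax(pred, 0.001), 0.999)
    pred <- pred / (1 - pred)
  }
  rio <- colMeans(matrix(pred, nrow = nrow(X)))
  structure(data.frame(value = grid, rio = rio),
            class = c("response_curve", "data.frame"),
            variable = variable, scale = scale)
}

#' Half-maximum crossing of a response curve
#'
#' Estimates the midpoint of a threshold-shaped response: the curve is
#' first replaced by its best monotone (isotonic) fit in the direction of
#' its overall trend — which removes spurious dips from sampling noise —
#' and the covariate value where the fit crosses the midpoint between its
#' minimum and maximum is found by linear interpolation.  For a
#' sigmoid-shaped response evaluated on the odds scale this estimates the
#' inflection point (see [response_curve()] for why the probability scale
#' is biased when suitable habitat is rare).
#'
#' @param curve `response_curve`.
#' @return numeric crossing value (`NA` for a flat curve).
#' @export
half_max_crossing <- function(curve) {
  y <- curve$rio; x <- curve$value
  if (diff(range(y)) == 0) return(NA_real_)
  increasing <- stats::cor(x, y) >= 0
  iso <- if (increasing) stats::isoreg(x, y)$yf else -stats::isoreg(x, -y)$yf
  if (diff(range(iso)) == 0) return(NA_real_)
  h <- (min(iso) + max(iso)) / 2
  d <- if (increasing) iso - h else h - iso
  for (i in seq_len(length(d) - 1)) {
    if (d[i] <= 0 && d[i + 1] > 0) {
      f <- -d[i] / (d[i + 1] - d[i])
      return(x[i] + f * (x[i + 1] - x[i]))
    }
  }
  x[which.min(abs(d))]
}
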