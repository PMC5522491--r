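#' Background lattice over a rectangular extent
#'
#' Points at the centres of a `spacing`-sized grid covering the bounds;
#' the count is `floor(width/spacing) * floor(height/spacing)`.  This is
#' the prediction lattice the suitability model scores (the field
#' workflow used a 1,000 m-spaced lattice).
#'
#' @param bounds numeric `c(xmin, ymin, xmax, ymax)` in planar metres.
#' @param spacing lattice spacing in metres.
#' @return `point_table` with role `background`.
#' @export
make_lattice <- function(bounds, spacing = 1000) {
  stopifnot(length(bounds) == 4, spacing > 0)
  w <- bounds[3] - bounds[1]; h <- bounds[4] - bounds[2]
  if (w <= 0 || h <= 0) stop("degenerate bounds")
  nx <- floor(w / spacing); ny <- floor(h / spacing)
  if (nx < 1 || ny < 1)
    stop(sprintf("spacing %g m exceeds the bounds extent (%g x %g m)",
                 spacing, w, h))
  xs <- bounds[1] + (seq_len(nx) - 0.5) * spacing
  ys <- bounds[4] - (seq_len(ny) - 0.5) * spacing
  point_table(rep(xs, times = ny), rep(ys, each = nx), "background")
}

#' Extract covariate values at points
#'
#' Appends one column per stack layer holding the value of the cell whose
#' half-open square contains the point, plus a logical `flagged` column.
#' Points outside the grids or hitting nodata in any layer are flagged,
#' never silently dropped.
#'
#' @param points `point_table`.
#' @param stack `raster_stack`.
#' @return the point table with covariate columns and `flagged` appended.
#' @export
extract_covariates <- function(points, stack) {
  stopifnot(inherits(stack, "raster_stack"))
  out <- as.data.frame(points)
  for (nm in names(stack))
    out[[nm]] <- grid_value_at(stack[[nm]], out$x, out$y)
  out$flagged <- Reduce(`|`, lapply(names(stack), function(nm) is.na(out[[nm]])))
  if (nrow(out) == 0) out$flagged <- logical(0)
  class(out) <- c("point_table", "data.frame")
  attr(out, "covariates") <- names(stack)
  out
}

#' Sample pseudo-absence points from the lattice
#'
#' Uniform random sample without replacement of `ratio * nrow(presence)`
#' lattice points, excluding lattice points that share a grid cell with a
#' presence (exclusion avoids contradictory labels; disable by passing
#' `exclude_presence_cells = FALSE`).  The field design used ratio 100:
#' 183 presences yield 18,300 pseudo-absences.
#'
#' @param lattice `point_table` of candidate background points.
#' @param presence `point_table` of presences.
#' @param ratio absences per presence (positive integer, default 100).
#' @param seed RNG seed; the draw is deterministic per seed.
#' @param grid optional `raster_grid` defining the cell geometry used for
#'   the presence-cell exclusion; defaults to a grid inferred from the
#'   lattice spacing.
#' @param exclude_presence_cells drop lattice points co-located with
#'   presences before sampling (default TRUE).
#' @return `point_table` with role `pseudo_absence`.
#' @export
sample_pseudo_absences <- function(lattice, presence, ratio = 100, seed = 1,
                                   grid = NULL, exclude_presence_cells = TRUE) {
  stopifnot(ratio >= 1, ratio == round(ratio), nrow(presence) >= 1)
  n_needed <- as.integer(ratio * nrow(presence))
  if (exclude_presence_cells) {
    if (is.null(grid)) {
      sp <- sort(unique(lattice$x))
      spacing <- if (length(sp) > 1) min(diff(sp)) else 1
      grid <- raster_grid(matrix(0, 1, 1), origin_x = min(lattice$x) - spacing / 2,
                          origin_y = max(lattice$y) + spacing / 2,
                          cell_size = spacing, name = "lattice")
      # only the origin/cell_size matter for keying cells; extend shape
      nx <- ceiling((max(lattice$x) - grid$origin_x) / spacing)
      ny <- ceiling((grid$origin_y - min(lattice$y)) / spacing)
      grid$values <- matrix(0, ny, nx)
    }
    key <- function(p) {
      rc <- cell_index(grid, p$x, p$y)
      paste(rc$row, rc$col)
    }
    free <- !(key(lattice) %in% key(presence))
  } else {
    free <- rep(TRUE, nrow(lattice))
  }
  n_avail <- sum(free)
  if (n_avail < n_needed)
    stop(sprintf("lattice too small: %d pseudo-absences required but only %d free lattice points available",
                 n_needed, n_avail))
  pick <- with_seed(seed, sample(which(free), n_needed))
  point_table(lattice$x[pick], lattice$y[pick], "pseudo_absence")
}

#' Assemble the training design
#'
#' Binds covariate-extracted presence (label 1) and pseudo-absence
#' (label 0) tables into a model-ready design.  The categorical `Landcv`
#' layer is one-hot encoded into indicator columns so the downstream
#' classifier sees no artificial ordering.  Flagged (nodata) rows are
#' dropped with a warning stating the count.
#'
#' @param presence,pseudo_absence covariate-extracted `point_table`s.
#' @param stack the `raster_stack` used for extraction (defines covariate
#'   names and which layers are categorical).
#' @param categorical names of integer-coded categorical layers
#'   (default `"Landcv"` when present).
#' @return object of class `training_design`: list with `features`
#'   (numeric data.frame), `labels` (integer 0/1 vector), the two point
#'   tables, `ratio` and the categorical level table.
#' @export
assemble_design <- function(presence, pseudo_absence, stack,
                            categorical = intersect("Landcv", names(stack))) {
  covs <- names(stack)
  for (tbl in list(presence, pseudo_absence))
    if (!all(covs %in% names(tbl)))
      stop("point table missing covariate column(s): ",
           paste(setdiff(covs, names(tbl)), collapse = ", "),
           " - run extract_covariates() first")
  if (nrow(pseudo_absence) == 0 || nrow(pseudo_absence) < nrow(presence))
    stop("ratio violated: pseudo-absence table smaller than presence table")
  if (any(paste(presence$x, presence$y) %in%
            paste(pseudo_absence$x, pseudo_absence$y)))
    stop("duplicate point between presence and pseudo-absence tables")
  both <- rbind(as.data.frame(presence)[c("x", "y", covs, "flagged")],
                as.data.frame(pseudo_absence)[c("x", "y", covs, "flagged")])
  labels <- c(rep(1L, nrow(presence)), rep(0L, nrow(pseudo_absence)))
  if (any(both$flagged)) {
    warning(sum(both$flagged), " row(s) dropped for nodata covariates")
    labels <- labels[!both$flagged]
    both <- both[!both$flagged, ]
  }
  feats <- both[covs]
  levels_tab <- list()
  for (cc in categorical) {
    lv <- sort(unique(feats[[cc]]))
    levels_tab[[cc]] <- lv
    for (l in lv)
      feats[[paste0(cc, "_", l)]] <- as.integer(feats[[cc]] == l)
    feats[[cc]] <- NULL
  }
  structure(list(features = feats, labels = labels,
                 presence = presence, pseudo_absence = pseudo_absence,
                 ratio = nrow(pseudo_absence) / nrow(presence),
                 categorical_levels = levels_tab),
            class = "training_design")
}

#' @export
print.training_design <- function(x, ...) {
  cat(sprintf("training_design: %d rows (%d presence + %d pseudo-absence, ratio %g), %d features\n",
              length(x$labels), sum(x$labels == 1), sum(x$labels == 0),
              x$ratio, ncol(x$features)))
  invisible(x)
}

# rebuild the design's feature encoding for new points (used by scoring)
encode_features <- function(points, feature_names, categorical_levels) {
  df <- as.data.frame(points)
  for (cc in names(categorical_levels)) {
    for (l in categorical_levels[[cc]])
      df[[paste0(cc, "_", l)]] <- as.integer(df[[cc]] == l)
  }
  missing <- setdiff(feature_names, names(df))
  if (length(missing))
    stop("points missing covariate column(s): ", paste(missing, collapse = ", "))
  df[feature_names]
}
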