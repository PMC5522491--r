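#' Virtual-species landscape simulation
#'
#' These generators build a synthetic analogue of the alpine study system:
#' spatially autocorrelated environmental covariates (elevation, two
#' bioclimatic layers, distance layers, a categorical land-cover layer), a
#' known threshold-shaped suitability truth, Bernoulli-style occurrence
#' sampling, a human-influence raster and protected-area polygons.  Every
#' generator is a pure function of its parameters and seed.
#'
#' @name synthetic_landscape
NULL

# run code under a local RNG state so generators do not disturb the caller
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# smoothed standard-normal white noise, rescaled to [0, 1]
# separable Gaussian kernel; edges handled by repeated mirror reflection,
# so any kernel width works on any grid of at least 2 cells a side
gaussian_field <- function(nrow, ncol, range_cells) {
  if (nrow < 2 || ncol < 2)
    stop(sprintf("grid %dx%d too small for smoothing", nrow, ncol))
  half <- max(1L, ceiling(3 * range_cells))
  k <- stats::dnorm(seq(-half, half), sd = range_cells)
  k <- k / sum(k)
  mirror <- function(n) {
    # indices 1..n extended by reflection on both sides, any overhang
    idx <- (1 - half):(n + half)
    period <- 2 * n - 2
    m <- ((idx - 1) %% period + period) %% period  # 0 .. period-1
    ifelse(m < n, m + 1L, period - m + 1L)
  }
  z <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  reflect_conv <- function(v) {
    padded <- v[mirror(length(v))]
    stats::filter(padded, k, sides = 2)[(half + 1):(half + length(v))]
  }
  z <- apply(z, 2, reflect_conv)
  z <- t(apply(z, 1, reflect_conv))
  rng <- range(z)
  if (diff(rng) == 0) return(matrix(0.5, nrow, ncol))
  (z - rng[1]) / diff(rng)
}

#' Generate a synthetic covariate stack
#'
#' Produces smoothed-random-field covariates rescaled to field-realistic
#' ranges: `Altitude` (1,000–6,000 m), `Bio_4` (temperature seasonality,
#' 2,000–12,000 units), `Bio_5` (max temperature of the warmest month,
#' -5–35 deg C), two distance-type layers (`Dist_water`, `Dist_road`,
#' 0–50,000 m) and an integer-coded land-cover layer `Landcv` with classes
#' herbaceous (1), shrub (2), barren (3) and water (4).
#'
#' @param shape integer c(rows, cols), at least 16 x 16.
#' @param cell_size cell size in metres.
#' @param seed RNG seed; the stack is a pure function of (parameters, seed).
#' @param autocorr_range smoothing kernel length in cells.
#' @return `raster_stack` of six layers.
#' @export
generate_covariates <- function(shape = c(64, 64), cell_size = 1000, seed = 1,
                                autocorr_range = 6) {
  stopifnot(length(shape) == 2, all(shape >= 16))
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  with_seed(seed, {
    mk <- function(m, lo, hi, name)
      raster_grid(lo + m * (hi - lo), origin_x = 0, origin_y = nr * cell_size,
                  cell_size = cell_size, name = name)
    # bottom-heavy hypsometry (power transform): high plateau is the rarer
    # land form, as in real mountain landscapes
    alt  <- mk(gaussian_field(nr, nc, autocorr_range)^1.7, 1000, 6000, "Altitude")
    bio4 <- mk(gaussian_field(nr, nc, autocorr_range), 2000, 12000, "Bio_4")
    # layers are mutually independent fields: cross-covariate correlation
    # is deliberately not emulated, keeping each response identifiable.
    # warm summers dominate the landscape (top-heavy skew): the cool
    # high-plateau tail is the habitat-limiting exception
    bio5 <- mk(gaussian_field(nr, nc, autocorr_range)^0.6, -5, 35, "Bio_5")
    dw   <- mk(gaussian_field(nr, nc, autocorr_range), 0, 50000, "Dist_water")
    dr   <- mk(gaussian_field(nr, nc, autocorr_range), 0, 50000, "Dist_road")
    lcf  <- gaussian_field(nr, nc, autocorr_range)
    qs   <- stats::quantile(lcf, c(0.40, 0.72, 0.90))
    lc   <- matrix(1L, nr, nc)                 # herbaceous
    lc[lcf > qs[1]] <- 2L                      # shrub
    lc[lcf > qs[2]] <- 3L                      # barren
    lc[lcf > qs[3]] <- 4L                      # water
    landcv <- raster_grid(lc, origin_x = 0, origin_y = nr * cell_size,
                          cell_size = cell_size, name = "Landcv")
    attr(landcv, "classes") <- c(herbaceous = 1, shrub = 2, barren = 3, water = 4)
    raster_stack(list(Altitude = alt, Bio_4 = bio4, Bio_5 = bio5,
                      Dist_water = dw, Dist_road = dr, Landcv = landcv))
  })
}

#' Default virtual-species response specification
#'
#' The default truth mirrors the breeding-habitat preference of the
#' black-necked crane: suitability increases with elevation (sigmoid
#' inflection 2,800 m), decreases with warm-month maximum temperature
#' (inflection 20.5 deg C), increases with temperature seasonality
#' (inflection 7,800 units) and strongly prefers herbaceous land cover.
#' Sigmoid scales are ~2.5% of each covariate's range, so each response
#' transitions over roughly 10% of the range.  The prevalence scaler caps
#' suitability at 0.9 in fully suitable cells.
#'
#' @return a `response_spec` list.
#' @export
default_response_spec <- function() {
  structure(list(
    responses = list(
      Altitude = list(type = "sigmoid", direction = 1,  inflection = 2800, scale = 125),
      Bio_5    = list(type = "sigmoid", direction = -1, inflection = 20.5, scale = 1),
      Bio_4    = list(type = "sigmoid", direction = 1,  inflection = 7800, scale = 250),
      Landcv   = list(type = "categorical",
                      weights = c(`1` = 1, `2` = 0.3, `3` = 0.05, `4` = 0.01))
    ),
    prevalence = 0.9), class = "response_spec")
}

sigmoid_response <- function(v, direction, inflection, scale)
  1 / (1 + exp(-direction * (v - inflection) / scale))

#' True suitability surface of a response specification
#'
#' Cellwise product of the per-covariate responses times the prevalence
#' scaler; each response maps its covariate into [0, 1] so the result is a
#' probability-like suitability in [0, 1].
#'
#' @param stack `raster_stack` containing every covariate the spec names.
#' @param spec `response_spec`; default [default_response_spec()].
#' @return `raster_grid` named `"suitability"`.
#' @export
true_suitability <- function(stack, spec = default_response_spec()) {
  missing <- setdiff(names(spec$responses), names(stack))
  if (length(missing))
    stop("response references missing layer(s): ", paste(missing, collapse = ", "))
  tmpl <- stack[[1]]
  suit <- matrix(spec$prevalence, nrow(tmpl$values), ncol(tmpl$values))
  for (nm in names(spec$responses)) {
    r <- spec$responses[[nm]]
    v <- stack[[nm]]$values
    resp <- switch(r$type,
      sigmoid = sigmoid_response(v, r$direction, r$inflection, r$scale),
      categorical = {
        w <- r$weights[as.character(v)]
        if (anyNA(w[!is.na(v)]))
          stop("categorical response for ", nm, " missing a class weight")
        matrix(w, nrow(v), ncol(v))
      },
      stop("unknown response type: ", r$type))
    suit <- suit * resp
  }
  raster_grid(suit, origin_x = tmpl$origin_x, origin_y = tmpl$origin_y,
              cell_size = tmpl$cell_size, name = "suitability")
}

#' Sample presence and testing occurrences from a suitability surface
#'
#' Cells are drawn without replacement with probability proportional to
#' suitability; points sit at cell centres.  The first `n_presence` draws
#' become training presences (nest analogues) and the next `n_test` the
#' held-out testing records, so the two sets are disjoint by construction.
#'
#' @param suitability `raster_grid` in [0, 1].
#' @param n_presence number of training presences (default 183).
#' @param n_test number of testing records (default 102).
#' @param seed RNG seed.
#' @return list with `point_table`s `presence` and `test`.
#' @export
sample_occurrences <- function(suitability, n_presence = 183, n_test = 102,
                               seed = 1) {
  v <- as.vector(t(suitability$values))  # row-major cell order
  v[is.na(v)] <- 0
  npos <- sum(v > 0)
  if (npos < n_presence + n_test)
    stop(sprintf("only %d cells with positive suitability; %d needed",
                 npos, n_presence + n_test))
  idx <- with_seed(seed,
                   sample.int(length(v), n_presence + n_test, prob = v))
  nc <- ncol(suitability$values)
  row <- (idx - 1L) %/% nc + 1L
  col <- (idx - 1L) %% nc + 1L
  ctr <- cell_centre(suitability, row, col)
  list(
    presence = point_table(ctr$x[seq_len(n_presence)],
                           ctr$y[seq_len(n_presence)], "presence"),
    test = if (n_test > 0)
      point_table(ctr$x[n_presence + seq_len(n_test)],
                  ctr$y[n_presence + seq_len(n_test)], "test")
    else point_table(numeric(0), numeric(0), "test"))
}

#' Generate a synthetic human-influence index raster
#'
#' Integer raster on the 0 (no influence) to 64 (severe influence) scale:
#' exponential distance-decay footprints around random settlement centres,
#' summed and clipped to [0, 64].
#'
#' @param shape c(rows, cols).
#' @param cell_size metres.
#' @param seed RNG seed.
#' @param settlement_count number of settlement centres (>= 0).
#' @param decay e-folding distance of a footprint, metres.
#' @return integer-valued `raster_grid` named `"HII"`.
#' @export
generate_hii <- function(shape = c(64, 64), cell_size = 1000, seed = 1,
                         settlement_count = 8, decay = 5 * cell_size) {
  stopifnot(settlement_count >= 0)
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  g <- raster_grid(matrix(0, nr, nc), origin_x = 0, origin_y = nr * cell_size,
                   cell_size = cell_size, name = "HII")
  if (settlement_count == 0) return(g)
  ctr <- cell_centre(g, rep(seq_len(nr), nc), rep(seq_len(nc), each = nr))
  hii <- with_seed(seed, {
    sx <- stats::runif(settlement_count, 0, nc * cell_size)
    sy <- stats::runif(settlement_count, 0, nr * cell_size)
    acc <- numeric(nr * nc)
    for (i in seq_len(settlement_count)) {
      d <- sqrt((ctr$x - sx[i])^2 + (ctr$y - sy[i])^2)
      acc <- acc + 64 * exp(-d / decay)
    }
    acc
  })
  g$values <- matrix(pmin(64, round(hii)), nr, nc)
  g
}

#' Generate synthetic protected-area polygons
#'
#' Random axis-aligned rectangles (each a few percent of the landscape)
#' are accumulated until their rasterized union covers approximately the
#' requested fraction of cells.
#'
#' @param shape c(rows, cols).
#' @param cell_size metres.
#' @param coverage_fraction target fraction of cells covered, in [0, 1).
#' @param seed RNG seed.
#' @return `polygon_set` labelled `"protected_area"`.
#' @export
generate_protected_areas <- function(shape = c(64, 64), cell_size = 1000,
                                     coverage_fraction = 0.25, seed = 1) {
  if (coverage_fraction >= 1 || coverage_fraction < 0)
    stop("coverage_fraction must be in [0, 1)")
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  if (coverage_fraction == 0)
    return(polygon_set(list(), label = "protected_area"))
  W <- nc * cell_size; H <- nr * cell_size
  # rectangle half-sizes capped at ~6 cells so the union cannot overshoot
  # the target by more than a few percent of the landscape
  covered <- matrix(FALSE, nr, nc)
  tmpl <- raster_grid(covered + 0, origin_x = 0, origin_y = H,
                      cell_size = cell_size, name = "tmpl")
  rects <- with_seed(seed, {
    out <- list()
    for (it in 1:10000) {
      if (mean(covered) >= coverage_fraction) break
      cx <- stats::runif(1, 0, W); cy <- stats::runif(1, 0, H)
      hw <- stats::runif(1, 2, 6) * cell_size
      hh <- stats::runif(1, 2, 6) * cell_size
      x0 <- max(0, cx - hw); x1 <- min(W, cx + hw)
      y0 <- max(0, cy - hh); y1 <- min(H, cy + hh)
      if (x1 - x0 < cell_size || y1 - y0 < cell_size) next
      ring <- rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0))
      out[[length(out) + 1]] <- list(ring)
      # rasterize incrementally with the centre rule
      cols <- which(tmpl$origin_x + (seq_len(nc) - 0.5) * cell_size > x0 &
                      tmpl$origin_x + (seq_len(nc) - 0.5) * cell_size < x1)
      rows <- which(H - (seq_len(nr) - 0.5) * cell_size > y0 &
                      H - (seq_len(nr) - 0.5) * cell_size < y1)
      covered[rows, cols] <- TRUE
    }
    out
  })
  polygon_set(rects, label = "protected_area")
}
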