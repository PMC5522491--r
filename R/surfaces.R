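#' Inverse-distance-weighted interpolation onto a grid
#'
#' Each cell centre receives the weighted mean of the `k` nearest scored
#' points, with weights `d^-power`; a cell coincident with a point (zero
#' distance) gets that point's value exactly.  When every cell centre
#' hosts a scored point — the situation after scoring a full lattice —
#' interpolation reduces to the identity map.
#'
#' @param scored_points `point_table` with an `rio` column (NA rows are
#'   ignored).
#' @param template `raster_grid` defining the output geometry.
#' @param power IDW power (> 0, default 2).
#' @param k_neighbors neighbours used per cell (default 12).
#' @return `raster_grid` named `"RIO"`.
#' @export
idw_interpolate <- function(scored_points, template, power = 2,
                            k_neighbors = 12) {
  stopifnot(power > 0, k_neighbors >= 1)
  pts <- as.data.frame(scored_points)
  if (!"rio" %in% names(pts)) stop("scored_points must carry an 'rio' column")
  pts <- pts[!is.na(pts$rio), ]
  if (nrow(pts) == 0) stop("no scored points")
  nr <- nrow(template$values); nc <- ncol(template$values)
  out <- matrix(NA_real_, nr, nc)
  # fast path: points sitting exactly on cell centres fill those cells
  rc <- cell_index(template, pts$x, pts$y)
  ctr <- cell_centre(template, rc$row, rc$col)
  on_centre <- !is.na(rc$row) &
    abs(ctr$x - pts$x) < 1e-9 & abs(ctr$y - pts$y) < 1e-9
  out[cbind(rc$row[on_centre], rc$col[on_centre])] <- pts$rio[on_centre]
  todo <- which(is.na(out))
  if (length(todo)) {
    k <- min(k_neighbors, nrow(pts))
    cells <- arrayInd(todo, dim(out))
    cc <- cell_centre(template, cells[, 1], cells[, 2])
    chunk <- 512L
    for (start in seq(1, length(todo), by = chunk)) {
      ii <- start:min(start + chunk - 1L, length(todo))
      d2 <- outer(cc$x[ii], pts$x, "-")^2 + outer(cc$y[ii], pts$y, "-")^2
      vals <- vapply(seq_along(ii), function(j) {
        dj <- d2[j, ]
        nb <- order(dj)[seq_len(k)]
        dn <- sqrt(dj[nb])
        if (dn[1] < 1e-12) return(pts$rio[nb[1]])
        w <- dn^(-power)
        sum(w * pts$rio[nb]) / sum(w)
      }, 0)
      out[todo[ii]] <- vals
    }
  }
  raster_grid(out, origin_x = template$origin_x, origin_y = template$origin_y,
              cell_size = template$cell_size, name = "RIO")
}

#' Binarize a continuous surface at a threshold
#'
#' @param rio `raster_grid` (typically RIO in [0, 1]).
#' @param threshold cut-off in [0, 1]; cells with value >= threshold
#'   (inclusive) become 1, others 0; nodata propagates.
#' @return binary `raster_grid` named `"<name>_binary"`.
#' @export
binarize <- function(rio, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  v <- rio$values
  m <- ifelse(is.na(v), NA_real_, as.numeric(v >= threshold))
  g <- raster_grid(m, origin_x = rio$origin_x, origin_y = rio$origin_y,
                   cell_size = rio$cell_size,
                   name = paste0(rio$name, "_binary"))
  g
}
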