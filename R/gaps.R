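#' Reclassify the human-influence index into equal-width bins
#'
#' Class index = `floor(value / interval)`; with the default five-unit
#' interval the scale maximum 64 folds into the final class (class 12).
#'
#' @param hii integer-valued `raster_grid` in [0, 64].
#' @param interval bin width (default 5).
#' @return `raster_grid` of class indices.
#' @export
reclassify_hii <- function(hii, interval = 5) {
  v <- hii$values
  fin <- v[!is.na(v)]
  if (any(fin < 0 | fin > 64))
    stop("HII values outside [0, 64]")
  g <- raster_grid(floor(v / interval), origin_x = hii$origin_x,
                   origin_y = hii$origin_y, cell_size = hii$cell_size,
                   name = "HII_class")
  g
}

#' Rasterize polygons onto a template grid (centre rule)
#'
#' A cell is 1 iff its centre lies inside any polygon of the set
#' (even-odd rule, holes excluded).
#'
#' @param polys `polygon_set`.
#' @param template `raster_grid` providing the geometry.
#' @return binary `raster_grid`.
#' @export
rasterize_polygons <- function(polys, template) {
  nr <- nrow(template$values); nc <- ncol(template$values)
  out <- raster_grid(matrix(0, nr, nc), origin_x = template$origin_x,
                     origin_y = template$origin_y,
                     cell_size = template$cell_size,
                     name = paste0(polys$label, "_mask"))
  if (length(polys$polygons) == 0) {
    warning("empty polygon set: all-zero mask")
    return(out)
  }
  idx <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  ctr <- cell_centre(template, idx$row, idx$col)
  inside <- points_in_polygons(polys, ctr$x, ctr$y)
  out$values[cbind(idx$row, idx$col)] <- as.numeric(inside)
  out
}

#' Conservation-gap overlay
#'
#' Overlays the binary prediction with protected areas and the
#' human-influence index.  A conservation gap is a predicted-presence
#' cell under human pressure (`HII >= hii_cutoff`) lying outside
#' protected areas.  Areas are counted in cells (equal-area planar grid).
#'
#' @param presence_mask binary `raster_grid` (1 = predicted presence).
#' @param hii integer `raster_grid` in [0, 64].
#' @param protected_mask binary `raster_grid` (1 = protected).
#' @param hii_cutoff human-pressure safety cut-off (default 10).
#' @param hii_interval bin width of the class-share table (default 5).
#' @return object of class `gap_summary`: fractions (of
#'   predicted-presence cells) `protected_fraction`,
#'   `hii_ge_cutoff_fraction`, `protected_of_pressured_fraction`,
#'   `gap_fraction`; `class_share` table over presence cells; the binary
#'   `gap_mask`; counts.
#' @export
conservation_gaps <- function(presence_mask, hii, protected_mask,
                              hii_cutoff = 10, hii_interval = 5) {
  check_aligned(presence_mask, hii)
  check_aligned(presence_mask, protected_mask)
  pres <- presence_mask$values == 1
  pres[is.na(pres)] <- FALSE
  n_pres <- sum(pres)
  if (n_pres == 0) stop("no predicted-presence cells")
  hv <- hii$values
  prot <- protected_mask$values == 1
  prot[is.na(prot)] <- FALSE
  pressured <- pres & !is.na(hv) & hv >= hii_cutoff
  gap <- pressured & !prot
  classes <- floor(hv[pres] / hii_interval)
  share <- table(factor(classes, levels = 0:floor(64 / hii_interval))) / n_pres
  gm <- raster_grid(ifelse(is.na(presence_mask$values), NA_real_,
                           as.numeric(gap)),
                    origin_x = presence_mask$origin_x,
                    origin_y = presence_mask$origin_y,
                    cell_size = presence_mask$cell_size, name = "gap_mask")
  structure(list(
    n_presence_cells = n_pres,
    protected_fraction = sum(pres & prot) / n_pres,
    hii_ge_cutoff_fraction = sum(pressured) / n_pres,
    protected_of_pressured_fraction =
      if (sum(pressured) > 0) sum(pressured & prot) / sum(pressured) else NA_real_,
    gap_fraction = sum(gap) / n_pres,
    class_share = as.data.frame(share, responseName = "share"),
    hii_cutoff = hii_cutoff,
    gap_mask = gm), class = "gap_summary")
}

#' @export
print.gap_summary <- function(x, ...) {
  cat(sprintf("gap_summary over %d predicted-presence cells (HII cutoff %g):\n",
              x$n_presence_cells, x$hii_cutoff))
  cat(sprintf("  protected:            %5.1f%%\n", 100 * x$protected_fraction))
  cat(sprintf("  under human pressure: %5.1f%%\n", 100 * x$hii_ge_cutoff_fraction))
  cat(sprintf("  of those, protected:  %5.1f%%\n",
              100 * x$protected_of_pressured_fraction))
  cat(sprintf("  conservation gap:     %5.1f%%\n", 100 * x$gap_fraction))
  invisible(x)
}
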