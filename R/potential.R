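#' Remove predicted-presence cells near known ranges and records
#'
#' Sets to 0 every presence cell whose centre lies within the Euclidean
#' buffer distance (boundary-inclusive, `<= distance`) of any breeding
#' record point or any known-range polygon; cells inside a polygon are at
#' distance 0.  The remaining cells are the candidate potential range.
#'
#' @param presence_mask binary `raster_grid`.
#' @param known_ranges `polygon_set` of current breeding ranges, or NULL.
#' @param records `point_table` of breeding records, or NULL.
#' @param distance buffer distance in metres (default 67,000, the
#'   breeding-season dispersal buffer).
#' @return binary `raster_grid` named `"potential_mask"`.
#' @export
buffer_exclude <- function(presence_mask, known_ranges = NULL, records = NULL,
                           distance = 67000) {
  stopifnot(distance >= 0)
  out <- presence_mask
  out$name <- "potential_mask"
  pres <- which(presence_mask$values == 1)
  if (length(pres) == 0) return(out)
  cells <- arrayInd(pres, dim(presence_mask$values))
  cc <- cell_centre(presence_mask, cells[, 1], cells[, 2])
  near <- rep(FALSE, length(pres))
  if (!is.null(records) && nrow(records) > 0) {
    for (start in seq(1, length(pres), by = 2048)) {
      ii <- start:min(start + 2047, length(pres))
      d2 <- outer(cc$x[ii], records$x, "-")^2 + outer(cc$y[ii], records$y, "-")^2
      near[ii] <- near[ii] | (sqrt(apply(d2, 1, min)) <= distance)
    }
  }
  if (!is.null(known_ranges) && length(known_ranges$polygons) > 0) {
    todo <- which(!near)
    if (length(todo)) {
      inside <- points_in_polygons(known_ranges, cc$x[todo], cc$y[todo])
      near[todo[inside]] <- TRUE
      todo <- todo[!inside]
      if (length(todo)) {
        dmin <- rep(Inf, length(todo))
        for (poly in known_ranges$polygons) for (ring in poly) {
          for (e in seq_len(nrow(ring) - 1)) {
            dmin <- pmin(dmin, dist_point_segment(
              cc$x[todo], cc$y[todo],
              ring[e, 1], ring[e, 2], ring[e + 1, 1], ring[e + 1, 2]))
          }
        }
        near[todo[dmin <= distance]] <- TRUE
      }
    }
  }
  out$values[pres[near]] <- 0
  out
}

# Euclidean distance from points to a segment, vectorized over points
dist_point_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

#' Aggregate presence pixels into clusters
#'
#' Connected components of the binary mask (8-connectivity by default);
#' components of at least `min_pixels` become clusters with their pixel
#' count, share of all presence pixels (%), centroid and bounding box.
#' Smaller components are counted as unassigned, so cluster pixel counts
#' plus the unassigned count always equal the total presence pixels.
#'
#' @param mask binary `raster_grid`.
#' @param min_pixels minimum component size to form a cluster (default 10).
#' @param connectivity 4 or 8 (default 8).
#' @return data.frame of class `cluster_table` (columns `id`, `pixels`,
#'   `share_pct`, `centroid_x`, `centroid_y`, `xmin`, `xmax`, `ymin`,
#'   `ymax`) with attributes `total_pixels`, `unassigned_pixels` and
#'   `labels` (a `raster_grid` of cluster ids, NA outside clusters).
#' @export
aggregate_clusters <- function(mask, min_pixels = 10, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  m <- mask$values == 1
  m[is.na(m)] <- FALSE
  nr <- nrow(m); nc <- ncol(m)
  on <- which(m)
  lab_grid <- raster_grid(matrix(NA_real_, nr, nc), origin_x = mask$origin_x,
                          origin_y = mask$origin_y, cell_size = mask$cell_size,
                          name = "cluster_labels")
  empty <- structure(
    data.frame(id = integer(0), pixels = integer(0), share_pct = numeric(0),
               centroid_x = numeric(0), centroid_y = numeric(0),
               xmin = numeric(0), xmax = numeric(0),
               ymin = numeric(0), ymax = numeric(0)),
    class = c("cluster_table", "data.frame"),
    total_pixels = length(on), unassigned_pixels = length(on),
    labels = lab_grid)
  if (length(on) == 0) return(empty)
  id_of <- match(seq_len(nr * nc), on)  # linear index -> vertex id
  offs <- if (connectivity == 8)
    rbind(c(1, 0), c(0, 1), c(1, 1), c(-1, 1)) else rbind(c(1, 0), c(0, 1))
  cells <- arrayInd(on, c(nr, nc))
  edges <- integer(0)
  for (k in seq_len(nrow(offs))) {
    r2 <- cells[, 1] + offs[k, 1]; c2 <- cells[, 2] + offs[k, 2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    nb <- id_of[(c2[ok] - 1) * nr + r2[ok]]
    src <- which(ok)[!is.na(nb)]
    nb <- nb[!is.na(nb)]
    edges <- c(edges, rbind(src, nb))
  }
  g <- igraph::make_empty_graph(n = length(on), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  memb <- igraph::components(g)$membership
  sizes <- table(memb)
  keep <- as.integer(names(sizes)[sizes >= min_pixels])
  if (length(keep) == 0) return(empty)
  # stable cluster ids: by size desc, then discovery order
  keep <- keep[order(-sizes[as.character(keep)], keep)]
  rows <- lapply(seq_along(keep), function(i) {
    cid <- keep[i]
    cells_i <- cells[memb == cid, , drop = FALSE]
    ctr <- cell_centre(mask, cells_i[, 1], cells_i[, 2])
    data.frame(id = i, pixels = nrow(cells_i),
               share_pct = 100 * nrow(cells_i) / length(on),
               centroid_x = mean(ctr$x), centroid_y = mean(ctr$y),
               xmin = min(ctr$x) - mask$cell_size / 2,
               xmax = max(ctr$x) + mask$cell_size / 2,
               ymin = min(ctr$y) - mask$cell_size / 2,
               ymax = max(ctr$y) + mask$cell_size / 2)
  })
  tab <- do.call(rbind, rows)
  for (i in seq_along(keep))
    lab_grid$values[on[memb == keep[i]]] <- i
  structure(tab, class = c("cluster_table", "data.frame"),
            total_pixels = length(on),
            unassigned_pixels = length(on) - sum(tab$pixels),
            labels = lab_grid)
}

#' Presence-pixel density surface
#'
#' For every cell, the number of presence-pixel centres within `radius`
#' of its centre, divided by the disc area `pi * radius^2` (pixels per
#' square metre).  No edge correction: the denominator is the full disc
#' area everywhere.
#'
#' @param mask binary `raster_grid`.
#' @param radius search radius in metres (>= cell size).
#' @return `raster_grid` named `"density"`.
#' @export
point_density <- function(mask, radius) {
  s <- mask$cell_size
  if (radius < s) stop("radius must be at least one cell size")
  m <- mask$values == 1
  m[is.na(m)] <- FALSE
  nr <- nrow(m); nc <- ncol(m)
  rad_cells <- floor(radius / s)
  counts <- matrix(0, nr, nc)
  mnum <- m + 0
  for (di in -rad_cells:rad_cells) for (dj in -rad_cells:rad_cells) {
    if (sqrt(di^2 + dj^2) * s > radius) next
    # shift mnum by (di, dj) and accumulate
    r_src <- max(1, 1 - di):min(nr, nr - di)
    c_src <- max(1, 1 - dj):min(nc, nc - dj)
    counts[r_src + di, c_src + dj] <-
      counts[r_src + di, c_src + dj] + mnum[r_src, c_src]
  }
  raster_grid(counts / (pi * radius^2), origin_x = mask$origin_x,
              origin_y = mask$origin_y, cell_size = s, name = "density")
}

#' Rank focal regions of the potential range
#'
#' Orders clusters by pixel share (ties by pixel count, then id) and
#' annotates each with its density-maximum cell — the focal point a field
#' survey would target first.
#'
#' @param clusters `cluster_table` from [aggregate_clusters()].
#' @param density `raster_grid` from [point_density()].
#' @param top_k number of regions to return (default all).
#' @return data.frame with columns `id`, `pixels`, `share_pct`, `peak_x`,
#'   `peak_y`, `peak_density`, ordered by priority.
#' @export
rank_focal_regions <- function(clusters, density, top_k = nrow(clusters)) {
  if (nrow(clusters) == 0) stop("empty cluster table")
  if (top_k > nrow(clusters)) {
    warning("top_k exceeds cluster count; returning all clusters")
    top_k <- nrow(clusters)
  }
  labels <- attr(clusters, "labels")
  check_aligned(labels, density)
  ord <- order(-clusters$share_pct, -clusters$pixels, clusters$id)
  sel <- clusters[ord[seq_len(top_k)], ]
  peaks <- lapply(sel$id, function(cid) {
    cells <- which(labels$values == cid, arr.ind = TRUE)
    dens <- density$values[cells]
    best <- cells[which.max(dens), , drop = FALSE]
    ctr <- cell_centre(density, best[1, 1], best[1, 2])
    data.frame(peak_x = ctr$x, peak_y = ctr$y, peak_density = max(dens))
  })
  cbind(sel[c("id", "pixels", "share_pct")], do.call(rbind, peaks),
        row.names = NULL)
}
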