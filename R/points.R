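#' Point tables
#'
#' Points are plain data.frames with columns `id` (unique integer), `x`,
#' `y` (planar metres) and `role` (one of `presence`, `pseudo_absence`,
#' `test`, `background`).  Covariate extraction appends one column per
#' stack layer plus a logical `flagged` column marking rows that fell on
#' nodata or outside the grid; scoring appends `rio`.
#'
#' @param x,y planar coordinates.
#' @param role role label stamped on all rows.
#' @param id optional ids; sequential if omitted.
#' @return data.frame of class `point_table`.
#' @export
point_table <- function(x, y, role, id = seq_along(x)) {
  role <- match.arg(role, c("presence", "pseudo_absence", "test", "background"))
  stopifnot(length(x) == length(y), !anyDuplicated(id))
  out <- data.frame(id = as.integer(id), x = as.numeric(x), y = as.numeric(y),
                    role = rep(role, length(x)), stringsAsFactors = FALSE)
  class(out) <- c("point_table", "data.frame")
  out
}

#' Read a point table from CSV
#'
#' The file must contain numeric `x` and `y` columns (planar metres).
#' Ids are assigned sequentially and the given role is stamped on every
#' row.
#'
#' @param path CSV path.
#' @param role role label for all rows.
#' @return `point_table`.
#' @export
read_points <- function(path, role) {
  if (!file.exists(path)) stop("point file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(df)))
    stop("point CSV must contain columns 'x' and 'y': ", path)
  if (nrow(df) == 0) return(point_table(numeric(0), numeric(0), role))
  xs <- suppressWarnings(as.numeric(df$x))
  ys <- suppressWarnings(as.numeric(df$y))
  bad <- which(!is.finite(xs) | !is.finite(ys))
  if (length(bad))
    stop("non-numeric coordinates in ", path, " at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  point_table(xs, ys, role)
}

#' Write a point table to CSV
#'
#' @param points `point_table` (extra columns such as covariates and `rio`
#'   are written too).
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_points <- function(points, path) {
  utils::write.csv(as.data.frame(points), path, row.names = FALSE)
  invisible(path)
}

#' Polygon sets
#'
#' A `polygon_set` is a list of polygons, each a list of rings (first the
#' outer ring, then any holes); a ring is a closed two-column matrix of
#' planar coordinates (first vertex repeated last).  Insideness uses the
#' even-odd rule across rings.
#'
#' @param polygons list of polygons as described above.
#' @param label set label, e.g. `"protected_area"` or
#'   `"current_breeding_range"`.
#' @return object of class `polygon_set`.
#' @export
polygon_set <- function(polygons, label = "polygons") {
  stopifnot(is.list(polygons))
  polygons <- lapply(polygons, function(p) {
    if (is.matrix(p)) p <- list(p)
    lapply(p, function(ring) {
      ring <- as.matrix(ring)
      stopifnot(ncol(ring) == 2, nrow(ring) >= 4)
      if (any(ring[1, ] != ring[nrow(ring), ]))
        ring <- rbind(ring, ring[1, ])  # close the ring
      ring
    })
  })
  structure(list(polygons = polygons, label = label), class = "polygon_set")
}

#' @export
print.polygon_set <- function(x, ...) {
  cat(sprintf("polygon_set '%s': %d polygon(s)\n", x$label, length(x$polygons)))
  invisible(x)
}

#' Even-odd point-in-polygon test for a whole polygon set
#'
#' @param polys `polygon_set`.
#' @param x,y point coordinates.
#' @return logical vector, `TRUE` where the point is inside any polygon
#'   of the set (holes excluded by ring parity).
#' @export
points_in_polygons <- function(polys, x, y) {
  stopifnot(inherits(polys, "polygon_set"))
  pts <- cbind(x, y)
  inside <- rep(FALSE, length(x))
  for (poly in polys$polygons) {
    parity <- rep(FALSE, length(x))
    for (ring in poly)
      parity <- xor(parity, mgcv::in.out(ring, pts))
    inside <- inside | parity
  }
  inside
}

#' Read polygons from a GeoJSON FeatureCollection
#'
#' Supports `Polygon` and `MultiPolygon` features with planar coordinates.
#'
#' @param path GeoJSON path.
#' @param label label for the returned set.
#' @return `polygon_set`.
#' @export
read_polygons <- function(path, label = NULL) {
  if (!file.exists(path)) stop("GeoJSON file not found: ", path)
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection: ", path)
  ring_mat <- function(ring)
    do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
  polys <- list()
  for (ft in gj$features) {
    geom <- ft$geometry
    if (is.null(geom)) next
    if (geom$type == "Polygon") {
      polys[[length(polys) + 1]] <- lapply(geom$coordinates, ring_mat)
    } else if (geom$type == "MultiPolygon") {
      for (pg in geom$coordinates)
        polys[[length(polys) + 1]] <- lapply(pg, ring_mat)
    } else {
      stop("unsupported GeoJSON geometry type: ", geom$type)
    }
  }
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  polygon_set(polys, label = label)
}

#' Write a polygon set to GeoJSON
#'
#' @param polys `polygon_set`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_polygons <- function(polys, path) {
  stopifnot(inherits(polys, "polygon_set"))
  features <- lapply(seq_along(polys$polygons), function(i) {
    rings <- lapply(polys$polygons[[i]], function(ring)
      lapply(seq_len(nrow(ring)), function(j) c(ring[j, 1], ring[j, 2])))
    list(type = "Feature",
         properties = list(id = i, label = polys$label),
         geometry = list(type = "Polygon", coordinates = rings))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
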