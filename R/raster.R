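#' Regular raster grid
#'
#' A `raster_grid` is a north-up regular grid of square cells: a numeric
#' matrix plus the planar coordinates of its top-left corner and the cell
#' size in metres.  It carries every gridded layer in the workflow —
#' environmental covariates, the relative index of occurrence (RIO)
#' surface, the human-influence index, and binary masks.
#'
#' Cell `(r, c)` (1-based, row-major, rows running south with increasing
#' `r`) covers the half-open square
#' `[origin_x + (c-1)*s, origin_x + c*s)` in x and
#' `(origin_y - r*s, origin_y - (r-1)*s]` in y, so every in-bounds point
#' maps to exactly one cell.  The sampling point of a cell is its centre.
#' Nodata cells are held as `NA` in memory; the `nodata` sentinel is only
#' used on disk.
#'
#' @param values numeric matrix (rows x cols); `NA` marks nodata.
#' @param origin_x,origin_y planar metres of the grid's top-left corner.
#' @param cell_size cell edge length in metres (> 0, square cells).
#' @param name label used in messages and file headers.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, origin_x = 0, origin_y = nrow(values) * cell_size,
                        cell_size = 1000, name = "layer") {
  if (!is.matrix(values)) values <- as.matrix(values)
  stopifnot(is.numeric(values), nrow(values) >= 1, ncol(values) >= 1)
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("cell_size must be a single positive number")
  structure(
    list(values = values, origin_x = as.numeric(origin_x),
         origin_y = as.numeric(origin_y), cell_size = as.numeric(cell_size),
         name = as.character(name)),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("raster_grid '%s': %d x %d cells of %g m, origin (%g, %g)\n",
              x$name, nrow(v), ncol(v), x$cell_size, x$origin_x, x$origin_y))
  fin <- v[is.finite(v)]
  if (length(fin))
    cat(sprintf("  range [%g, %g], %d nodata cells\n",
                min(fin), max(fin), sum(is.na(v))))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' Check that two grids share origin, cell size and shape
#'
#' @param a,b `raster_grid` objects.
#' @param tol absolute tolerance on origins and cell size, metres.
#' @return `TRUE` invisibly; errors if the grids are not aligned.
#' @export
check_aligned <- function(a, b, tol = 1e-6) {
  stopifnot(inherits(a, "raster_grid"), inherits(b, "raster_grid"))
  ok <- all(dim(a$values) == dim(b$values)) &&
    abs(a$origin_x - b$origin_x) < tol &&
    abs(a$origin_y - b$origin_y) < tol &&
    abs(a$cell_size - b$cell_size) < tol
  if (!ok)
    stop(sprintf("grids '%s' and '%s' are not aligned (origin/cell_size/shape differ)",
                 a$name, b$name))
  invisible(TRUE)
}

#' Cell indices of planar points (half-open convention)
#'
#' Maps points to 1-based (row, col) indices.  Points outside the grid get
#' `NA` indices.  On the shared edge between two cells a point belongs to
#' the cell whose half-open square contains it, so the assignment is
#' always unique.
#'
#' @param grid `raster_grid`.
#' @param x,y numeric vectors of planar coordinates.
#' @return data.frame with columns `row`, `col` (`NA` = out of bounds).
#' @export
cell_index <- function(grid, x, y) {
  s <- grid$cell_size
  col <- floor((x - grid$origin_x) / s) + 1L
  row <- floor((grid$origin_y - y) / s) + 1L
  # top edge y == origin_y belongs to row 1; right/bottom edges are outside
  row[y == grid$origin_y] <- 1L
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  bad <- row < 1L | row > nr | col < 1L | col > nc | !is.finite(x) | !is.finite(y)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Cell-centre coordinates of grid indices
#'
#' Inverse of [cell_index()] on in-bounds cells: `cell_index(cell_centre(r, c))`
#' returns `(r, c)` exactly.
#'
#' @param grid `raster_grid`.
#' @param row,col 1-based indices (vectors).
#' @return data.frame with columns `x`, `y`.
#' @export
cell_centre <- function(grid, row, col) {
  s <- grid$cell_size
  data.frame(x = grid$origin_x + (col - 0.5) * s,
             y = grid$origin_y - (row - 0.5) * s)
}

#' Values of a grid at planar points
#'
#' @param grid `raster_grid`.
#' @param x,y coordinates.
#' @return numeric vector; `NA` for out-of-bounds points or nodata cells.
#' @export
grid_value_at <- function(grid, x, y) {
  rc <- cell_index(grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc$row)
  out[ok] <- grid$values[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' Read a raster from an ESRI ASCII grid file
#'
#' Reads the plain-text ASCII grid format (`ncols`/`nrows`/`xllcorner`/
#' `yllcorner`/`cellsize`/`NODATA_value` header followed by rows of values,
#' north row first).  Cells equal to the nodata sentinel become `NA`.
#'
#' @param path file path.
#' @param name layer label; defaults to the file name without extension.
#' @return `raster_grid`.
#' @export
read_raster <- function(path, name = NULL) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path, n = 7L)
  hdr <- list()
  nhdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                   "cellsize", "nodata_value", "dx", "dy")) {
      hdr[[key]] <- as.numeric(parts[2]); nhdr <- nhdr + 1L
    } else break
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner"))
    if (is.null(hdr[[k]])) stop("malformed ASCII grid header in ", path,
                                ": missing ", k)
  if (!is.null(hdr$dx) || !is.null(hdr$dy)) {
    if (is.null(hdr$dx) || is.null(hdr$dy) || hdr$dx != hdr$dy)
      stop("non-square cells in ", path,
           sprintf(" (dx=%s, dy=%s); only square-cell grids are supported",
                   hdr$dx, hdr$dy))
    hdr$cellsize <- hdr$dx
  }
  if (is.null(hdr$cellsize)) stop("malformed ASCII grid header in ", path,
                                  ": missing cellsize")
  vals <- scan(path, what = double(), skip = nhdr, quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d values in %s, found %d", nr * nc, path, length(vals)))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  raster_grid(m, origin_x = hdr$xllcorner,
              origin_y = hdr$yllcorner + nr * hdr$cellsize,
              cell_size = hdr$cellsize, name = name)
}

#' Write a raster to an ESRI ASCII grid file
#'
#' Values are written at full double precision so that
#' `read_raster(write_raster(g))` reproduces `g` exactly.
#'
#' @param grid `raster_grid`.
#' @param path output path.
#' @param nodata sentinel written for `NA` cells.
#' @return `path` invisibly.
#' @export
write_raster <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "raster_grid"))
  v <- grid$values
  if (any(v == nodata, na.rm = TRUE))
    stop("grid contains the nodata sentinel ", nodata, " as a real value")
  nr <- nrow(v); nc <- ncol(v)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", nc),
    paste("nrows", nr),
    paste("xllcorner", formatC(grid$origin_x, format = "g", digits = 17)),
    paste("yllcorner", formatC(grid$origin_y - nr * grid$cell_size,
                               format = "g", digits = 17)),
    paste("cellsize", formatC(grid$cell_size, format = "g", digits = 17)),
    paste("NODATA_value", nodata)), con)
  v[is.na(v)] <- nodata
  txt <- apply(v, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " "))
  writeLines(txt, con)
  invisible(path)
}

#' Stack of aligned raster layers
#'
#' A named list of mutually aligned `raster_grid`s; alignment is checked,
#' never assumed.
#'
#' @param layers named list of `raster_grid`s.
#' @return the list with class `raster_stack`.
#' @export
raster_stack <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 1)
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    names(layers) <- vapply(layers, function(g) g$name, "")
  for (i in seq_along(layers)[-1]) check_aligned(layers[[1]], layers[[i]])
  structure(layers, class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("raster_stack of %d layers: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}
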