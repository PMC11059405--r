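# A minimal georeferenced raster: a numeric matrix stored north-first (row 1
# is the northernmost row, matching the ESRI ASCII convention), a lower-left
# corner, a square cell size in degrees, and a nodata sentinel. Values are
# held as NA internally; the sentinel only appears on disk.

#' Construct a raster grid
#'
#' @param values Numeric matrix, row 1 = northernmost row.
#' @param xllcorner,yllcorner Coordinates of the lower-left corner of the
#'   lower-left cell (degrees).
#' @param cellsize Cell size (degrees, > 0); cells are square.
#' @param nodata Nodata sentinel used on disk (default -9999). In memory,
#'   missing cells are `NA`.
#' @param crs Coordinate reference system label (default WGS84 geographic).
#' @return An object of class `irmap_raster`.
#' @examples
#' raster_grid(matrix(1:6, nrow = 2), xllcorner = 0, yllcorner = 0,
#'             cellsize = 0.5)
#' @export
raster_grid <- function(values, xllcorner, yllcorner, cellsize,
                        nodata = -9999, crs = "EPSG:4326") {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("values must be a numeric matrix")
  }
  if (nrow(values) < 1 || ncol(values) < 1) abort("raster must be non-empty")
  if (!is.numeric(cellsize) || length(cellsize) != 1 || cellsize <= 0) {
    abort("cellsize must be a single positive number")
  }
  if (any(values == nodata, na.rm = TRUE)) {
    values[values == nodata] <- NA_real_
  }
  structure(
    list(values = values, xllcorner = as.numeric(xllcorner),
         yllcorner = as.numeric(yllcorner), cellsize = as.numeric(cellsize),
         nodata = as.numeric(nodata), crs = crs),
    class = "irmap_raster")
}

#' @export
print.irmap_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<irmap_raster> %d x %d cells, cellsize %g deg, origin (%g, %g), crs %s\n",
              nrow(v), ncol(v), x$cellsize, x$xllcorner, x$yllcorner, x$crs))
  ok <- sum(!is.na(v))
  rng <- if (ok) sprintf("[%g, %g]", min(v, na.rm = TRUE), max(v, na.rm = TRUE)) else "-"
  cat(sprintf("  valid cells: %d / %d, range %s\n", ok, length(v), rng))
  invisible(x)
}

#' @export
dim.irmap_raster <- function(x) dim(x$values)

raster_compatible <- function(a, b, what = c("grids")) {
  tol <- 1e-9
  checks <- c(
    rows = nrow(a$values) == nrow(b$values),
    cols = ncol(a$values) == ncol(b$values),
    xllcorner = abs(a$xllcorner - b$xllcorner) < tol,
    yllcorner = abs(a$yllcorner - b$yllcorner) < tol,
    cellsize = abs(a$cellsize - b$cellsize) < tol
  )
  if (!all(checks)) {
    abort(sprintf("%s are not co-registered: mismatch in %s",
                  what[1], paste(names(checks)[!checks], collapse = ", ")))
  }
  invisible(TRUE)
}

#' Raster cells as a tibble
#'
#' One row per cell with the cell-centre coordinates, row/column indices
#' (row 1 = northernmost) and the cell value (`NA` for nodata).
#'
#' @param x An `irmap_raster`.
#' @param ... Unused.
#' @return Tibble with columns `lon`, `lat`, `row`, `col`, `value`.
#' @export
as_tibble.irmap_raster <- function(x, ...) {
  nr <- nrow(x$values); nc <- ncol(x$values)
  grid <- tidyr::expand_grid(row = seq_len(nr), col = seq_len(nc))
  dplyr::mutate(grid,
                lon = x$xllcorner + (.data$col - 0.5) * x$cellsize,
                lat = x$yllcorner + (nr - .data$row + 0.5) * x$cellsize,
                value = x$values[cbind(.data$row, .data$col)]) |>
    dplyr::select("lon", "lat", "row", "col", "value")
}

#' Read / write an ESRI ASCII grid
#'
#' The plain-text raster dialect with a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by the
#' data rows, northernmost row first. Cells equal to the `NODATA_value`
#' are mapped to `NA` on read and written back as the sentinel.
#'
#' @param path File path.
#' @return `read_ascii_grid()` returns an `irmap_raster`;
#'   `write_ascii_grid()` returns `path` invisibly.
#' @examples
#' g <- raster_grid(matrix(runif(6), 2), 0, 0, 0.5)
#' f <- tempfile(fileext = ".asc")
#' write_ascii_grid(g, f)
#' g2 <- read_ascii_grid(f)
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  keys <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  header <- list()
  i <- 1
  while (i <= length(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) == 2 && tolower(parts[1]) %in% keys) {
      header[[tolower(parts[1])]] <- as.numeric(parts[2])
      i <- i + 1
    } else break
  }
  missing <- setdiff(keys, names(header))
  if (length(missing)) {
    abort(paste0("malformed ESRI ASCII header: missing key(s) ",
                 paste(missing, collapse = ", ")))
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(header$nrows); nc <- as.integer(header$ncols)
  if (length(vals) != nr * nc) {
    abort(sprintf("expected %d values (%d x %d), found %d",
                  nr * nc, nr, nc, length(vals)))
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)  # north-first rows
  raster_grid(m, header$xllcorner, header$yllcorner, header$cellsize,
              nodata = header$nodata_value)
}

#' @rdname read_ascii_grid
#' @param grid An `irmap_raster`.
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(inherits(grid, "irmap_raster"))
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  header <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$xllcorner),
    sprintf("yllcorner %.10g", grid$yllcorner),
    sprintf("cellsize %.10g", grid$cellsize),
    sprintf("NODATA_value %.10g", grid$nodata)
  )
  body <- apply(v, 1, function(row) paste(format(row, trim = TRUE,
                                                 digits = 10,
                                                 scientific = FALSE),
                                          collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Locate points in raster cells
#'
#' Half-open cell convention: a point belongs to the cell
#' `[x, x + cellsize) x [y, y + cellsize)`, so points exactly on the top or
#' right edge of the grid fall off-grid.
#'
#' @param grid An `irmap_raster`.
#' @param lon,lat Point coordinates (degrees), vectorised.
#' @return Tibble with columns `row`, `col` (NA when off-grid) and `value`.
#' @export
cell_lookup <- function(grid, lon, lat) {
  stopifnot(inherits(grid, "irmap_raster"))
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  col <- floor((lon - grid$xllcorner) / grid$cellsize) + 1
  row_from_bottom <- floor((lat - grid$yllcorner) / grid$cellsize) + 1
  row <- nr - row_from_bottom + 1
  off <- col < 1 | col > nc | row < 1 | row > nr |
    !is.finite(lon) | !is.finite(lat)
  col[off] <- NA_integer_; row[off] <- NA_integer_
  value <- rep(NA_real_, length(lon))
  ok <- !is.na(row)
  value[ok] <- grid$values[cbind(row[ok], col[ok])]
  tibble(row = as.integer(row), col = as.integer(col), value = value)
}
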