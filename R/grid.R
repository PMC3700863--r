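#' Define an analysis grid
#'
#' A `grid_spec` describes a regular geographic (WGS84 longitude/latitude)
#' grid by its bounding box and square cell size in decimal degrees. Layers on
#' the grid are stored as matrices with row 1 at the northern edge (the usual
#' raster orientation); cell centres are at
#' `lon_min + (col - 0.5) * cell_size` and `lat_max - (row - 0.5) * cell_size`.
#'
#' @param lon_min,lon_max,lat_min,lat_max Bounding box in decimal degrees.
#' @param cell_size Cell edge length in decimal degrees (2.5 arc-minutes is
#'   `2.5 / 60`).
#' @return An object of class `grid_spec` with fields `lon_min`, `lon_max`,
#'   `lat_min`, `lat_max`, `cell_size`, `n_rows`, `n_cols`, `crs`.
#' @examples
#' spec <- grid_spec(26, 45, 36, 42, cell_size = 0.5)
#' spec$n_rows # 12
#' spec$n_cols # 38
#' @export
grid_spec <- function(lon_min, lon_max, lat_min, lat_max, cell_size) {
  stopifnot(is.numeric(lon_min), is.numeric(lon_max),
            is.numeric(lat_min), is.numeric(lat_max),
            is.numeric(cell_size), cell_size > 0)
  if (lon_max <= lon_min || lat_max <= lat_min)
    stop("grid_spec: empty extent (max must exceed min)")
  n_cols <- as.integer(round((lon_max - lon_min) / cell_size))
  n_rows <- as.integer(round((lat_max - lat_min) / cell_size))
  if (n_cols < 1L || n_rows < 1L)
    stop("grid_spec: degenerate grid with zero cells")
  structure(
    list(lon_min = lon_min, lon_max = lon_max,
         lat_min = lat_min, lat_max = lat_max,
         cell_size = cell_size, n_rows = n_rows, n_cols = n_cols,
         crs = "EPSG:4326"),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d rows x %d cols, cell %.6f deg\n",
              x$n_rows, x$n_cols, x$cell_size))
  cat(sprintf("  lon [%g, %g], lat [%g, %g], %s\n",
              x$lon_min, x$lon_max, x$lat_min, x$lat_max, x$crs))
  invisible(x)
}

#' Number of cells in a grid
#' @param spec A [grid_spec()].
#' @return Integer cell count.
#' @export
n_cells <- function(spec) spec$n_rows * spec$n_cols

#' Cell-centre coordinates
#'
#' @param spec A [grid_spec()].
#' @param cells Optional integer vector of cell indices (row-major, row 1 =
#'   north); defaults to all cells.
#' @return A data.frame with columns `cell`, `row`, `col`, `lon`, `lat`.
#' @export
cell_centers <- function(spec, cells = NULL) {
  if (is.null(cells)) cells <- seq_len(n_cells(spec))
  cells <- as.integer(cells)
  stopifnot(all(cells >= 1L), all(cells <= n_cells(spec)))
  row <- (cells - 1L) %/% spec$n_cols + 1L
  col <- (cells - 1L) %% spec$n_cols + 1L
  data.frame(
    cell = cells, row = row, col = col,
    lon = spec$lon_min + (col - 0.5) * spec$cell_size,
    lat = spec$lat_max - (row - 0.5) * spec$cell_size)
}

#' Locate coordinates on the grid
#'
#' Cell membership uses half-open intervals `[edge, edge + cell_size)` in both
#' axes, so a point exactly on an interior cell edge belongs to the
#' higher-index (east/north) cell; points on the far east/north boundary of
#' the grid fall outside.
#'
#' @param spec A [grid_spec()].
#' @param lon,lat Coordinate vectors in decimal degrees.
#' @return Integer vector of cell indices; `NA` for points outside the grid.
#' @export
cell_at <- function(spec, lon, lat) {
  stopifnot(length(lon) == length(lat))
  col <- floor((lon - spec$lon_min) / spec$cell_size) + 1
  irow <- floor((lat - spec$lat_min) / spec$cell_size) + 1  # 1 = south edge
  row <- spec$n_rows - irow + 1
  ok <- is.finite(col) & is.finite(row) &
    col >= 1 & col <= spec$n_cols & row >= 1 & row <= spec$n_rows
  out <- rep(NA_integer_, length(lon))
  out[ok] <- as.integer((row[ok] - 1) * spec$n_cols + col[ok])
  out
}

# matrix <-> row-major cell vector (cell = (row-1)*n_cols + col)
as_cell_vector <- function(mat) as.vector(t(mat))
as_grid_matrix <- function(vec, spec)
  matrix(vec, spec$n_rows, spec$n_cols, byrow = TRUE)

same_grid <- function(a, b, tol = 1e-9) {
  is.list(a) && is.list(b) &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$lon_min - b$lon_min) < tol && abs(a$lat_min - b$lat_min) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

#' Write a layer as an ESRI ASCII grid
#'
#' Plain-text raster interchange format (`ncols/nrows/xllcorner/yllcorner/`
#' `cellsize/NODATA_value` header followed by rows north to south). `NA`
#' cells are written as the nodata value.
#'
#' @param mat Matrix on the grid (row 1 = north).
#' @param spec A [grid_spec()].
#' @param path Output file path.
#' @param nodata Nodata sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(mat, spec, path, nodata = -9999) {
  stopifnot(is.matrix(mat), nrow(mat) == spec$n_rows, ncol(mat) == spec$n_cols)
  mat[is.na(mat)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", spec$n_cols),
    sprintf("nrows %d", spec$n_rows),
    sprintf("xllcorner %.10g", spec$lon_min),
    sprintf("yllcorner %.10g", spec$lat_min),
    sprintf("cellsize %.10g", spec$cell_size),
    sprintf("NODATA_value %g", nodata)), con)
  utils::write.table(format(mat, digits = 9, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File written by [write_ascii_grid()] or any conforming ASCII
#'   grid.
#' @return A list with `spec` (a [grid_spec()]) and `data` (matrix, `NA` for
#'   nodata cells).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("read_ascii_grid: incomplete header in ", path)
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  mat <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) mat[mat == hdr$nodata_value] <- NA
  spec <- grid_spec(hdr$xllcorner, hdr$xllcorner + hdr$ncols * hdr$cellsize,
                    hdr$yllcorner, hdr$yllcorner + hdr$nrows * hdr$cellsize,
                    hdr$cellsize)
  list(spec = spec, data = mat)
}
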