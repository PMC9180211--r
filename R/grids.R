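# Georeferenced raster grids (geographic WGS84, cell-center registration)
# and ESRI ASCII grid I/O.

#' Grid specification
#'
#' Cell-center registered geographic grid: `origin_lon`/`origin_lat` are the
#' center of the south-west cell, `cell_size` the spacing in degrees (square
#' cells), rows run south to north and columns west to east.
#'
#' @param origin_lon,origin_lat center of the south-west cell, degrees.
#' @param cell_size cell spacing, degrees (> 0).
#' @param nrows,ncols grid dimensions.
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(origin_lon, origin_lat, cell_size, nrows, ncols) {
  stopifnot(is.finite(origin_lon), is.finite(origin_lat),
            is.finite(cell_size), cell_size > 0,
            nrows >= 1, ncols >= 1)
  structure(list(origin_lon = origin_lon, origin_lat = origin_lat,
                 cell_size = cell_size, nrows = as.integer(nrows),
                 ncols = as.integer(ncols), crs = "WGS84",
                 registration = "cell-center"),
            class = "grid_spec")
}

#' Georeferenced raster grid
#'
#' @param spec a [grid_spec()].
#' @param values numeric matrix `nrows x ncols`; row 1 is the southernmost
#'   row, column 1 the westernmost column.
#' @param nodata value marking missing cells (kept as `NA` internally).
#' @return object of class `geo_grid`.
#' @export
geo_grid <- function(spec, values, nodata = -9999) {
  stopifnot(inherits(spec, "grid_spec"))
  values <- as.matrix(values)
  if (nrow(values) != spec$nrows || ncol(values) != spec$ncols)
    stop("values do not match grid spec dimensions", call. = FALSE)
  structure(list(spec = spec, values = values, nodata = nodata),
            class = "geo_grid")
}

# cell-center coordinates
grid_lons <- function(g) g$spec$origin_lon + (seq_len(g$spec$ncols) - 1) * g$spec$cell_size
grid_lats <- function(g) g$spec$origin_lat + (seq_len(g$spec$nrows) - 1) * g$spec$cell_size

#' @export
print.geo_grid <- function(x, ...) {
  s <- x$spec
  cat(sprintf("geo_grid: %d x %d cells of %g deg, SW center (%.4f, %.4f)\n",
              s$nrows, s$ncols, s$cell_size, s$origin_lon, s$origin_lat))
  v <- x$values[is.finite(x$values)]
  if (length(v))
    cat(sprintf("  values: [%.4g, %.4g], %d NA cells\n", min(v), max(v),
                sum(!is.finite(x$values))))
  invisible(x)
}

#' Quick-look plot of a raster grid
#'
#' @param x a [geo_grid()].
#' @param ... passed to [graphics::image()].
#' @export
plot.geo_grid <- function(x, ...) {
  image(grid_lons(x), grid_lats(x), t(x$values), xlab = "lon", ylab = "lat",
        col = hcl.colors(64, "viridis"), useRaster = TRUE, ...)
  invisible(x)
}

#' Read an ESRI ASCII grid
#'
#' Supports `xllcorner`/`yllcorner` and `xllcenter`/`yllcenter` headers;
#' nodata cells become `NA`.
#'
#' @param path file path.
#' @return a [geo_grid()].
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path, n = 6)
  hdr <- list()
  nhdr <- 0
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      nhdr <- nhdr + 1
    } else break
  }
  if (is.null(hdr$ncols) || is.null(hdr$nrows) || is.null(hdr$cellsize))
    stop("not an ESRI ASCII grid: ", path, call. = FALSE)
  cs <- hdr$cellsize
  ox <- if (!is.null(hdr$xllcenter)) hdr$xllcenter else hdr$xllcorner + cs / 2
  oy <- if (!is.null(hdr$yllcenter)) hdr$yllcenter else hdr$yllcorner + cs / 2
  nodata <- hdr$nodata_value %||% -9999
  vals <- scan(path, skip = nhdr, quiet = TRUE)
  if (length(vals) != hdr$nrows * hdr$ncols)
    stop("cell count does not match header in ", path, call. = FALSE)
  # file rows run north to south; internal rows run south to north
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m <- m[rev(seq_len(hdr$nrows)), , drop = FALSE]
  m[m == nodata] <- NA
  geo_grid(grid_spec(ox, oy, cs, hdr$nrows, hdr$ncols), m, nodata)
}

#' Write an ESRI ASCII grid
#'
#' @param grid a [geo_grid()].
#' @param path output path.
#' @param digits significant digits written per cell.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(grid, path, digits = 10) {
  stopifnot(inherits(grid, "geo_grid"))
  s <- grid$spec
  m <- grid$values
  m[!is.finite(m)] <- grid$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", s$ncols),
    sprintf("nrows %d", s$nrows),
    sprintf("xllcorner %.10g", s$origin_lon - s$cell_size / 2),
    sprintf("yllcorner %.10g", s$origin_lat - s$cell_size / 2),
    sprintf("cellsize %.10g", s$cell_size),
    sprintf("NODATA_value %g", grid$nodata)
  ), con)
  for (i in rev(seq_len(s$nrows)))
    writeLines(paste(signif(m[i, ], digits), collapse = " "), con)
  invisible(path)
}
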