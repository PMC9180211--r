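# Overlay of an intensity raster with a population raster: per-intensity
# population exposure.

#' Population exposure by intensity class
#'
#' For every population cell, samples the intensity raster at the population
#' cell center by nearest neighbour, bins the value into classes V..XI, and
#' accumulates the cell's persons into the class total.  Population is the
#' accumulation unit and is never resampled, so persons are conserved
#' exactly: `sum(Pe) + below_V + unassessed == total population`.
#'
#' Nearest-neighbour (not bilinear) sampling keeps class boundaries sharp —
#' intensity classes are ordinal.  Population cells falling outside the
#' intensity raster's extent are counted in an `unassessed` bucket rather
#' than silently dropped; nodata population cells count as zero persons and
#' are tallied.
#'
#' @param intensity a [geo_grid()] of continuous intensity.
#' @param pop a [geo_grid()] of persons per cell (non-negative).
#' @return an [exposure_vector()] with attribute `diagnostics`: list with
#'   `below_v`, `unassessed`, `nodata_cells`, `total_population`.
#' @export
compute_exposure <- function(intensity, pop) {
  stopifnot(inherits(intensity, "geo_grid"), inherits(pop, "geo_grid"))
  if (!identical(intensity$spec$crs, pop$spec$crs))
    stop("intensity and population rasters use different CRS", call. = FALSE)

  is_ <- intensity$spec
  lon_min <- is_$origin_lon - is_$cell_size / 2
  lon_max <- is_$origin_lon + (is_$ncols - 0.5) * is_$cell_size
  lat_min <- is_$origin_lat - is_$cell_size / 2
  lat_max <- is_$origin_lat + (is_$nrows - 0.5) * is_$cell_size

  plons <- grid_lons(pop)
  plats <- grid_lats(pop)
  if (max(plons) < lon_min || min(plons) > lon_max ||
      max(plats) < lat_min || min(plats) > lat_max)
    stop("population and intensity rasters have disjoint extents",
         call. = FALSE)

  persons <- pop$values
  nodata_cells <- sum(!is.finite(persons))
  persons[!is.finite(persons)] <- 0
  if (any(persons < 0)) stop("population must be non-negative", call. = FALSE)

  # nearest intensity cell per population cell center
  ci <- round((plats - is_$origin_lat) / is_$cell_size) + 1  # row (lat)
  cj <- round((plons - is_$origin_lon) / is_$cell_size) + 1  # col (lon)
  inside_i <- ci >= 1 & ci <= is_$nrows
  inside_j <- cj >= 1 & cj <= is_$ncols
  inside <- outer(inside_i, inside_j, `&`)

  unassessed <- sum(persons[!inside])

  idx <- cbind(rep(pmin(pmax(ci, 1), is_$nrows), times = length(cj)),
               rep(pmin(pmax(cj, 1), is_$ncols), each = length(ci)))
  ival <- matrix(intensity$values[idx], nrow = length(ci))
  if (any(!is.finite(ival[inside])))
    stop("intensity raster contains non-finite values", call. = FALSE)
  cls <- matrix(NA_integer_, nrow(ival), ncol(ival))
  cls[inside] <- bin_intensity(ival[inside])

  pe <- setNames(numeric(7), paste0("pe", intensity_classes()))
  sel <- inside & !is.na(cls)
  if (any(sel)) {
    sums <- tapply(persons[sel], factor(cls[sel], levels = 5:11), sum)
    sums[is.na(sums)] <- 0
    pe[] <- as.numeric(sums)
  }
  below_v <- sum(persons[inside & is.na(cls)])

  out <- exposure_vector(pe)
  attr(out, "diagnostics") <- list(below_v = below_v, unassessed = unassessed,
                                   nodata_cells = nodata_cells,
                                   total_population = sum(persons))
  out
}

#' Write / read an exposure vector as CSV
#'
#' Two-column CSV (`class`, `persons`), one row per intensity class V..XI.
#'
#' @param exposure an [exposure_vector()].
#' @param path file path.
#' @return `path` (write) or an `exposure_vector` (read).
#' @export
write_exposure_csv <- function(exposure, path) {
  df <- data.frame(class = intensity_classes(), persons = as.numeric(exposure))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_exposure_csv
#' @export
read_exposure_csv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("class", "persons") %in% names(df)))
  exposure_vector(setNames(df$persons, paste0("pe", df$class)))
}
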