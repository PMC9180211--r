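# Synthetic fixtures: HDI tables, damaging-earthquake catalogs with known
# generating parameters, clustered population rasters and analytic
# radiation-pattern intensity fields.  Every generator is deterministic
# under a fixed seed.

#' Synthetic HDI table
#'
#' Smooth logistic rise of the human development index over a year range,
#' emulating the steady growth of a developing region across the catalog
#' era.
#'
#' @param years year range covered.
#' @param start,end HDI at the first and last year.
#' @return an [hdi_table()].
#' @export
gen_hdi_table <- function(years = 1950:2021, start = 0.22, end = 0.78) {
  stopifnot(start > 0, end <= 1, start < end)
  u <- (years - min(years)) / diff(range(years))
  s <- 1 / (1 + exp(-6 * (u - 0.5)))
  s <- (s - min(s)) / diff(range(s))
  hdi_table(data.frame(year = years, hdi = start + (end - start) * s))
}

# default per-region generating parameters of the synthetic catalog: the
# log-linear ratio rises from ~1e-8 at intensity V to ~1e-2 at XI, in the
# range of empirical fatality-ratio laws for damaging earthquakes
.default_gen_beta <- c(a = -14.2, b = -13.9, c = -14.6, d = -14.0, e = -14.4)
.default_gen_theta <- c(a = 1.10, b = 1.05, c = 1.15, d = 1.08, e = 1.12)

#' Catalog generator specification
#'
#' @param n_events events per region.
#' @param beta,theta generating parameters, named by region code (scalars
#'   are recycled).
#' @param zeta lognormal noise scale on recorded fatalities (`0` =
#'   noise-free).
#' @param regions region codes to generate.
#' @param years year range events are drawn from.
#' @param max_class_range range the per-event maximum intensity class is
#'   drawn from.
#' @param log10_hi,log10_width per-class log10 exposure ranges: class I
#'   draws `log10 Pe ~ U(hi_I - width, hi_I)` with
#'   `hi_I = log10_hi - 0.3 (I - 5)`.
#' @param seed integer seed.
#' @return list of class `catalog_gen_spec`.
#' @export
catalog_gen_spec <- function(n_events = 20, beta = .default_gen_beta,
                             theta = .default_gen_theta, zeta = 0.5,
                             regions = names(region_labels()),
                             years = c(1970, 2018),
                             max_class_range = c(10, 11),
                             log10_hi = 7.2, log10_width = 1.5,
                             seed = 1L) {
  stopifnot(zeta >= 0, n_events >= 1)
  if (length(beta) == 1) beta <- setNames(rep(beta, length(regions)), regions)
  if (length(theta) == 1) theta <- setNames(rep(theta, length(regions)), regions)
  structure(list(n_events = n_events, beta = beta, theta = theta,
                 zeta = zeta, regions = regions, years = years,
                 max_class_range = max_class_range, log10_hi = log10_hi,
                 log10_width = log10_width, seed = as.integer(seed)),
            class = "catalog_gen_spec")
}

#' Generate a synthetic damaging-earthquake catalog
#'
#' Draws per-event exposure vectors (log-uniform person counts per class up
#' to a random maximum class), computes the model expectation `E_i` under
#' the generating parameters (including the HDI correction for the event's
#' year), and records `O_i = max(1, round(E_i * exp(zeta * z_i)))` with
#' `z_i` standard normal.  With `zeta = 0`, `O_i = max(1, round(E_i))`
#' exactly.  Events floored to 1 fatality are flagged in the `floored`
#' column.
#'
#' @param spec a [catalog_gen_spec()].
#' @param hdi an [hdi_table()] covering `spec$years`.
#' @return catalog data frame (see [read_catalog()]) with extra columns
#'   `E_true` and `floored`.
#' @export
gen_catalog <- function(spec = catalog_gen_spec(), hdi = gen_hdi_table()) {
  stopifnot(inherits(spec, "catalog_gen_spec"))
  hdi <- if (inherits(hdi, "hdi_table")) hdi else hdi_table(hdi)
  set.seed(spec$seed)
  I <- intensity_classes()
  hi <- spec$log10_hi - 0.3 * (I - 5)
  rows <- list()
  for (rg in spec$regions) {
    b <- spec$beta[[rg]]; th <- spec$theta[[rg]]
    for (ev in seq_len(spec$n_events)) {
      year <- sample(seq(spec$years[1], spec$years[2]), 1)
      maxc <- sample(seq(spec$max_class_range[1], spec$max_class_range[2]), 1)
      pe <- numeric(7)
      keep <- I <= maxc
      pe[keep] <- 10^runif(sum(keep), hi[keep] - spec$log10_width, hi[keep])
      if (all(pe == 0))
        stop("generated event has all-zero exposure (unusable)", call. = FALSE)
      params <- list(coefficients = rbind(c(beta = b, theta = th)))
      rownames(params$coefficients) <- rg
      E <- estimate_fatalities(exposure_vector(pe), rg, year, params, hdi)
      z <- if (spec$zeta > 0) rnorm(1) else 0
      O_raw <- round_half_up(E * exp(spec$zeta * z))
      O <- max(1, O_raw)
      rows[[length(rows) + 1]] <- data.frame(
        id = sprintf("%s%03d", rg, ev), region_code = rg, year = year,
        magnitude = NA_real_, O = O,
        pe5 = pe[1], pe6 = pe[2], pe7 = pe[3], pe8 = pe[4], pe9 = pe[5],
        pe10 = pe[6], pe11 = pe[7],
        E_true = E, floored = O_raw < 1)
    }
  }
  do.call(rbind, rows)
}

#' Generate a clustered population raster
#'
#' Population density as a mixture of Gaussian blobs over a uniform floor,
#' emulating settlement clustering in gridded ambient-population products;
#' cell values are rounded persons and sum to `total_persons` to within
#' rounding (`n_cells / 2`).  `n_clusters = 0` gives a uniform raster
#' (exact sum, unrounded).
#'
#' @param spec a [grid_spec()].
#' @param n_clusters number of settlement clusters.
#' @param total_persons total population across the raster.
#' @param seed integer seed.
#' @param floor_frac fraction of the population spread uniformly.
#' @return a [geo_grid()] of persons per cell.
#' @export
gen_population <- function(spec, n_clusters = 8, total_persons = 1e6,
                           seed = 1L, floor_frac = 0.1) {
  stopifnot(inherits(spec, "grid_spec"), total_persons >= 0)
  set.seed(seed)
  nr <- spec$nrows; nc <- spec$ncols
  if (n_clusters == 0) {
    m <- matrix(total_persons / (nr * nc), nr, nc)
    return(geo_grid(spec, m))
  }
  lon <- spec$origin_lon + (seq_len(nc) - 1) * spec$cell_size
  lat <- spec$origin_lat + (seq_len(nr) - 1) * spec$cell_size
  w <- matrix(floor_frac / (nr * nc), nr, nc)
  ext <- spec$cell_size * max(nr, nc)
  for (cl in seq_len(n_clusters)) {
    c_lon <- runif(1, min(lon), max(lon))
    c_lat <- runif(1, min(lat), max(lat))
    sd <- runif(1, 0.02, 0.12) * ext
    amp <- runif(1, 0.5, 1.5)
    g <- amp * outer(exp(-((lat - c_lat) / sd)^2 / 2),
                     exp(-((lon - c_lon) / sd)^2 / 2))
    w <- w + g * (1 - floor_frac) / n_clusters
  }
  m <- round_half_up(total_persons * w / sum(w))
  geo_grid(spec, m)
}

#' Generate an analytic radiation-pattern intensity field
#'
#' Isoseismal-style field with logarithmic distance decay and an optional
#' four-lobed azimuthal modulation mimicking the butterfly-shaped surface
#' pattern of a strike-slip double couple:
#' `I(r, phi) = I0 - decay * log10(max(r, r0) / r0)
#'  + lobe * |sin 2(phi - strike)|`, clamped to \[1, 12\].  With
#' `lobe = 0` the maximum sits at the epicenter.
#'
#' @param spec a [grid_spec()].
#' @param epicenter `c(lon, lat)`.
#' @param I0 epicentral intensity (<= 12).
#' @param decay_per_log10km intensity lost per decade of epicentral
#'   distance (default 2.5, giving damaging-intensity footprints of a few
#'   tens of km for a moderate crustal event).
#' @param lobe_amplitude amplitude of the azimuthal lobes, intensity units.
#' @param strike lobe orientation, degrees clockwise from north.
#' @param r0 saturation radius, km.
#' @return a [geo_grid()] of continuous intensity.
#' @export
gen_intensity_field <- function(spec, epicenter, I0 = 9,
                                decay_per_log10km = 2.5,
                                lobe_amplitude = 0, strike = 0, r0 = 2) {
  stopifnot(inherits(spec, "grid_spec"), I0 <= 12)
  lon <- spec$origin_lon + (seq_len(spec$ncols) - 1) * spec$cell_size
  lat <- spec$origin_lat + (seq_len(spec$nrows) - 1) * spec$cell_size
  # local flat-earth offsets in km
  kx <- outer(rep(1, spec$nrows),
              (lon - epicenter[1]) * 111.32 * cos(epicenter[2] * pi / 180))
  ky <- outer((lat - epicenter[2]) * 110.57, rep(1, spec$ncols))
  r <- sqrt(kx^2 + ky^2)
  phi <- atan2(kx, ky)                       # azimuth from north, clockwise
  I <- I0 - decay_per_log10km * log10(pmax(r, r0) / r0) +
    lobe_amplitude * abs(sin(2 * (phi - strike * pi / 180)))
  geo_grid(spec, pmin(pmax(I, 1), 12))
}
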