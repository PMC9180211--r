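# Raster containers, ESRI ASCII I/O and the intensity/population overlay.

test_that("ESRI ASCII grids round-trip including nodata", {
  spec <- grid_spec(99.5, 25.25, 0.05, 6, 8)
  m <- matrix(runif(48, 0, 100), 6, 8)
  m[2, 3] <- NA
  g <- geo_grid(spec, m)
  path <- withr::local_tempfile(fileext = ".asc")
  write_esri_ascii(g, path)
  back <- read_esri_ascii(path)
  expect_equal(back$spec$origin_lon, spec$origin_lon)
  expect_equal(back$spec$origin_lat, spec$origin_lat)
  expect_equal(back$spec$cell_size, spec$cell_size)
  expect_equal(back$values, m, tolerance = 1e-9)
  expect_true(is.na(back$values[2, 3]))
})

test_that("uniform intensity assigns the whole population to one class", {
  spec <- grid_spec(100, 30, 0.01, 10, 10)
  intens <- geo_grid(spec, matrix(7.0, 10, 10))
  popm <- matrix(123.45, 10, 10)
  pe <- compute_exposure(intens, geo_grid(spec, popm))
  expect_equal(unname(pe["pe7"]), sum(popm))
  expect_equal(sum(pe[-3]), 0)
  d <- attr(pe, "diagnostics")
  expect_equal(d$below_v, 0)
  expect_equal(d$unassessed, 0)
})

test_that("a 3x3 toy overlay matches the cell-by-cell oracle", {
  spec <- grid_spec(0, 0, 1, 3, 3)
  iv <- matrix(c(4.2, 5.4, 6.6,
                 7.5, 8.0, 9.4,
                 10.6, 3.0, 5.0), 3, 3, byrow = TRUE)
  pv <- matrix(1:9, 3, 3, byrow = TRUE)
  pe <- compute_exposure(geo_grid(spec, iv), geo_grid(spec, pv))
  # brute-force oracle
  oracle <- setNames(numeric(7), paste0("pe", 5:11))
  below <- 0
  for (i in 1:3) for (j in 1:3) {
    cls <- floor(iv[i, j] + 0.5)
    if (cls >= 5) oracle[paste0("pe", min(cls, 11))] <-
        oracle[paste0("pe", min(cls, 11))] + pv[i, j]
    else below <- below + pv[i, j]
  }
  expect_equal(as.numeric(pe), unname(oracle))
  expect_equal(attr(pe, "diagnostics")$below_v, below)
})

test_that("population mass is conserved across the overlay", {
  set.seed(77)
  for (trial in 1:25) {
    ispec <- grid_spec(10 + runif(1, -0.1, 0.1), 20 + runif(1, -0.1, 0.1),
                       0.05, sample(5:12, 1), sample(5:12, 1))
    pspec <- grid_spec(10, 20, 0.03, sample(8:20, 1), sample(8:20, 1))
    intens <- geo_grid(ispec, matrix(runif(ispec$nrows * ispec$ncols, 2, 12.4),
                                     ispec$nrows, ispec$ncols))
    pm <- matrix(rpois(pspec$nrows * pspec$ncols, 50),
                 pspec$nrows, pspec$ncols)
    pm[sample(length(pm), 3)] <- NA
    pop <- geo_grid(pspec, pm)
    pe <- suppressWarnings(compute_exposure(intens, pop))
    d <- attr(pe, "diagnostics")
    total <- sum(pm, na.rm = TRUE)
    expect_lt(abs(sum(pe) + d$below_v + d$unassessed - total) /
                max(total, 1), 1e-6)
    expect_equal(d$nodata_cells, 3)
  }
})

test_that("overlay is invariant to population-cell refinement under uniform intensity", {
  ispec <- grid_spec(0, 0, 0.1, 8, 8)
  intens <- geo_grid(ispec, matrix(6.7, 8, 8))
  pspec <- grid_spec(0.05, 0.05, 0.1, 6, 6)
  popm <- matrix(runif(36, 0, 1000), 6, 6)
  pe1 <- compute_exposure(intens, geo_grid(pspec, popm))
  # split every population cell into 4 equal quarters
  fine <- matrix(0, 12, 12)
  for (i in 1:6) for (j in 1:6)
    fine[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)] <- popm[i, j] / 4
  pspec2 <- grid_spec(0.05 - 0.025, 0.05 - 0.025, 0.05, 12, 12)
  pe2 <- compute_exposure(intens, geo_grid(pspec2, fine))
  expect_equal(as.numeric(pe1), as.numeric(pe2))
})

test_that("disjoint extents and CRS mismatches are errors", {
  a <- geo_grid(grid_spec(0, 0, 0.1, 5, 5), matrix(7, 5, 5))
  b <- geo_grid(grid_spec(50, 50, 0.1, 5, 5), matrix(10, 5, 5))
  expect_error(compute_exposure(a, b), "disjoint")
  d <- a
  d$spec$crs <- "UTM48N"
  expect_error(compute_exposure(d, a), "CRS")
})

test_that("exposure CSV round-trips", {
  pe <- exposure_vector(c(pe5 = 100, pe8 = 2.5, pe11 = 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_exposure_csv(pe, path)
  expect_equal(as.numeric(read_exposure_csv(path)), as.numeric(pe))
})
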