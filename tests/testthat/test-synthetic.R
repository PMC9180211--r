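# Synthetic generators: determinism, mass targets, closed-form fields and
# parameter recovery from generated catalogs.

test_that("generators are byte-identical under a fixed seed", {
  hdi <- gen_hdi_table()
  s <- catalog_gen_spec(n_events = 5, zeta = 0.4, seed = 123)
  expect_identical(gen_catalog(s, hdi), gen_catalog(s, hdi))
  spec <- grid_spec(0, 0, 0.02, 20, 20)
  expect_identical(gen_population(spec, 4, 1e5, seed = 9),
                   gen_population(spec, 4, 1e5, seed = 9))
  expect_false(identical(gen_population(spec, 4, 1e5, seed = 9),
                         gen_population(spec, 4, 1e5, seed = 10)))
})

test_that("synthetic HDI tables are valid and increasing", {
  hdi <- gen_hdi_table(1950:2021, start = 0.22, end = 0.78)
  expect_s3_class(hdi, "hdi_table")
  expect_true(all(diff(hdi$hdi) >= 0))
  expect_equal(range(hdi$hdi), c(0.22, 0.78))
  expect_gte(hdi_factor(hdi, 1960), 1)
})

test_that("generated catalogs follow the noise model", {
  hdi <- gen_hdi_table()
  # zeta = 0: O = max(1, round(E)) exactly
  cat0 <- gen_catalog(catalog_gen_spec(n_events = 10, zeta = 0, seed = 4,
                                       regions = "b"), hdi)
  expect_equal(cat0$O, pmax(1, floor(cat0$E_true + 0.5)))
  expect_equal(cat0$floored, cat0$O == 1 & floor(cat0$E_true + 0.5) < 1)
  expect_true(all(catalog_exposure_matrix(cat0) >= 0))
  expect_true(all(rowSums(catalog_exposure_matrix(cat0)) > 0))
  # years within the HDI coverage used for fitting
  expect_true(all(cat0$year >= min(hdi$year) & cat0$year <= max(hdi$year)))
  # noisy catalogs have multiplicative lognormal scatter
  cat1 <- gen_catalog(catalog_gen_spec(n_events = 200, zeta = 0.5, seed = 4,
                                       regions = "b"), hdi)
  lr <- log(cat1$O / cat1$E_true)
  expect_lt(abs(sd(lr) - 0.5), 0.08)
})

test_that("noise-free catalogs return the generating parameters", {
  hdi <- gen_hdi_table()
  spec <- catalog_gen_spec(n_events = 12, zeta = 0, seed = 21,
                           regions = c("a", "d"))
  m <- fit_fatality_model(gen_catalog(spec, hdi), hdi)
  for (rg in c("a", "d")) {
    expect_lt(abs(coef(m)[rg, "beta"] - spec$beta[[rg]]), 0.01)
    expect_lt(abs(coef(m)[rg, "theta"] - spec$theta[[rg]]), 0.01)
  }
})

test_that("population rasters hit the mass target and cluster", {
  spec <- grid_spec(0, 0, 0.02, 25, 40)
  pop <- gen_population(spec, n_clusters = 6, total_persons = 1e6, seed = 2)
  expect_lt(abs(sum(pop$values) - 1e6), 25 * 40 / 2)
  expect_true(all(pop$values >= 0))
  # clustered rasters are more peaked than uniform ones
  uni <- gen_population(spec, n_clusters = 0, total_persons = 1e6)
  expect_equal(sum(uni$values), 1e6)
  expect_equal(max(uni$values), min(uni$values))
  expect_gt(max(pop$values), 3 * max(uni$values))
})

test_that("the analytic intensity field obeys its closed form", {
  spec <- grid_spec(99, 25, 0.01, 81, 81)
  epi <- c(99 + 0.40, 25 + 0.40)
  f <- gen_intensity_field(spec, epi, I0 = 9, decay_per_log10km = 2.5,
                           lobe_amplitude = 0, r0 = 1)
  # maximum at the epicenter cell when lobe = 0
  w <- which(f$values == max(f$values), arr.ind = TRUE)
  expect_equal(unname(w[1, ]), c(41, 41))
  expect_equal(f$values[41, 41], 9)
  # decay: one decade of distance loses exactly `decay` intensity units
  lon_at <- function(km) epi[1] + km / (111.32 * cos(epi[2] * pi / 180))
  i1 <- 9 - 2.5 * log10(10 / 1)
  val <- gen_intensity_field(grid_spec(lon_at(10), epi[2], 0.01, 1, 1),
                             epi, I0 = 9, decay_per_log10km = 2.5,
                             lobe_amplitude = 0, r0 = 1)$values[1, 1]
  expect_equal(val, i1, tolerance = 1e-6)
  # 180-degree rotational symmetry of the lobed field
  g <- gen_intensity_field(spec, epi, I0 = 9, decay_per_log10km = 2.5,
                           lobe_amplitude = 1.2, strike = 30, r0 = 1)
  v <- g$values
  rot <- v[rev(seq_len(81)), rev(seq_len(81))]
  expect_equal(v, rot, tolerance = 1e-10)
})
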