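# Fatality ratio, HDI correction, expectation, fit objective, residuals and
# fitting.

test_that("fatality ratio follows the log-linear law and clamps at 1", {
  expect_equal(fatality_ratio(8, beta = -7, theta = 0.5), 1e-3)
  expect_equal(fatality_ratio(11, beta = -12, theta = 1), 0.1)
  expect_equal(fatality_ratio(5, beta = 0, theta = 0), 1)        # clamped
  expect_equal(fatality_ratio(11, beta = 2, theta = 1), 1)       # clamped hard
  expect_gt(fatality_ratio(11, beta = 2, theta = 1, clamp = FALSE), 1)
  # strictly increasing in I for theta > 0 (before clamping)
  r <- fatality_ratio(5:11, beta = -10, theta = 0.8, clamp = FALSE)
  expect_true(all(diff(r) > 0))
  expect_error(fatality_ratio(4, -7, 0.5), "5..11")
  expect_error(fatality_ratio(12, -7, 0.5), "5..11")
})

test_that("HDI factor interpolates, refuses extrapolation, handles constants", {
  hdi <- tiny_hdi()
  expect_equal(hdi_factor(hdi, 2021), 1)
  expect_equal(hdi_factor(hdi, 1976), 2)
  expect_equal(hdi_factor(flat_hdi(), 1981), 1)
  # linear interpolation between bracketing years
  h1998 <- approx(c(1976, 2000), c(0.38, 0.59), xout = 1998)$y
  expect_equal(hdi_factor(hdi, 1998), 0.76 / h1998)
  expect_error(hdi_factor(hdi, 1950), "coverage")
  expect_error(hdi_factor(hdi, 2030), "coverage")
  expect_error(hdi_table(data.frame(year = 2000, hdi = 1.2)), "\\(0, 1\\]")
})

test_that("expected fatalities: single-term value, linearity, zero exposure", {
  hdi <- flat_hdi()
  pars <- list(coefficients = rbind(e = c(beta = -7, theta = 0.5)))
  pe <- exposure_vector(c(pe8 = 1e5))
  expect_equal(estimate_fatalities(pe, "e", 2000, pars, hdi), 100)
  expect_equal(estimate_fatalities(exposure_vector(), "e", 2000, pars, hdi), 0)
  # linearity: E(c * Pe) = c * E(Pe)
  pe2 <- exposure_vector(setNames(runif(7, 0, 1e5), paste0("pe", 5:11)))
  E1 <- estimate_fatalities(pe2, "e", 2000, pars, hdi)
  E3 <- estimate_fatalities(exposure_vector(3.5 * as.numeric(pe2)), "e",
                            2000, pars, hdi)
  expect_equal(E3, 3.5 * E1)
  # HDI correction scales older events up
  hdi2 <- tiny_hdi()
  expect_equal(estimate_fatalities(pe, "e", 1976, pars, hdi2), 200)
  expect_error(estimate_fatalities(pe, "b", 2000, pars, hdi), "region 'b'")
})

test_that("moving exposure mass to higher intensity never lowers E", {
  hdi <- flat_hdi()
  pars <- list(coefficients = rbind(a = c(beta = -9, theta = 0.6)))
  base <- setNames(rep(1e4, 7), paste0("pe", 5:11))
  E0 <- estimate_fatalities(exposure_vector(base), "a", 2000, pars, hdi)
  for (from in 1:6) {
    shifted <- base
    shifted[from] <- shifted[from] - 5e3
    shifted[from + 1] <- shifted[from + 1] + 5e3
    E1 <- estimate_fatalities(exposure_vector(shifted), "a", 2000, pars, hdi)
    expect_gte(E1, E0)
  }
})

test_that("fit objective matches hand values and returns -Inf on exact fits", {
  expect_equal(fit_objective(c(20, 50), c(10, 100)),
               log(1300) + mean(c(log(2)^2, log(0.5)^2)))
  expect_identical(fit_objective(c(10, 100), c(10, 100)), -Inf)
  # closed-form single event: E = e*10, O = 10
  expect_equal(fit_objective(exp(1) * 10, 10),
               log((10 * (exp(1) - 1))^2) + 1)
  expect_error(fit_objective(c(1, 2), c(1, 0)), "> 0")
  expect_error(fit_objective(numeric(0), numeric(0)), "non-empty")
})

test_that("log residual is the RMS of ln(E/O)", {
  expect_equal(log_residual(c(10, 100), c(10, 100)), 0)
  expect_equal(log_residual(c(10 * exp(1), 10 / exp(1)), c(10, 10)), 1)
  expect_equal(log_residual(2, 1), log(2))
  expect_error(log_residual(numeric(0), numeric(0)), "non-empty")
})

test_that("fitting recovers a known law from a hand-built catalog", {
  cat_df <- toy_catalog(beta = -7, theta = 0.5, n = 8)
  fit <- fit_params(cat_df, flat_hdi(), "e")
  # O was rounded to integers, so recovery is near-exact, not exact
  expect_lt(abs(fit$beta - (-7)), 0.05)
  expect_lt(abs(fit$theta - 0.5), 0.01)
  expect_equal(fit$diagnostics$n, 8)
  expect_equal(fit$diagnostics$within_order, 1)
  expect_false(fit$diagnostics$degenerate)
})

test_that("fitting requires two usable events and names the region", {
  cat_df <- toy_catalog(n = 3)
  cat_df$O[2:3] <- 0   # excluded by the O >= 1 rule
  expect_error(fit_params(cat_df, flat_hdi(), "e"), "region 'e'")
  expect_error(fit_params(cat_df, flat_hdi(), "a"), "no catalog events")
})

test_that("single-intensity-class catalogs are flagged as degenerate", {
  hdi <- flat_hdi()
  rows <- lapply(1:4, function(i) {
    pe <- setNames(numeric(7), paste0("pe", 5:11))
    pe["pe8"] <- 10^(3 + i / 2)
    E <- 10^(-7 + 0.5 * 8) * pe["pe8"]
    data.frame(id = paste0("d", i), region_code = "c", year = 2000,
               magnitude = 6, O = max(1, round(E)), as.list(pe))
  })
  cat_df <- do.call(rbind, rows)
  expect_warning(fit <- fit_params(cat_df, hdi, "c"), "only beta \\+ theta")
  expect_true(fit$diagnostics$degenerate)
  expect_equal(fit$diagnostics$classes_used, 8)
  # the identified combination beta + 8 theta is still recovered
  expect_lt(abs((fit$beta + 8 * fit$theta) - (-7 + 8 * 0.5)), 0.02)
})

test_that("the fitted model object exposes coherent methods", {
  hdi <- gen_hdi_table()
  cat_df <- gen_catalog(catalog_gen_spec(n_events = 8, zeta = 0.3, seed = 5,
                                         regions = c("a", "e")), hdi)
  m <- fit_fatality_model(cat_df, hdi)
  expect_s3_class(m, "fatality_model")
  expect_equal(rownames(coef(m)), c("a", "e"))
  expect_equal(length(fitted(m)), 16)
  expect_equal(names(residuals(m)), names(fitted(m)))
  # zeta is the RMS of the residuals
  expect_equal(m$zeta_pooled, sqrt(mean(residuals(m)^2)))
  s <- summary(m)
  expect_equal(s$table$region, c("a", "e"))
  expect_output(print(m), "stratified")
  # predict reproduces the training expectations
  p <- predict(m, cat_df)
  expect_equal(unname(p[1:3]), unname(fitted(m)[cat_df$id[1:3]]))
  pl <- predict(m, cat_df[1:2, ], type = "estimate")
  expect_s3_class(pl[[1]], "fatality_estimate")
  # simulate is reproducible under a seed and respects the floor at 1
  s1 <- simulate(m, nsim = 2, seed = 9)
  s2 <- simulate(m, nsim = 2, seed = 9)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 1))
})

test_that("catalog CSV round-trips and validation names offending rows", {
  cat_df <- toy_catalog(n = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_catalog(cat_df, path)
  back <- read_catalog(path)
  expect_equal(back$O, cat_df$O)
  expect_equal(back$pe7, cat_df$pe7)
  bad <- cat_df
  bad$pe6[2] <- -5
  bad$region_code[3] <- "z"
  expect_error(validate_catalog(bad), "t02, t03")
})

test_that("fitted parameters round-trip through JSON", {
  hdi <- gen_hdi_table()
  m <- fit_fatality_model(gen_catalog(catalog_gen_spec(
    n_events = 6, zeta = 0, seed = 2, regions = "d"), hdi), hdi)
  path <- withr::local_tempfile(fileext = ".json")
  write_params_json(m, path)
  p <- read_params_json(path)
  expect_equal(p$regions$d$beta, unname(coef(m)["d", "beta"]))
  expect_equal(p$regions$d$theta, unname(coef(m)["d", "theta"]))
  expect_equal(p$zeta, m$zeta_pooled)
  # usable directly as params in estimate_fatalities
  pe <- exposure_vector(c(pe9 = 1e4))
  expect_equal(
    estimate_fatalities(pe, "d", 2000, p, hdi),
    estimate_fatalities(pe, "d", 2000, m, hdi))
})
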