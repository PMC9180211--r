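# Empirical fatality model: log-linear fatality ratio per intensity class,
# HDI correction, regional stratification, and the mixed absolute/log fit
# objective.

#' Intensity classes of the fatality model
#'
#' Damaging macroseismic intensities run from class V to class XI: the
#' minimum and maximum intensities observed for damaging earthquakes in the
#' underlying catalog.  All exposure vectors and fatality-ratio evaluations
#' are indexed by these seven classes.
#'
#' @return integer vector `5:11`.
#' @export
intensity_classes <- function() 5:11

#' Region codes of the stratified model
#'
#' The model is stratified into five sub-regions reflecting differences in
#' tectonics, historical seismicity and building stock.
#'
#' @return named character vector mapping region code to label.
#' @export
region_labels <- function() {
  c(a = "Xinjiang", b = "Qinghai-Tibet Plateau", c = "Northeast",
    d = "North China", e = "South China")
}

.check_intensity <- function(I) {
  if (any(!is.finite(I)) || any(I < 5) || any(I > 11))
    stop("intensity class must lie in 5..11 (V..XI)", call. = FALSE)
  invisible(I)
}

#' Fatality ratio at a given intensity
#'
#' The fatality ratio r(I) — expected deaths per exposed person at intensity
#' class I — follows a log-linear law `log(r) = beta + theta * I`.  Because a
#' ratio of persons is a proportion, r is clamped at 1.
#'
#' @param I integer intensity class(es), 5..11.
#' @param beta,theta intercept and slope of the log-linear law.
#' @param base base of the logarithm (default 10, the convention for
#'   fatality-ratio models).
#' @param clamp clamp the ratio at 1 (default `TRUE`).
#' @return numeric vector of fatality ratios in (0, 1].
#' @examples
#' fatality_ratio(8, beta = -7, theta = 0.5)  # 1e-3
#' @export
fatality_ratio <- function(I, beta, theta, base = 10, clamp = TRUE) {
  .check_intensity(I)
  r <- base^(beta + theta * I)
  if (clamp) r <- pmin(r, 1)
  r
}

#' Human-development-index table
#'
#' Wraps a `year`/`hdi` data frame as an HDI table used to normalise fatality
#' ratios across eras of building resilience: ratios of older events are
#' scaled by `HDI(max_year) / HDI(event_year)`.
#'
#' @param x data frame with numeric columns `year` and `hdi` (values in
#'   (0, 1]).
#' @return an object of class `hdi_table`.
#' @seealso [hdi_factor()], [gen_hdi_table()]
#' @export
hdi_table <- function(x) {
  if (!is.data.frame(x) || !all(c("year", "hdi") %in% names(x)))
    stop("HDI table needs columns 'year' and 'hdi'", call. = FALSE)
  x <- x[order(x$year), c("year", "hdi")]
  if (any(!is.finite(x$hdi)) || any(x$hdi <= 0) || any(x$hdi > 1))
    stop("HDI values must lie in (0, 1]", call. = FALSE)
  if (anyDuplicated(x$year)) stop("duplicated years in HDI table", call. = FALSE)
  structure(x, class = c("hdi_table", "data.frame"),
            max_year = max(x$year))
}

#' HDI correction factor for an event year
#'
#' Returns `HDI(max_year) / HDI(event_year)`, the factor by which the
#' fatality ratio of an event is scaled to the reference (most recent) year
#' of the table.  Years between table entries are linearly interpolated;
#' years outside the table are an error (no extrapolation).
#'
#' @param table an [hdi_table()].
#' @param event_year calendar year of the event.
#' @return positive scalar; `>= 1` whenever HDI is non-decreasing in time.
#' @export
hdi_factor <- function(table, event_year) {
  if (!inherits(table, "hdi_table")) table <- hdi_table(table)
  if (length(event_year) != 1L || !is.finite(event_year))
    stop("event_year must be a single finite year", call. = FALSE)
  if (event_year < min(table$year) || event_year > max(table$year))
    stop(sprintf("year %s outside HDI table coverage [%d, %d]",
                 format(event_year), min(table$year), max(table$year)),
         call. = FALSE)
  h_event <- approx(table$year, table$hdi, xout = event_year)$y
  h_ref <- table$hdi[match(attr(table, "max_year"), table$year)]
  h_ref / h_event
}

#' Per-intensity population exposure vector
#'
#' @param x numeric vector of non-negative person counts; either length 7
#'   (classes V..XI in order) or named `pe5`..`pe11` (missing classes are
#'   zero).
#' @return named numeric vector `pe5`..`pe11`, class `exposure_vector`.
#' @export
exposure_vector <- function(x = numeric(0)) {
  nm <- paste0("pe", intensity_classes())
  out <- setNames(numeric(7), nm)
  if (length(x)) {
    if (is.null(names(x))) {
      if (length(x) != 7) stop("unnamed exposure must have length 7", call. = FALSE)
      out[] <- as.numeric(x)
    } else {
      bad <- setdiff(names(x), nm)
      if (length(bad)) stop("unknown exposure classes: ",
                            paste(bad, collapse = ", "), call. = FALSE)
      out[names(x)] <- as.numeric(x)
    }
  }
  if (any(!is.finite(out)) || any(out < 0))
    stop("exposure must be non-negative and finite", call. = FALSE)
  structure(out, class = "exposure_vector")
}

#' @export
print.exposure_vector <- function(x, ...) {
  cat("Population exposure by intensity class (persons)\n")
  print(setNames(round(as.numeric(x)), c("V", "VI", "VII", "VIII", "IX",
                                         "X", "XI")))
  d <- attr(x, "diagnostics")
  if (!is.null(d))
    cat(sprintf("below V: %.0f | unassessed: %.0f | nodata cells: %d | total: %.0f\n",
                d$below_v, d$unassessed, d$nodata_cells,
                d$total_population))
  invisible(x)
}

# exposure columns of a catalog data frame as an N x 7 matrix
#' Exposure matrix of a catalog
#'
#' Extracts the `pe5`..`pe11` columns of a catalog data frame as an
#' events-by-classes matrix.
#'
#' @param catalog catalog data frame (see [read_catalog()]).
#' @return numeric matrix with one row per event and columns `pe5`..`pe11`.
#' @export
catalog_exposure_matrix <- function(catalog) {
  nm <- paste0("pe", intensity_classes())
  miss <- setdiff(nm, names(catalog))
  if (length(miss)) stop("catalog lacks exposure columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  m <- as.matrix(catalog[, nm, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

# normalise the various ways of supplying fitted parameters
as_fatality_params <- function(params) {
  if (inherits(params, "fatality_model"))
    return(list(coefficients = params$coefficients, zeta = params$zeta,
                log_base = params$settings$log_base %||% 10,
                clamp = params$settings$clamp %||% TRUE))
  if (is.list(params) && !is.null(params$regions)) {
    cf <- do.call(rbind, lapply(params$regions, function(p)
      c(beta = p$beta, theta = p$theta)))
    rownames(cf) <- names(params$regions)
    return(list(coefficients = cf, zeta = params$zeta %||% NA_real_,
                log_base = params$log_base %||% 10,
                clamp = params$clamp %||% TRUE))
  }
  if (is.list(params) && !is.null(params$coefficients))
    return(list(coefficients = params$coefficients,
                zeta = params$zeta %||% NA_real_,
                log_base = params$log_base %||% 10,
                clamp = params$clamp %||% TRUE))
  stop("cannot interpret 'params' as fatality-model parameters", call. = FALSE)
}

#' Expected fatalities for an exposure vector
#'
#' Evaluates the fatality expectation
#' `E = sum_{I=V..XI} r(I; beta_region, theta_region) * hdi_factor * Pe(I)`,
#' the core of the estimation model.  E is linear in the exposure and zero
#' for an all-zero exposure vector.
#'
#' @param exposure an [exposure_vector()] (or coercible vector).
#' @param region region code, one of `names(region_labels())` present in
#'   `params`.
#' @param event_year calendar year of the event (for the HDI correction).
#' @param params a fitted [fit_fatality_model()] object, a parameter list as
#'   read by [read_params_json()], or a list with a `coefficients` matrix.
#' @param hdi an [hdi_table()].
#' @return expected number of fatalities (non-negative scalar).
#' @examples
#' hdi <- hdi_table(data.frame(year = 2021, hdi = 0.76))
#' pars <- list(coefficients = rbind(e = c(beta = -7, theta = 0.5)))
#' pe <- exposure_vector(c(pe8 = 1e5))
#' estimate_fatalities(pe, "e", 2021, pars, hdi)  # 100
#' @export
estimate_fatalities <- function(exposure, region, event_year, params, hdi) {
  pe <- exposure_vector(unclass(exposure))
  p <- as_fatality_params(params)
  if (!region %in% rownames(p$coefficients))
    stop(sprintf("no fitted parameters for region '%s'", region), call. = FALSE)
  b <- p$coefficients[region, "beta"]
  th <- p$coefficients[region, "theta"]
  r <- fatality_ratio(intensity_classes(), b, th, base = p$log_base,
                      clamp = p$clamp)
  h <- hdi_factor(hdi, event_year)
  sum(r * h * as.numeric(pe))
}

#' Fit objective for the fatality model
#'
#' The regression objective combines an absolute and a logarithmic error
#' term: `epsilon = ln[(1/N) sum (E_i - O_i)^2] + (1/N) sum [ln(E_i/O_i)]^2`.
#' The first term drives agreement for the large, fatal events; the second
#' keeps small events within the right order of magnitude.
#'
#' A perfect fit (`E == O` elementwise) returns `-Inf`: the squared-error
#' term's logarithm diverges, and `-Inf` is accepted as the true infimum.
#'
#' @param E,O positive numeric vectors of equal length: estimated and
#'   recorded fatalities per event.
#' @return scalar objective value (possibly `-Inf`).
#' @examples
#' fit_objective(c(20, 50), c(10, 100))  # ~7.6506
#' @export
fit_objective <- function(E, O) {
  if (length(E) != length(O) || length(E) < 1)
    stop("E and O must be non-empty vectors of equal length", call. = FALSE)
  if (any(!is.finite(E)) || any(!is.finite(O)))
    stop("E and O must be finite", call. = FALSE)
  if (any(E <= 0) || any(O <= 0))
    stop("all estimated and recorded fatalities must be > 0; pre-filter zero-fatality events",
         call. = FALSE)
  log(mean((E - O)^2)) + mean(log(E / O)^2)
}

#' Pooled log residual of the fitted model
#'
#' The root-mean-square of `ln(E_i / O_i)` over fitted events: the scale
#' parameter of the lognormal fatality-range distribution used by
#' [range_probability()].
#'
#' @inheritParams fit_objective
#' @return non-negative scalar.
#' @examples
#' log_residual(c(10 * exp(1), 10 / exp(1)), c(10, 10))  # 1
#' @export
log_residual <- function(E, O) {
  if (length(E) < 1 || length(E) != length(O))
    stop("E and O must be non-empty vectors of equal length", call. = FALSE)
  if (any(E <= 0) || any(O <= 0)) stop("E and O must be > 0", call. = FALSE)
  sqrt(mean(log(E / O)^2))
}

# vectorised objective over a (beta, theta) parameter sweep, in chunks so the
# grid x events matrix stays small
.objective_grid <- function(beta, theta, Pe, h, O, base = 10, clamp = TRUE,
                            chunk = 5e5) {
  G <- length(beta)
  N <- length(O)
  I <- intensity_classes()
  out <- numeric(G)
  per <- max(1L, as.integer(chunk / max(1L, N)))
  logO <- log(O)
  for (s in seq(1L, G, by = per)) {
    e <- min(G, s + per - 1L)
    idx <- s:e
    R <- base^(outer(beta[idx], rep(1, 7)) + outer(theta[idx], I))
    if (clamp) R[R > 1] <- 1
    Em <- R %*% t(Pe)
    Em <- sweep(Em, 2L, h, `*`)
    D <- sweep(Em, 2L, O, `-`)
    L <- sweep(log(Em), 2L, logO, `-`)
    out[idx] <- log(rowMeans(D * D)) + rowMeans(L * L)
  }
  out
}

#' Fit the fatality-ratio parameters for one region
#'
#' Minimises [fit_objective()] over the region's usable events by a coarse
#' deterministic grid search over `(beta, theta)` followed by derivative-free
#' (Nelder-Mead) local refinement.  Events with fewer recorded fatalities
#' than `min_fatalities` or with all-zero exposure are excluded (the log term
#' of the objective is undefined at `O = 0`); exclusions are reported in the
#' diagnostics.
#'
#' @param catalog catalog data frame (see [read_catalog()]).
#' @param hdi an [hdi_table()] covering all event years used.
#' @param region region code to fit.
#' @param beta_grid,theta_grid coarse search grids.
#' @param refine run Nelder-Mead refinement from the best grid node.
#' @param log_base,clamp fatality-ratio law settings, see [fatality_ratio()].
#' @param min_fatalities minimum recorded fatalities for an event to enter
#'   the fit (default 1).
#' @return list with elements `beta`, `theta` and `diagnostics` (final
#'   objective `epsilon`, number of events `n`, per-event `log_resid`
#'   `ln(E/O)`, fitted `E`, `within_order` fraction with
#'   `|log10(E/O)| <= 1`, `excluded` event ids, and a `degenerate` flag set
#'   when all exposure sits in a single intensity class so only
#'   `beta + theta * I0` is identified).
#' @export
fit_params <- function(catalog, hdi, region,
                       beta_grid = seq(-20, 0, by = 0.1),
                       theta_grid = seq(0, 3, by = 0.1),
                       refine = TRUE, log_base = 10, clamp = TRUE,
                       min_fatalities = 1) {
  ev <- catalog[catalog$region_code == region, , drop = FALSE]
  if (!nrow(ev))
    stop(sprintf("no catalog events for region '%s'", region), call. = FALSE)
  Pe <- catalog_exposure_matrix(ev)
  usable <- ev$O >= min_fatalities & rowSums(Pe) > 0
  excluded <- as.character(ev$id[!usable])
  ev <- ev[usable, , drop = FALSE]
  Pe <- Pe[usable, , drop = FALSE]
  if (nrow(ev) < 2)
    stop(sprintf("region '%s' has %d usable event(s); at least 2 are required",
                 region, nrow(ev)), call. = FALSE)
  hdi <- if (inherits(hdi, "hdi_table")) hdi else hdi_table(hdi)
  h <- vapply(ev$year, function(y) hdi_factor(hdi, y), numeric(1))
  O <- as.numeric(ev$O)

  grid <- expand.grid(beta = beta_grid, theta = theta_grid,
                      KEEP.OUT.ATTRS = FALSE)
  gobj <- .objective_grid(grid$beta, grid$theta, Pe, h, O, log_base, clamp)
  best <- which.min(gobj)
  par <- c(grid$beta[best], grid$theta[best])

  I <- intensity_classes()
  fn <- function(p) {
    r <- log_base^(p[1] + p[2] * I)
    if (clamp) r <- pmin(r, 1)
    E <- as.numeric(Pe %*% r) * h
    se <- mean((E - O)^2)
    # floor keeps the optimizer on finite values; exported fit_objective()
    # reports the true -Inf sentinel for exact fits
    log(max(se, 1e-300)) + mean(log(E / O)^2)
  }
  if (refine) {
    opt <- optim(par, fn, method = "Nelder-Mead",
                 control = list(maxit = 4000, reltol = 1e-14))
    if (opt$value <= fn(par)) par <- opt$par
  }
  beta <- par[1]; theta <- par[2]
  if (theta <= 0)
    warning(sprintf("fitted theta = %.3f <= 0 in region '%s': fatality ratio not increasing with intensity",
                    theta, region), call. = FALSE)
  r <- fatality_ratio(I, beta, theta, base = log_base, clamp = clamp)
  E <- as.numeric(Pe %*% r) * h
  lr <- log(E / O)
  classes_used <- which(colSums(Pe) > 0)
  degenerate <- length(classes_used) == 1L
  if (degenerate)
    warning(sprintf("region '%s': exposure confined to intensity class %d; only beta + theta*%d is identified",
                    region, I[classes_used], I[classes_used]), call. = FALSE)
  eps <- if (all(E == O)) -Inf else fit_objective(E, O)
  list(beta = beta, theta = theta,
       diagnostics = list(epsilon = eps, n = nrow(ev),
                          ids = as.character(ev$id), E = E, O = O,
                          log_resid = lr,
                          within_order = mean(abs(log10(E / O)) <= 1),
                          excluded = excluded, degenerate = degenerate,
                          classes_used = I[classes_used]))
}

#' Fit the regionally stratified fatality model
#'
#' Fits `(beta, theta)` independently for each region via [fit_params()] and
#' pools the log residual `zeta` (RMS of `ln(E/O)`) across all fitted events.
#' Per-region residual scales are also returned for users who prefer a
#' region-specific `zeta`.
#'
#' @param catalog catalog data frame with columns `id`, `region_code`,
#'   `year`, `O` (recorded fatalities) and `pe5`..`pe11`.
#' @param hdi an [hdi_table()] (or plain `year`/`hdi` data frame).
#' @param regions region codes to fit (default: all present in the catalog).
#' @param zeta_scope `"pooled"` (default: one `zeta` across regions, the
#'   published convention) or `"per_region"`.
#' @inheritParams fit_params
#' @return an object of class `fatality_model`: list with `coefficients`
#'   (regions x `(beta, theta)` matrix), `zeta`, `zeta_by_region`,
#'   `diagnostics` (per region, see [fit_params()]), `fitted`, `residuals`
#'   (named by event id), `hdi`, `settings` and `call`.
#' @seealso [predict.fatality_model()], [simulate.fatality_model()]
#' @export
fit_fatality_model <- function(catalog, hdi,
                               regions = sort(unique(catalog$region_code)),
                               beta_grid = seq(-20, 0, by = 0.1),
                               theta_grid = seq(0, 3, by = 0.1),
                               refine = TRUE, log_base = 10, clamp = TRUE,
                               min_fatalities = 1,
                               zeta_scope = c("pooled", "per_region")) {
  zeta_scope <- match.arg(zeta_scope)
  hdi <- if (inherits(hdi, "hdi_table")) hdi else hdi_table(hdi)
  fits <- lapply(regions, function(rg)
    fit_params(catalog, hdi, rg, beta_grid, theta_grid, refine,
               log_base, clamp, min_fatalities))
  names(fits) <- regions
  cf <- do.call(rbind, lapply(fits, function(f) c(beta = f$beta, theta = f$theta)))
  rownames(cf) <- regions
  lr_all <- unlist(lapply(fits, function(f) f$diagnostics$log_resid),
                   use.names = FALSE)
  zeta_pooled <- sqrt(mean(lr_all^2))
  zeta_region <- vapply(fits, function(f)
    sqrt(mean(f$diagnostics$log_resid^2)), numeric(1))
  fitted_E <- unlist(unname(lapply(fits, function(f)
    setNames(f$diagnostics$E, f$diagnostics$ids))))
  resid_lr <- unlist(unname(lapply(fits, function(f)
    setNames(f$diagnostics$log_resid, f$diagnostics$ids))))
  structure(list(
    coefficients = cf,
    zeta = if (zeta_scope == "pooled") zeta_pooled else zeta_region,
    zeta_pooled = zeta_pooled,
    zeta_by_region = zeta_region,
    zeta_scope = zeta_scope,
    diagnostics = lapply(fits, `[[`, "diagnostics"),
    fitted = fitted_E,
    residuals = resid_lr,
    nobs = sum(vapply(fits, function(f) f$diagnostics$n, numeric(1))),
    hdi = hdi,
    settings = list(log_base = log_base, clamp = clamp,
                    min_fatalities = min_fatalities,
                    beta_grid = range(beta_grid), theta_grid = range(theta_grid)),
    call = match.call()
  ), class = "fatality_model")
}
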