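# CSV / JSON interfaces: damaging-earthquake catalogs, HDI tables, fitted
# parameters, estimate reports.

#' Read a damaging-earthquake catalog
#'
#' Expected columns: `id`, `region_code`, `year`, `magnitude` (optional
#' metadata), `O` (recorded fatalities) and per-intensity exposure
#' `pe5`..`pe11` in persons.  Rows failing validation are reported by id.
#'
#' @param path CSV file path.
#' @return validated catalog data frame.
#' @export
read_catalog <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_catalog(df)
}

#' @rdname read_catalog
#' @param catalog catalog data frame.
#' @export
write_catalog <- function(catalog, path) {
  write.csv(catalog, path, row.names = FALSE)
  invisible(path)
}

#' Validate a catalog data frame
#'
#' @param df candidate catalog.
#' @return `df`, invisibly valid, or an error listing offending rows.
#' @export
validate_catalog <- function(df) {
  need <- c("id", "region_code", "year", "O", paste0("pe", 5:11))
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("catalog lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  Pe <- catalog_exposure_matrix(df)
  bad <- !is.finite(df$O) | df$O < 0 |
    apply(!is.finite(Pe) | Pe < 0, 1, any) |
    !df$region_code %in% names(region_labels())
  if (any(bad))
    stop("invalid catalog rows: ",
         paste(df$id[bad], collapse = ", "),
         " (negative/non-finite values or unknown region code)",
         call. = FALSE)
  df
}

#' Read an HDI table from CSV
#'
#' @param path CSV with columns `year`, `hdi`.
#' @return an [hdi_table()].
#' @export
read_hdi <- function(path) hdi_table(read.csv(path))

#' @rdname read_hdi
#' @param hdi an [hdi_table()] or `year`/`hdi` data frame.
#' @export
write_hdi <- function(hdi, path) {
  write.csv(as.data.frame(unclass(hdi))[c("year", "hdi")], path,
            row.names = FALSE)
  invisible(path)
}

#' Serialize fitted parameters to JSON
#'
#' Layout: `{"regions": {"a": {"beta": ..., "theta": ...}, ...},
#' "zeta": ..., "fit_meta": {...}}`.
#'
#' @param model fitted [fit_fatality_model()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_params_json <- function(model, path) {
  cf <- coef(model)
  regions <- lapply(rownames(cf), function(rg)
    list(beta = unname(cf[rg, "beta"]), theta = unname(cf[rg, "theta"])))
  names(regions) <- rownames(cf)
  meta <- list(n_events = model$nobs,
               zeta_by_region = as.list(model$zeta_by_region),
               within_order = lapply(model$diagnostics, `[[`, "within_order"),
               log_base = model$settings$log_base,
               clamp = model$settings$clamp)
  jsonlite::write_json(list(regions = regions, zeta = model$zeta_pooled,
                            fit_meta = meta),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read fitted parameters from JSON
#'
#' @param path JSON written by [write_params_json()].
#' @return parameter list usable as `params` in [estimate_fatalities()].
#' @export
read_params_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$regions)) stop("not a parameter file: ", path, call. = FALSE)
  # regions may simplify to a data-frame-like list; normalise
  regs <- lapply(p$regions, function(x) list(beta = x$beta, theta = x$theta))
  list(regions = regs, zeta = p$zeta,
       log_base = p$fit_meta$log_base %||% 10,
       clamp = p$fit_meta$clamp %||% TRUE)
}

#' Write a fatality-estimate report as JSON
#'
#' Layout: `{"expected": ..., "rounded": ..., "range_probs": {...},
#' "level": "IV", "inputs_digest": {...}}`.  No timestamps are written, so
#' identical inputs yield byte-identical reports.
#'
#' @param estimate a [fatality_estimate()].
#' @param path output path.
#' @param inputs_digest named list of input-file MD5 digests (optional).
#' @return `path`, invisibly.
#' @export
write_estimate_json <- function(estimate, path, inputs_digest = NULL) {
  jsonlite::write_json(list(
    expected = estimate$expected,
    rounded = estimate$rounded,
    range_probs = as.list(estimate$range_probs),
    level = estimate$level,
    zeta = estimate$zeta,
    inputs_digest = inputs_digest
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
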