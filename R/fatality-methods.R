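# S3 methods for the fitted fatality model.

#' @export
print.fatality_model <- function(x, ...) {
  cat("Regionally stratified empirical fatality model\n")
  cat(sprintf("  events fitted: %d in %d region(s)\n", x$nobs,
              nrow(x$coefficients)))
  cat("  coefficients (log r = beta + theta * I):\n")
  print(round(x$coefficients, 4))
  cat(sprintf("  log residual zeta (%s): %s\n", x$zeta_scope,
              paste(round(x$zeta, 4), collapse = ", ")))
  invisible(x)
}

#' @export
coef.fatality_model <- function(object, ...) object$coefficients

#' @export
fitted.fatality_model <- function(object, ...) object$fitted

#' Residuals of a fatality model
#'
#' @param object fitted [fit_fatality_model()] object.
#' @param type `"log"` for `ln(E/O)` (the residual entering `zeta`) or
#'   `"response"` for `E - O`.
#' @param ... unused.
#' @export
residuals.fatality_model <- function(object, type = c("log", "response"), ...) {
  type <- match.arg(type)
  if (type == "log") return(object$residuals)
  O <- unlist(unname(lapply(object$diagnostics,
                            function(d) setNames(d$O, d$ids))))
  object$fitted - O[names(object$fitted)]
}

#' @export
summary.fatality_model <- function(object, ...) {
  d <- object$diagnostics
  tab <- data.frame(
    region = names(d),
    n = vapply(d, function(x) x$n, numeric(1)),
    beta = object$coefficients[, "beta"],
    theta = object$coefficients[, "theta"],
    epsilon = vapply(d, function(x) x$epsilon, numeric(1)),
    zeta = object$zeta_by_region,
    within_order = vapply(d, function(x) x$within_order, numeric(1)),
    degenerate = vapply(d, function(x) x$degenerate, logical(1)),
    row.names = NULL
  )
  structure(list(table = tab, zeta_pooled = object$zeta_pooled,
                 nobs = object$nobs,
                 excluded = lapply(d, `[[`, "excluded")),
            class = "summary.fatality_model")
}

#' @export
print.summary.fatality_model <- function(x, ...) {
  cat("Fatality model fit summary\n")
  tab <- x$table
  tab$within_order <- sprintf("%.0f%%", 100 * tab$within_order)
  print(tab, digits = 4, row.names = FALSE)
  cat(sprintf("pooled zeta: %.4f over %d events\n", x$zeta_pooled, x$nobs))
  nex <- sum(lengths(x$excluded))
  if (nex) cat(sprintf("excluded (O < minimum or zero exposure): %d event(s)\n", nex))
  invisible(x)
}

#' Predict fatalities for new events
#'
#' @param object fitted [fit_fatality_model()] object.
#' @param newdata data frame with columns `region_code`, `year` and
#'   `pe5`..`pe11` (one row per event).
#' @param type `"expected"` returns the numeric expectations; `"estimate"`
#'   returns a list of [fatality_estimate()] objects including range
#'   probabilities and response level.
#' @param ... unused.
#' @return numeric vector or list of `fatality_estimate`s.
#' @export
predict.fatality_model <- function(object, newdata,
                                   type = c("expected", "estimate"), ...) {
  type <- match.arg(type)
  Pe <- catalog_exposure_matrix(newdata)
  E <- vapply(seq_len(nrow(newdata)), function(i)
    estimate_fatalities(Pe[i, ], newdata$region_code[i], newdata$year[i],
                        object, object$hdi), numeric(1))
  if (!is.null(newdata$id)) names(E) <- as.character(newdata$id)
  if (type == "expected") return(E)
  zeta <- if (length(object$zeta) > 1)
    object$zeta[as.character(newdata$region_code)] else
      rep(object$zeta, length(E))
  lapply(seq_along(E), function(i) fatality_estimate(E[i], zeta[i]))
}

#' Simulate recorded fatality counts from the fitted model
#'
#' Draws `O* = max(1, round(E * exp(zeta * z)))`, `z ~ N(0,1)`, for each
#' event in `newdata` (default: the training events) — the same
#' multiplicative lognormal noise model assumed by the range probabilities.
#'
#' @param object fitted [fit_fatality_model()] object.
#' @param nsim number of simulated catalogs.
#' @param seed optional integer seed, handled as in [stats::simulate()].
#' @param newdata events to simulate for (see [predict.fatality_model()]).
#' @param ... unused.
#' @return data frame with one column per simulation.
#' @export
simulate.fatality_model <- function(object, nsim = 1, seed = NULL,
                                    newdata = NULL, ...) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv())) runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  E <- if (is.null(newdata)) object$fitted else predict(object, newdata)
  zeta <- object$zeta_pooled
  out <- as.data.frame(lapply(seq_len(nsim), function(s)
    pmax(1, round_half_up(E * exp(zeta * rnorm(length(E)))))))
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- names(E)
  out
}

#' Plot fitted fatality-ratio curves
#'
#' Draws `r(I) = base^(beta + theta I)` per region over the damaging
#' intensity range on a log scale.
#'
#' @param x fitted [fit_fatality_model()] object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.fatality_model <- function(x, ...) {
  I <- intensity_classes()
  cf <- x$coefficients
  r <- sapply(rownames(cf), function(rg)
    fatality_ratio(I, cf[rg, "beta"], cf[rg, "theta"],
                   base = x$settings$log_base, clamp = x$settings$clamp))
  graphics::matplot(I, r, type = "b", log = "y", pch = 16, lty = 1,
                    xlab = "intensity class", ylab = "fatality ratio r(I)",
                    ...)
  legend("topleft", legend = rownames(cf), col = seq_len(nrow(cf)),
         pch = 16, lty = 1, bty = "n")
  invisible(x)
}
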