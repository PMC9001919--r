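#' Fit the bio-logger-to-cloacal calibration offset
#'
#' The dorsal skin loggers read slightly cooler than cloacal (core)
#' temperature. The correction is additive only — the published comparison
#' reports a mean difference, not a regression slope — so the fit is the mean
#' of the paired differences, its standard error, and the Pearson correlation
#' of the two columns.
#'
#' @param pairs Two-column data frame or matrix of paired readings:
#'   `logger_c` then `cloacal_c`, degrees C.
#' @return A `calibration_fit` list: `n_pairs`, `mean_offset`
#'   (cloacal - logger), `se_offset`, `pearson_r`.
#' @export
#' @examples
#' fit_offset(data.frame(logger_c = c(20, 30), cloacal_c = c(21.32, 31.32)))
fit_offset <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (ncol(pairs) < 2L) stop("pairs needs two columns: logger_c, cloacal_c")
  logger <- as.numeric(pairs[[1L]])
  cloacal <- as.numeric(pairs[[2L]])
  if (length(logger) < 2L) stop("need at least 2 calibration pairs")
  if (!all(is.finite(logger)) || !all(is.finite(cloacal))) {
    stop("non-finite calibration reading")
  }
  if (sd(logger) == 0) stop("zero variance in the logger column: Pearson r undefined")
  if (sd(cloacal) == 0) stop("zero variance in the cloacal column: Pearson r undefined")
  d <- cloacal - logger
  structure(
    list(
      n_pairs = length(d),
      mean_offset = mean(d),
      se_offset = sd(d) / sqrt(length(d)),
      pearson_r = cor(logger, cloacal)
    ),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "<calibration_fit> n=%d pairs: cloacal - logger = %.3f C (SE %.3f), Pearson r = %.3f\n",
    x$n_pairs, x$mean_offset, x$se_offset, x$pearson_r
  ))
  invisible(x)
}

#' Apply a calibration offset to a trace
#'
#' Shifts every temperature by `+mean_offset` (logger to cloacal scale) and
#' records the correction in the trace. Annotation thresholds are NOT
#' auto-shifted: if you annotate a corrected trace against the same physical
#' ambient boundary, shift the section threshold by the same amount.
#' Hysteresis detection itself is translation-invariant.
#'
#' @param trace A [therm_trace].
#' @param fit A `calibration_fit` from [fit_offset].
#' @return A corrected [therm_trace] with a `calibration_offset_c` attribute.
#' @export
apply_offset <- function(trace, fit) {
  stopifnot(inherits(trace, "therm_trace"), inherits(fit, "calibration_fit"))
  out <- trace
  out$temp <- trace$temp + fit$mean_offset
  attr(out, "calibration_offset_c") <- fit$mean_offset
  out
}
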