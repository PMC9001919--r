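#' Reference set-point range
#'
#' The band of temperatures an accurately thermoregulating animal is expected
#' to occupy — here, the cohort-level thermal passivity range derived from a
#' designated baseline (no-wind) treatment, used as the reference for the
#' accuracy index db.
#'
#' @param lower,upper Bounds in degrees C, `upper >= lower`.
#' @return A `reference_range` list.
#' @export
reference_range <- function(lower, upper) {
  stopifnot(is.numeric(lower), is.numeric(upper), is.finite(lower),
            is.finite(upper))
  if (upper < lower) stop("upper bound must be >= lower bound")
  structure(list(lower = lower, upper = upper), class = "reference_range")
}

#' Accuracy of thermoregulation (db)
#'
#' Mean deviation of all temperature samples from a reference set-point
#' range: a sample inside the range contributes zero; a sample outside
#' contributes its distance to the nearest bound. Lower db means more
#' accurate thermoregulation. With `method = "midpoint"` the deviation is
#' instead the absolute distance to the range midpoint (an alternative
#' reading of "deviation from the mean range"; off by default).
#'
#' @param temps Numeric vector of temperatures (degrees C), all sections.
#' @param ref A [reference_range].
#' @param method `"range"` (default, deviation-from-range) or `"midpoint"`.
#' @return db in degrees C (non-negative scalar).
#' @export
#' @examples
#' compute_db(c(30, 32, 34), reference_range(29.1, 34.7))  # 0
compute_db <- function(temps, ref, method = c("range", "midpoint")) {
  method <- match.arg(method)
  stopifnot(inherits(ref, "reference_range"))
  temps <- as.numeric(temps)
  if (length(temps) == 0L) stop("db needs at least one sample")
  if (!all(is.finite(temps))) stop("non-finite temperature in db input")
  dev <- switch(method,
    range = pmax(ref$lower - temps, temps - ref$upper, 0),
    midpoint = abs(temps - (ref$lower + ref$upper) / 2)
  )
  mean(dev)
}

#' Summarize one annotated trace
#'
#' Computes the seven thermoregulation parameters plus db for one trace:
#' mean skin temperature over the whole test, means of the upper and lower
#' set-points (absent if a kind never occurred), the thermal passivity range
#' TPR = mean upper - mean lower, the global maximum T_max, the percentage of
#' test time spent thermoregulating, the shuttle count, and db against the
#' supplied reference range. A plausibility flag (not an error) is raised
#' when T_max reaches the ceiling, the signature of logger battery drift
#' near the species' critical thermal maximum; exclusion is the caller's
#' decision.
#'
#' @param at A `therm_annotation` from [annotate].
#' @param ref A [reference_range] for db.
#' @param plausibility_ceiling Degrees C; default 41.
#' @return A `therm_summary` list. Absent set-point means are `NULL`
#'   (rendered as NA by [summaries_to_df]), never 0.
#' @export
summarize_trace <- function(at, ref, plausibility_ceiling = 41) {
  stopifnot(inherits(at, "therm_annotation"), inherits(ref, "reference_range"))
  tr <- at$trace
  ev <- at$events
  upper <- ev$temp[ev$kind == "upper"]
  lower <- ev$temp[ev$kind == "lower"]
  mean_upper <- if (length(upper) > 0L) mean(upper) else NULL
  mean_lower <- if (length(lower) > 0L) mean(lower) else NULL
  tpr <- if (!is.null(mean_upper) && !is.null(mean_lower)) {
    mean_upper - mean_lower
  } else {
    NULL
  }
  t_max <- max(tr$temp)
  structure(
    list(
      animal_id = tr$animal_id,
      treatment = tr$treatment,
      mean_tsk = mean(tr$temp),
      mean_upper = mean_upper,
      mean_lower = mean_lower,
      tpr = tpr,
      t_max = t_max,
      pct_time_thermoregulating =
        100 * sum(at$labels == "thermoregulating") / length(tr$temp),
      n_shuttles = at$n_shuttles,
      db = compute_db(tr$temp, ref),
      is_thermoregulator = at$is_thermoregulator,
      n_bouts = nrow(at$bouts),
      plausibility_warning = t_max >= plausibility_ceiling
    ),
    class = "therm_summary"
  )
}

#' @export
print.therm_summary <- function(x, ...) {
  fmt <- function(v) if (is.null(v)) "absent" else sprintf("%.2f", v)
  cat(sprintf(
    paste0(
      "<therm_summary> animal %s, treatment %s m/s (%s)\n",
      "  mean T_sk %.2f C | T_max %.2f C | upper %s | lower %s | TPR %s C\n",
      "  %.1f%% time thermoregulating | %d shuttle(s) | %d bout(s) | db %.2f C%s\n"
    ),
    x$animal_id, x$treatment,
    if (x$is_thermoregulator) "thermoregulator" else "non-thermoregulator",
    x$mean_tsk, x$t_max, fmt(x$mean_upper), fmt(x$mean_lower), fmt(x$tpr),
    x$pct_time_thermoregulating, x$n_shuttles, x$n_bouts, x$db,
    if (x$plausibility_warning) " [T_max plausibility warning]" else ""
  ))
  invisible(x)
}

#' Derive the reference set-point range from baseline summaries
#'
#' Pools the per-trace set-point means of the thermoregulators in a baseline
#' treatment: the reference lower bound is the mean of their mean lower
#' set-points, the upper bound the mean of their mean upper set-points.
#' Non-thermoregulators and traces lacking either set-point kind are
#' excluded.
#'
#' @param summaries List of `therm_summary` objects (typically the no-wind
#'   treatment).
#' @return A [reference_range].
#' @export
derive_reference_range <- function(summaries) {
  eligible <- Filter(function(s) {
    inherits(s, "therm_summary") && s$is_thermoregulator &&
      !is.null(s$mean_upper) && !is.null(s$mean_lower)
  }, summaries)
  if (length(eligible) == 0L) {
    stop("no eligible summaries: need >= 1 thermoregulator with both set-point means")
  }
  reference_range(
    lower = mean(vapply(eligible, function(s) s$mean_lower, numeric(1))),
    upper = mean(vapply(eligible, function(s) s$mean_upper, numeric(1)))
  )
}
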