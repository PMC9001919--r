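#' Construct a skin-temperature trace
#'
#' A trace is one uniformly sampled skin-temperature (`T_sk`) time series for
#' one animal in one test, together with the metadata needed to interpret it:
#' sampling interval, logger quantization step, and the ambient reference
#' temperature (`T_a`) that separates thermoregulating from
#' non-thermoregulating sections.
#'
#' @param temp Numeric vector of temperatures (degrees C), one per sample.
#' @param dt Sampling interval in seconds (default 2, the logger setting).
#' @param time Optional vector of sample times in seconds from test start;
#'   defaults to `(0, dt, 2*dt, ...)`. Must be uniformly spaced by `dt`.
#' @param animal_id Animal identifier (character scalar).
#' @param treatment Treatment label; by convention the windspeed in m/s.
#' @param resolution Logger quantization step in degrees C (default 0.0625).
#' @param ta_ref Ambient reference temperature in degrees C (default 18).
#'
#' @return An object of class `therm_trace`: a list with fields `animal_id`,
#'   `treatment`, `time`, `temp`, `dt`, `resolution`, `ta_ref`.
#' @export
#' @examples
#' tr <- therm_trace(c(18, 18.5, 19), dt = 2)
#' length(tr$temp)
therm_trace <- function(temp, dt = 2, time = NULL,
                        animal_id = "unknown", treatment = "0",
                        resolution = 0.0625, ta_ref = 18) {
  temp <- as.numeric(temp)
  if (length(temp) < 2L) {
    stop("a trace needs at least 2 samples, got ", length(temp))
  }
  if (!all(is.finite(temp))) {
    stop("non-finite temperature at row ", which(!is.finite(temp))[1L])
  }
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("dt must be a single positive number of seconds")
  }
  if (!is.numeric(resolution) || resolution <= 0) {
    stop("resolution must be > 0")
  }
  if (is.null(time)) {
    time <- (seq_along(temp) - 1) * dt
  } else {
    time <- as.numeric(time)
    if (length(time) != length(temp)) {
      stop("time and temp must have equal length")
    }
    check_uniform_time(time, dt)
  }
  structure(
    list(
      animal_id = as.character(animal_id),
      treatment = as.character(treatment),
      time = time,
      temp = temp,
      dt = dt,
      resolution = resolution,
      ta_ref = ta_ref
    ),
    class = "therm_trace"
  )
}

# Uniform-sampling check shared by the constructor and the reader.
# Tolerance is generous relative to the 1e-9 s invariant because times travel
# through decimal text; 1e-6 s is far below any plausible logger interval.
check_uniform_time <- function(time, dt, tol = 1e-6) {
  d <- diff(time)
  bad <- which(abs(d - dt) > tol)
  if (length(bad) > 0L) {
    stop(sprintf(
      "non-uniform sampling: interval %.9g s between rows %d and %d (expected dt = %.9g s)",
      d[bad[1L]], bad[1L], bad[1L] + 1L, dt
    ))
  }
  invisible(TRUE)
}

#' @export
print.therm_trace <- function(x, ...) {
  cat(sprintf(
    "<therm_trace> animal %s, treatment %s m/s: %d samples @ %g s (%.1f min), T %.2f-%.2f C\n",
    x$animal_id, x$treatment, length(x$temp), x$dt,
    length(x$temp) * x$dt / 60, min(x$temp), max(x$temp)
  ))
  invisible(x)
}

#' @export
length.therm_trace <- function(x) length(x$temp)

meta_path_for <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".meta.json")
}

#' Read a temperature trace from CSV
#'
#' Expects a comma-separated file with a header naming columns `time_s`
#' (seconds from test start) and `temp_c` (degrees C). Metadata (animal id,
#' treatment, resolution, ambient reference) is resolved, in order of
#' precedence, from the `metadata` argument, then a JSON sidecar file
#' `<stem>.meta.json` if present, then package defaults. The sampling
#' interval is inferred from the time column, checked for uniformity, and —
#' when a `dt` is also supplied via metadata — checked for agreement.
#'
#' @param path Path to the trace CSV.
#' @param metadata Optional named list of overrides: any of `animal_id`,
#'   `treatment`, `dt`, `resolution`, `ta_ref`.
#' @return A [therm_trace] object.
#' @export
read_trace <- function(path, metadata = list()) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, colClasses = NA, stringsAsFactors = FALSE)
  for (col in c("time_s", "temp_c")) {
    if (!col %in% names(df)) {
      stop("missing required column '", col, "' in ", path)
    }
  }
  time <- suppressWarnings(as.numeric(df$time_s))
  temp <- suppressWarnings(as.numeric(df$temp_c))
  if (anyNA(time)) stop("non-numeric time value at row ", which(is.na(time))[1L])
  if (anyNA(temp)) stop("non-numeric temperature value at row ", which(is.na(temp))[1L])

  meta <- list()
  mp <- meta_path_for(path)
  if (file.exists(mp)) {
    meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  }
  meta[names(metadata)] <- metadata

  dt_inferred <- if (length(time) >= 2L) time[2L] - time[1L] else NA_real_
  if (!is.finite(dt_inferred) || dt_inferred <= 0) {
    stop("cannot infer a positive sampling interval from the time column")
  }
  if (!is.null(meta$dt) && abs(meta$dt - dt_inferred) > 1e-6) {
    stop(sprintf(
      "metadata dt (%g s) disagrees with the time column (%g s)",
      meta$dt, dt_inferred
    ))
  }
  check_uniform_time(time, dt_inferred)

  therm_trace(
    temp = temp, dt = dt_inferred, time = time,
    animal_id = meta$animal_id %||% "unknown",
    treatment = meta$treatment %||% "0",
    resolution = meta$resolution %||% 0.0625,
    ta_ref = meta$ta_ref %||% 18
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a temperature trace to CSV (plus JSON metadata sidecar)
#'
#' Writes columns `time_s,temp_c` and a sidecar `<stem>.meta.json` carrying
#' the trace metadata so that [read_trace] reproduces the object exactly.
#'
#' @param trace A [therm_trace].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "therm_trace"))
  df <- data.frame(time_s = trace$time, temp_c = trace$temp)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- trace[c("animal_id", "treatment", "dt", "resolution", "ta_ref")]
  jsonlite::write_json(meta, meta_path_for(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an annotated trace
#'
#' Writes the per-sample table `time_s,temp_c,label,event` (the `event` column
#' is `upper`/`lower` on the set-point samples and blank elsewhere) plus a
#' structured JSON sidecar `<stem>.annotation.json` holding the event list,
#' bout ranges, shuttle count and classification. All indices in the files
#' are 0-based; bouts are half-open `[start, end)`.
#'
#' @param at A `therm_annotation` as returned by [annotate].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_annotated <- function(at, path) {
  stopifnot(inherits(at, "therm_annotation"))
  tr <- at$trace
  event_col <- rep("", length(tr$temp))
  if (nrow(at$events) > 0L) {
    event_col[at$events$index + 1L] <- at$events$kind
  }
  df <- data.frame(
    time_s = tr$time, temp_c = tr$temp,
    label = at$labels, event = event_col
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- list(
    meta = tr[c("animal_id", "treatment", "dt", "resolution", "ta_ref")],
    events = if (nrow(at$events) > 0L) at$events else list(),
    bouts = if (nrow(at$bouts) > 0L) at$bouts else list(),
    n_shuttles = at$n_shuttles,
    is_thermoregulator = at$is_thermoregulator
  )
  jsonlite::write_json(side, annotation_path_for(path),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

annotation_path_for <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".annotation.json")
}

#' Read an annotated trace written by [write_annotated]
#'
#' @param path Path to the annotated CSV.
#' @return A `therm_annotation` object.
#' @export
read_annotated <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c("numeric", "numeric", "character", "character"),
                 na.strings = character(0))
  side <- jsonlite::read_json(annotation_path_for(path), simplifyVector = TRUE)
  tr <- therm_trace(
    temp = df$temp_c, dt = side$meta$dt, time = df$time_s,
    animal_id = side$meta$animal_id, treatment = side$meta$treatment,
    resolution = side$meta$resolution, ta_ref = side$meta$ta_ref
  )
  events <- empty_events()
  if (length(side$events) > 0L && NROW(side$events) > 0L) {
    events <- data.frame(
      kind = as.character(side$events$kind),
      index = as.integer(side$events$index),
      temp = as.numeric(side$events$temp),
      stringsAsFactors = FALSE
    )
  }
  bouts <- empty_bouts()
  if (length(side$bouts) > 0L && NROW(side$bouts) > 0L) {
    bouts <- data.frame(
      start = as.integer(side$bouts$start),
      end = as.integer(side$bouts$end)
    )
  }
  new_annotation(
    trace = tr, labels = df$label, events = events, bouts = bouts,
    n_shuttles = as.integer(side$n_shuttles),
    is_thermoregulator = as.logical(side$is_thermoregulator)
  )
}

empty_events <- function() {
  data.frame(kind = character(0), index = integer(0), temp = numeric(0),
             stringsAsFactors = FALSE)
}

empty_bouts <- function() {
  data.frame(start = integer(0), end = integer(0))
}

new_annotation <- function(trace, labels, events, bouts,
                           n_shuttles, is_thermoregulator) {
  structure(
    list(
      trace = trace, labels = labels, events = events, bouts = bouts,
      n_shuttles = n_shuttles, is_thermoregulator = is_thermoregulator
    ),
    class = "therm_annotation"
  )
}

#' @export
print.therm_annotation <- function(x, ...) {
  cat(sprintf(
    "<therm_annotation> %d samples, %d bout(s), %d set-point event(s), %s\n",
    length(x$trace$temp), nrow(x$bouts), nrow(x$events),
    if (x$is_thermoregulator) "thermoregulator" else "non-thermoregulator"
  ))
  invisible(x)
}

#' Collect per-trace summaries into a data frame
#'
#' @param summaries A list of `therm_summary` objects (see [summarize_trace]).
#' @return A data frame, one row per summary. Absent set-point means are NA.
#' @export
summaries_to_df <- function(summaries) {
  stopifnot(length(summaries) > 0L)
  rows <- lapply(summaries, function(s) {
    stopifnot(inherits(s, "therm_summary"))
    data.frame(
      animal_id = s$animal_id, treatment = s$treatment,
      mean_tsk = s$mean_tsk,
      mean_upper = s$mean_upper %||% NA_real_,
      mean_lower = s$mean_lower %||% NA_real_,
      tpr = s$tpr %||% NA_real_,
      t_max = s$t_max,
      pct_time_thermoregulating = s$pct_time_thermoregulating,
      n_shuttles = s$n_shuttles,
      db = s$db,
      is_thermoregulator = s$is_thermoregulator,
      n_bouts = s$n_bouts,
      plausibility_warning = s$plausibility_warning,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
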