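#' Annotator configuration
#'
#' @param hysteresis Reversal sensitivity in degrees C: a direction change is
#'   only recognised once the temperature has moved at least this far back
#'   from the running extreme of the current warming/cooling segment
#'   (default 2, the published labelling sensitivity).
#' @param section_threshold Temperature separating thermoregulating from
#'   non-thermoregulating samples, in degrees C. `NULL` (default) means "use
#'   the trace's ambient reference `ta_ref`", i.e. 18 C for the default setup.
#' @param min_section_samples Minimum length (in samples) of a
#'   thermoregulating run; shorter runs are relabelled non-thermoregulating.
#'   Default 1, i.e. no smoothing.
#' @return An `annotator_config` list.
#' @export
annotator_config <- function(hysteresis = 2.0, section_threshold = NULL,
                             min_section_samples = 1L) {
  if (!is.numeric(hysteresis) || hysteresis <= 0) {
    stop("hysteresis must be > 0")
  }
  if (min_section_samples < 1L) stop("min_section_samples must be >= 1")
  structure(
    list(
      hysteresis = hysteresis,
      section_threshold = section_threshold,
      min_section_samples = as.integer(min_section_samples)
    ),
    class = "annotator_config"
  )
}

resolve_threshold <- function(trace, cfg) {
  cfg$section_threshold %||% trace$ta_ref
}

#' Label thermoregulating sections and find bouts
#'
#' A sample is thermoregulating iff its temperature is strictly above the
#' section threshold (the animal is in the heated zone, above ambient);
#' otherwise it is non-thermoregulating. Contiguous thermoregulating runs
#' shorter than `min_section_samples` are relabelled; a bout is a maximal
#' remaining thermoregulating run.
#'
#' @param trace A [therm_trace].
#' @param cfg An [annotator_config].
#' @return A list with `labels` (character vector, `"thermoregulating"` /
#'   `"non_thermoregulating"`) and `bouts` (data frame of 0-based half-open
#'   `[start, end)` sample ranges, time-ordered).
#' @export
label_sections <- function(trace, cfg = annotator_config()) {
  stopifnot(inherits(trace, "therm_trace"))
  thr <- resolve_threshold(trace, cfg)
  hot <- trace$temp > thr
  if (cfg$min_section_samples > 1L && any(hot)) {
    r <- rle(hot)
    drop <- r$values & r$lengths < cfg$min_section_samples
    r$values[drop] <- FALSE
    hot <- inverse.rle(r)
  }
  labels <- ifelse(hot, "thermoregulating", "non_thermoregulating")
  bouts <- empty_bouts()
  if (any(hot)) {
    r <- rle(hot)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    bouts <- data.frame(start = starts[keep] - 1L, end = ends[keep])
  }
  list(labels = labels, bouts = bouts)
}

#' Detect set-point events within one bout
#'
#' Single forward pass over the bout with a three-state machine
#' (unknown/warming/cooling). The running extreme of the current segment is
#' tracked with first-occurrence tie-breaking. From the unknown state the
#' direction becomes warming once the temperature is at least `hysteresis`
#' above the running minimum, or cooling once at least `hysteresis` below the
#' running maximum; this initial determination is not counted as a direction
#' change. While warming, a drop of at least `hysteresis` below the running
#' maximum confirms a reversal: an `upper` set-point event is emitted at the
#' running-maximum sample, the state flips to cooling, and the running
#' minimum restarts at the current sample (symmetrically for cooling). A
#' trailing rise or fall that never reverses by `hysteresis` inside the bout
#' produces no event. Detector state never carries across bouts.
#'
#' @param trace A [therm_trace].
#' @param bout Length-2 integer vector: 0-based half-open `[start, end)`.
#' @param cfg An [annotator_config].
#' @return A list with `events` (data frame: `kind` in upper/lower, `index`
#'   0-based, `temp`) and `n_direction_changes` (= number of events).
#' @export
detect_setpoints <- function(trace, bout, cfg = annotator_config()) {
  stopifnot(inherits(trace, "therm_trace"))
  start <- as.integer(bout[1L]) + 1L   # to 1-based
  end <- as.integer(bout[2L])          # inclusive 1-based end
  stopifnot(start >= 1L, end <= length(trace$temp), start <= end)
  x <- trace$temp
  h <- cfg$hysteresis

  state <- "unknown"
  run_max <- x[start]; i_max <- start
  run_min <- x[start]; i_min <- start
  kinds <- character(0); idx <- integer(0); temps <- numeric(0)

  for (i in seq.int(start, end)) {
    xi <- x[i]
    if (xi > run_max) { run_max <- xi; i_max <- i }
    if (xi < run_min) { run_min <- xi; i_min <- i }
    if (state == "unknown") {
      if (xi >= run_min + h) {
        state <- "warming"
      } else if (xi <= run_max - h) {
        state <- "cooling"
      }
    } else if (state == "warming") {
      if (xi <= run_max - h) {
        kinds <- c(kinds, "upper"); idx <- c(idx, i_max)
        temps <- c(temps, run_max)
        state <- "cooling"
        run_min <- xi; i_min <- i
      }
    } else { # cooling
      if (xi >= run_min + h) {
        kinds <- c(kinds, "lower"); idx <- c(idx, i_min)
        temps <- c(temps, run_min)
        state <- "warming"
        run_max <- xi; i_max <- i
      }
    }
  }

  events <- if (length(kinds) > 0L) {
    data.frame(kind = kinds, index = idx - 1L, temp = temps,
               stringsAsFactors = FALSE)
  } else {
    empty_events()
  }
  list(events = events, n_direction_changes = length(kinds))
}

#' Classify a trace as thermoregulator or not
#'
#' An animal is a thermoregulator iff it exhibited strictly more than two
#' confirmed changes in the direction of temperature change (shuttles) while
#' in the heated zone, totalled over all bouts of the trace.
#'
#' @param n_direction_changes_total Total confirmed direction changes.
#' @return Logical scalar.
#' @export
classify_thermoregulator <- function(n_direction_changes_total) {
  stopifnot(is.numeric(n_direction_changes_total),
            n_direction_changes_total >= 0)
  n_direction_changes_total > 2
}

#' Annotate a trace
#'
#' Composition of [label_sections] and per-bout [detect_setpoints]: labels
#' every sample, segments the bouts, runs the hysteresis detector in each
#' bout with freshly reset state, concatenates the events in time order,
#' counts shuttles and attaches the thermoregulator classification.
#'
#' @param trace A [therm_trace].
#' @param cfg An [annotator_config].
#' @return A `therm_annotation`: list with `trace`, `labels`, `events`,
#'   `bouts`, `n_shuttles`, `is_thermoregulator`.
#' @export
annotate <- function(trace, cfg = annotator_config()) {
  sec <- label_sections(trace, cfg)
  events <- empty_events()
  total <- 0L
  if (nrow(sec$bouts) > 0L) {
    per_bout <- lapply(seq_len(nrow(sec$bouts)), function(b) {
      detect_setpoints(trace, c(sec$bouts$start[b], sec$bouts$end[b]), cfg)
    })
    events <- do.call(rbind, c(list(empty_events()),
                               lapply(per_bout, `[[`, "events")))
    total <- sum(vapply(per_bout, `[[`, integer(1), "n_direction_changes"))
  }
  new_annotation(
    trace = trace, labels = sec$labels, events = events, bouts = sec$bouts,
    n_shuttles = as.integer(total),
    is_thermoregulator = classify_thermoregulator(total)
  )
}
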