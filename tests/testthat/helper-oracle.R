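# Independent brute-force reference for hysteresis set-point detection.
#
# Deliberately NOT a single-pass state machine: it works segment by segment,
# recomputing the running extreme of the current segment from scratch at
# every sample (quadratic time), and locating each extremum with
# which.max/which.min (first occurrence). Used to cross-check the package's
# O(n) detector on random walks, including ties and plateaus.
oracle_detect <- function(x, h) {
  n <- length(x)
  kinds <- character(0); idx <- integer(0); temps <- numeric(0)
  seg <- 1L    # current segment start (extremum search window start)
  dir <- 0L    # 0 unknown, +1 warming, -1 cooling
  j <- 1L
  repeat {
    advanced <- FALSE
    if (dir == 0L) {
      for (k in j:n) {
        if (x[k] >= min(x[seg:k]) + h) {
          dir <- 1L; j <- k; advanced <- TRUE; break
        }
        if (x[k] <= max(x[seg:k]) - h) {
          dir <- -1L; j <- k; advanced <- TRUE; break
        }
      }
    } else if (dir == 1L) {
      for (k in j:n) {
        M <- max(x[seg:k])
        if (x[k] <= M - h) {
          pk <- seg - 1L + which.max(x[seg:k])
          kinds <- c(kinds, "upper"); idx <- c(idx, pk); temps <- c(temps, M)
          seg <- k; j <- k; dir <- -1L; advanced <- TRUE; break
        }
      }
    } else {
      for (k in j:n) {
        m <- min(x[seg:k])
        if (x[k] >= m + h) {
          pk <- seg - 1L + which.min(x[seg:k])
          kinds <- c(kinds, "lower"); idx <- c(idx, pk); temps <- c(temps, m)
          seg <- k; j <- k; dir <- 1L; advanced <- TRUE; break
        }
      }
    }
    if (!advanced) break
  }
  data.frame(kind = kinds, index = idx - 1L, temp = temps,
             stringsAsFactors = FALSE)
}

# Run the package detector over a bare numeric vector as a single bout.
detect_on_vector <- function(x, h = 2) {
  tr <- therm_trace(x, dt = 2, ta_ref = -Inf)
  detect_setpoints(tr, c(0L, length(x)), annotator_config(hysteresis = h))
}

# Quantized random walk resembling a logger trace fragment; plateaus and
# exact ties are common at this step/resolution ratio.
random_walk <- function(n = 80, step_sd = 0.4, start = 25,
                        resolution = 0.0625) {
  round((start + cumsum(rnorm(n, 0, step_sd))) / resolution) * resolution
}
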