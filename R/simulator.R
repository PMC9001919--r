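#' Simulation configuration for one synthetic trace
#'
#' The generative model is first-order Newtonian heat exchange with a
#' behaviour-dependent equilibrium: the latent (noise-free) body temperature
#' relaxes toward the basking-spot equilibrium `t_hot` at rate `k_warm` while
#' basking, and toward ambient `ta` at rate `k_cool` while cooling,
#' `T'[t+1] = T_env + (T'[t] - T_env) * exp(-k * dt)`. A thermoregulator
#' starts at ambient, basks until the latent temperature reaches its upper
#' set-point, cools until it reaches its lower set-point, and repeats; at
#' each lower set-point it may instead leave the heated zone for a rest at
#' ambient (probability `p_rest`, duration `rest_s`), producing the
#' multi-bout traces seen in real tests; and once a behavioural quit time
#' has passed (fraction `quit_frac` of the test, jittered per animal), it
#' leaves for good at the next lower set-point — thermoregulation need not
#' fill the whole test. A non-thermoregulator basks until it reaches its
#' upper set-point once (or until `exit_after_s` elapses) and then stays at
#' ambient. The observed series is the latent series plus
#' Gaussian measurement noise, quantized to the logger resolution.
#'
#' Defaults mirror the experimental setup they emulate: 90 min at 2 s
#' sampling, 0.0625 C logger resolution, 18 C ambient, 35 C basking-tile
#' maximum, and the no-wind set-point range 29.1-34.7 C. Set-points are
#' re-drawn with jitter `setpoint_jitter_sd` after every switch (behavioural
#' spread); the controller always switches on the latent temperature, so
#' behavioural and measurement noise stay separable.
#'
#' @param duration_s Test duration, seconds (default 5400 = 90 min).
#' @param dt_s Sampling interval, seconds (default 2).
#' @param resolution Logger quantization step, degrees C (default 0.0625).
#' @param ta Ambient temperature, degrees C (default 18).
#' @param t_hot Basking equilibrium temperature, degrees C (default 35).
#' @param true_upper,true_lower Nominal upper/lower set-points, degrees C
#'   (defaults 34.7 and 29.1).
#' @param k_warm,k_cool Newtonian rate constants, 1/s (defaults 0.02 and
#'   0.003: a few-gram animal heats under the lamp with a time constant of
#'   about a minute and cools passively several times slower while still in
#'   the heated zone, where the substrate gradient keeps it above ambient).
#' @param k_rest Rate constant, 1/s, while out of the heated zone (rests and
#'   permanent exits): full contact with ambient substrate cools the animal
#'   about as fast as the lamp warms it (default 0.02).
#' @param noise_sd Measurement noise SD, degrees C (default 0.1).
#' @param setpoint_jitter_sd Behavioural SD of the per-shuttle set-point
#'   draw, degrees C (default 0.3; 0 disables jitter).
#' @param mode `"thermoregulator"` or `"non_thermoregulator"`.
#' @param exit_after_s Non-thermoregulator only: leave the heated zone after
#'   this long even if the upper set-point was never reached (default 1800).
#' @param p_rest Thermoregulator only: probability, at each lower set-point,
#'   of leaving the heated zone for a rest (default 0.04).
#' @param rest_s Rest duration at ambient, seconds (default 360).
#' @param quit_frac Thermoregulator only: fraction of the test after which
#'   the animal stops thermoregulating at its next lower set-point and stays
#'   at ambient. Default 1 (shuttle to the end); a simulated treatment
#'   cohort lowers it for the low-cost treatments.
#' @param quit_frac_sd Per-animal SD of the quit fraction (default 0.08).
#' @param seed Optional integer seed; the trace is reproducible from it.
#' @return A validated `sim_config` list.
#' @export
simulation_config <- function(duration_s = 5400, dt_s = 2,
                              resolution = 0.0625,
                              ta = 18, t_hot = 35,
                              true_upper = 34.7, true_lower = 29.1,
                              k_warm = 0.02, k_cool = 0.003, k_rest = 0.02,
                              noise_sd = 0.1, setpoint_jitter_sd = 0.3,
                              mode = c("thermoregulator",
                                       "non_thermoregulator"),
                              exit_after_s = 1800,
                              p_rest = 0.04, rest_s = 360,
                              quit_frac = 1, quit_frac_sd = 0.08,
                              seed = NULL) {
  mode <- match.arg(mode)
  if (!(true_lower < true_upper)) stop("need true_lower < true_upper")
  if (!(true_upper <= t_hot)) stop("need true_upper <= t_hot")
  if (!(ta < true_lower)) stop("need ta < true_lower")
  if (k_warm <= 0 || k_cool <= 0 || k_rest <= 0) {
    stop("rate constants must be > 0")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (setpoint_jitter_sd < 0) stop("setpoint_jitter_sd must be >= 0")
  if (p_rest < 0 || p_rest > 1) stop("p_rest must be in [0, 1]")
  if (quit_frac <= 0) stop("quit_frac must be > 0")
  if (quit_frac_sd < 0) stop("quit_frac_sd must be >= 0")
  if (duration_s < 2 * dt_s) stop("duration must cover at least 2 samples")
  structure(
    list(
      duration_s = duration_s, dt_s = dt_s, resolution = resolution,
      ta = ta, t_hot = t_hot,
      true_upper = true_upper, true_lower = true_lower,
      k_warm = k_warm, k_cool = k_cool, k_rest = k_rest,
      noise_sd = noise_sd, setpoint_jitter_sd = setpoint_jitter_sd,
      mode = mode, exit_after_s = exit_after_s,
      p_rest = p_rest, rest_s = rest_s,
      quit_frac = quit_frac, quit_frac_sd = quit_frac_sd, seed = seed
    ),
    class = "sim_config"
  )
}

quantize <- function(x, resolution) round(x / resolution) * resolution

# Draw a jittered set-point, kept inside its physically reachable band.
draw_setpoint <- function(nominal, sd, lo, hi) {
  min(max(nominal + rnorm(1L, 0, sd), lo), hi)
}

#' Simulate one temperature trace
#'
#' @param cfg A [simulation_config].
#' @param animal_id,treatment Metadata attached to the returned trace.
#' @return A [therm_trace] whose `"truth"` attribute records the ground
#'   truth: mode, number of in-zone direction changes (`n_switches`), the
#'   realized upper/lower set-points at each switch, switch times, rest
#'   count, and the nominal set-points. See [sim_truth].
#' @export
simulate_trace <- function(cfg, animal_id = "sim", treatment = "0") {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  n <- as.integer(round(cfg$duration_s / cfg$dt_s))
  dt <- cfg$dt_s
  decay <- c(bask = exp(-cfg$k_warm * dt),
             cool = exp(-cfg$k_cool * dt),
             rest = exp(-cfg$k_rest * dt),
             gone = exp(-cfg$k_rest * dt))
  up_hi <- cfg$t_hot - 0.05          # a set-point at t_hot is unreachable
  lo_lo <- cfg$ta + 0.5

  latent <- numeric(n)
  latent[1L] <- cfg$ta
  state <- "bask"
  rest_until <- -Inf
  quit_after <- if (cfg$quit_frac >= 1) {
    Inf
  } else {
    cfg$duration_s * max(0.05, rnorm(1L, cfg$quit_frac, cfg$quit_frac_sd))
  }
  cur_upper <- draw_setpoint(cfg$true_upper, cfg$setpoint_jitter_sd,
                             cfg$true_lower + 0.5, up_hi)
  cur_lower <- draw_setpoint(cfg$true_lower, cfg$setpoint_jitter_sd,
                             lo_lo, cur_upper - 0.5)
  upper_sp <- numeric(0); lower_sp <- numeric(0)
  switch_t <- numeric(0); switch_kind <- character(0)
  n_rests <- 0L
  states <- character(n)
  states[1L] <- state

  for (i in 2L:n) {
    t_now <- (i - 1L) * dt
    env <- if (state == "bask") cfg$t_hot else cfg$ta
    latent[i] <- env + (latent[i - 1L] - env) * decay[[state]]

    if (cfg$mode == "thermoregulator") {
      if (state == "bask" && latent[i] >= cur_upper) {
        upper_sp <- c(upper_sp, cur_upper)
        switch_t <- c(switch_t, t_now); switch_kind <- c(switch_kind, "upper")
        state <- "cool"
        cur_lower <- draw_setpoint(cfg$true_lower, cfg$setpoint_jitter_sd,
                                   lo_lo, cur_upper - 0.5)
      } else if (state == "cool" && latent[i] <= cur_lower) {
        if (t_now >= quit_after) {
          state <- "gone"   # done thermoregulating for the day
        } else if (runif(1L) < cfg$p_rest) {
          # leave the heated zone: cool on toward ambient, re-enter later
          n_rests <- n_rests + 1L
          state <- "rest"
          rest_until <- t_now + cfg$rest_s
        } else {
          lower_sp <- c(lower_sp, cur_lower)
          switch_t <- c(switch_t, t_now)
          switch_kind <- c(switch_kind, "lower")
          state <- "bask"
        }
        cur_upper <- draw_setpoint(cfg$true_upper, cfg$setpoint_jitter_sd,
                                   cfg$true_lower + 0.5, up_hi)
      } else if (state == "rest" && t_now >= rest_until) {
        state <- "bask"
      }
    } else { # non_thermoregulator
      if (state == "bask") {
        if (latent[i] >= cur_upper) {
          upper_sp <- c(upper_sp, cur_upper)
          switch_t <- c(switch_t, t_now)
          switch_kind <- c(switch_kind, "upper")
          state <- "gone"
        } else if (t_now >= cfg$exit_after_s) {
          state <- "gone"
        }
      }
    }
    states[i] <- state
  }

  noise <- if (cfg$noise_sd > 0) rnorm(n, 0, cfg$noise_sd) else numeric(n)
  observed <- quantize(latent + noise, cfg$resolution)

  tr <- therm_trace(
    temp = observed, dt = dt,
    animal_id = animal_id, treatment = treatment,
    resolution = cfg$resolution, ta_ref = cfg$ta
  )
  attr(tr, "truth") <- list(
    mode = cfg$mode,
    is_thermoregulator = cfg$mode == "thermoregulator",
    n_switches = length(switch_kind),
    switch_times_s = switch_t,
    switch_kinds = switch_kind,
    upper_setpoints = upper_sp,
    lower_setpoints = lower_sp,
    n_rests = n_rests,
    true_upper = cfg$true_upper,
    true_lower = cfg$true_lower,
    states = states,
    latent = latent
  )
  tr
}

#' Ground truth of a simulated trace
#'
#' @param trace A trace produced by [simulate_trace].
#' @return The ground-truth list (`NULL` for a non-simulated trace).
#' @export
sim_truth <- function(trace) attr(trace, "truth")

#' Default treatment effects for a simulated cohort
#'
#' Three windspeed analogues with effects shaped like the published
#' findings: set-points shift down as windspeed rises (both bounds, with the
#' broadest passivity range in the middle treatment), convective cooling
#' accelerates (`k_cool` multiplier), thermoregulation is attempted more
#' often (`p_thermoregulate`, defaults 17/28, 23/28, 23/28), rests away
#' from the heated zone shrink (`rest_scale` multiplies `p_rest`), and the
#' behavioural quit point moves later (`quit_frac`), so time spent
#' thermoregulating rises with windspeed — under low cost the animal meets
#' its thermal needs early and spends the remainder off the heat.
#'
#' @return A data frame with one row per treatment.
#' @export
default_treatments <- function() {
  data.frame(
    label = c("0", "2", "6"),
    delta_upper = c(0, -0.8, -2.4),
    delta_lower = c(0, -1.3, -2.2),
    p_thermoregulate = c(17, 23, 23) / 28,
    k_cool_mult = c(1.0, 1.6, 2.5),
    rest_scale = c(1.0, 0.5, 0.2),
    quit_frac = c(0.55, 0.70, 0.85),
    stringsAsFactors = FALSE
  )
}

#' Cohort configuration
#'
#' @param n_per_treatment Animals per treatment (default 28; every animal is
#'   tested once under every treatment, a repeated-measures design).
#' @param treatments Data frame of per-treatment effects, as
#'   [default_treatments]: columns `label`, `delta_upper`, `delta_lower`
#'   (additive set-point shifts, degrees C), `p_thermoregulate`,
#'   `k_cool_mult`, `rest_scale`, `quit_frac`.
#' @param base A [simulation_config] giving the no-effect baseline.
#' @param seed Integer cohort seed; per-trace child seeds derive from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_per_treatment = 28,
                          treatments = default_treatments(),
                          base = simulation_config(),
                          seed = 1L) {
  stopifnot(n_per_treatment >= 1, inherits(base, "sim_config"))
  treatments <- as.data.frame(treatments)
  need <- c("label", "delta_upper", "delta_lower", "p_thermoregulate",
            "k_cool_mult", "rest_scale", "quit_frac")
  missing <- setdiff(need, names(treatments))
  if (length(missing) > 0L) {
    stop("treatments is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(treatments$p_thermoregulate < 0 | treatments$p_thermoregulate > 1)) {
    stop("p_thermoregulate must be in [0, 1]")
  }
  structure(
    list(
      n_per_treatment = as.integer(n_per_treatment),
      treatments = treatments, base = base, seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Simulate a cohort of traces across treatments
#'
#' Every animal appears once per treatment. For each animal-by-treatment
#' test, thermoregulator status is drawn Bernoulli(`p_thermoregulate`), the
#' treatment's set-point shifts and cooling-rate multiplier are applied, and
#' a trace is simulated from a child seed derived deterministically from the
#' cohort seed.
#'
#' @param cfg A [cohort_config].
#' @return A list with `traces` (list of [therm_trace] with truth attached)
#'   and `manifest` (data frame: `trace_id`, `animal_id`, `treatment`,
#'   `is_thermoregulator_truth`, `true_upper`, `true_lower`, `seed`).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  n_tr <- nrow(cfg$treatments)
  n_tests <- cfg$n_per_treatment * n_tr
  child_seeds <- sample.int(.Machine$integer.max - 1L, n_tests)
  status_draw <- runif(n_tests)

  traces <- vector("list", n_tests)
  rows <- vector("list", n_tests)
  k <- 0L
  for (j in seq_len(n_tr)) {
    tre <- cfg$treatments[j, ]
    for (a in seq_len(cfg$n_per_treatment)) {
      k <- k + 1L
      animal <- sprintf("s%02d", a)
      is_thermo <- status_draw[k] < tre$p_thermoregulate
      scfg <- cfg$base
      scfg$true_upper <- cfg$base$true_upper + tre$delta_upper
      scfg$true_lower <- cfg$base$true_lower + tre$delta_lower
      scfg$k_cool <- cfg$base$k_cool * tre$k_cool_mult
      scfg$p_rest <- cfg$base$p_rest * tre$rest_scale
      scfg$quit_frac <- tre$quit_frac
      scfg$mode <- if (is_thermo) "thermoregulator" else "non_thermoregulator"
      scfg$seed <- child_seeds[k]
      traces[[k]] <- simulate_trace(scfg, animal_id = animal,
                                    treatment = tre$label)
      rows[[k]] <- data.frame(
        trace_id = sprintf("%s_w%s", animal, tre$label),
        animal_id = animal, treatment = tre$label,
        is_thermoregulator_truth = is_thermo,
        true_upper = scfg$true_upper, true_lower = scfg$true_lower,
        seed = child_seeds[k],
        stringsAsFactors = FALSE
      )
    }
  }
  list(traces = traces, manifest = do.call(rbind, rows))
}

#' Write a simulated cohort to disk
#'
#' One `<trace_id>.csv` (+ metadata sidecar) per trace, a
#' `<trace_id>.truth.json` ground-truth file, and a `manifest.json`.
#'
#' @param cohort Result of [simulate_cohort].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(cohort$traces)) {
    tr <- cohort$traces[[k]]
    id <- cohort$manifest$trace_id[k]
    write_trace(tr, file.path(dir, paste0(id, ".csv")))
    truth <- sim_truth(tr)
    truth$states <- NULL   # bulky per-sample vectors stay out of the files
    truth$latent <- NULL
    jsonlite::write_json(truth, file.path(dir, paste0(id, ".truth.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
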