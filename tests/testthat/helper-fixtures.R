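# The 16-sample worked micro-trace: one bout with three confirmed set-point
# events (upper@5 = 30.0, lower@8 = 27.5, upper@11 = 31.0) at the default
# 2 C hysteresis and 18 C section threshold.
micro_temps <- c(18.0, 19.0, 21.0, 24.0, 27.0, 30.0, 29.0, 28.0,
                 27.5, 28.5, 30.5, 31.0, 29.5, 28.9, 27.0, 18.0)

micro_trace <- function() {
  therm_trace(micro_temps, dt = 2, animal_id = "micro", treatment = "0")
}

default_ref <- function() reference_range(29.1, 34.7)
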