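test_that("section labelling uses a strict threshold and finds bouts", {
  tr <- therm_trace(c(18, 19, 18))
  sec <- label_sections(tr)
  expect_equal(sec$labels, c("non_thermoregulating", "thermoregulating",
                             "non_thermoregulating"))
  expect_equal(sec$bouts, data.frame(start = 1L, end = 2L))

  # exactly at the threshold is ambient, not thermoregulating
  sec <- label_sections(therm_trace(rep(18, 5)))
  expect_equal(nrow(sec$bouts), 0L)
  expect_true(all(sec$labels == "non_thermoregulating"))

  sec <- label_sections(micro_trace())
  expect_equal(sec$bouts, data.frame(start = 1L, end = 15L))
})

test_that("short thermoregulating runs can be smoothed away, one-sidedly", {
  tr <- therm_trace(c(18, 19, 18, 19, 19, 18, 19, 19, 19, 18))
  sec <- label_sections(tr, annotator_config(min_section_samples = 3))
  expect_equal(sec$bouts, data.frame(start = 6L, end = 9L))
  # short NON-thermoregulating runs are never relabelled
  tr2 <- therm_trace(c(19, 19, 18, 19, 19))
  sec2 <- label_sections(tr2, annotator_config(min_section_samples = 2))
  expect_equal(nrow(sec2$bouts), 2L)
})

test_that("the worked micro-trace annotates exactly as specified", {
  at <- annotate(micro_trace())
  expect_equal(at$events$kind, c("upper", "lower", "upper"))
  expect_equal(at$events$index, c(5L, 8L, 11L))
  expect_equal(at$events$temp, c(30.0, 27.5, 31.0))
  expect_equal(at$n_shuttles, 3L)
  expect_true(at$is_thermoregulator)
  expect_equal(at$bouts, data.frame(start = 1L, end = 15L))
})

test_that("no reversal of at least the hysteresis produces no events", {
  ramp <- seq(18, 31, length.out = 40)
  expect_equal(detect_on_vector(ramp)$n_direction_changes, 0L)

  tri <- 25 + 1.9 * c(seq(0, 1, 0.1), seq(0.9, 0, -0.1))
  tri <- rep(tri, 4)
  expect_equal(detect_on_vector(tri)$n_direction_changes, 0L)
})

test_that("plateau extrema take the first sample attaining the extreme", {
  x <- c(20, 23, 25, 25, 25, 22.9, 20, 20, 20, 23)
  res <- detect_on_vector(x)
  expect_equal(res$events$kind, c("upper", "lower"))
  expect_equal(res$events$index, c(2L, 6L))   # first 25, first 20 after peak
  expect_equal(res$events$temp, c(25, 20))
})

test_that("classification is strictly more-than-two direction changes", {
  expect_true(classify_thermoregulator(3))
  expect_false(classify_thermoregulator(2))
  expect_false(classify_thermoregulator(0))
})

test_that("flat ambient trace yields no bouts, no events, non-thermoregulator", {
  at <- annotate(therm_trace(rep(18, 50)))
  expect_equal(nrow(at$bouts), 0L)
  expect_equal(nrow(at$events), 0L)
  expect_false(at$is_thermoregulator)
})

test_that("detector state resets at bout boundaries", {
  # two bouts, each a single confirmed peak; run globally the dip to ambient
  # would chain them into an upper+lower+upper sequence
  x <- c(18, 25, 30, 27.5, 19, 18, 17, 18, 25, 30, 27.5, 19, 18)
  at <- annotate(therm_trace(x))
  expect_equal(nrow(at$bouts), 2L)
  expect_equal(at$events$kind, c("upper", "upper"))
  expect_equal(at$n_shuttles, 2L)
  expect_false(at$is_thermoregulator)
})

test_that("single-pass detector matches the brute-force oracle on random walks", {
  set.seed(101)
  for (i in 1:60) {
    x <- random_walk(n = sample(20:120, 1), step_sd = runif(1, 0.1, 1))
    got <- detect_on_vector(x)$events
    want <- oracle_detect(x, 2)
    expect_identical(got, want)
  }
})

test_that("events alternate and adjacent events differ by >= hysteresis", {
  set.seed(202)
  for (i in 1:40) {
    x <- random_walk(n = 150, step_sd = 0.6)
    ev <- detect_on_vector(x)$events
    if (nrow(ev) >= 2L) {
      expect_true(all(ev$kind[-1] != ev$kind[-nrow(ev)]))
      expect_true(all(abs(diff(ev$temp)) >= 2))
    }
  }
})

test_that("annotation is idempotent", {
  tr <- simulate_trace(simulation_config(duration_s = 1200, seed = 77))
  a1 <- annotate(tr)
  a2 <- annotate(a1$trace)
  expect_equal(a2$events, a1$events)
  expect_identical(a2$labels, a1$labels)
  expect_equal(a2$bouts, a1$bouts)
})

test_that("quantization does not perturb annotation when hysteresis >> resolution", {
  cfg <- simulation_config(duration_s = 1800, noise_sd = 0,
                           setpoint_jitter_sd = 0, p_rest = 0, seed = 5)
  tr <- simulate_trace(cfg)
  raw <- sim_truth(tr)$latent
  tr_raw <- therm_trace(raw, dt = tr$dt, resolution = tr$resolution,
                        ta_ref = tr$ta_ref)
  ev_q <- annotate(tr)$events
  ev_r <- annotate(tr_raw)$events
  expect_equal(ev_q$kind, ev_r$kind)
  # quantization flattens the slow approach to an extremum into a plateau,
  # so the first-occurrence index may land a few samples early
  expect_true(all(abs(ev_q$index - ev_r$index) <= 6L))
  expect_true(all(abs(ev_q$temp - ev_r$temp) <= tr$resolution))
})
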