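test_that("simulation is reproducible from its seed", {
  cfg <- simulation_config(duration_s = 1200, seed = 42)
  t1 <- simulate_trace(cfg)
  t2 <- simulate_trace(cfg)
  expect_identical(t1$temp, t2$temp)
  expect_identical(sim_truth(t1)$n_switches, sim_truth(t2)$n_switches)
  t3 <- simulate_trace(simulation_config(duration_s = 1200, seed = 43))
  expect_false(identical(t1$temp, t3$temp))
})

test_that("config validation catches impossible worlds", {
  expect_error(simulation_config(true_lower = 35, true_upper = 34), "true_lower <")
  expect_error(simulation_config(true_upper = 36), "t_hot")
  expect_error(simulation_config(ta = 30), "ta <")
  expect_error(simulation_config(k_warm = 0), "rate constants")
  expect_error(simulation_config(noise_sd = -1), "noise_sd")
  expect_error(simulation_config(p_rest = 2), "p_rest")
})

test_that("observed temperatures are quantized to the logger resolution", {
  tr <- simulate_trace(simulation_config(duration_s = 600, seed = 7))
  steps <- tr$temp / tr$resolution
  expect_equal(steps, round(steps))
})

test_that("a noiseless non-thermoregulator decays to ambient", {
  cfg <- simulation_config(noise_sd = 0, setpoint_jitter_sd = 0,
                           mode = "non_thermoregulator",
                           exit_after_s = 600, seed = 1)
  tr <- simulate_trace(cfg)
  expect_lte(abs(tail(tr$temp, 1) - cfg$ta), cfg$resolution)
  at <- annotate(tr)
  expect_lte(nrow(at$events), 1L)
  expect_false(at$is_thermoregulator)
})

test_that("noiseless annotation recovers set-points within the overshoot bound", {
  cfg <- simulation_config(noise_sd = 0, setpoint_jitter_sd = 0, p_rest = 0,
                           seed = 11)
  tr <- simulate_trace(cfg)
  s <- summarize_trace(annotate(tr), default_ref())
  bound_up <- (cfg$t_hot - cfg$true_upper) * (1 - exp(-cfg$k_warm * cfg$dt_s)) +
    cfg$resolution
  bound_lo <- (cfg$true_lower - cfg$ta) * (1 - exp(-cfg$k_cool * cfg$dt_s)) +
    cfg$resolution
  expect_lte(abs(s$mean_upper - cfg$true_upper), bound_up)
  expect_lte(abs(s$mean_lower - cfg$true_lower), bound_lo)
})

test_that("ground-truth switch count matches annotated shuttles within 1 per bout", {
  for (seed in c(2, 21, 22)) {
    cfg <- simulation_config(noise_sd = 0, setpoint_jitter_sd = 0, p_rest = 0,
                             seed = seed)
    tr <- simulate_trace(cfg)
    at <- annotate(tr)
    expect_lte(abs(sim_truth(tr)$n_switches - at$n_shuttles), nrow(at$bouts))
  }
})

test_that("faster convective cooling means more shuttles per unit time", {
  mk <- function(k_cool) {
    cfg <- simulation_config(noise_sd = 0, setpoint_jitter_sd = 0, p_rest = 0,
                             k_cool = k_cool, seed = 3)
    sim_truth(simulate_trace(cfg))$n_switches
  }
  expect_gt(mk(0.009), mk(0.003))
})

test_that("rests split a trace into multiple bouts", {
  cfg <- simulation_config(p_rest = 1, rest_s = 600, noise_sd = 0,
                           setpoint_jitter_sd = 0, seed = 9)
  tr <- simulate_trace(cfg)
  at <- annotate(tr)
  expect_gt(nrow(at$bouts), 1L)
  expect_gt(sim_truth(tr)$n_rests, 0L)
})

test_that("cohort generation respects its probabilities and design", {
  cc <- cohort_config(n_per_treatment = 6, seed = 5,
                      treatments = transform(default_treatments(),
                                             p_thermoregulate = 1))
  co <- simulate_cohort(cc)
  expect_true(all(co$manifest$is_thermoregulator_truth))
  expect_equal(length(co$traces), 18L)
  # repeated-measures design: every animal appears once per treatment
  tab <- table(co$manifest$animal_id, co$manifest$treatment)
  expect_true(all(tab == 1L))
  # child seeds differ, so traces differ
  expect_gt(length(unique(co$manifest$seed)), 1L)
})

test_that("a cohort with injected shifts recovers the set-point ordering", {
  co <- simulate_cohort(cohort_config(n_per_treatment = 10, seed = 8))
  ref <- default_ref()
  df <- summaries_to_df(lapply(co$traces,
                               function(tr) summarize_trace(annotate(tr), ref)))
  tab <- summarize_cohort(df, co$manifest)
  tab <- tab[match(c("0", "2", "6"), tab$treatment), ]
  expect_true(all(diff(tab$mean_upper_mean) < 0))
  expect_true(all(diff(tab$mean_lower_mean) < 0))
})

test_that("written cohorts round-trip through the manifest and truth files", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(cohort_config(
    n_per_treatment = 2, seed = 4,
    base = simulation_config(duration_s = 600)
  ))
  write_cohort(co, dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(nrow(man), 6L)
  tr <- read_trace(file.path(dir, paste0(man$trace_id[1], ".csv")))
  expect_identical(tr$temp, co$traces[[1]]$temp)
  truth <- jsonlite::read_json(
    file.path(dir, paste0(man$trace_id[1], ".truth.json")),
    simplifyVector = TRUE
  )
  expect_equal(truth$n_switches, sim_truth(co$traces[[1]])$n_switches)
})
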