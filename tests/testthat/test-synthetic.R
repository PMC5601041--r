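# Synthetic oddball cohort generator: determinism, design counts, fixture
# round trip, and recovery of the generator's own ground truth through the
# pipeline.

tiny_cfg <- function(...) {
  synth_config(n_subjects = 1, sessions = 1, trials_per_session = 10,
               target_fraction = 0.2, seed = 99, ...)
}

test_that("the generator is bit-identical under a fixed configuration", {
  cfg <- tiny_cfg()
  a <- generate_subject(cfg, 1)
  b <- generate_subject(cfg, 1)
  expect_identical(a$recordings[[1]]$voltages, b$recordings[[1]]$voltages)
  expect_identical(a$events, b$events)
  # a different subject index gives a different stream
  c2 <- generate_subject(cfg, 2)
  expect_false(identical(a$recordings[[1]]$voltages,
                         c2$recordings[[1]]$voltages))
})

test_that("each session has the exact target/standard split", {
  cfg <- synth_config(n_subjects = 1, sessions = 2, trials_per_session = 20,
                      seed = 5)
  sub <- generate_subject(cfg, 1)
  for (ev in sub$events) {
    expect_equal(nrow(ev), 20)
    expect_equal(sum(ev$condition == "target"), 4)
    expect_equal(sum(ev$condition == "standard"), 16)
  }
  expect_error(synth_config(trials_per_session = 10, target_fraction = 0.15),
               "whole number")
})

test_that("recordings carry the recorded-reference tag and montage structure", {
  sub <- generate_subject(tiny_cfg(), 1)
  rec <- sub$recordings[[1]]
  expect_identical(rec$reference, "FCz")
  expect_equal(length(rec$labels), 63)
  expect_equal(sum(!rec$scalp), 2)
  expect_equal(rec$sampling_rate, 500)
})

test_that("fixture files round trip numerically", {
  cfg <- tiny_cfg()
  cohort <- generate_cohort(cfg, subjects = 1)
  dir <- file.path(tempdir(), "cohort_fixture")
  write_fixture(cohort, dir)
  expect_true(file.exists(file.path(dir, "montage.sfp")))
  rec0 <- cohort$subjects$sub1$recordings[[1]]
  rec <- read_fixture_recording(file.path(dir, "sub-1", "ses-1_eeg.csv"))
  expect_identical(rec$labels, rec0$labels)
  expect_equal(rec$voltages, rec0$voltages, tolerance = 1e-12,
               ignore_attr = TRUE)
  gt <- jsonlite::read_json(file.path(dir, "sub-1", "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_identical(gt$reference, "FCz")
  expect_equal(gt$components$amp_mult,
               cohort$subjects$sub1$ground_truth$components$amp_mult,
               tolerance = 1e-12)
})

test_that("with zero noise and jitter the averaged ERP equals the template", {
  cfg <- synth_config(n_subjects = 1, sessions = 1, trials_per_session = 10,
                      noise_rms_uv = 0, sensor_noise_uv = 0,
                      amp_jitter_sd = 0, lat_jitter_sd = 0,
                      artifact_rate = 0, seed = 3)
  sub <- generate_subject(cfg, 1)
  rest_op <- full_rest_operator()
  res <- analyze_subject(sub, 1, rest_op, references = "AR")
  # template: the projected component sum, same preprocessing, AR reference
  fwd <- restcm:::synth_forward(cfg)
  comp <- cfg$components
  fs <- cfg$sampling_rate
  tt <- seq(0, 1.25, by = 1 / fs)
  tpl <- matrix(0, nrow(fwd$scalp61), length(tt))
  g_fcz <- fwd$comp_gain[fwd$scalp61$label, ] -
    matrix(fwd$comp_gain["FCz", ], nrow(fwd$scalp61), nrow(comp), byrow = TRUE)
  for (i in seq_len(nrow(comp))) {
    u <- 2 * pi * comp$f_hz[i] * (tt - 0.25 - comp$t0_s[i])
    h <- exp(-(u / comp$gamma[i])^2) * cos(u)
    tpl <- tpl + comp$amp_target_uv[i] * outer(g_fcz[, i], h)
  }
  tpl_rec <- scalp_recording(tpl, fwd$scalp61$label, fs, reference = "FCz")
  tpl_pre <- apply_common_reference(preprocess(tpl_rec), "AR")
  # compare peak amplitudes at Pz in a window around the P3b peak
  times <- recording_times(tpl_pre) - 0.25
  win <- times > 0.25 & times < 0.5
  peak_tpl <- max(tpl_pre$voltages["Pz", win])
  p3 <- res$p300
  erp_peak <- p3$amplitude[p3$condition == "target"]
  # the pipeline's three-electrode measure on the template
  tpl_erp <- tpl_pre
  tpl_erp$t0 <- -0.25
  tpl_p3 <- p300_measures(tpl_erp)
  expect_equal(erp_peak, tpl_p3$amplitude, tolerance = 0.02 * peak_tpl)
})

test_that("averaging noise falls as the square root of the trial count", {
  mk <- function(trials, seed) {
    cfg <- synth_config(n_subjects = 1, sessions = 1,
                        trials_per_session = trials,
                        amp_jitter_sd = 0, lat_jitter_sd = 0,
                        artifact_rate = 0, seed = seed)
    sub <- generate_subject(cfg, 1)
    rec <- preprocess(sub$recordings[[1]])
    ep <- make_epochs(rec, sub$events[[1]], reject = NULL)
    avg <- average_erp(ep, "standard")
    avg$voltages[avg$scalp, ]
  }
  # residual against the noiseless template, RMS over channels and samples
  cfg0 <- synth_config(n_subjects = 1, sessions = 1, trials_per_session = 10,
                       noise_rms_uv = 0, sensor_noise_uv = 0,
                       amp_jitter_sd = 0, lat_jitter_sd = 0,
                       artifact_rate = 0, seed = 1)
  sub0 <- generate_subject(cfg0, 1)
  rec0 <- preprocess(sub0$recordings[[1]])
  tpl <- average_erp(make_epochs(rec0, sub0$events[[1]], reject = NULL),
                     "standard")$voltages[1:61, ]
  rms <- function(trials, seed) {
    res <- mk(trials, seed = seed)
    sqrt(mean((res - tpl)^2))
  }
  # a single realization of the RMS ratio has ~10-15% sampling spread
  # (spatially correlated background); average over three fixed seeds
  ratios <- vapply(17:19, function(sd) rms(40, sd) / rms(10, sd), 0)
  expect_lt(abs(mean(ratios) - 0.5), 0.5 * 0.25)   # halves, within 25%
})

test_that("pipeline recovers a known parietal component from its own cohort", {
  # single 10 uV (at Pz) parietal component at 360 ms, clean recording
  comp <- default_components()
  comp <- comp[comp$name == "P3b", ]
  cfg <- synth_config(n_subjects = 1, sessions = 1, trials_per_session = 10,
                      components = comp, noise_rms_uv = 1, sensor_noise_uv = 0.5,
                      amp_jitter_sd = 0, lat_jitter_sd = 0, artifact_rate = 0,
                      seed = 8)
  sub <- generate_subject(cfg, 1)
  res <- analyze_subject(sub, 1, full_rest_operator(), references = "REST")
  p3 <- res$p300[res$p300$condition == "target", ]
  expect_equal(p3$latency, 0.36, tolerance = 0.012)
  # oracle: the same three-electrode measure on the noiseless projected
  # template (infinity reference, which REST estimates)
  fwd <- restcm:::synth_forward(cfg)
  tt <- seq(-0.2, 0.8, by = 1 / 250)
  u <- 2 * pi * comp$f_hz * (tt - comp$t0_s)
  h <- exp(-(u / comp$gamma)^2) * cos(u)
  tpl <- scalp_recording(
    comp$amp_target_uv * outer(fwd$comp_gain[fwd$scalp61$label, "P3b"], h),
    fwd$scalp61$label, 250, t0 = -0.2)
  tpl_amp <- p300_measures(tpl)$amplitude
  expect_equal(p3$amplitude, tpl_amp, tolerance = 1 / tpl_amp)  # within 1 uV
})
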