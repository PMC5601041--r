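# Filtering/decimation, epoching, averaging, P300 measures, stage statistics
# and cross-condition correlation on controlled inputs.

flat_labels <- function(n) paste0("ch", seq_len(n))

test_that("preprocessing preserves DC, kills 20 Hz, halves the rate", {
  fs <- 500
  t <- (0:4999) / fs
  dc <- matrix(2.5, 2, length(t))
  rec <- scalp_recording(dc, flat_labels(2), fs)
  out <- preprocess(rec)
  expect_equal(out$sampling_rate, 250)
  expect_equal(ncol(out$voltages), length(t) / 2)
  expect_equal(max(abs(out$voltages - 2.5)), 0, tolerance = 1e-8)
  s20 <- matrix(sin(2 * pi * 20 * t), 1, length(t))
  out20 <- preprocess(scalp_recording(s20, "a", fs))
  mid <- 500:1500   # away from the edges
  expect_lt(max(abs(out20$voltages[, mid])), 0.01)
  # analytic forward-backward 4th-order Butterworth magnitude at 20 Hz
  expect_lt(1 / (1 + (20 / 6)^8), 1e-4)
  expect_error(preprocess(rec, lowpass = 300), "Nyquist")
  expect_error(preprocess(rec, decimate_to = 333), "divide")
})

test_that("epochs are cut, baselined and rejected per the contract", {
  fs <- 250
  n <- 5000
  set.seed(31)
  v <- matrix(rnorm(3 * n, sd = 5), 3)
  rec <- scalp_recording(v, flat_labels(3), fs)
  ev <- data.frame(onset_s = c(0.5, 4, 8, 12, 19.9),
                   condition = c("a", "b", "a", "b", "a"))
  ep <- make_epochs(rec, ev)
  # event at 19.9 s has no room for 800 ms post-stimulus: skipped
  expect_equal(length(ep$skipped), 1)
  expect_equal(dim(ep$data), c(3, 250, 4))
  # baseline: pre-stimulus mean is zero per channel and epoch
  bi <- ep$times < 0
  for (i in 1:4)
    expect_lt(max(abs(rowMeans(ep$data[, bi, i]))), 1e-10)
  # rejection boundary: exactly 75 uV retained, above rejected (strict)
  mk <- function(peak) {
    vv <- matrix(0, 3, n)
    vv[2, 1000 + 50] <- peak
    make_epochs(scalp_recording(vv, flat_labels(3), fs),
                data.frame(onset_s = 4, condition = "a"))
  }
  expect_false(mk(75)$rejected)
  expect_true(mk(76)$rejected)
  expect_match(mk(76)$reject_reason, "amplitude")
})

test_that("averaging is the sample mean over retained epochs", {
  fs <- 250
  tpl <- matrix(sin(2 * pi * 3 * (0:249) / fs), 2, 250, byrow = TRUE)
  n <- 3000
  v <- matrix(0, 2, n)
  onsets <- c(2, 6, 10)
  for (o in onsets) {
    idx <- round(o * fs) + 1 + 0:249
    v[, idx - 50] <- v[, idx - 50] + 0   # keep zeros before baseline window
    v[, round(o * fs) + 1 + 0:249] <- tpl
  }
  rec <- scalp_recording(v, flat_labels(2), fs)
  ep <- make_epochs(rec, data.frame(onset_s = onsets, condition = "a"),
                    baseline = NULL, reject = NULL)
  avg <- average_erp(ep, "a")
  expect_equal(attr(avg, "n_averaged"), 3)
  expect_equal(avg$voltages, ep$data[, , 1], tolerance = 1e-12,
               ignore_attr = TRUE)
  # linearity: average of epochs + c equals average + c
  ep2 <- ep; ep2$data <- ep$data + 4
  avg2 <- average_erp(ep2, "a")
  expect_equal(avg2$voltages, avg$voltages + 4, tolerance = 1e-12)
  expect_error(average_erp(ep, "nope"), "no retained epochs")
})

test_that("re-referencing and averaging commute on retained epochs", {
  set.seed(32)
  m <- sim_montage()
  fs <- 250
  n <- 4000
  v <- matrix(rnorm(nrow(m) * n, sd = 3), nrow(m))
  ev <- data.frame(onset_s = c(2, 5, 8), condition = "a")
  rec <- scalp_recording(v, m$label, fs)
  avg_then_ar <- apply_common_reference(
    average_erp(make_epochs(rec, ev, reject = NULL), "a"), "AR")
  ar_then_avg <- average_erp(
    make_epochs(apply_common_reference(rec, "AR"), ev, reject = NULL), "a")
  expect_equal(avg_then_ar$voltages, ar_then_avg$voltages, tolerance = 1e-10)
})

test_that("P300 measures average the three midline peak readings", {
  m <- sim_montage()
  fs <- 250
  v <- matrix(0, nrow(m), 250)
  times <- (0:249) / fs - 0.2
  peak_at <- function(lbl, amp, lat) {
    i <- which(m$label == lbl)
    v[i, ] <<- amp * exp(-((times - lat) / 0.05)^2)
  }
  peak_at("Cz", 8, 0.30); peak_at("CPz", 10, 0.36); peak_at("Pz", 12, 0.42)
  erp <- scalp_recording(v, m$label, fs, t0 = -0.2)
  res <- p300_measures(erp)
  expect_equal(res$amplitude, 10, tolerance = 1e-6)
  expect_equal(res$latency, 0.36, tolerance = 1e-6)
  # flat signal: amplitude 0, latency undefined
  res0 <- p300_measures(scalp_recording(matrix(0, nrow(m), 250), m$label,
                                        fs, t0 = -0.2))
  expect_equal(res0$amplitude, 0)
  expect_true(is.na(res0$latency))
})

test_that("stage statistics produce the full design table and sane nulls", {
  set.seed(33)
  subs <- 1:6; refs <- c("REST", "AR", "LM"); conds <- c("target", "standard")
  times <- seq(0.2, 0.796, by = 0.004)
  rows <- expand.grid(subject = subs, reference = refs, condition = conds)
  cm <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    data.frame(rows[i, ], row.names = NULL, time = times,
               x = rnorm(length(times), sd = 0.05),
               y = rnorm(length(times), sd = 0.05) + 0.1 * rows$subject[i],
               defined = TRUE, speed = abs(rnorm(length(times))))
  }))
  # identical data for all references -> F exactly 0, Tukey p = 1
  cm_same <- cm
  base <- cm_same[cm_same$reference == "REST", ]
  for (r in refs) cm_same[cm_same$reference == r, c("x", "y", "speed")] <-
    base[, c("x", "y", "speed")]
  st <- stage_statistics(cm_same)
  expect_equal(nrow(st$table), 6 * 3 * 2 * 3)   # subjects x refs x conds x stages
  expect_equal(st$tests$S1$y$anova$F, 0, tolerance = 1e-20)
  expect_true(all(st$tests$S2$y$tukey$p_adj > 0.999))
})

test_that("condition correlation pairs lagged stage windows", {
  times <- seq(0.210, 0.800, by = 0.004)   # grid aligned with the windows
  v <- 1 + sin(2 * pi * 2 * times)
  vt <- data.frame(time = times, speed = v)
  # identical curves: R = 1, slope = 1 in S2/S3
  res <- condition_correlation(vt, vt)
  expect_equal(res$S2$R, 1, tolerance = 1e-12)
  expect_equal(res$S2$slope, 1, tolerance = 1e-12)
  expect_equal(res$S3$R, 1, tolerance = 1e-12)
  # S1 window spans 26 paired samples (inclusive endpoints, 250 Hz)
  expect_equal(res$S1$n, 26)
  # negated curve: R = -1
  vs <- data.frame(time = times, speed = -v)
  expect_equal(condition_correlation(vt, vs)$S2$R, -1, tolerance = 1e-12)
  # the S1 lag shifts the standard window 40 ms earlier: a curve shifted by
  # exactly 40 ms correlates perfectly in S1
  vshift <- data.frame(time = times, speed = 1 + sin(2 * pi * 2 * (times + 0.04)))
  expect_equal(condition_correlation(vt, vshift)$S1$R, 1, tolerance = 1e-9)
})
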