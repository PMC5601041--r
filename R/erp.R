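# ERP analysis chain: zero-phase low-pass filtering and decimation, epoching
# with baseline correction and amplitude-threshold artifact rejection,
# averaging, P300 peak measures, stage-resolved CM statistics, and
# cross-condition velocity correlations.

#' Low-pass filter and decimate a recording
#'
#' Applies a zero-phase Butterworth low-pass (filtered forward and backward,
#' so effective attenuation is the squared magnitude response and latencies
#' are preserved), then decimates by sample picking to the target rate.  With
#' the default 6 Hz cutoff the signal is far below the decimated Nyquist, so
#' no separate anti-alias stage is needed.
#'
#' @param rec A `scalp_recording`.
#' @param lowpass Cutoff frequency, Hz.
#' @param order Butterworth order (applied twice by filtfilt).
#' @param decimate_to Target sampling rate, Hz; must divide the input rate.
#'   `NULL` keeps the input rate.
#' @return The filtered, decimated `scalp_recording`.
#' @export
preprocess <- function(rec, lowpass = 6, order = 4, decimate_to = 250) {
  stopifnot(inherits(rec, "scalp_recording"))
  fs <- rec$sampling_rate
  if (lowpass >= fs / 2)
    stop("low-pass cutoff must be below the Nyquist frequency")
  bf <- signal::butter(order, lowpass / (fs / 2), type = "low")
  # odd-reflection padding suppresses the zero-state edge transients of
  # filtfilt; three filter time constants are ample
  n <- ncol(rec$voltages)
  npad <- min(n - 1, ceiling(10 * fs / lowpass))
  v <- t(apply(rec$voltages, 1, function(ch) {
    left <- 2 * ch[1] - ch[(npad + 1):2]
    right <- 2 * ch[n] - ch[(n - 1):(n - npad)]
    y <- signal::filtfilt(bf, c(left, ch, right))
    y[(npad + 1):(npad + n)]
  }))
  if (!is.null(decimate_to)) {
    step <- fs / decimate_to
    if (abs(step - round(step)) > 1e-9)
      stop("target rate must divide the sampling rate")
    v <- v[, seq(1, ncol(v), by = round(step)), drop = FALSE]
    fs <- decimate_to
  }
  scalp_recording(v, rec$labels, fs, reference = rec$reference,
                  scalp = rec$scalp, t0 = rec$t0)
}

#' Cut condition-labeled epochs with baseline correction and rejection
#'
#' Epochs are cut on the half-open window `[tmin, tmax)` around each stimulus
#' onset; each epoch and channel has the mean over the baseline interval
#' `[tmin, 0)` subtracted; epochs in which any rejection channel exceeds the
#' threshold in absolute value (strictly) are marked rejected.  Events too
#' close to the recording edge are skipped (logged in the `skipped`
#' attribute).
#'
#' @param rec A preprocessed `scalp_recording`.
#' @param events Data frame with columns `onset_s` and `condition`.
#' @param tmin,tmax Epoch window relative to stimulus onset, seconds.
#' @param baseline Baseline interval, seconds; `NULL` disables correction.
#' @param reject Rejection threshold, microvolts (strict `|v| > reject`);
#'   `NULL` disables rejection.
#' @param reject_labels Channels the threshold applies to; defaults to all
#'   scalp channels of the recording.
#' @return Object of class `eeg_epochs`: `data` (channels x samples x
#'   trials), `condition`, `rejected`, `reject_reason`, `times`, `labels`,
#'   `scalp`, `sampling_rate`.
#' @export
make_epochs <- function(rec, events, tmin = -0.2, tmax = 0.8,
                        baseline = c(-0.2, 0), reject = 75,
                        reject_labels = NULL) {
  stopifnot(inherits(rec, "scalp_recording"),
            all(c("onset_s", "condition") %in% names(events)))
  fs <- rec$sampling_rate
  nsamp <- ncol(rec$voltages)
  rel <- seq(round(tmin * fs), round(tmax * fs) - 1)
  times <- rel / fs
  if (is.null(reject_labels)) reject_labels <- rec$labels[rec$scalp]
  ri <- match(reject_labels, rec$labels)
  if (anyNA(ri)) stop("unknown rejection channels")

  onset_idx <- round(events$onset_s * fs) + 1
  ok <- onset_idx + rel[1] >= 1 & onset_idx + rel[length(rel)] <= nsamp
  skipped <- which(!ok)
  keep <- which(ok)
  data <- array(NA_real_, c(nrow(rec$voltages), length(rel), length(keep)),
                dimnames = list(rec$labels, NULL, NULL))
  for (i in seq_along(keep))
    data[, , i] <- rec$voltages[, onset_idx[keep[i]] + rel]
  if (!is.null(baseline)) {
    bi <- times >= baseline[1] - 1e-9 & times < baseline[2] - 1e-9
    if (!any(bi)) stop("baseline interval contains no samples")
    for (i in seq_along(keep)) {
      bm <- rowMeans(data[, bi, i, drop = FALSE])
      data[, , i] <- data[, , i] - bm
    }
  }
  rejected <- logical(length(keep))
  reason <- character(length(keep))
  if (!is.null(reject)) {
    for (i in seq_along(keep)) {
      mx <- max(abs(data[ri, , i]))
      if (mx > reject) {
        rejected[i] <- TRUE
        reason[i] <- sprintf("amplitude %.1f uV > %g uV", mx, reject)
      }
    }
  }
  structure(
    list(data = data, condition = as.character(events$condition)[keep],
         rejected = rejected, reject_reason = reason,
         times = times, labels = rec$labels, scalp = rec$scalp,
         sampling_rate = fs, reference = rec$reference, skipped = skipped),
    class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("Epochs: %d trials (%d rejected, %d skipped), %d channels x %d samples @ %g Hz\n",
              length(x$condition), sum(x$rejected), length(x$skipped),
              dim(x$data)[1], dim(x$data)[2], x$sampling_rate))
  print(table(condition = x$condition, rejected = x$rejected))
  invisible(x)
}

#' Average retained epochs of one condition
#'
#' @param ep An `eeg_epochs` object.
#' @param condition Condition label to average.
#' @return A `scalp_recording` holding the sample-wise mean over retained
#'   epochs, with attribute `n_averaged` and `t0` set to the epoch start.
#' @export
average_erp <- function(ep, condition) {
  stopifnot(inherits(ep, "eeg_epochs"))
  sel <- which(ep$condition == condition & !ep$rejected)
  if (!length(sel)) stop("no retained epochs for condition '", condition, "'")
  avg <- apply(ep$data[, , sel, drop = FALSE], c(1, 2), mean)
  out <- scalp_recording(avg, ep$labels, ep$sampling_rate,
                         reference = ep$reference, scalp = ep$scalp,
                         t0 = ep$times[1])
  attr(out, "n_averaged") <- length(sel)
  out
}

#' P300 amplitude and latency
#'
#' The per-electrode positive peak (maximum voltage) and its time are located
#' within the search window at each of the midline electrodes, then averaged
#' across them; the means are the P300 amplitude and latency.
#'
#' @param erp An averaged `scalp_recording` (stimulus-locked, `t0` < 0).
#' @param window Peak search window, seconds post-stimulus.
#' @param electrodes Electrodes averaged for the measure.
#' @return List: `amplitude` (microvolts), `latency` (seconds; `NA` if the
#'   signal is flat in the window at any electrode), and the per-electrode
#'   `peaks` table.
#' @export
p300_measures <- function(erp, window = c(0.25, 0.5),
                          electrodes = c("Cz", "CPz", "Pz")) {
  stopifnot(inherits(erp, "scalp_recording"))
  if (!all(electrodes %in% erp$labels))
    stop("missing electrodes: ",
         paste(setdiff(electrodes, erp$labels), collapse = ", "))
  times <- recording_times(erp)
  wi <- which(times >= window[1] - 1e-9 & times <= window[2] + 1e-9)
  if (!length(wi)) stop("search window outside the epoch")
  peaks <- data.frame(electrode = electrodes, amplitude = NA_real_,
                      latency = NA_real_)
  for (i in seq_along(electrodes)) {
    seg <- erp$voltages[electrodes[i], wi]
    peaks$amplitude[i] <- max(seg)
    peaks$latency[i] <- if (diff(range(seg)) == 0) NA_real_
                        else times[wi[which.max(seg)]]
  }
  list(amplitude = mean(peaks$amplitude),
       latency = if (anyNA(peaks$latency)) NA_real_ else mean(peaks$latency),
       peaks = peaks)
}

#' Stage windows of the ERP time course
#'
#' Three post-stimulus stages: the anterior-to-posterior travel (S1), the
#' parietal P300 plateau (S2), and the frontal return (S3).
#'
#' @param S1,S2,S3 Time intervals in seconds post-stimulus.
#' @return List of class `stage_windows`.
#' @export
stage_windows <- function(S1 = c(0.210, 0.350), S2 = c(0.350, 0.480),
                          S3 = c(0.480, 0.740)) {
  w <- list(S1 = S1, S2 = S2, S3 = S3)
  ends <- unlist(w)
  if (any(diff(ends) < 0)) stop("stage windows must be increasing")
  structure(w, class = "stage_windows")
}

in_window <- function(times, w) times >= w[1] - 1e-9 & times <= w[2] + 1e-9

#' Stage-resolved CM statistics across references
#'
#' Takes stacked per-subject CM trajectories and velocities (one row per time
#' sample) and computes, per subject, reference, condition and stage, the
#' mean CM coordinates and mean traveling speed; then tests the reference
#' effect per stage and measure with a one-way repeated-measures ANOVA
#' (Greenhouse-Geisser corrected) and Tukey pairwise comparisons, using the
#' subject-level stage means as observations.
#'
#' @param cm_data Data frame with columns `subject`, `reference`,
#'   `condition`, `time`, `x`, `y`, `defined`, `speed`.
#' @param stages A [stage_windows()].
#' @param condition Condition whose reference effect is tested.
#' @param measures Columns tested (default CM y-coordinate and speed).
#' @return List: `table` (subject x reference x condition x stage means) and
#'   `tests` (per stage, per measure: `anova` and `tukey`).
#' @export
stage_statistics <- function(cm_data, stages = stage_windows(),
                             condition = "target",
                             measures = c("y", "speed")) {
  need <- c("subject", "reference", "condition", "time", "defined")
  stopifnot(all(need %in% names(cm_data)))
  refs <- unique(cm_data$reference)
  rows <- list()
  for (st in names(stages)) {
    sel <- cm_data[in_window(cm_data$time, stages[[st]]) & cm_data$defined, ]
    agg <- stats::aggregate(
      sel[, intersect(c("x", "y", "z", "speed"), names(sel)), drop = FALSE],
      by = list(subject = sel$subject, reference = sel$reference,
                condition = sel$condition),
      FUN = mean, na.rm = TRUE)
    agg$stage <- st
    rows[[st]] <- agg
  }
  tab <- do.call(rbind, rows)
  tests <- list()
  for (st in names(stages)) {
    tests[[st]] <- list()
    sub <- tab[tab$stage == st & tab$condition == condition, ]
    for (ms in measures) {
      wide <- stats::reshape(
        sub[, c("subject", "reference", ms)],
        idvar = "subject", timevar = "reference", direction = "wide")
      m <- as.matrix(wide[, -1, drop = FALSE])
      colnames(m) <- sub("^.*\\.", "", colnames(m))
      if (anyNA(m)) stop("incomplete subject x reference table for stage ",
                         st, ", measure ", ms)
      a <- rm_anova_gg(m)
      tests[[st]][[ms]] <- list(
        anova = a,
        tukey = tukey_hsd(m, ms_error = a$ms_error, df_error = a$df_error))
    }
  }
  list(table = tab, tests = tests)
}

#' Cross-condition correlation of group-mean CM traveling velocity
#'
#' Correlates the group-mean velocity curves of the two stimulus conditions
#' within each stage.  In S1 the target window is lagged relative to the
#' standard window (the target course runs ~40 ms later); S2 and S3 pair
#' identical windows.  Windows are inclusive of both endpoints.
#'
#' @param vel_target,vel_standard Data frames `time`, `speed` (group means
#'   across subjects, common time base).
#' @param windows List of per-stage window pairs, each
#'   `list(target = c(t1, t2), standard = c(t1, t2))`; the defaults pair
#'   target 250-350 ms with standard 210-310 ms in S1 and identical windows
#'   in S2 (350-480 ms) and S3 (480-740 ms).
#' @return Per-stage list: `R`, `p`, `slope`, `intercept`, `n`.
#' @export
condition_correlation <- function(vel_target, vel_standard,
                                  windows = list(
                                    S1 = list(target = c(0.250, 0.350),
                                              standard = c(0.210, 0.310)),
                                    S2 = list(target = c(0.350, 0.480),
                                              standard = c(0.350, 0.480)),
                                    S3 = list(target = c(0.480, 0.740),
                                              standard = c(0.480, 0.740)))) {
  out <- list()
  for (st in names(windows)) {
    wt <- windows[[st]]$target
    ws <- windows[[st]]$standard
    x <- vel_target$speed[in_window(vel_target$time, wt)]
    y <- vel_standard$speed[in_window(vel_standard$time, ws)]
    if (length(x) != length(y))
      stop("window sample counts differ in stage ", st,
           " (", length(x), " vs ", length(y), ")")
    ok <- !is.na(x) & !is.na(y)
    out[[st]] <- pearson_corr_fit(x[ok], y[ok])
  }
  out
}
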