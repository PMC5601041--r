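# Seedable generator of multi-subject, two-condition visual-oddball ERP
# cohorts: equivalent-dipole ERP components projected through the
# three-shell forward model, spatially correlated dipolar background noise,
# sensor noise, eye-blink artifacts, and the recording reference (FCz) of
# the emulated 63-channel system.

#' Synthetic oddball cohort configuration
#'
#' Defaults describe a 12-subject cohort recorded at 500 Hz in three sessions
#' of 150 trials (exact 30 target / 120 standard split per session) with the
#' standard trial protocol (cue 250 ms, fixation 500 ms, stimulus 500 ms).
#'
#' The ERP is built from lumped equivalent dipoles on the midline: P200
#' (frontal, 0.20 s, both conditions), P250 (fronto-central, 0.25 s, larger
#' for standard), a target-dominant fronto-central P3a (0.31 s) and parietal
#' P3b (0.36 s, ~10 uV at Pz), and a late frontal slow wave (0.62 s, both
#' conditions) that carries the return of the positive center of mass to
#' frontal sites during the recovery stage.  The P3a/P3b pair makes the CM
#' drift continuously along the midline through the P300 plateau instead of
#' sitting on a single static source.
#'
#' Component amplitudes are specified in microvolts at a named electrode of
#' the infinity-referenced scalp map and converted to dipole moments through
#' the forward model.  Inter-subject variability: lognormal amplitude
#' scaling (sdlog `amp_jitter_sd`) and Gaussian latency shifts
#' (`lat_jitter_sd`, seconds), drawn per subject and component.
#'
#' @param n_subjects,sessions,trials_per_session,target_fraction Design.
#' @param sampling_rate Hz.
#' @param components Data frame of component parameters (see defaults).
#' @param amp_jitter_sd,lat_jitter_sd Inter-subject jitter.
#' @param noise_rms_uv Median per-channel RMS of the dipolar background, uV.
#' @param sensor_noise_uv White sensor noise RMS, uV.
#' @param noise_dipoles Number of background dipoles per session.
#' @param noise_lowpass_hz Low-pass cutoff of the background time courses.
#' @param artifact_rate Fraction of trials hit by an eye-blink artifact.
#' @param seed Base seed; per-subject streams are derived deterministically.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 12, sessions = 3,
                         trials_per_session = 150, target_fraction = 0.20,
                         sampling_rate = 500,
                         components = default_components(),
                         amp_jitter_sd = 0.2, lat_jitter_sd = 0.02,
                         noise_rms_uv = 12, sensor_noise_uv = 3,
                         noise_dipoles = 20, noise_lowpass_hz = 30,
                         artifact_rate = 0.08, seed = 1) {
  stopifnot(target_fraction > 0, target_fraction < 1)
  n_target <- trials_per_session * target_fraction
  if (abs(n_target - round(n_target)) > 1e-9)
    stop("target_fraction must give a whole number of target trials")
  structure(
    list(n_subjects = n_subjects, sessions = sessions,
         trials_per_session = trials_per_session,
         target_fraction = target_fraction,
         sampling_rate = sampling_rate, components = components,
         amp_jitter_sd = amp_jitter_sd, lat_jitter_sd = lat_jitter_sd,
         noise_rms_uv = noise_rms_uv, sensor_noise_uv = sensor_noise_uv,
         noise_dipoles = noise_dipoles, noise_lowpass_hz = noise_lowpass_hz,
         artifact_rate = artifact_rate, seed = seed,
         # protocol timing, seconds
         cue_s = 0.25, fixation_s = 0.50, stimulus_s = 0.50,
         lead_in_s = 1.0, lead_out_s = 1.0),
    class = "synth_config")
}

#' Default ERP component table
#'
#' @return Data frame: `name`, dipole position (`px, py, pz`, radial
#'   orientation), peak time `t0_s`, Gabor frequency `f_hz` and damping
#'   `gamma`, calibration electrode, per-condition amplitudes (uV), and
#'   `lag_standard_s` - the timing offset of the standard-condition course
#'   relative to the target course (the endogenous components of the
#'   frequent standard stimulus run ~40 ms earlier, matching the oddball
#'   literature's stimulus-evaluation lag).
#' @export
default_components <- function() {
  data.frame(
    name = c("P200", "P250", "P3a", "P3b", "SW"),
    px = c(0, 0, 0, 0, 0),
    py = c(0.55, 0.35, 0.15, -0.45, 0.50),
    pz = c(0.35, 0.55, 0.62, 0.50, 0.40),
    t0_s = c(0.20, 0.25, 0.31, 0.36, 0.62),
    lag_standard_s = c(0, 0, -0.04, -0.04, -0.04),
    f_hz = c(6.0, 5.0, 3.5, 3.0, 1.5),
    gamma = c(2, 2, 2, 2, 2),
    amp_electrode = c("Fz", "FCz", "Cz", "Pz", "Fz"),
    amp_target_uv = c(6.0, 3.5, 6.0, 10.0, 4.0),
    amp_standard_uv = c(6.0, 7.0, 1.0, 2.5, 4.0),
    stringsAsFactors = FALSE)
}

# Deterministic, order-independent per-subject seed stream.
subject_seed <- function(seed, subject) {
  (as.numeric(seed) * 1000003 + subject * 7919) %% 2147483629
}

# Forward machinery shared by all subjects of one configuration: the
# recording montage (61 scalp + 2 EOG), the FCz reference position, and the
# infinity-reference gains of the component dipoles at the 62 scalp+reference
# electrodes.
synth_forward <- function(cfg, model = head_model()) {
  mont63 <- easycap63_montage()
  scalp61 <- mont63[mont63$scalp, ]
  class(scalp61) <- c("eeg_montage", "data.frame")
  lf_mont <- rbind(scalp61, standard_electrode("FCz"))
  class(lf_mont) <- c("eeg_montage", "data.frame")
  comp <- cfg$components
  pos <- as.matrix(comp[, c("px", "py", "pz")])
  lf <- leadfield_infinity(model, lf_mont, dipole_set(pos))
  # radial unit moments; calibrated so the infinity-referenced map peaks at
  # the stated microvolt value at the calibration electrode
  gain <- matrix(0, nrow(lf$gain), nrow(comp),
                 dimnames = list(lf$labels, comp$name))
  for (i in seq_len(nrow(comp))) {
    u <- pos[i, ] / sqrt(sum(pos[i, ]^2))
    g <- lf$gain[, (3 * i - 2):(3 * i)] %*% u
    ref_val <- g[comp$amp_electrode[i], 1]
    if (abs(ref_val) < 1e-12)
      stop("component ", comp$name[i],
           " produces no potential at its calibration electrode")
    gain[, i] <- g / ref_val      # 1 uV at the calibration electrode
  }
  list(model = model, montage63 = mont63, scalp61 = scalp61,
       lf_montage = lf_mont, comp_gain = gain)
}

#' Generate one subject of the synthetic oddball cohort
#'
#' @param cfg A [synth_config()].
#' @param subject Subject index (1-based); the random stream is derived
#'   deterministically from `cfg$seed` and this index.
#' @param fwd Optional precomputed forward machinery (internal reuse).
#' @return List: `recordings` (one FCz-referenced 63-channel
#'   `scalp_recording` per session), `events` (per session data frame
#'   `onset_s`, `condition`), `ground_truth` (per-component subject
#'   amplitudes and latencies, artifact trials).
#' @export
generate_subject <- function(cfg, subject, fwd = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(fwd)) fwd <- synth_forward(cfg)
  set.seed(subject_seed(cfg$seed, subject))
  fs <- cfg$sampling_rate
  comp <- cfg$components
  nc <- nrow(comp)
  amp_mult <- exp(stats::rnorm(nc, 0, cfg$amp_jitter_sd))
  lat_shift <- stats::rnorm(nc, 0, cfg$lat_jitter_sd)

  trial_s <- cfg$cue_s + cfg$fixation_s + cfg$stimulus_s
  stim_offset <- cfg$cue_s + cfg$fixation_s
  session_s <- cfg$lead_in_s + cfg$trials_per_session * trial_s +
    cfg$lead_out_s
  n_samp <- round(session_s * fs)
  n_target <- round(cfg$trials_per_session * cfg$target_fraction)

  labels63 <- fwd$montage63$label
  scalp_labels <- fwd$scalp61$label
  eog_labels <- setdiff(labels63, scalp_labels)
  g_fcz <- fwd$comp_gain[scalp_labels, , drop = FALSE] -
    matrix(fwd$comp_gain["FCz", ], length(scalp_labels), nc, byrow = TRUE)

  recordings <- list(); events <- list(); artifact_trials <- list()
  for (ses in seq_len(cfg$sessions)) {
    cond <- sample(c(rep("target", n_target),
                     rep("standard", cfg$trials_per_session - n_target)))
    onsets <- cfg$lead_in_s + (seq_len(cfg$trials_per_session) - 1) * trial_s +
      stim_offset
    # component signal, built sparsely around each stimulus
    v <- matrix(0, length(scalp_labels), n_samp)
    for (tr in seq_len(cfg$trials_per_session)) {
      for (i in seq_len(nc)) {
        is_target <- cond[tr] == "target"
        a <- if (is_target) comp$amp_target_uv[i] else comp$amp_standard_uv[i]
        if (a == 0) next
        t0 <- onsets[tr] + comp$t0_s[i] + lat_shift[i] +
          if (is_target) 0 else comp$lag_standard_s[i]
        hw <- comp$gamma[i] / (2 * pi * comp$f_hz[i]) * 3   # envelope support
        i1 <- max(1, floor((t0 - hw) * fs) + 1)
        i2 <- min(n_samp, ceiling((t0 + hw) * fs) + 1)
        tt <- (seq(i1, i2) - 1) / fs
        u <- 2 * pi * comp$f_hz[i] * (tt - t0)
        h <- exp(-(u / comp$gamma[i])^2) * cos(u)
        v[, i1:i2] <- v[, i1:i2] +
          (a * amp_mult[i]) * outer(g_fcz[, i], h)
      }
    }
    # dipolar background: random deep dipoles, low-pass-filtered Gaussian
    # time courses, scaled to the configured median per-channel RMS
    if (cfg$noise_rms_uv > 0) {
      ndip <- cfg$noise_dipoles
      # uniform in the ball of radius 0.6 (deep sources)
      dirs <- matrix(stats::rnorm(ndip * 3), ndip, 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      npos <- dirs * (0.6 * stats::runif(ndip)^(1 / 3))
      nori <- matrix(stats::rnorm(nrow(npos) * 3), ncol = 3)
      nori <- nori / sqrt(rowSums(nori^2))
      nlf <- leadfield_infinity(fwd$model, fwd$lf_montage, dipole_set(npos))
      gn <- sapply(seq_len(nrow(npos)), function(j)
        nlf$gain[, (3 * j - 2):(3 * j)] %*% nori[j, ])
      gn_fcz <- gn[match(scalp_labels, fwd$lf_montage$label), , drop = FALSE] -
        matrix(gn[match("FCz", fwd$lf_montage$label), ],
               length(scalp_labels), nrow(npos), byrow = TRUE)
      bf <- signal::butter(2, cfg$noise_lowpass_hz / (fs / 2), type = "low")
      tcn <- sapply(seq_len(nrow(npos)), function(j)
        signal::filter(bf, stats::rnorm(n_samp)))
      bg <- gn_fcz %*% t(tcn)
      sc <- cfg$noise_rms_uv / stats::median(sqrt(rowMeans(bg^2)))
      v <- v + sc * bg
    }
    if (cfg$sensor_noise_uv > 0)
      v <- v + matrix(stats::rnorm(length(v), 0, cfg$sensor_noise_uv),
                      nrow(v))
    # EOG channels and blink artifacts leaking onto frontal sites
    eog <- matrix(stats::rnorm(length(eog_labels) * n_samp, 0, 10),
                  length(eog_labels), n_samp,
                  dimnames = list(eog_labels, NULL))
    art <- which(stats::runif(cfg$trials_per_session) < cfg$artifact_rate)
    if (length(art)) {
      leak <- 120 * pmax(0, fwd$scalp61$y)^4
      for (tr in art) {
        bt <- onsets[tr] + stats::runif(1, -0.2, 0.6)
        idx <- max(1, round((bt - 0.15) * fs)):min(n_samp, round((bt + 0.15) * fs))
        bw <- exp(-((idx / fs - bt) / 0.06)^2)
        v[, idx] <- v[, idx] + outer(leak, bw)
        eog["VEOG", idx] <- eog["VEOG", idx] + 150 * bw
      }
    }
    full <- rbind(v, eog)[match(labels63, c(scalp_labels, eog_labels)), ]
    recordings[[ses]] <- scalp_recording(
      full, labels63, fs, reference = "FCz",
      scalp = fwd$montage63$scalp)
    events[[ses]] <- data.frame(onset_s = onsets, condition = cond,
                                stringsAsFactors = FALSE)
    artifact_trials[[ses]] <- art
  }
  list(recordings = recordings, events = events,
       ground_truth = list(
         subject = subject,
         components = data.frame(comp[, c("name", "t0_s")],
                                 amp_mult = amp_mult,
                                 latency_s = comp$t0_s + lat_shift),
         artifact_trials = artifact_trials))
}

#' Generate a full synthetic cohort
#'
#' Convenience wrapper holding all subjects in memory; for large default
#' cohorts, prefer iterating [generate_subject()] and processing each subject
#' before generating the next.
#'
#' @param cfg A [synth_config()].
#' @param subjects Subject indices to generate.
#' @return List of class `synth_cohort` with one [generate_subject()] result
#'   per subject, plus `config`.
#' @export
generate_cohort <- function(cfg, subjects = seq_len(cfg$n_subjects)) {
  fwd <- synth_forward(cfg)
  out <- lapply(subjects, function(s) generate_subject(cfg, s, fwd = fwd))
  names(out) <- paste0("sub", subjects)
  structure(list(subjects = out, config = cfg), class = "synth_cohort")
}

#' Write a cohort to disk as plain-text files
#'
#' Layout: `<dir>/sub-XX/ses-Y_eeg.csv` (channels x samples, label column
#' first), `ses-Y_events.csv`, one shared `montage.sfp`, and per-subject
#' `ground_truth.json`.
#'
#' @param cohort A `synth_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_sfp(easycap63_montage(), file.path(dir, "montage.sfp"))
  for (nm in names(cohort$subjects)) {
    sub <- cohort$subjects[[nm]]
    sdir <- file.path(dir, sub("sub", "sub-", nm))
    dir.create(sdir, showWarnings = FALSE)
    for (ses in seq_along(sub$recordings)) {
      rec <- sub$recordings[[ses]]
      df <- data.frame(label = rec$labels, rec$voltages,
                       check.names = FALSE)
      utils::write.csv(df, file.path(sdir, sprintf("ses-%d_eeg.csv", ses)),
                       row.names = FALSE)
      utils::write.csv(sub$events[[ses]],
                       file.path(sdir, sprintf("ses-%d_events.csv", ses)),
                       row.names = FALSE)
    }
    gt <- sub$ground_truth
    gt$sampling_rate <- cohort$config$sampling_rate
    gt$reference <- "FCz"
    jsonlite::write_json(gt, file.path(sdir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  invisible(dir)
}

#' Read one session written by [write_fixture()]
#'
#' @param eeg_csv Path to a `ses-*_eeg.csv` file.
#' @param sampling_rate Sampling rate of the stored recording, Hz.
#' @param reference Reference tag of the stored recording.
#' @return A `scalp_recording`.
#' @export
read_fixture_recording <- function(eeg_csv, sampling_rate = 500,
                                   reference = "FCz") {
  df <- utils::read.csv(eeg_csv, check.names = FALSE)
  labels <- df$label
  v <- as.matrix(df[, -1])
  scalp_recording(v, labels, sampling_rate, reference = reference,
                  scalp = !(labels %in% c("VEOG", "HEOG")))
}
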