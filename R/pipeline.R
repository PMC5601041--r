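# End-to-end oddball study driver: generates (or receives) subjects, runs the
# preprocessing / re-referencing / epoching / averaging chain per reference,
# and collects P300 measures, CM trajectories and traveling velocities.
# Subjects are processed one at a time so the full default cohort never has
# to be held in memory.

#' REST operator for the synthetic recording system
#'
#' Builds the transfer matrix standardizing FCz-referenced recordings of the
#' 61 scalp channels to the reference at infinity, using the packaged montage
#' (plus the FCz reference position) and the default dipole grid as source
#' model.
#'
#' @param model A [head_model()].
#' @param grid Source grid for the minimum-norm model.
#' @param recorded_reference Label of the recording reference electrode.
#' @param sv_cutoff Pseudoinverse cutoff.
#' @return A `rest_operator` built for the recorded reference.
#' @export
recording_rest_operator <- function(model = head_model(),
                                    grid = build_dipole_grid(),
                                    recorded_reference = "FCz",
                                    sv_cutoff = 1e-4) {
  mont63 <- easycap63_montage()
  scalp <- mont63[mont63$scalp, ]
  class(scalp) <- c("eeg_montage", "data.frame")
  lf_mont <- rbind(scalp, standard_electrode(recorded_reference))
  class(lf_mont) <- c("eeg_montage", "data.frame")
  lf <- leadfield_infinity(model, lf_mont, grid)
  lf_ref <- leadfield_for_reference(lf, recorded_reference)
  rest_transfer_matrix(lf, lf_ref, sv_cutoff = sv_cutoff)
}

#' Run the oddball ERP analysis for one subject
#'
#' Chain per session: low-pass filter and decimate, then per reference:
#' re-reference (REST through the supplied operator; AR/LM as common
#' references), epoch with baseline correction and +/-75 uV rejection,
#' average per condition.  From the averages: P300 amplitude/latency and the
#' 2D CM trajectory (200-800 ms) with its traveling velocity.
#'
#' @param subject_data A [generate_subject()] result (or an equivalent list
#'   of `recordings` and `events`).
#' @param subject Subject identifier used in the output tables.
#' @param rest_op A [recording_rest_operator()].
#' @param references Character vector from `{"REST", "AR", "LM"}`.
#' @param lowpass,decimate_to Preprocessing parameters.
#' @param reject Epoch rejection threshold, uV.
#' @param cm_window CM trajectory window, seconds post-stimulus.
#' @return List: `p300` (per reference x condition), `cm` (long table of
#'   trajectory + speed samples), `retention` (epoch counts).
#' @export
analyze_subject <- function(subject_data, subject, rest_op,
                            references = c("REST", "AR", "LM"),
                            lowpass = 6, decimate_to = 250, reject = 75,
                            cm_window = c(0.2, 0.8)) {
  cmm <- cm_montage(easycap63_montage())
  p300_rows <- list(); cm_rows <- list(); ret_rows <- list()
  # preprocess each session once; re-referencing commutes with the
  # (linear, per-channel) filtering
  pre <- lapply(subject_data$recordings, preprocess,
                lowpass = lowpass, decimate_to = decimate_to)
  for (ref in references) {
    reref <- lapply(pre, function(rec) {
      if (ref == "REST") apply_rest(rec, rest_op)
      else apply_common_reference(rec, ref)
    })
    eps <- mapply(function(rec, ev) make_epochs(rec, ev, reject = reject),
                  reref, subject_data$events, SIMPLIFY = FALSE)
    data <- do.call(abind3, lapply(eps, `[[`, "data"))
    ep <- eps[[1]]
    ep$data <- data
    ep$condition <- unlist(lapply(eps, `[[`, "condition"))
    ep$rejected <- unlist(lapply(eps, `[[`, "rejected"))
    for (cond in c("target", "standard")) {
      erp <- average_erp(ep, cond)
      p3 <- p300_measures(erp)
      p300_rows[[paste(ref, cond)]] <- data.frame(
        subject = subject, reference = ref, condition = cond,
        amplitude = p3$amplitude, latency = p3$latency,
        n_averaged = attr(erp, "n_averaged"))
      traj <- cm_trajectory(erp, cmm, window = cm_window,
                            dimensionality = "2D")
      vel <- traveling_velocity(traj)
      cm_rows[[paste(ref, cond)]] <- data.frame(
        subject = subject, reference = ref, condition = cond,
        time = traj$time, x = traj$x, y = traj$y, defined = traj$defined,
        speed = c(NA_real_, vel$speed))
    }
    ret_rows[[ref]] <- data.frame(
      subject = subject, reference = ref,
      n_trials = length(ep$condition), n_rejected = sum(ep$rejected))
  }
  list(p300 = do.call(rbind, p300_rows),
       cm = do.call(rbind, cm_rows),
       retention = do.call(rbind, ret_rows))
}

# bind 3D arrays along the third dimension
abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  n3 <- sum(vapply(xs, function(x) dim(x)[3], 0L))
  out <- array(NA_real_, c(d[1], d[2], n3), dimnames = dimnames(xs[[1]]))
  at <- 0L
  for (x in xs) {
    out[, , at + seq_len(dim(x)[3])] <- x
    at <- at + dim(x)[3]
  }
  out
}

#' Run the full synthetic oddball study
#'
#' Generates each subject of the configured cohort, analyzes it with
#' [analyze_subject()], and assembles the cohort-level tables: P300 measures,
#' CM/velocity samples, group-mean velocity curves per condition and
#' reference, stage statistics and cross-condition correlations.
#'
#' @param cfg A [synth_config()].
#' @param references References analyzed.
#' @param stages A [stage_windows()].
#' @param rest_op Optional precomputed [recording_rest_operator()].
#' @param verbose Print per-subject progress.
#' @return List of class `oddball_study`: `p300`, `cm`, `retention`,
#'   `stage` (output of [stage_statistics()]), `correlation` (per reference,
#'   output of [condition_correlation()] on the group-mean REST velocity
#'   curves), `group_velocity` (long table), `config`.
#' @export
oddball_study <- function(cfg = synth_config(),
                          references = c("REST", "AR", "LM"),
                          stages = stage_windows(), rest_op = NULL,
                          verbose = FALSE) {
  if (is.null(rest_op)) rest_op <- recording_rest_operator()
  fwd <- synth_forward(cfg)
  p300 <- list(); cm <- list(); ret <- list()
  for (s in seq_len(cfg$n_subjects)) {
    if (verbose) message("subject ", s, "/", cfg$n_subjects)
    sd <- generate_subject(cfg, s, fwd = fwd)
    res <- analyze_subject(sd, s, rest_op, references = references)
    p300[[s]] <- res$p300; cm[[s]] <- res$cm; ret[[s]] <- res$retention
  }
  p300 <- do.call(rbind, c(p300, make.row.names = FALSE))
  cm <- do.call(rbind, c(cm, make.row.names = FALSE))
  ret <- do.call(rbind, c(ret, make.row.names = FALSE))
  # group-mean velocity curves
  gv <- stats::aggregate(speed ~ reference + condition + time, cm, mean,
                         na.rm = TRUE, na.action = stats::na.pass)
  stage <- stage_statistics(cm, stages = stages)
  correlation <- list()
  for (ref in references) {
    vt <- gv[gv$reference == ref & gv$condition == "target", ]
    vs <- gv[gv$reference == ref & gv$condition == "standard", ]
    correlation[[ref]] <- condition_correlation(
      vt[order(vt$time), ], vs[order(vs$time), ])
  }
  structure(
    list(p300 = p300, cm = cm, retention = ret, stage = stage,
         correlation = correlation, group_velocity = gv, config = cfg),
    class = "oddball_study")
}

#' @export
print.oddball_study <- function(x, ...) {
  cat(sprintf("Oddball study: %d subjects, references %s\n",
              x$config$n_subjects,
              paste(unique(x$p300$reference), collapse = ", ")))
  amp <- stats::aggregate(amplitude ~ reference + condition, x$p300, mean)
  cat("Mean P300 amplitude (uV):\n"); print(amp, row.names = FALSE)
  invisible(x)
}
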