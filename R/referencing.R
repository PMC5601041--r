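# Re-referencing of scalp recordings: common references (AR, LM, vertex /
# recorded channel) and the reference electrode standardization technique
# (REST), which rebuilds the infinity-referenced potentials through a
# minimum-norm source estimate.

#' Multichannel scalp recording
#'
#' @param voltages Channels x samples matrix, microvolts.
#' @param labels Channel names (one per row).
#' @param sampling_rate Sampling rate, Hz.
#' @param reference Reference tag: `"infinity"`, `"AR"`, `"LM"`, or a channel
#'   label (e.g. `"Cz"`, `"FCz"`) for data recorded against that electrode.
#' @param scalp Logical per channel; non-scalp channels (EOG) are excluded
#'   from the average reference.
#' @param t0 Time of the first sample, seconds (0 for continuous data;
#'   negative for stimulus-locked averages with a pre-stimulus baseline).
#' @return An object of class `scalp_recording`.
#' @export
scalp_recording <- function(voltages, labels, sampling_rate,
                            reference = "infinity",
                            scalp = rep(TRUE, length(labels)), t0 = 0) {
  voltages <- as.matrix(voltages)
  stopifnot(nrow(voltages) == length(labels), length(scalp) == length(labels))
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be positive")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  rownames(voltages) <- labels
  structure(
    list(voltages = voltages, labels = as.character(labels),
         sampling_rate = sampling_rate,
         reference = canonical_reference(reference),
         scalp = as.logical(scalp), t0 = t0),
    class = "scalp_recording")
}

#' @export
print.scalp_recording <- function(x, ...) {
  cat(sprintf("Scalp recording: %d channels x %d samples @ %g Hz, reference %s\n",
              nrow(x$voltages), ncol(x$voltages), x$sampling_rate, x$reference))
  invisible(x)
}

#' Sample times of a recording
#' @param rec A `scalp_recording`.
#' @return Numeric vector of sample times, seconds.
#' @export
recording_times <- function(rec) {
  rec$t0 + (seq_len(ncol(rec$voltages)) - 1) / rec$sampling_rate
}

#' Apply a common (scalp) reference
#'
#' Subtracts, per sample, the reference combination from every channel:
#' `"AR"` the mean of all scalp channels, `"LM"` the mean of TP9 and TP10,
#' `"CZ"`/`"Cz"` (or any channel label) that channel.
#'
#' @param rec A `scalp_recording`.
#' @param reference `"AR"`, `"LM"`, or a channel label.
#' @return The re-referenced `scalp_recording`.
#' @export
apply_common_reference <- function(rec, reference) {
  stopifnot(inherits(rec, "scalp_recording"))
  reference <- canonical_reference(reference)
  v <- rec$voltages
  ref <- switch(reference,
    AR = colMeans(v[rec$scalp, , drop = FALSE]),
    LM = {
      if (!all(c("TP9", "TP10") %in% rec$labels))
        stop("LM reference requires channels TP9 and TP10; ",
             "they are not present in this recording")
      colMeans(v[c("TP9", "TP10"), , drop = FALSE])
    },
    {
      if (!(reference %in% rec$labels))
        stop("reference channel '", reference, "' not in the recording")
      v[reference, ]
    })
  rec$voltages <- sweep(v, 2, ref, "-")
  rec$reference <- reference
  rec
}

#' Moore-Penrose pseudoinverse by singular value decomposition
#'
#' Singular values below `cutoff` times the largest are truncated.
#'
#' @param a Matrix.
#' @param cutoff Relative singular-value cutoff.
#' @return List with the pseudoinverse `pinv` and the retained `rank`.
#' @keywords internal
svd_pinv <- function(a, cutoff = 1e-4) {
  s <- svd(a)
  if (s$d[1] == 0) stop("degenerate input: all singular values are zero")
  keep <- s$d > cutoff * s$d[1]
  r <- sum(keep)
  pinv <- s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
  list(pinv = pinv, rank = r)
}

#' REST transfer matrix
#'
#' Builds the linear operator `U = G %*% pinv(G_ref)` that standardizes
#' recordings made against a scalp reference to the reference at infinity:
#' the minimum-norm source estimate `S = pinv(G_ref) V_ref` is re-projected
#' through the infinity-reference lead field `G`.
#'
#' @param lf_inf Infinity-reference `lead_field`.
#' @param lf_ref The same lead field re-referenced with
#'   [leadfield_for_reference()] to the reference the data carry.
#' @param sv_cutoff Relative singular-value cutoff for the pseudoinverse.
#' @return An object of class `rest_operator`: `U` (channels x channels),
#'   `built_for` (the reference tag of `lf_ref`), `labels`, `source_rank`.
#' @export
rest_transfer_matrix <- function(lf_inf, lf_ref, sv_cutoff = 1e-4) {
  stopifnot(inherits(lf_inf, "lead_field"), inherits(lf_ref, "lead_field"))
  if (!identical(lf_inf$reference, "infinity"))
    stop("lf_inf must be an infinity-reference lead field")
  if (identical(lf_ref$reference, "infinity"))
    stop("lf_ref must carry a scalp reference (AR, LM, or a channel)")
  if (!identical(dim(lf_inf$gain), dim(lf_ref$gain)) ||
      !identical(lf_inf$labels, lf_ref$labels))
    stop("lead fields must share montage and source grid")
  if (all(lf_ref$gain == 0)) stop("degenerate input: all-zero lead field")
  p <- svd_pinv(lf_ref$gain, cutoff = sv_cutoff)
  U <- lf_inf$gain %*% p$pinv
  dimnames(U) <- list(lf_inf$labels, lf_inf$labels)
  structure(
    list(U = U, built_for = lf_ref$reference, labels = lf_inf$labels,
         source_rank = p$rank, sv_cutoff = sv_cutoff),
    class = "rest_operator")
}

#' @export
print.rest_operator <- function(x, ...) {
  cat(sprintf("REST operator: %d channels, built for reference %s, source rank %d\n",
              nrow(x$U), x$built_for, x$source_rank))
  invisible(x)
}

#' Re-reference a recording to infinity with REST
#'
#' Applies a [rest_transfer_matrix()] to a recording carrying the reference
#' the operator was built for.  Channels present in the operator but absent
#' from the recording must be the physical reference electrode itself (whose
#' signal is identically zero); they are filled with zeros before the
#' multiplication and dropped afterwards.
#'
#' @param rec A `scalp_recording` whose `reference` matches `op$built_for`.
#' @param op A `rest_operator`.
#' @return The recording re-expressed against the reference at infinity.
#' @export
apply_rest <- function(rec, op) {
  stopifnot(inherits(rec, "scalp_recording"), inherits(op, "rest_operator"))
  if (!identical(rec$reference, op$built_for))
    stop("recording reference '", rec$reference,
         "' does not match the reference the REST operator was built for ('",
         op$built_for, "')")
  extra <- setdiff(op$labels, rec$labels)
  if (length(extra) && !identical(extra, op$built_for))
    stop("operator channels missing from the recording: ",
         paste(extra, collapse = ", "))
  scalp_idx <- match(op$labels, rec$labels)          # NA for the reference row
  v <- matrix(0, length(op$labels), ncol(rec$voltages))
  v[!is.na(scalp_idx), ] <- rec$voltages[scalp_idx[!is.na(scalp_idx)], ]
  out <- op$U %*% v
  keep <- op$labels %in% rec$labels
  rest_v <- out[keep, , drop = FALSE]
  # carry through any channels (EOG) that are not part of the operator
  passthrough <- setdiff(rec$labels, op$labels)
  ord <- match(rec$labels, c(op$labels[keep], passthrough))
  full <- rbind(rest_v, rec$voltages[passthrough, , drop = FALSE])[ord, , drop = FALSE]
  scalp_recording(full, rec$labels, rec$sampling_rate,
                  reference = "infinity", scalp = rec$scalp, t0 = rec$t0)
}
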