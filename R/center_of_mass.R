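# Positive center of mass of scalp topographies, its trajectory, traveling
# velocity, and the relative CM error between references.
#
# The positive CM at time t is the electrode-coordinate average weighted by
# the strictly positive channel voltages m_i(t) > 0:
#   X(t) = sum(a_i m_i) / sum(m_i),  and likewise Y(t), Z(t),
# with (a_i, b_i, c_i) the unit-sphere electrode coordinates.  When no
# channel is positive the CM is undefined (a flagged, valid outcome).

#' Positive center of mass of one scalp topography
#'
#' @param voltages Per-channel voltages (microvolts), one per montage row.
#' @param montage An `eeg_montage` (or positions matrix with columns x,y,z).
#' @param dimensionality `"2D"` (coordinates x, y) or `"3D"`.
#' @return Named numeric vector of CM coordinates, or `NA`s if no channel is
#'   strictly positive.
#' @examples
#' m <- cm_montage(easycap63_montage())
#' positive_cm(rep(1, nrow(m)), m)           # centroid of all electrodes
#' positive_cm(rep(-1, nrow(m)), m)          # undefined -> NAs
#' @export
positive_cm <- function(voltages, montage, dimensionality = c("2D", "3D")) {
  dimensionality <- match.arg(dimensionality)
  P <- if (is.matrix(montage)) montage else montage_positions(montage)
  stopifnot(length(voltages) == nrow(P))
  nd <- if (dimensionality == "2D") 2L else 3L
  pos <- voltages > 0
  if (!any(pos)) return(stats::setNames(rep(NA_real_, nd), c("x", "y", "z")[1:nd]))
  w <- voltages[pos]
  stats::setNames(colSums(P[pos, 1:nd, drop = FALSE] * w) / sum(w),
                  c("x", "y", "z")[1:nd])
}

# Vectorized positive CM over the columns of a channels x samples matrix.
# Returns list(coords = samples x d, defined = logical).
cm_of_matrix <- function(v, P, nd = 2L) {
  vp <- pmax(v, 0)
  den <- colSums(vp)
  defined <- den > 0
  num <- t(P[, 1:nd, drop = FALSE]) %*% vp          # d x samples
  coords <- t(sweep(num, 2, ifelse(defined, den, 1), "/"))
  coords[!defined, ] <- NA_real_
  colnames(coords) <- c("x", "y", "z")[1:nd]
  list(coords = coords, defined = defined)
}

#' Center-of-mass trajectory of a recording
#'
#' Computes one positive CM per sample over a time window, at the recording's
#' sampling rate.  The window is half-open, `[start, end)`.
#'
#' @param rec A `scalp_recording` (typically an averaged ERP with `t0` set to
#'   the epoch start).
#' @param montage The CM montage; every montage label must be a channel of
#'   `rec`.  EOG and mastoid channels should already have been dropped (see
#'   [cm_montage()]).
#' @param window Time interval `c(start, end)` in seconds (stimulus onset is
#'   time 0 for epoched data).
#' @param dimensionality `"2D"` or `"3D"`.
#' @return A data frame of class `cm_trajectory`: `time`, coordinates, and
#'   `defined`; attributes `sampling_rate` and `dimensionality`.
#' @export
cm_trajectory <- function(rec, montage, window = c(0.2, 0.8),
                          dimensionality = c("2D", "3D")) {
  dimensionality <- match.arg(dimensionality)
  stopifnot(inherits(rec, "scalp_recording"), length(window) == 2,
            window[2] > window[1])
  montage <- as_montage(montage)
  if (!all(montage$label %in% rec$labels))
    stop("montage channels missing from the recording: ",
         paste(setdiff(montage$label, rec$labels), collapse = ", "))
  times <- recording_times(rec)
  keep <- times >= window[1] - 1e-9 & times < window[2] - 1e-9
  if (!any(keep)) stop("window outside the recording")
  v <- rec$voltages[montage$label, keep, drop = FALSE]
  P <- montage_positions(montage)
  nd <- if (dimensionality == "2D") 2L else 3L
  cm <- cm_of_matrix(v, P, nd)
  out <- data.frame(time = times[keep], cm$coords, defined = cm$defined)
  attr(out, "sampling_rate") <- rec$sampling_rate
  attr(out, "dimensionality") <- dimensionality
  class(out) <- c("cm_trajectory", "data.frame")
  out
}

#' Traveling velocity of a CM trajectory
#'
#' Physical speed of the CM point between consecutive samples after scaling
#' the normalized head coordinates to a sphere of radius `scale_radius`:
#' `speed(t) = scale_radius * ||coords(t) - coords(t-1)|| / dt`, in m/s.
#' The speed is undefined (NA) across transitions where either CM is
#' undefined.
#'
#' @param traj A [cm_trajectory()] (or data frame with `time`, coordinate
#'   columns and `defined`).
#' @param scale_radius Physical head radius in meters (default 0.10 m).
#' @return Data frame `time`, `speed` with one row per sample transition
#'   (length = trajectory length - 1); `time` is the time of the later
#'   sample.
#' @export
traveling_velocity <- function(traj, scale_radius = 0.10) {
  stopifnot(nrow(traj) >= 2)
  coord_cols <- intersect(c("x", "y", "z"), names(traj))
  dt <- diff(traj$time)
  if (any(dt <= 0)) stop("sample times must be strictly increasing (dt > 0)")
  xy <- as.matrix(traj[, coord_cols, drop = FALSE])
  step <- sqrt(rowSums(diff(xy)^2))
  ok <- traj$defined[-nrow(traj)] & traj$defined[-1]
  speed <- ifelse(ok, scale_radius * step / dt, NA_real_)
  data.frame(time = traj$time[-1], speed = speed)
}

#' Relative CM error between a transformed and the infinity reference
#'
#' `Err = ||CM_ref - CM_ir|| / ||CM_ir||`, the Euclidean distance between the
#' two CM points relative to the norm of the infinity-reference CM.
#'
#' @param cm_ref CM coordinates under the transformed reference.
#' @param cm_ir CM coordinates under the reference at infinity (the
#'   standard).
#' @return Nonnegative scalar.
#' @export
cm_error <- function(cm_ref, cm_ir) {
  stopifnot(length(cm_ref) == length(cm_ir))
  if (anyNA(cm_ref) || anyNA(cm_ir))
    stop("CM error requires both CMs to be defined")
  n_ir <- sqrt(sum(cm_ir^2))
  if (n_ir == 0)
    stop("undefined CM error: infinity-reference CM has zero norm")
  sqrt(sum((cm_ref - cm_ir)^2)) / n_ir
}

#' Write a CM trajectory (with optional velocity) to CSV
#'
#' @param traj A [cm_trajectory()].
#' @param path Output path.
#' @param velocity Optional output of [traveling_velocity()] to merge.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, velocity = NULL) {
  out <- as.data.frame(traj)
  if (!is.null(velocity))
    out$speed <- c(NA_real_, velocity$speed)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
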