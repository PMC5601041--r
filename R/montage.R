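# Electrode montages: ideal spherical extended 10/20 positions and .sfp I/O.
#
# Positions are constructed on the unit sphere from the classical landmark
# arcs: x to the right ear, y to the nasion, z to the vertex.  They are an
# idealized fixture of standard angular placements, not digitized ground
# truth for any particular cap.

#' Electrode montage container
#'
#' @param labels Unique channel names.
#' @param positions n x 3 matrix of Cartesian coordinates; scalp positions
#'   are normalized to the unit sphere.
#' @param scalp Logical vector, `FALSE` for non-scalp channels (EOG).
#' @return A data frame of class `eeg_montage` with columns
#'   `label, x, y, z, scalp`.
#' @export
montage <- function(labels, positions, scalp = rep(TRUE, length(labels))) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, nrow(positions) == length(labels),
            length(scalp) == length(labels))
  if (anyDuplicated(labels))
    stop("montage labels must be unique")
  r <- sqrt(rowSums(positions^2))
  if (any(r <= 0)) stop("zero-length electrode position")
  positions <- positions / r   # project to the unit sphere
  out <- data.frame(label = as.character(labels),
                    x = positions[, 1], y = positions[, 2], z = positions[, 3],
                    scalp = as.logical(scalp),
                    stringsAsFactors = FALSE)
  class(out) <- c("eeg_montage", "data.frame")
  out
}

as_montage <- function(x) {
  if (inherits(x, "eeg_montage")) return(x)
  stopifnot(is.data.frame(x), all(c("label", "x", "y", "z") %in% names(x)))
  montage(x$label, as.matrix(x[, c("x", "y", "z")]),
          scalp = if ("scalp" %in% names(x)) x$scalp else rep(TRUE, nrow(x)))
}

#' Positions of montage electrodes as a matrix
#' @param m An `eeg_montage`.
#' @return n x 3 numeric matrix with label rownames.
#' @export
montage_positions <- function(m) {
  m <- as_montage(m)
  p <- as.matrix(m[, c("x", "y", "z")])
  rownames(p) <- m$label
  p
}

# Circle through three points on the unit sphere; interpolate at arc fraction
# s in [0, 1] from `a` to `b` (both on the circle through a, mid, b).
arc_point <- function(a, mid, b, s) {
  n <- cross3(mid - a, b - a)
  n <- n / sqrt(sum(n^2))
  h <- sum(n * a)
  cen <- h * n
  rho <- sqrt(max(0, 1 - h^2))
  u <- (a - cen) / rho
  v <- cross3(n, u)
  ang_b <- atan2(sum((b - cen) * v), sum((b - cen) * u))
  if (ang_b < 0) ang_b <- ang_b + 2 * pi
  th <- s * ang_b
  cen + rho * (cos(th) * u + sin(th) * v)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Ideal spherical positions for the extended 10/20 labels used here.
# Midline and coronal electrodes lie on the nasion-inion and ear-to-ear great
# circles at 10% steps; the outer 10% ring is the z = sin(18 deg) circle;
# interior rows subdivide the arc from the ring electrode through the midline
# electrode of the same row.
standard_positions_1020 <- function() {
  deg <- pi / 180
  pos <- list()
  # midline: angle alpha from nasion along the x = 0 great circle
  mid_alpha <- c(Fpz = 18, AFz = 36, Fz = 54, FCz = 72, Cz = 90,
                 CPz = 108, Pz = 126, POz = 144, Oz = 162)
  for (nm in names(mid_alpha)) {
    a <- mid_alpha[[nm]] * deg
    pos[[nm]] <- c(0, cos(a), sin(a))
  }
  # coronal: angle beta from the left ear along the y = 0 great circle
  cor_beta <- c(T7 = 18, C5 = 36, C3 = 54, C1 = 72,
                C2 = 108, C4 = 126, C6 = 144, T8 = 162)
  for (nm in names(cor_beta)) {
    b <- cor_beta[[nm]] * deg
    pos[[nm]] <- c(-cos(b), 0, sin(b))
  }
  # outer 10% ring: z = sin(18 deg), azimuth phi in the xy-plane
  ring_phi <- c(Fpz = 90, Fp1 = 108, AF7 = 126, F7 = 144, FT7 = 162,
                T7 = 180, TP7 = 198, P7 = 216, PO7 = 234, O1 = 252,
                Oz = 270, O2 = 288, PO8 = 306, P8 = 324, TP8 = 342,
                T8 = 0, FT8 = 18, F8 = 36, AF8 = 54, Fp2 = 72)
  zr <- sin(18 * deg); cr <- cos(18 * deg)
  for (nm in names(ring_phi)) {
    p <- ring_phi[[nm]] * deg
    pos[[nm]] <- c(cr * cos(p), cr * sin(p), zr)
  }
  # interior rows: equal arc subdivisions between ring and midline electrodes
  subdiv <- list(
    list(left = "F7",  mid = "Fz",  names = c("F5", "F3", "F1"),   frac = c(1, 2, 3) / 4),
    list(left = "FT7", mid = "FCz", names = c("FC5", "FC3", "FC1"), frac = c(1, 2, 3) / 4),
    list(left = "TP7", mid = "CPz", names = c("CP5", "CP3", "CP1"), frac = c(1, 2, 3) / 4),
    list(left = "P7",  mid = "Pz",  names = c("P5", "P3", "P1"),   frac = c(1, 2, 3) / 4),
    list(left = "AF7", mid = "AFz", names = "AF3", frac = 0.5),
    list(left = "PO7", mid = "POz", names = "PO3", frac = 0.5))
  mirror <- function(p) c(-p[1], p[2], p[3])
  right_of <- function(lbl) chartr("7531", "8642", lbl)  # F7->F8, FC1->FC2, ...
  for (row in subdiv) {
    L <- pos[[row$left]]; M <- pos[[row$mid]]; R <- mirror(L)
    for (i in seq_along(row$names)) {
      p <- arc_point(L, M, R, row$frac[i] / 2)   # fractions of the half-arc L->M
      pos[[row$names[i]]] <- p
      pos[[right_of(row$names[i])]] <- mirror(p)
    }
  }
  # mastoid electrodes: 10% (18 deg) below TP7/TP8 at the same azimuth
  zb <- sin(-18 * deg); cb <- cos(-18 * deg)
  pos[["TP9"]]  <- c(cb * cos(198 * deg), cb * sin(198 * deg), zb)
  pos[["TP10"]] <- c(cb * cos(342 * deg), cb * sin(342 * deg), zb)
  pos
}

#' Packaged extended 10/20 recording montage
#'
#' The 63-channel cap emulated by the synthetic cohort: 59 scalp electrodes
#' (extended 10/20, FCz and AFz reserved as reference and ground), the two
#' mastoids TP9/TP10, and two EOG placeholder channels (VEOG, HEOG) flagged
#' as non-scalp.  Positions are idealized unit-sphere placements (a fixture,
#' not digitized coordinates).
#'
#' @param labels Optional subset of labels to return, in the given order.
#' @return An `eeg_montage`.
#' @examples
#' m <- easycap63_montage()
#' nrow(m)                 # 63
#' nrow(cm_montage(m))     # 59
#' @export
easycap63_montage <- function(labels = NULL) {
  pos <- standard_positions_1020()
  scalp59 <- c("Fp1", "Fpz", "Fp2", "AF7", "AF3", "AF4", "AF8",
               "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
               "FT7", "FC5", "FC3", "FC1", "FC2", "FC4", "FC6", "FT8",
               "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
               "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
               "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
               "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2")
  all_labels <- c(scalp59, "TP9", "TP10", "VEOG", "HEOG")
  deg <- pi / 180
  pos[["VEOG"]] <- c(cos(-18 * deg) * cos(105 * deg),
                     cos(-18 * deg) * sin(105 * deg), sin(-18 * deg))
  pos[["HEOG"]] <- c(cos(-8 * deg) * cos(55 * deg),
                     cos(-8 * deg) * sin(55 * deg), sin(-8 * deg))
  m <- montage(all_labels, do.call(rbind, pos[all_labels]),
               scalp = !(all_labels %in% c("VEOG", "HEOG")))
  if (!is.null(labels)) {
    missing <- setdiff(labels, m$label)
    if (length(missing))
      stop("unknown labels: ", paste(missing, collapse = ", "))
    m <- m[match(labels, m$label), ]
    class(m) <- c("eeg_montage", "data.frame")
  }
  m
}

#' Position of an extended 10/20 electrode not in the recording montage
#'
#' Used for the physical recording reference (FCz) when building lead fields
#' for REST.
#'
#' @param label An extended 10/20 label (e.g. `"FCz"`, `"AFz"`).
#' @return A one-row `eeg_montage`.
#' @export
standard_electrode <- function(label) {
  pos <- standard_positions_1020()
  if (!(label %in% names(pos)))
    stop("no standard position for label '", label, "'")
  montage(label, matrix(pos[[label]], 1))
}

#' Montage used for center-of-mass analysis
#'
#' Drops the EOG channels (VEOG, HEOG) and the mastoids (TP9, TP10),
#' leaving the 59-electrode set used for CM computation.
#'
#' @param m An `eeg_montage`.
#' @return The reduced montage.
#' @export
cm_montage <- function(m) {
  m <- as_montage(m)
  out <- m[!(m$label %in% c("VEOG", "HEOG", "TP9", "TP10")), ]
  rownames(out) <- NULL
  class(out) <- c("eeg_montage", "data.frame")
  out
}

#' Read an .sfp electrode file
#'
#' Plain-text format with one `label x y z` row per electrode.  Scalp
#' positions are normalized to the unit sphere on load; rows whose label is
#' VEOG or HEOG are flagged non-scalp.
#'
#' @param path File path.
#' @return An `eeg_montage`.
#' @export
read_sfp <- function(path) {
  d <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("label", "x", "y", "z"))
  montage(d$label, as.matrix(d[, c("x", "y", "z")]),
          scalp = !(d$label %in% c("VEOG", "HEOG")))
}

#' Write an .sfp electrode file
#'
#' @param m An `eeg_montage`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sfp <- function(m, path) {
  m <- as_montage(m)
  lines <- sprintf("%s\t%.10f\t%.10f\t%.10f", m$label, m$x, m$y, m$z)
  writeLines(lines, path)
  invisible(path)
}
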