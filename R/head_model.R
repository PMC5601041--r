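# Three-concentric-sphere volume conductor and analytic lead fields.

#' Three-concentric-sphere head model
#'
#' Defines the spherical volume conductor used by all forward computations:
#' three concentric shells (brain, skull, scalp) with normalized radii and
#' dimensionless conductivity ratios. The sphere center is the coordinate
#' origin; x points to the right ear, y to the nasion, z to the vertex.
#'
#' @param radii Increasing radii of (inner skull, outer skull, scalp);
#'   the scalp radius must be 1 (normalized head units).
#' @param conductivities Conductivity ratios of (brain, skull, scalp).
#' @return An object of class `head_model`.
#' @examples
#' head_model()
#' @export
head_model <- function(radii = c(0.87, 0.92, 1.0),
                       conductivities = c(1.0, 0.0125, 1.0)) {
  stopifnot(length(radii) == 3, length(conductivities) == 3)
  if (any(diff(radii) <= 0))
    stop("head model radii must be strictly increasing")
  if (abs(radii[3] - 1.0) > 1e-12)
    stop("outermost (scalp) radius must be 1.0 in normalized head units")
  if (any(conductivities <= 0))
    stop("conductivities must be positive")
  structure(
    list(radii = as.numeric(radii),
         conductivities = as.numeric(conductivities),
         origin = c(0, 0, 0)),
    class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat("Three-concentric-sphere head model\n")
  cat(sprintf("  radii (inner skull, outer skull, scalp): %s\n",
              paste(format(x$radii), collapse = ", ")))
  cat(sprintf("  conductivities (brain, skull, scalp):    %s\n",
              paste(format(x$conductivities), collapse = ", ")))
  invisible(x)
}

# Per-degree surface transfer coefficients tau_n for a unit-strength exterior
# harmonic source in the innermost shell, with the source coefficient scaled
# so that its potential at the inner-skull radius r1 is 1 (keeps the linear
# system well conditioned at high degree).  The surface potential expansion is
#   V(1) = (1 / 4 pi sigma_brain) * sum_n c_n (n m_r P_n + m_t P_n^1),
#   c_n  = (tau_n / r1^2) * (b / r1)^(n - 1),
# where b is the dipole eccentricity.  In the homogeneous limit
# tau_n / r1^(n+1) = (2n + 1) / n, the classic bounded-sphere factor.
shell_transfer <- function(model, n_max) {
  r1 <- model$radii[1]; r2 <- model$radii[2]
  s <- model$conductivities
  tau <- numeric(n_max)
  for (n in seq_len(n_max)) {
    q <- (r1 / r2)^n
    p <- (r1 / r2)^(n + 1)
    w <- r2^n
    u <- r2^(n + 1)
    A <- rbind(
      c(1,          -q,             -1,                  0,             0),
      c(s[1] * n,   -s[2] * n * q,   s[2] * (n + 1),     0,             0),
      c(0,           1,              p,                 -w,            -1),
      c(0,           s[2] * n,      -s[2] * (n + 1) * p, -s[3] * n * w, s[3] * (n + 1)),
      c(0,           0,              0,                  n,            -(n + 1) * u))
    b <- c(-1, s[1] * (n + 1), 0, 0, 0)
    x <- solve(A, b)
    tau[n] <- x[4] + x[5] * u
  }
  tau
}

# Series evaluation of scalp potentials for one dipole against a matrix of
# scalp electrode positions.  Returns an n_electrode x 3 matrix: potentials
# for unit dipole moments along x, y, z.  `tau` comes from shell_transfer().
dipole_gain <- function(model, position, electrodes, tau,
                        tol = 1e-10, min_terms = 10) {
  r1 <- model$radii[1]
  sigma <- model$conductivities[1]
  b <- sqrt(sum(position^2))
  if (b >= r1)
    stop(sprintf("dipole at radius %.4f is at or outside the inner skull (%.4f)",
                 b, r1))
  bh <- if (b < 1e-12) c(0, 0, 1) else position / b
  ne <- nrow(electrodes)
  # electrodes assumed on the unit sphere
  x <- as.vector(electrodes %*% bh)              # cos(gamma)
  sg <- sqrt(pmax(0, 1 - x^2))
  # tangential unit vectors in the (dipole, electrode) plane, zero where the
  # electrode is (anti)parallel to the dipole axis (P_n^1 vanishes there)
  th <- (electrodes - outer(x, bh)) / ifelse(sg > 1e-12, sg, 1)
  th[sg <= 1e-12, ] <- 0

  n_max <- length(tau)
  ratio <- b / r1
  Sr <- numeric(ne); St <- numeric(ne)
  Pprev <- rep(1, ne); Pcur <- x                  # P_0, P_1
  Qprev <- rep(0, ne); Qcur <- sg                 # P_0^1, P_1^1 (no CS phase)
  scale0 <- 1 / r1^2
  pow <- 1                                        # (b/r1)^(n-1)
  converged <- FALSE
  small_run <- 0L
  for (n in seq_len(n_max)) {
    cn <- tau[n] * scale0 * pow
    tr <- cn * n * Pcur
    tt <- cn * Qcur
    Sr <- Sr + tr
    St <- St + tt
    ref <- max(max(abs(Sr)), max(abs(St)), 1e-300)
    if (max(max(abs(tr)), max(abs(tt))) < tol * ref && n >= min_terms) {
      small_run <- small_run + 1L
      if (small_run >= 2L) { converged <- TRUE; break }
    } else small_run <- 0L
    pow <- pow * ratio
    Pnext <- ((2 * n + 1) * x * Pcur - n * Pprev) / (n + 1)
    Qnext <- ((2 * n + 1) * x * Qcur - (n + 1) * Qprev) / n
    Pprev <- Pcur; Pcur <- Pnext
    Qprev <- Qcur; Qcur <- Qnext
  }
  if (!converged && pow * max(abs(tau[n_max]), 1) > tol * 1e2 && ratio > 0.995)
    stop("Legendre series did not converge at maximum degree; ",
         "dipole too close to the inner-skull boundary")
  (outer(Sr, bh) + sweep(th, 1, St, "*")) / (4 * pi * sigma)
}

#' Scalp potential of a current dipole in the three-shell head model
#'
#' Evaluates the analytic Legendre-series solution for the electric potential
#' produced on the scalp surface by a current dipole inside the innermost
#' (brain) shell, with the reference at infinity.
#'
#' @param model A [head_model()].
#' @param dipole_position Coordinate triple inside the inner skull
#'   (normalized head units).
#' @param dipole_moment Dipole moment vector (arbitrary units; the potential
#'   is linear in the moment).
#' @param electrode_position Coordinate triple on the scalp surface
#'   (radius 1).
#' @param n_max Maximum series degree.
#' @param tol Relative tolerance for series truncation.
#' @return Scalar potential (infinity reference), in potential units per unit
#'   dipole moment.
#' @export
dipole_potential <- function(model, dipole_position, dipole_moment,
                             electrode_position, n_max = 200, tol = 1e-10) {
  stopifnot(inherits(model, "head_model"),
            length(dipole_position) == 3, length(dipole_moment) == 3,
            length(electrode_position) == 3)
  er <- sqrt(sum(electrode_position^2))
  if (abs(er - 1) > 1e-6)
    stop("electrode must lie on the scalp surface (radius 1)")
  tau <- shell_transfer(model, n_max)
  g <- dipole_gain(model, as.numeric(dipole_position),
                   matrix(electrode_position / er, nrow = 1), tau, tol = tol)
  sum(g * dipole_moment)
}

#' Cubic dipole source grid
#'
#' Enumerates an origin-anchored cubic lattice of dipole positions confined to
#' a ball, optionally restricted to the upper hemisphere (z >= 0).  Both
#' constraints are inclusive.  With the default spacing 0.0905 and radius
#' limit 0.86 the upper-hemisphere grid has exactly 1994 points.  Enumeration
#' order is deterministic (lexicographic in the (k, i, j) lattice indices,
#' i.e. z-plane by z-plane).
#'
#' @param spacing Inter-grid distance (normalized head units).
#' @param radius_limit Ball radius containing the grid.
#' @param hemisphere_only Keep only points with z >= 0.
#' @return An object of class `dipole_grid` with a `positions` matrix
#'   (n x 3).
#' @examples
#' g <- build_dipole_grid()
#' nrow(g$positions)  # 1994
#' @export
build_dipole_grid <- function(spacing = 0.0905, radius_limit = 0.86,
                              hemisphere_only = TRUE) {
  stopifnot(spacing > 0, radius_limit > 0)
  nmax <- floor(radius_limit / spacing)
  idx <- seq(-nmax, nmax)
  ks <- if (hemisphere_only) 0:nmax else idx
  rows <- vector("list", length(ks))
  r2 <- (radius_limit / spacing)^2
  ri <- 1L
  for (k in ks) {
    plane <- expand.grid(j = idx, i = idx)   # i varies slowest within plane
    keep <- plane$i^2 + plane$j^2 + k^2 <= r2
    if (any(keep))
      rows[[ri]] <- cbind(plane$i[keep], plane$j[keep], k)
    ri <- ri + 1L
  }
  m <- do.call(rbind, rows)
  # order within plane: i then j (lexicographic (k, i, j))
  m <- m[order(rep(ks, times = vapply(rows, function(r)
    if (is.null(r)) 0L else nrow(r), 0L)), m[, 1], m[, 2]), , drop = FALSE]
  structure(
    list(positions = unname(m * spacing),
         spacing = spacing, radius_limit = radius_limit,
         hemisphere_only = hemisphere_only),
    class = "dipole_grid")
}

#' Fixed-position dipole set
#'
#' Wraps explicit dipole coordinates in the same container as
#' [build_dipole_grid()], for lead fields over hand-chosen sources (e.g. the
#' equivalent dipoles of simulated ERP components).
#'
#' @param positions n x 3 matrix of dipole coordinates.
#' @return A `dipole_grid` object.
#' @export
dipole_set <- function(positions) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3)
  structure(
    list(positions = unname(positions), spacing = NA_real_,
         radius_limit = NA_real_, hemisphere_only = NA),
    class = "dipole_grid")
}

#' @export
print.dipole_grid <- function(x, ...) {
  cat(sprintf("Dipole grid: %d positions", nrow(x$positions)))
  if (!is.na(x$spacing))
    cat(sprintf(" (spacing %.4f, radius <= %.2f%s)",
                x$spacing, x$radius_limit,
                if (isTRUE(x$hemisphere_only)) ", z >= 0" else ""))
  cat("\n")
  invisible(x)
}

#' Infinity-reference lead field
#'
#' Builds the gain matrix mapping unit dipole moments (orientation order x, y,
#' z per dipole) to scalp potentials with the reference at infinity.
#'
#' @param model A [head_model()].
#' @param montage An electrode montage ([montage()]); all rows must be scalp
#'   electrodes.
#' @param grid A [build_dipole_grid()] or [dipole_set()].
#' @param n_max,tol Series truncation controls (see [dipole_potential()]).
#' @return An object of class `lead_field`: `gain` (electrodes x
#'   3*dipoles), `labels`, `reference` ("infinity"), `montage`, `grid`.
#' @export
leadfield_infinity <- function(model, montage, grid, n_max = 200, tol = 1e-10) {
  stopifnot(inherits(model, "head_model"), inherits(grid, "dipole_grid"))
  montage <- as_montage(montage)
  if (!all(montage$scalp))
    stop("lead fields are defined for scalp electrodes only; drop EOG rows")
  E <- as.matrix(montage[, c("x", "y", "z")])
  E <- E / sqrt(rowSums(E^2))
  nd <- nrow(grid$positions)
  tau <- shell_transfer(model, n_max)
  gain <- matrix(0, nrow(E), 3L * nd)
  for (j in seq_len(nd)) {
    g <- tryCatch(
      dipole_gain(model, grid$positions[j, ], E, tau, tol = tol),
      error = function(e) stop("dipole ", j, ": ", conditionMessage(e)))
    gain[, (3L * j - 2L):(3L * j)] <- g
  }
  rownames(gain) <- montage$label
  structure(
    list(gain = gain, labels = montage$label, reference = "infinity",
         montage = montage, grid = grid, model = model),
    class = "lead_field")
}

#' Re-reference a lead field
#'
#' Derives the lead field a recording system with a scalp reference would see,
#' by subtracting the reference combination from every row of the
#' infinity-reference gain matrix.
#'
#' @param lf An infinity-reference `lead_field`.
#' @param reference `"AR"` (mean of all rows), `"LM"` (mean of the TP9 and
#'   TP10 rows), or a channel label such as `"Cz"` or `"FCz"` (that row);
#'   `"CZ"` is accepted as an alias for `"Cz"`.
#' @return A `lead_field` with updated `reference` tag.
#' @export
leadfield_for_reference <- function(lf, reference) {
  stopifnot(inherits(lf, "lead_field"))
  if (!identical(lf$reference, "infinity"))
    stop("expected an infinity-reference lead field, got reference '",
         lf$reference, "'")
  reference <- canonical_reference(reference)
  g <- lf$gain
  ref_row <- switch(reference,
    AR = colMeans(g),
    LM = {
      if (!all(c("TP9", "TP10") %in% lf$labels))
        stop("LM reference requires TP9 and TP10 in the montage")
      colMeans(g[c("TP9", "TP10"), , drop = FALSE])
    },
    {
      if (!(reference %in% lf$labels))
        stop("reference channel '", reference, "' not in the montage")
      g[reference, ]
    })
  lf$gain <- sweep(g, 2, ref_row, "-")
  lf$reference <- reference
  lf
}

# "CZ" is the conventional name of the vertex reference; the vertex channel
# label is "Cz".
canonical_reference <- function(reference) {
  stopifnot(is.character(reference), length(reference) == 1)
  if (reference == "CZ") "Cz" else reference
}

#' Persist a lead field as a delimited matrix plus JSON sidecar
#'
#' @param lf A `lead_field`.
#' @param path Output path for the gain matrix (CSV); the sidecar is written
#'   next to it with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_leadfield <- function(lf, path) {
  stopifnot(inherits(lf, "lead_field"))
  utils::write.table(lf$gain, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(
    labels = lf$labels, reference = lf$reference,
    model = list(radii = lf$model$radii,
                 conductivities = lf$model$conductivities),
    grid = list(spacing = lf$grid$spacing,
                radius_limit = lf$grid$radius_limit,
                hemisphere_only = lf$grid$hemisphere_only,
                n_dipoles = nrow(lf$grid$positions),
                positions = lf$grid$positions))
  jsonlite::write_json(meta, sub("\\.[^.]+$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a lead field written by [write_leadfield()]
#'
#' @param path Path to the gain CSV.
#' @return A `lead_field` (montage positions are not restored; labels are).
#' @export
read_leadfield <- function(path) {
  gain <- as.matrix(utils::read.table(path, sep = ","))
  meta <- jsonlite::read_json(sub("\\.[^.]+$", ".json", path),
                              simplifyVector = TRUE)
  dimnames(gain) <- list(meta$labels, NULL)
  structure(
    list(gain = gain, labels = meta$labels, reference = meta$reference,
         montage = NULL,
         grid = dipole_set(meta$grid$positions),
         model = head_model(meta$model$radii, meta$model$conductivities)),
    class = "lead_field")
}
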