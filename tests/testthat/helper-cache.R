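# Shared expensive fixtures, built lazily once per test run.

.cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .cache)) assign(name, builder(), envir = .cache)
  get(name, envir = .cache)
}

# 61-channel simulation montage (CM electrodes + mastoids)
sim_montage <- function() {
  m <- easycap63_montage()
  m <- m[m$scalp, ]
  class(m) <- c("eeg_montage", "data.frame")
  m
}

# full infinity lead field over the default grid
full_leadfield <- function() cached("lf61", function() {
  leadfield_infinity(head_model(), sim_montage(), build_dipole_grid())
})

# full simulation comparison (default settings)
full_simulation <- function() cached("simres", function() {
  lf <- full_leadfield()
  run_reference_comparison(head_model(), lf$montage, lf$grid, lf = lf)
})

# REST operator for the recording system (FCz reference)
full_rest_operator <- function() cached("restop", function() {
  recording_rest_operator()
})

# full default synthetic study (12 subjects); the expensive end-to-end run
full_study <- function() cached("study", function() {
  oddball_study(synth_config(seed = 1), rest_op = full_rest_operator())
})

# small source grid for REST algebra tests
coarse_leadfield <- function() cached("lf_coarse", function() {
  leadfield_infinity(head_model(), sim_montage(),
                     build_dipole_grid(spacing = 0.18, radius_limit = 0.86))
})

# closed-form potential on the surface of a homogeneous unit sphere
# (independent oracle for the three-shell series in the equal-conductivity
# limit): image-free analytic sum of the Legendre series
homogeneous_sphere_potential <- function(dipole_position, dipole_moment,
                                         electrode_position, sigma = 1) {
  b <- sqrt(sum(dipole_position^2))
  stopifnot(b > 1e-6)
  bh <- dipole_position / b
  e <- electrode_position
  dvec <- e - dipole_position
  d <- sqrt(sum(dvec^2))
  x <- sum(bh * e)
  sg <- sqrt(max(0, 1 - x^2))
  th <- if (sg > 1e-12) (e - x * bh) / sg else c(0, 0, 0)
  mr <- sum(dipole_moment * bh)
  mt <- sum(dipole_moment * th)
  (1 / (4 * pi * sigma)) *
    (2 * sum(dipole_moment * dvec) / d^3 +
       mr * (1 / d - 1) / b +
       mt * sg * (d + 1) / (d * (1 - b * x + d)))
}

random_rotation <- function() {
  qr_q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(qr_q) < 0) qr_q[, 1] <- -qr_q[, 1]
  qr_q
}
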