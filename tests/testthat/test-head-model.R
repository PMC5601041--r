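# Forward model: geometry validation, dipole grid, analytic series, lead
# fields and their reference transforms.

test_that("head model validates geometry and conductivities", {
  hm <- head_model()
  expect_equal(hm$radii, c(0.87, 0.92, 1.0))
  expect_equal(hm$conductivities, c(1.0, 0.0125, 1.0))
  expect_error(head_model(radii = c(0.92, 0.87, 1.0)), "increasing")
  expect_error(head_model(radii = c(0.87, 0.92, 1.1)), "radius")
  expect_error(head_model(conductivities = c(1, -1, 1)), "positive")
})

test_that("dipole grid reproduces the lattice counts and ordering", {
  g <- build_dipole_grid(0.0905, 0.86, hemisphere_only = TRUE)
  expect_equal(nrow(g$positions), 1994)
  expect_true(all(rowSums(g$positions^2) <= 0.86^2 + 1e-12))
  expect_true(all(g$positions[, 3] >= 0))
  # origin-anchored lattice
  expect_true(all(abs(g$positions / 0.0905 -
                        round(g$positions / 0.0905)) < 1e-9))
  # deterministic lexicographic (k, i, j) order
  key <- g$positions[, 3] * 1e6 + g$positions[, 1] * 1e3 + g$positions[, 2]
  expect_false(is.unsorted(key))

  expect_equal(nrow(build_dipole_grid(2.0, 0.86)$positions), 1)
  full <- build_dipole_grid(0.0905, 0.86, hemisphere_only = FALSE)
  # independent brute-force lattice enumeration
  nmax <- floor(0.86 / 0.0905)
  cnt <- 0L
  for (i in -nmax:nmax) for (j in -nmax:nmax) for (k in -nmax:nmax)
    if ((i^2 + j^2 + k^2) * 0.0905^2 <= 0.86^2) cnt <- cnt + 1L
  expect_equal(nrow(full$positions), cnt)
  expect_equal(cnt, 3695)   # 2 * 1994 - 293 points on the z = 0 plane
})

test_that("dipole potential is linear and zero for zero moment", {
  hm <- head_model()
  e <- c(0, 0.6, 0.8)
  p <- c(0.2, 0.1, 0.4)
  expect_identical(dipole_potential(hm, p, c(0, 0, 0), e), 0)
  m1 <- c(1, 0.5, -0.2); m2 <- c(-0.3, 0.2, 1)
  v1 <- dipole_potential(hm, p, m1, e)
  v2 <- dipole_potential(hm, p, m2, e)
  v12 <- dipole_potential(hm, p, 2 * m1 + 3 * m2, e)
  expect_equal(v12, 2 * v1 + 3 * v2, tolerance = 1e-12)
})

test_that("equal conductivities reduce to the homogeneous-sphere closed form", {
  hm <- head_model(conductivities = c(1, 1, 1))
  set.seed(11)
  worst <- 0
  for (i in 1:120) {
    p <- stats::runif(3, -0.5, 0.5)
    if (sqrt(sum(p^2)) < 0.05) next
    m <- stats::rnorm(3)
    e <- stats::rnorm(3); e <- e / sqrt(sum(e^2))
    v <- dipole_potential(hm, p, m, e)
    v0 <- homogeneous_sphere_potential(p, m, e)
    worst <- max(worst, abs(v - v0) / abs(v0))
  }
  expect_lt(worst, 1e-6)
})

test_that("potential is invariant under joint rotation", {
  hm <- head_model()
  set.seed(4)
  for (i in 1:5) {
    R <- random_rotation()
    p <- c(0.25, -0.1, 0.35); m <- c(0.3, 1, -0.5); e <- c(0.48, -0.6, 0.64)
    e <- e / sqrt(sum(e^2))
    v <- dipole_potential(hm, p, m, e)
    vr <- dipole_potential(hm, as.vector(R %*% p), as.vector(R %*% m),
                           as.vector(R %*% e))
    expect_equal(vr, v, tolerance = 1e-10)
  }
})

test_that("dipole at or outside the inner skull is a domain error", {
  hm <- head_model()
  expect_error(dipole_potential(hm, c(0, 0, 0.87), c(0, 0, 1), c(0, 0, 1)),
               "inner skull")
  expect_error(dipole_potential(hm, c(0, 0, 0.9), c(0, 0, 1), c(0, 0, 1)),
               "inner skull")
  expect_error(dipole_potential(hm, c(0, 0, 0.5), c(0, 0, 1), c(0, 0, 0.9)),
               "scalp")
})

test_that("series truncation is converged on the most eccentric grid dipole", {
  hm <- head_model()
  g <- build_dipole_grid()
  r <- sqrt(rowSums(g$positions^2))
  pos <- g$positions[which.max(r), ]
  mont <- sim_montage()
  E <- montage_positions(mont)
  tau200 <- restcm:::shell_transfer(hm, 200)
  tau400 <- restcm:::shell_transfer(hm, 400)
  g200 <- restcm:::dipole_gain(hm, pos, E, tau200, tol = 0)
  g400 <- restcm:::dipole_gain(hm, pos, E, tau400, tol = 0)
  expect_lt(max(abs(g200 - g400)) / max(abs(g400)), 1e-8)
})

test_that("lead field columns match single-dipole potentials and symmetry", {
  hm <- head_model()
  mont <- sim_montage()
  grid <- dipole_set(rbind(c(0.2, 0.1, 0.3), c(0, 0, 0.5), c(0, 0, 0)))
  lf <- leadfield_infinity(hm, mont, grid)
  expect_equal(dim(lf$gain), c(nrow(mont), 9))
  for (o in 1:3) {
    m <- c(0, 0, 0); m[o] <- 1
    v <- vapply(seq_len(nrow(mont)), function(i)
      dipole_potential(hm, c(0.2, 0.1, 0.3), m,
                       unlist(mont[i, c("x", "y", "z")])), 0)
    expect_equal(unname(lf$gain[, o]), v, tolerance = 1e-10)
  }
  # axial symmetry: z-dipole on the z-axis gives equal potentials at equal
  # colatitude
  gz <- lf$gain[, 6]                       # dipole 2, z orientation
  colat <- round(acos(mont$z), 9)
  for (cl in unique(colat)) {
    vals <- gz[colat == cl]
    if (length(vals) > 1)
      expect_lt(diff(range(vals)), 1e-9 * max(abs(gz)))
  }
})

test_that("reference lead fields satisfy their defining row constraints", {
  lf <- coarse_leadfield()
  lfcz <- leadfield_for_reference(lf, "CZ")
  expect_identical(lfcz$reference, "Cz")
  expect_equal(max(abs(lfcz$gain["Cz", ])), 0)
  lfar <- leadfield_for_reference(lf, "AR")
  expect_lt(max(abs(colSums(lfar$gain))), 1e-10)
  lflm <- leadfield_for_reference(lf, "LM")
  expect_lt(max(abs(colMeans(lflm$gain[c("TP9", "TP10"), ]))), 1e-10)
  expect_error(leadfield_for_reference(lf, "Nope"), "not in the montage")
  expect_error(leadfield_for_reference(lfcz, "AR"), "infinity")
})

test_that("lead fields persist through the CSV + sidecar round trip", {
  lf <- leadfield_infinity(head_model(), sim_montage(),
                           dipole_set(rbind(c(0.1, 0.2, 0.3))))
  path <- file.path(tempdir(), "lf.csv")
  write_leadfield(lf, path)
  lf2 <- read_leadfield(path)
  expect_equal(lf2$gain, lf$gain, tolerance = 1e-12)
  expect_identical(lf2$reference, "infinity")
  expect_equal(lf2$grid$positions, lf$grid$positions)
})
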