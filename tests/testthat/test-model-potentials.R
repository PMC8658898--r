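test_that("built-in surfaces evaluate their closed forms", {
  h <- harmonic_surface(k = 1, x0 = 0, units = "au")
  expect_equal(surface_energy(h, 0.2), 0.02)
  expect_equal(as.vector(surface_gradient(h, 0.2)), 0.2)

  m <- morse_surface(de = 2, a = 1.5, re = 1.1, units = "au")
  expect_equal(surface_energy(m, 1.1), 0)
  expect_equal(as.vector(surface_gradient(m, 1.1)), 0)

  dw <- double_well_surface(v0 = 1, a = 0.5, units = "au")
  expect_equal(surface_energy(dw, c(0.5, 0, 0)), 0)
  expect_equal(surface_energy(dw, c(0, 0, 0)), 1) # barrier top

  lin <- linear_surface(c(2, 0, 0), intercept = 1, units = "au")
  expect_equal(surface_energy(lin, c(0.25, 3, -1)), 1.5)
})

test_that("non-finite geometries are rejected with the offending coordinate", {
  h <- harmonic_surface(k = 1, x0 = c(0, 0), units = "au")
  expect_error(surface_energy(h, c(1, NaN)),
               regexp = "coordinate 2", class = "rpdyn_surface_error")
  expect_error(surface_energy(h, c(1, 2, 3)), class = "rpdyn_surface_error")
})

test_that("nonpositive force constants and ranges are parameter errors", {
  expect_error(toy_photodetachment_system(k = -1),
               class = "rpdyn_parameter_error")
  expect_error(toy_photodetachment_system(alpha = 0),
               class = "rpdyn_parameter_error")
  expect_error(harmonic_surface(k = 0, x0 = 0), class = "rpdyn_parameter_error")
  expect_error(toy_torsional_system(v2 = -0.1), class = "rpdyn_parameter_error")
})

test_that("gradients of every built-in surface match finite differences", {
  set.seed(31)
  pair <- toy_photodetachment_system()
  tor <- toy_torsional_system("trans")
  surfaces <- list(
    harmonic_surface(k = c(1.2, 0.5, 2), x0 = c(0.1, -0.2, 0), units = "au"),
    morse_surface(2, 1.5, 1.1, units = "au"),
    double_well_surface(1, 0.5, units = "au"),
    cubic_surface(0.8, units = "au"),
    linear_surface(c(1, -2, 0.5), units = "au"),
    pair$anion, pair$neutral, tor$anion, tor$neutral
  )
  templates <- list(rnorm(3), 1.3, rnorm(3), rnorm(3), rnorm(3),
                    to_au(rpdyn:::.flatten_geometry(pair$template), "length"),
                    to_au(rpdyn:::.flatten_geometry(pair$template), "length"),
                    to_au(rpdyn:::.flatten_geometry(tor$template), "length"),
                    to_au(rpdyn:::.flatten_geometry(tor$template), "length"))
  for (i in seq_along(surfaces)) {
    for (rep in 1:3) {
      q <- templates[[i]] + rnorm(length(templates[[i]]), sd = 0.05)
      g <- as.vector(surface_gradient(surfaces[[i]], q))
      gn <- fd_gradient(surfaces[[i]], q)
      scale <- max(1e-8, max(abs(gn)))
      expect_lt(max(abs(g - gn)) / scale, 1e-6)
    }
  }
})

test_that("finite-difference Hessians are symmetric and match analytic ones", {
  h <- harmonic_surface(k = c(1.5, 0.7, 1), x0 = c(0, 0, 0), units = "au")
  hess <- surface_hessian(h, c(0.3, -1, 2))
  expect_equal(hess, diag(c(1.5, 0.7, 1)))
  pair <- toy_photodetachment_system()
  q <- to_au(rpdyn:::.flatten_geometry(pair$template), "length")
  hn <- surface_hessian(pair$anion, q) # no analytic Hessian: finite diff
  expect_equal(hn, t(hn))
  # curvature along the antisymmetric stretch at the minimum: moving the
  # atoms by -+1/sqrt(2) changes the bond length by sqrt(2), so the
  # directional curvature is 2k
  bond_dir <- c(-1, 0, 0, 1, 0, 0) / sqrt(2)
  k_au <- to_au(1.4, "energy") / to_au(1, "length")^2
  expect_equal(as.vector(bond_dir %*% hn %*% bond_dir), 2 * k_au,
               tolerance = 1e-4)
})

test_that("centroid Taylor forces are exact on quadratics and at the centroid", {
  set.seed(5)
  hmat <- crossprod(matrix(rnorm(36, sd = 0.5), 6)) + diag(0.5, 6)
  qs <- quadratic_surface(hmat, gradient0 = rnorm(6), q0 = rnorm(6),
                          units = "au")
  cfg <- make_config_au(array(rnorm(2 * 6 * 3, sd = 0.4), c(2, 6, 3)),
                        masses = c(1, 2), n_beads = 6)
  f_exact <- taylor_bead_forces(qs, cfg, "exact_beads")
  f_taylor <- taylor_bead_forces(qs, cfg, "centroid_taylor")
  expect_equal(f_taylor, f_exact, tolerance = 1e-12)

  # a bead exactly at the centroid feels gradient(Q_c)
  cub <- cubic_surface(1, units = "au")
  pos <- matrix(0, 3, 4)
  pos[1, ] <- c(-0.1, 0.1, -0.2, 0.2) # centroid at 0
  cfg0 <- structure(list(n_atoms = 1L, n_beads = 4L, masses = 1, labels = "X",
                         positions = cbind(pos, 0), momenta = matrix(0, 3, 5)),
                    class = "bead_configuration")
  f <- taylor_bead_forces(cub, cfg0, "centroid_taylor")
  expect_equal(f[, 5], as.vector(surface_gradient(cub, c(0, 0, 0))))
})

test_that("Taylor remainder on a cubic is the analytic 3 delta^2", {
  cub <- cubic_surface(1, units = "au")
  pos <- matrix(0, 3, 2)
  pos[1, ] <- c(0.1, -0.1) # centroid 0, one bead at delta = 0.1
  cfg <- structure(list(n_atoms = 1L, n_beads = 2L, masses = 1, labels = "X",
                        positions = pos, momenta = pos * 0),
                   class = "bead_configuration")
  err <- taylor_bead_forces(cub, cfg, "exact_beads") -
    taylor_bead_forces(cub, cfg, "centroid_taylor")
  expect_equal(abs(err[1, 1]), 0.03, tolerance = 1e-12)
})

test_that("Taylor error scales quadratically with bead spread", {
  cub <- cubic_surface(1, units = "au")
  eps <- 10^seq(-2, 0, length.out = 9)
  pattern <- c(-1, -0.6, -0.2, 0.2, 0.6, 1, 0.5, -0.5)
  pattern <- pattern - mean(pattern)
  errs <- vapply(eps, function(e) {
    pos <- matrix(0, 3, 8)
    pos[1, ] <- e * pattern
    cfg <- structure(list(n_atoms = 1L, n_beads = 8L, masses = 1,
                          labels = "X", positions = pos, momenta = pos * 0),
                     class = "bead_configuration")
    max(abs(taylor_bead_forces(cub, cfg, "exact_beads") -
              taylor_bead_forces(cub, cfg, "centroid_taylor")))
  }, numeric(1))
  slope <- unname(coef(lm(log(errs) ~ log(eps)))[2])
  expect_lt(abs(slope - 2), 0.1)
})

test_that("toy photodetachment surfaces obey their defining energetics", {
  pair <- toy_photodetachment_system()
  far <- rbind(c(-50, 0, 0), c(50, 0, 0))
  q_far <- to_au(rpdyn:::.flatten_geometry(far), "length")
  expect_equal(from_au(surface_energy(pair$neutral, q_far), "energy"), 3.7,
               tolerance = 1e-6)
  expect_equal(binding_energy(pair, pair$template), 0.9 + 3.7,
               tolerance = 1e-10)
  tor <- toy_torsional_system("trans")
  expect_equal(binding_energy(tor, tor$template), 0.9 + 3.7,
               tolerance = 1e-10)
})
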