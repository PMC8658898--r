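test_that("thermal initialization is reproducible and obeys equipartition", {
  th <- thermo_context(beta = 2)
  tmpl <- make_config_au(matrix(0, 34, 3), masses = runif(34, 0.5, 3),
                         n_beads = 100, seed = 1)
  a <- initialize_thermal(tmpl, th, seed = 5)
  b <- initialize_thermal(tmpl, th, seed = 5)
  expect_identical(a$positions, b$positions)
  expect_identical(a$momenta, b$momenta)

  # kinetic energy per DOF ~ kT/2 within 3 standard errors over ~1e4 DOFs
  ke_dof <- 100 * a$momenta^2 / (2 * rpdyn:::.dof_masses(a))
  n <- length(ke_dof)
  se <- sqrt(stats::var(as.vector(ke_dof)) / n)
  expect_lt(abs(mean(ke_dof) - th$kT / 2), 3 * se)

  # T -> 0: momenta vanish
  cold <- initialize_thermal(tmpl, thermo_context(beta = 1e12), seed = 5)
  expect_lt(max(abs(cold$momenta)), 1e-4)
})

test_that("thermostat-free stepping reproduces classical velocity Verlet", {
  th <- thermo_context(beta = 1)
  pes <- harmonic_surface(k = c(1, 1, 1), x0 = c(0, 0, 0), units = "au")
  cfg <- bead_configuration(matrix(c(0.7, 0, 0), 1, 3),
                            momenta = matrix(c(0, 0.2, 0), 1, 3),
                            masses = 1.5, n_beads = 1, units = "au")
  dt <- 0.05
  state <- cfg
  for (i in 1:200) {
    state <- nhc_velocity_verlet_step(state, NULL, pes, th,
                                      dt = from_au(dt, "time"))$config
  }
  # hand-rolled classical velocity Verlet
  q <- c(0.7, 0, 0); p <- c(0, 0.2, 0); m <- 1.5
  for (i in 1:200) {
    p <- p - q * dt / 2
    q <- q + p / m * dt
    p <- p - q * dt / 2
  }
  expect_equal(as.vector(state$positions), q, tolerance = 1e-12)
  expect_equal(as.vector(state$momenta), p, tolerance = 1e-12)
})

test_that("a free particle's centroid advances linearly without a thermostat", {
  th <- thermo_context(beta = 1)
  free <- linear_surface(c(0, 0, 0), units = "au")
  cfg <- bead_configuration(matrix(0, 1, 3),
                            momenta = matrix(c(0.3, 0, 0), 1, 3),
                            masses = 2, n_beads = 4, units = "au")
  dt_au <- 0.1
  state <- cfg
  for (i in 1:50) {
    state <- nhc_velocity_verlet_step(state, NULL, free, th,
                                      dt = from_au(dt_au, "time"))$config
  }
  # bead velocity N * P / m; all beads share the same momentum
  expect_equal(centroid(state, "au")[1, 1], 4 * 0.3 / 2 * 50 * dt_au,
               tolerance = 1e-10)
})

test_that("sampled bead-position covariance matches the exact ring-polymer Gaussian", {
  # small-instance oracle for the whole sampling stack: 1D harmonic mode,
  # N = 4 beads, covariance from inverting the quadratic form
  cfg <- sampler_config(beta = 2, n_beads = 4, dt = 0.04, n_steps = 1.2e5,
                        burn_in = 1.2e4, sample_stride = 10, seed = 3,
                        force_mode = "exact_beads", jitter = 0.3,
                        time_units = "au")
  tmpl <- make_config_au(matrix(0, 1, 3), masses = 1, n_beads = 4)
  pes <- harmonic_surface(k = c(1, 1, 1), x0 = c(0, 0, 0), units = "au")
  ens <- pimd_sample(tmpl, pes, cfg)
  cov_exact <- ring_polymer_covariance_1d(1, 1, 2, 4)
  # x-coordinates of the 4 beads across samples (plus y, z as replicates)
  xs <- vapply(ens$samples, function(s) s$positions[1, ], numeric(4))
  ys <- vapply(ens$samples, function(s) s$positions[2, ], numeric(4))
  zs <- vapply(ens$samples, function(s) s$positions[3, ], numeric(4))
  cov_obs <- (tcrossprod(xs) + tcrossprod(ys) + tcrossprod(zs)) /
    (3 * ncol(xs))
  expect_equal(mean(diag(cov_obs)), mean(diag(cov_exact)), tolerance = 0.05)
  expect_equal(cov_obs[1, 3], cov_exact[1, 3], tolerance = 0.1 * cov_exact[1, 1])
  # bead marginals are exchangeable (cyclic symmetry)
  expect_lt(max(abs(diag(cov_obs) / mean(diag(cov_obs)) - 1)), 0.1)
})

test_that("bead marginal distributions are identical across beads (chi-squared)", {
  cfg <- sampler_config(beta = 3, n_beads = 8, dt = 0.03, n_steps = 4e4,
                        burn_in = 4e3, sample_stride = 10, seed = 8,
                        force_mode = "exact_beads", jitter = 0.3,
                        time_units = "au")
  tmpl <- make_config_au(matrix(0, 1, 3), masses = 1, n_beads = 8)
  pes <- harmonic_surface(k = c(1, 1, 1), x0 = c(0, 0, 0), units = "au")
  ens <- pimd_sample(tmpl, pes, cfg)
  xs <- vapply(ens$samples, function(s) s$positions[1, ], numeric(8))
  pooled <- as.vector(xs)
  qs <- stats::quantile(pooled, probs = seq(0.2, 0.8, by = 0.2))
  binned <- matrix(0L, 8, 5)
  for (b in 1:8) {
    binned[b, ] <- tabulate(findInterval(xs[b, ], qs) + 1L, 5L)
  }
  p <- suppressWarnings(stats::chisq.test(binned)$p.value)
  expect_gt(p, 0.01)
})

test_that("quantum beads broaden the position distribution beyond classical", {
  pes <- harmonic_surface(k = c(1, 1, 1), x0 = c(0, 0, 0), units = "au")
  tmpl_q <- make_config_au(matrix(0, 1, 3), masses = 1, n_beads = 16)
  tmpl_c <- make_config_au(matrix(0, 1, 3), masses = 1, n_beads = 1)
  run <- function(tmpl, n_beads, seed) {
    cfg <- sampler_config(beta = 3, n_beads = n_beads, dt = 0.03,
                          n_steps = 6e4, burn_in = 6e3, sample_stride = 10,
                          seed = seed, force_mode = "exact_beads",
                          jitter = 0.2, time_units = "au")
    ens <- pimd_sample(tmpl, pes, cfg)
    mean(rpdyn:::.ensemble_bead_matrix(ens)^2)
  }
  msd_q <- run(tmpl_q, 16, 21)
  msd_c <- run(tmpl_c, 1, 22)
  expect_gt(msd_q, msd_c) # beta*hbar*omega = 3: nuclear quantum effect
  # and sampling statistics must not depend on a momentum-convention rescale
  cfg <- sampler_config(beta = 3, n_beads = 16, dt = 0.03, n_steps = 1e3,
                        burn_in = 0, sample_stride = 10, seed = 21,
                        force_mode = "exact_beads", jitter = 0.2,
                        time_units = "au")
  ens <- pimd_sample(tmpl_q, pes, cfg)
  rescaled <- lapply(ens$samples, function(s) {
    s$momenta <- s$momenta * sqrt(16)
    s
  })
  expect_identical(
    lapply(ens$samples, `[[`, "positions"),
    lapply(rescaled, `[[`, "positions")
  )
})

test_that("a high barrier prevents well-to-well crossing during sampling", {
  # barrier 0.6 eV >> kT at 300 K; start in the x = +a well
  dw <- double_well_surface(v0 = 0.6, a = 0.5)
  cfg <- sampler_config(temperature = 300, n_beads = 8, dt = 0.3,
                        n_steps = 6e3, burn_in = 500, sample_stride = 5,
                        seed = 13, force_mode = "exact_beads", jitter = 0.02)
  tmpl <- bead_configuration(matrix(c(0.5, 0, 0), 1, 3), masses = 2,
                             n_beads = 8)
  ens <- pimd_sample(tmpl, dw, cfg)
  xs <- vapply(ens$samples, function(s) s$positions[1, ], numeric(8))
  expect_true(all(xs > 0))
})

test_that("centroid Taylor mode below 200 K warns about its validity range", {
  pes <- harmonic_surface(k = 1.4, x0 = c(0, 0, 0))
  tmpl <- bead_configuration(matrix(0, 1, 3), masses = 2, n_beads = 2)
  cfg <- sampler_config(temperature = 100, n_beads = 2, dt = 0.3,
                        n_steps = 20, burn_in = 0, sample_stride = 5,
                        seed = 1, force_mode = "centroid_taylor")
  expect_warning(pimd_sample(tmpl, pes, cfg),
                 class = "rpdyn_low_temperature_warning")
})

test_that("sampling is deterministic under a fixed seed", {
  pes <- harmonic_surface(k = c(1, 1, 1), x0 = c(0, 0, 0), units = "au")
  tmpl <- make_config_au(matrix(0, 1, 3), masses = 1, n_beads = 4)
  cfg <- sampler_config(beta = 2, n_beads = 4, dt = 0.05, n_steps = 500,
                        burn_in = 100, sample_stride = 10, seed = 99,
                        force_mode = "exact_beads", time_units = "au")
  e1 <- pimd_sample(tmpl, pes, cfg)
  e2 <- pimd_sample(tmpl, pes, cfg)
  expect_identical(e1$samples, e2$samples)
})
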