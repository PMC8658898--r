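make_toy_ensemble <- function(n_beads = 4, n_steps = 3000, seed = 2) {
  pair <- toy_photodetachment_system()
  cfg <- sampler_config(temperature = 300, n_beads = n_beads, dt = 0.3,
                        n_steps = n_steps, sample_stride = 10, seed = seed,
                        force_mode = "exact_beads", jitter = 0.03)
  list(pair = pair, ensemble = pimd_sample(pair, config = cfg))
}

test_that("vertical detachment carries positions and momenta over bitwise", {
  x <- make_toy_ensemble()
  ev <- detach(x$ensemble, x$pair, selection = c(3, 7, 11))
  expect_length(ev$events, 3)
  for (k in seq_along(ev$events)) {
    i <- ev$events[[k]]$index
    expect_identical(ev$events[[k]]$positions, x$ensemble$samples[[i]]$positions)
    expect_identical(ev$events[[k]]$momenta, x$ensemble$samples[[i]]$momenta)
  }
  expect_error(detach(x$ensemble, x$pair, selection = integer(0)),
               class = "rpdyn_state_error")
})

test_that("a constant-shift surface pair gives every event the same E_b", {
  x <- make_toy_ensemble()
  shifted <- surface_pair(x$pair$anion,
                          shift_surface(x$pair$anion, 2.5),
                          masses = x$pair$masses, labels = x$pair$labels,
                          template = x$pair$template)
  ev <- detach(x$ensemble, shifted, selection = 1:10)
  ebs <- vapply(ev$events, `[[`, 0, "e_b")
  expect_equal(ebs, rep(2.5, 10), tolerance = 1e-9)
})

test_that("detachment at the anion minimum has E_b = A + E_inf", {
  pair <- toy_photodetachment_system()
  ens <- gaussian_ensemble(1, sigma = 1e-12, center = pair$template,
                           masses = pair$masses, n_beads = 4, seed = 1)
  ev <- detach(ens, pair)
  expect_equal(ev$events[[1]]$e_b, 4.6, tolerance = 1e-6)
})

test_that("a classical oscillation has period 2 pi / omega to 0.1%", {
  th <- thermo_context(beta = 1)
  pes <- harmonic_surface(k = c(1, 1, 1), x0 = c(0, 0, 0), units = "au")
  cfg <- bead_configuration(matrix(c(0.4, 0, 0), 1, 3), masses = 1,
                            n_beads = 1, units = "au")
  period <- 2 * pi # omega = 1
  dt_au <- period / 1000
  tr <- propagate_nve(cfg, pes, th, dt = dt_au, max_steps = 5000,
                      time_units = "au")
  x <- tr$centroid_positions[, 1]
  # measure the period from linear interpolation of downward zero crossings
  crossings <- which(x[-1] < 0 & x[-length(x)] >= 0)
  tcross <- vapply(crossings, function(i) {
    t1 <- tr$time_fs[i]; t2 <- tr$time_fs[i + 1]
    t1 + (t2 - t1) * x[i] / (x[i] - x[i + 1])
  }, numeric(1))
  measured <- mean(diff(tcross))
  expect_lt(abs(measured / from_au(period, "time") - 1), 1e-3)
})

test_that("free-particle propagation conserves the Hamiltonian exactly", {
  th <- thermo_context(beta = 1)
  free <- linear_surface(c(0, 0, 0), units = "au")
  cfg <- bead_configuration(matrix(0, 1, 3),
                            momenta = matrix(c(0.3, -0.1, 0), 1, 3),
                            masses = 1, n_beads = 1, units = "au")
  tr <- propagate_nve(cfg, free, th, dt = 0.1, max_steps = 300,
                      time_units = "au")
  expect_identical(max(abs(tr$hamiltonian_ev - tr$hamiltonian_ev[1])), 0)
})

test_that("propagation is time-reversible to 1e-8 relative", {
  pair <- toy_photodetachment_system()
  th <- thermo_context(temperature = 300)
  cfg <- initialize_thermal(
    bead_configuration(pair$template, masses = pair$masses, n_beads = 8),
    th, seed = 6, jitter = 0.03)
  fwd <- propagate_nve(cfg, pair$anion, th, dt = 0.05, max_steps = 1000)
  back <- fwd$final
  back$momenta <- -back$momenta
  rev <- propagate_nve(back, pair$anion, th, dt = 0.05, max_steps = 1000)
  err <- max(abs(rev$final$positions - cfg$positions)) /
    max(abs(cfg$positions))
  expect_lt(err, 1e-8)
})

test_that("ensemble propagation is order-independent and deterministic", {
  x <- make_toy_ensemble(n_beads = 2, n_steps = 1500)
  ev <- detach(x$ensemble, x$pair, selection = 1:6)
  run <- function(events) {
    run_ensemble(events, x$pair$neutral, thermo = x$ensemble$thermo,
                 dt = 0.3, max_steps = 80)
  }
  t1 <- run(ev)
  ev_perm <- ev
  perm <- c(4, 1, 6, 2, 5, 3)
  ev_perm$events <- ev$events[perm]
  t2 <- run(ev_perm)
  for (k in seq_along(perm)) {
    expect_identical(t2$trajectories[[k]]$centroid_positions,
                     t1$trajectories[[perm[k]]]$centroid_positions)
  }
  t3 <- run(ev)
  expect_identical(t1$trajectories[[1]]$final$positions,
                   t3$trajectories[[1]]$final$positions)
  expect_length(t1, 6)
})

test_that("integration blow-ups yield an error status, not an exception", {
  bad <- potential_surface(
    "pathological", ndof = 3,
    energy = function(q) -1e6 * q[1, ]^4,
    gradient = function(q) rbind(-4e6 * q[1, ]^3, 0 * q[2, ], 0 * q[3, ]))
  th <- thermo_context(beta = 1)
  cfg <- bead_configuration(matrix(c(0.5, 0, 0), 1, 3), masses = 1,
                            n_beads = 1, units = "au")
  tr <- propagate_nve(cfg, bad, th, dt = 1, max_steps = 200,
                      time_units = "au")
  expect_identical(tr$status, "error")
})

test_that("energy bookkeeping closes on the dissociative toy system", {
  x <- make_toy_ensemble(n_beads = 4, n_steps = 4000)
  sel <- seq(1, length(x$ensemble), by = 16)
  ev <- detach(x$ensemble, x$pair, sel)
  trs <- run_ensemble(ev, x$pair$neutral, dt = 0.2, max_steps = 900,
                      stop_rule = stop_rule_distance(
                        x$pair$meta$fragments, r_diss = 10, sustain = 10))
  pr <- analyze_products(trs, x$pair$meta$fragments, cutoff = 120)
  diss <- pr$mechanism != "undissociated"
  expect_gt(mean(diss), 0.9)
  v_n0 <- vapply(ev$events, function(e) {
    mean(from_au(surface_energy(x$pair$neutral, e$positions), "energy"))
  }, numeric(1))[diss]
  # initial translational energy also feeds the release
  dofm <- rep(to_au(x$pair$masses, "mass"), each = 3L)
  ek0 <- vapply(ev$events, function(e) {
    vel <- matrix(from_au(4 * rowMeans(e$momenta) / dofm, "velocity"),
                  ncol = 3L, byrow = TRUE)
    relative_kinetic_energy(vel, x$pair$masses, x$pair$meta$fragments)
  }, numeric(1))[diss]
  # available energy above the asymptote bounds the translational release;
  # the residual (internal energy of ring polymer + fragments) is >= 0
  resid <- mean(v_n0 - 3.7 + ek0) - mean(pr$e_k[diss])
  expect_gt(resid, -0.01) # closes to sampling error
  drift <- vapply(trs$trajectories, function(t) {
    max(abs(t$hamiltonian_ev - t$hamiltonian_ev[1])) / abs(t$hamiltonian_ev[1])
  }, numeric(1))
  expect_lt(max(drift), 1e-3) # conservation at this production step size
})
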