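test_that("kinetic-energy release follows the reduced-mass closed form", {
  frg <- fragment_definition(1, 2)
  v_equal <- rbind(c(0.3, -0.1, 0.2), c(0.3, -0.1, 0.2))
  expect_equal(relative_kinetic_energy(v_equal, c(3, 7), frg), 0)

  # two unit masses at +-v along x: mu = 1/2, v_rel = 2v -> E_k = m v^2
  v <- 0.01
  ev_to_amu <- 1 / from_au(to_au(1, "mass") * to_au(1, "velocity")^2, "energy")
  ek <- relative_kinetic_energy(rbind(c(v, 0, 0), c(-v, 0, 0)), c(1, 1), frg)
  expect_equal(ek, v^2 / ev_to_amu, tolerance = 1e-12)

  # CO2/HOCO-like masses, v_rel = 0.02 angstrom/fs
  ek2 <- relative_kinetic_energy(rbind(c(0.02, 0, 0), c(0, 0, 0)),
                                 c(44, 45), frg)
  expect_equal(ek2, 0.5 * (44 * 45 / 89) * 0.02^2 * 103.6427,
               tolerance = 1e-4)
  expect_equal(ek2, 0.4611, tolerance = 2e-4)
})

test_that("kinetic-energy release is Galilean invariant", {
  set.seed(14)
  frg <- fragment_definition(c(1, 2), c(3, 4))
  m <- c(1, 16, 12, 16)
  v <- matrix(rnorm(12, sd = 0.02), 4, 3)
  e0 <- relative_kinetic_energy(v, m, frg)
  boost <- matrix(rep(c(0.31, -0.12, 0.05), each = 4), 4, 3)
  expect_equal(relative_kinetic_energy(v + boost, m, frg), e0,
               tolerance = 1e-12)
  expect_error(relative_kinetic_energy(v, m, list(a = integer(0), b = 3)),
               class = "rpdyn_state_error")
  expect_error(fragment_definition(c(1, 2), c(2, 3)),
               class = "rpdyn_state_error")
})

test_that("dihedral angles reproduce constructed geometries", {
  # planar zigzag (all-anti): 180 degrees
  zig <- rbind(c(-1, 1, 0), c(0, 0, 0), c(1.4, 0, 0), c(2.4, -1, 0))
  expect_equal(dihedral_angle(zig, 1, 2, 3, 4), 180)
  # planar syn: 0 degrees
  syn <- rbind(c(-1, 1, 0), c(0, 0, 0), c(1.4, 0, 0), c(2.4, 1, 0))
  expect_equal(dihedral_angle(syn, 1, 2, 3, 4), 0)
  # l rotated +90 degrees out of the ijk plane about the j->k axis
  rot <- syn
  rot[4, ] <- rotate_about_axis(syn[4, ], syn[3, ], syn[3, ] - syn[2, ], 90)
  expect_equal(dihedral_angle(rot, 1, 2, 3, 4), 90, tolerance = 1e-9)
  # standard torsion convention: invariant under order reversal
  set.seed(15)
  for (rep in 1:5) {
    g <- matrix(rnorm(12, sd = 2), 4, 3)
    expect_equal(dihedral_angle(g, 1, 2, 3, 4), dihedral_angle(g, 4, 3, 2, 1),
                 tolerance = 1e-9)
  }
  # collinear triple is an error
  lin <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))
  expect_error(dihedral_angle(lin, 1, 2, 3, 4),
               class = "rpdyn_geometry_error")
})

test_that("channel classification uses the (-90, 270] reporting convention", {
  expect_equal(report_dihedral(-135), 225)
  expect_equal(report_dihedral(225), 225)
  expect_equal(report_dihedral(c(-90 + 1e-9, 270)), c(-90 + 1e-9, 270),
               tolerance = 1e-12)
  expect_identical(classify_channel(175), "trans")
  expect_identical(classify_channel(10), "cis")
  expect_identical(classify_channel(90), "cis") # half-open boundary
  expect_identical(classify_channel(90.0001), "trans")
  expect_identical(classify_channel(-91), "trans") # maps to 269
  expect_identical(classify_channel(c(-30, 200)), c("cis", "trans"))
})

test_that("classification of a rigidly moved geometry is unchanged", {
  set.seed(16)
  tor <- toy_torsional_system("trans")
  g <- tor$template
  d0 <- dihedral_angle(g, 1, 2, 3, 4)
  for (rep in 1:5) {
    r <- random_rotation_matrix()
    g2 <- g %*% t(r) + matrix(rep(rnorm(3, sd = 5), each = 4), 4, 3)
    d2 <- dihedral_angle(g2, 1, 2, 3, 4)
    # circular comparison: +180 and -180 are the same torsion
    expect_lt(min(abs(c(d2 - d0, d2 - d0 + 360, d2 - d0 - 360))), 1e-8)
    expect_identical(classify_channel(d2), classify_channel(d0))
  }
})

test_that("dissociation timing finds the first sustained velocity plateau", {
  dt <- 0.3
  # exactly constant speed from t = 60 fs (the 200 ramp frames end below 0.1)
  speeds <- c(seq(0, 0.1, length.out = 201)[1:200], rep(0.1, 300))
  tr <- synthetic_two_body_trajectory(speeds, dt = dt)
  res <- dissociation_time(tr, list(a = 1, b = 2))
  expect_equal(res$time_fs, 60)
  expect_identical(res$mechanism, "direct")

  # flat only after 90 fs -> indirect under the 75 fs cutoff
  speeds2 <- c(seq(0, 0.06, length.out = 100),
               0.06 + 0.02 * sin(seq(0, 20, length.out = 200)),
               rep(0.08, 200))
  tr2 <- synthetic_two_body_trajectory(speeds2, dt = dt)
  res2 <- dissociation_time(tr2, list(a = 1, b = 2))
  expect_identical(res2$mechanism, "indirect")
  expect_equal(res2$time_fs, 90, tolerance = dt)

  # a bound oscillation never plateaus
  pair <- toy_photodetachment_system()
  th <- thermo_context(temperature = 300)
  cfg <- initialize_thermal(
    bead_configuration(pair$template, masses = pair$masses, n_beads = 1),
    th, seed = 17, jitter = 0.02)
  tr3 <- propagate_nve(cfg, pair$anion, th, dt = 0.3, max_steps = 400)
  res3 <- dissociation_time(tr3, pair$meta$fragments)
  expect_identical(res3$mechanism, "undissociated")
  expect_true(is.na(res3$time_fs))
})

test_that("Boltzmann isomer ratios match closed forms", {
  expect_equal(boltzmann_ratio(0, 300), 1)
  kb_t <- 8.617333262e-5 * 300
  expect_equal(boltzmann_ratio(kb_t, 300), exp(-1), tolerance = 1e-9)
  r <- boltzmann_ratio(0.38, 300)
  expect_equal(round(log10(r)), -6) # "roughly 1:10^-6"
})

test_that("product records assemble into a complete tibble", {
  speeds <- c(seq(0, 0.1, length.out = 50), rep(0.1, 150))
  tr <- synthetic_two_body_trajectory(speeds, dt = 0.3)
  tr$e_b <- 4.5
  out <- analyze_products(list(tr), fragment_definition(1, 2))
  expect_s3_class(out, "tbl_df")
  expect_named(out, c("id", "e_b", "e_k", "dihedral", "channel", "t_diss",
                      "mechanism", "status"))
  expect_identical(out$mechanism, "direct")
  expect_gt(out$e_k, 0)
  expect_true(is.na(out$dihedral)) # no dihedral requested for a 2-atom system
})
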