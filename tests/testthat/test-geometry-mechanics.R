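test_that("tether forces are Hookean and close under Newton's third law", {
  p <- tiny_params()
  st <- initialize_spindle(p, seed = 1)
  f0 <- spindle_forces(st, p)
  # at initialization every minus end sits on its anchor: zero tether force
  expect_lt(max(abs(f0$mt_tether)), 1e-9)

  # displace one MT along x: restoring force k_tether * d toward the site
  d <- 0.02
  st$mt$geom[1, "cx"] <- st$mt$geom[1, "cx"] + d
  f1 <- spindle_forces(st, p)
  expect_equal(f1$mt_tether[1, 1], -p$geometry$tether_spring_constant * d,
               tolerance = 1e-9)
  expect_lt(max(abs(f1$mt_tether[-1, ])), 1e-9)

  # randomized configuration: total tether force on (SPBs + MTs) vanishes
  rnd <- make_fixture("randomized_force_closure", p, seed = 8)
  fr <- spindle_forces(rnd, p)
  tot <- colSums(fr$mt_tether) + fr$spb_tether[[1]] + fr$spb_tether[[2]]
  expect_lt(max(abs(tot)), 1e-9)
})

test_that("steric forces act at contact, equal and opposite, zero at range", {
  p <- tiny_params()
  st <- initialize_spindle(p, seed = 2)
  d_mt <- p$geometry$mt_diameter

  # two perpendicular crossing rods at 0.8 x diameter separation, placed far
  # from everything else near the centre
  st$mt$geom[1, ] <- c(0, 0, 0, 1, 0, 0, 0.8)
  st$mt$geom[2, ] <- c(0, 0.0, 0.8 * d_mt, 0, 1, 0, 0.8)
  # park the remaining rods far away in tiny form
  for (i in 3:nrow(st$mt$geom)) {
    st$mt$geom[i, 1:3] <- st$mt$geom[i, 1:3] * 0 + c(0, -1.2, 0.4 + 0.01 * i)
    st$mt$geom[i, 7] <- 0.02
  }
  f <- spindle_forces(st, p)
  # equal and opposite along the common normal (z)
  expect_equal(f$mt_steric[1, ], -f$mt_steric[2, ], tolerance = 1e-12)
  expect_lt(f$mt_steric[1, 3], 0)
  expect_gt(f$mt_steric[2, 3], 0)
  expect_lt(max(abs(f$mt_steric[1:2, 1:2])), 1e-12)
  # WCA magnitude at r = 0.8 sigma
  r <- 0.8 * d_mt
  eps <- p$control$steric_strength * p$ratchet$thermal_energy * 1e-3
  sr6 <- (d_mt / r)^6
  expect_equal(abs(f$mt_steric[1, 3]), 24 * eps * (2 * sr6^2 - sr6) / r,
               tolerance = 1e-9)

  # out of range: beyond the WCA cutoff the interaction is exactly zero
  st$mt$geom[2, 3] <- 2^(1 / 6) * d_mt * 1.01
  f2 <- spindle_forces(st, p)
  expect_equal(max(abs(f2$mt_steric[1:2, ])), 0)
})

test_that("crosslink forces and torques close over a randomized state", {
  p <- tiny_params()
  st <- make_fixture("randomized_force_closure", p, seed = 5, n_xl_bound = 12)
  f <- spindle_forces(st, p)
  # net force closes
  expect_lt(max(abs(colSums(f$mt_crosslink))), 1e-9)
  # net torque about the origin closes: sum of (torque about centre + c x F)
  tq <- f$torque_crosslink
  for (i in seq_len(nrow(tq))) {
    cc <- st$mt$geom[i, 1:3]
    Fv <- f$mt_crosslink[i, ]
    tq[i, ] <- tq[i, ] + c(cc[2] * Fv[3] - cc[3] * Fv[2],
                           cc[3] * Fv[1] - cc[1] * Fv[3],
                           cc[1] * Fv[2] - cc[2] * Fv[1])
  }
  expect_lt(max(abs(colSums(tq))), 1e-9)
})

test_that("free objects diffuse at their input coefficients", {
  # rod translational and rotational diffusion within 5%
  for (L in c(0.5, 2)) {
    z <- spindlesim:::cpp_rod_diffusion(L, 0.025, 1, 4.11, 5e-4, 2000, 60,
                                        seed = 17)
    expect_lt(abs(z$D_par_hat / z$D_par - 1), 0.05)
    expect_lt(abs(z$D_perp_hat / z$D_perp - 1), 0.05)
    expect_lt(abs(z$D_rot_hat / z$D_rot - 1), 0.05)
  }

  # SPB diffusion on the envelope: MSD ~ 4 D t in the flat limit
  p <- spindle_params(
    geometry = list(sites_per_spb = 1, tether_spring_constant = 0),
    crosslinkers = list(number = 0),
    control = list(timestep = 1e-3, total_time = 5, frame_interval = 0.5,
                   initial_pole_angle = 2))  # poles far apart: no interactions
  D <- p$geometry$spb_diffusion_coefficient
  disp2 <- sapply(1:60, function(i) {
    r <- run_simulation(p, seed = 1000 + i)
    tr <- r$trajectory
    (tr$spb1_x - tr$spb1_x[1])^2 + (tr$spb1_y - tr$spb1_y[1])^2 +
      (tr$spb1_z - tr$spb1_z[1])^2
  })
  msd <- rowMeans(disp2)
  tt <- seq(0, 5, by = 0.5)
  fit <- coef(stats::lm(msd ~ tt + 0))
  expect_lt(abs(fit / (4 * D) - 1), 0.2)
})

test_that("SPBs stay on the envelope sphere through a crowded run", {
  p <- fast_reference(total_time = 20)
  r <- run_simulation(p, seed = 6)
  R <- p$geometry$envelope_diameter / 2
  r1 <- sqrt(r$trajectory$spb1_x^2 + r$trajectory$spb1_y^2 +
               r$trajectory$spb1_z^2)
  r2 <- sqrt(r$trajectory$spb2_x^2 + r$trajectory$spb2_y^2 +
               r$trajectory$spb2_z^2)
  expect_lt(max(abs(c(r1, r2) - R)), 1e-9)
})
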