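# independent reimplementation of the wall-force reconstruction, used as the
# oracle against the compiled engine implementation
wall_force_oracle <- function(L, F_w, R_tube, gam = 0.5772156649, a = 0.5416,
                              cc = 4.038, blend = 1, r_mt = 0.0125) {
  b <- sqrt(2) * R_tube
  den <- max(log(2 * b / r_mt) - gam, 0.1)
  f_lin <- F_w * L / (2 * R_tube * den)
  f_nm <- F_w * (1 + a * exp(-cc * L / b) * cos(cc * L / b))
  ifelse(L <= 0 | F_w <= 0, 0,
         exp(-L / b) * f_lin + (1 - exp(-L / blend)) * f_nm)
}

test_that("wall force satisfies its boundary conditions", {
  withr::with_seed(4, {
    for (i in 1:20) {
      p <- spindle_params(wall_force = list(
        asymptotic_force = runif(1, 0.1, 20),
        tube_radius = runif(1, 0.02, 0.2)))
      expect_identical(wall_force(0, p), 0)  # F(0) = 0 exactly
    }
  })

  p <- spindle_params(wall_force = list(asymptotic_force = 14.8))
  Fw <- p$wall_force$asymptotic_force
  Rt <- p$wall_force$tube_radius
  expect_lt(abs(wall_force(100 * Rt, p) - Fw) / Fw, 0.01)  # asymptote

  p0 <- spindle_params(wall_force = list(asymptotic_force = 0))
  expect_true(all(wall_force(seq(0, 5, by = 0.1), p0) == 0))

  expect_error(wall_force(-0.1, p), ">= 0")
})

test_that("wall force matches the independent oracle and is continuous", {
  p <- spindle_params(wall_force = list(asymptotic_force = 7.6))
  L <- seq(0, 8, by = 0.002)
  got <- wall_force(L, p)
  want <- wall_force_oracle(L, 7.6, p$wall_force$tube_radius,
                            r_mt = p$geometry$mt_diameter / 2)
  expect_lt(max(abs(got - want)), 1e-6)

  # continuity: adjacent grid values differ by at most slope * step; a
  # discontinuity would appear as an O(1) jump
  expect_lt(max(abs(diff(got))), 0.2)

  # monotone approach to the asymptote beyond the oscillation decay
  far <- L >= 10 * p$wall_force$tube_radius
  expect_true(all(diff(got[far]) >= -1e-12))

  expect_equal(wall_const_b(p), sqrt(2) * p$wall_force$tube_radius)
})

test_that("engine and R wall-force paths agree on protruding tips", {
  # a state with one MT protruding 0.3 um past the envelope
  p <- spindle_params(wall_force = list(asymptotic_force = 7.6))
  st <- initialize_spindle(p, seed = 3)
  R <- p$geometry$envelope_diameter / 2
  Lmt <- 1
  prot <- 0.3
  st$mt$geom[1, ] <- c((R + prot - Lmt / 2), 0, 0, 1, 0, 0, Lmt)
  f <- spindle_forces(st, p)
  fmag <- sqrt(sum(f$mt_wall[1, ]^2))
  expect_equal(fmag, wall_force(prot, p), tolerance = 1e-9)
  # directed radially inward at the tip: here along -x
  expect_lt(f$mt_wall[1, 1], 0)
  # the tip load equals the axial component (rod along the radius)
  expect_equal(f$axial_load[1], fmag, tolerance = 1e-9)
})
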