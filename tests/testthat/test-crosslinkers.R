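test_that("antiparallel gate follows the orientation threshold", {
  u <- c(0, 0, 1)
  expect_true(is_antiparallel(u, -u))
  expect_false(is_antiparallel(u, u))
  # slightly past perpendicular counts under the hemisphere rule
  v <- c(sqrt(1 - 0.05^2), 0, -0.05)
  expect_true(is_antiparallel(c(0, 0, 1), c(-0.05, 0, -sqrt(1 - 0.05^2))))
  expect_true(is_antiparallel(u, v * 0 + c(0.9987, 0, -0.05)))
  # a stricter alignment threshold excludes near-perpendicular pairs
  expect_false(is_antiparallel(u, c(0.9987, 0, -0.05), threshold = -0.5))
})

test_that("crosslink springs are Hookean and equal-and-opposite", {
  p <- tiny_params()
  r0 <- p$crosslinkers$rest_length
  k <- p$crosslinkers$spring_constant

  at_rest <- crosslink_force(c(0, 0, 0), c(r0, 0, 0), p)
  expect_equal(at_rest$force_on_a, c(0, 0, 0))

  d <- 0.011
  out <- crosslink_force(c(0, 0, 0), c(r0 + d, 0, 0), p)
  expect_equal(out$force_on_a, c(k * d, 0, 0))       # attractive
  expect_equal(out$force_on_b, -out$force_on_a)      # Newton's third law
  expect_equal(out$extension, d)

  comp <- crosslink_force(c(0, 0, 0), c(r0 - d, 0, 0), p)
  expect_lt(comp$force_on_a[1], 0)                   # repulsive

  expect_equal(crosslink_energy_kt(r0, p), 0)
  expect_gt(crosslink_energy_kt(r0 + d, p), 0)
})

test_that("parallel filaments are never crosslinked and counts are conserved", {
  p <- spindle_params(crosslinkers = list(number = 20),
                      control = list(timestep = 2e-4))
  st <- make_fixture("frozen_parallel_pair", p, seed = 3,
                     separation = p$crosslinkers$rest_length)
  eq <- simulate_crosslink_equilibrium(st, p, t_burn = 10, n_samples = 500,
                                       sample_interval = 0.1, seed = 4)
  expect_equal(eq$occupancy[3], 0)                   # no two-head binding
  expect_equal(sum(eq$occupancy), 500 * 20)          # population conserved
  expect_gt(eq$occupancy[2], 0)                      # single heads do bind
})

test_that("zero crosslinkers or zero rates give a frozen population", {
  p0 <- spindle_params(crosslinkers = list(number = 0))
  st <- make_fixture("frozen_antiparallel_pair", p0, seed = 1)
  eq <- simulate_crosslink_equilibrium(st, p0, t_burn = 1, n_samples = 10,
                                       sample_interval = 0.1, seed = 1)
  expect_equal(sum(eq$occupancy), 0)

  pz <- spindle_params(crosslinkers = list(
    number = 15, one_head_on_rate = 0, one_head_off_rate = 0,
    two_head_on_rate_scale = 0, two_head_off_rate = 0),
    control = list(timestep = 2e-4))
  st <- make_fixture("frozen_antiparallel_pair", pz, seed = 2)
  eq <- simulate_crosslink_equilibrium(st, pz, t_burn = 5, n_samples = 100,
                                       sample_interval = 0.1, seed = 3)
  expect_identical(eq$occupancy, c(100 * 15, 0, 0))  # everything stays free
})

test_that("bound heads relax a stretched crosslink on frozen filaments", {
  # two antiparallel MTs; a crosslink placed far off-register relaxes toward
  # the minimum-energy register by head diffusion with spring drift
  p <- spindle_params(crosslinkers = list(number = 1),
                      control = list(timestep = 1e-4))
  st <- make_fixture("frozen_antiparallel_pair", p, seed = 1,
                     separation = p$crosslinkers$rest_length, mt_length = 2)
  # head coordinates chosen 0.4 um out of register (x0 + x1 = 2 at register)
  st$xl$state[1] <- 2L
  st$xl$mt0[1] <- 1L
  st$xl$mt1[1] <- 2L
  st$xl$geom[1, "x0"] <- 1.2
  st$xl$geom[1, "x1"] <- 1.2   # register requires x1 = 2 - x0 = 0.8
  pz <- p
  pz$crosslinkers$two_head_off_rate <- 0   # keep it bound while it relaxes
  pz$crosslinkers$one_head_off_rate <- 0
  pz$crosslinkers$one_head_on_rate <- 0
  eq <- simulate_crosslink_equilibrium(st, pz, t_burn = 2, n_samples = 50,
                                       sample_interval = 0.02, seed = 7)
  mis <- abs(eq$two_bound_pos_a + eq$two_bound_pos_b - 2)
  expect_lt(mean(mis), 0.05)   # mean register mismatch relaxed from 0.4
})
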