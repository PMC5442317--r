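test_that("stabilization scaling is local, binary and directional", {
  p <- spindle_params(stabilization = list(rescue_factor = 10))
  di <- p$dynamic_instability
  L <- 2

  # identity factors leave everything unchanged
  p1 <- spindle_params(stabilization = list(growth_factor = 1,
                                            shrink_factor = 1,
                                            catastrophe_factor = 1,
                                            rescue_factor = 1))
  out <- stabilization_scaling(L, head_positions = L, p1, enabled = TRUE)
  expect_equal(out[1:4], p1$dynamic_instability[1:4])

  # disabled stabilization (the rescue-factor-deletion mimic)
  out <- stabilization_scaling(L, head_positions = L, p, enabled = FALSE)
  expect_equal(out[1:4], di[1:4])
  expect_false(out$stabilized)

  # crosslink beyond the threshold distance from the plus end
  s <- p$stabilization$stabilization_length
  out <- stabilization_scaling(L, head_positions = L - 1.5 * s, p,
                               enabled = TRUE)
  expect_equal(out[1:4], di[1:4])

  # crosslink at half the threshold distance: full scaling, rescue exactly x10
  out <- stabilization_scaling(L, head_positions = L - 0.5 * s, p,
                               enabled = TRUE)
  expect_true(out$stabilized)
  expect_equal(out$rescue_frequency, di$rescue_frequency * 10)
  expect_equal(out$catastrophe_frequency,
               di$catastrophe_frequency / p$stabilization$catastrophe_factor)
  expect_equal(out$shrinking_speed,
               di$shrinking_speed / p$stabilization$shrink_factor)
  expect_equal(out$growth_speed,
               di$growth_speed * p$stabilization$growth_factor)

  # multiple crosslinks do not stack
  out2 <- stabilization_scaling(L, head_positions = c(L, L - 0.01, L - 0.02),
                                p, enabled = TRUE)
  expect_equal(out2, out)

  expect_error(stabilization_scaling(L, head_positions = L + 1, p),
               "outside")
})

test_that("switching waiting times are exponential at the configured rates", {
  # unbounded-growth parameters so no shrinking spell is censored by the
  # renucleation floor (censoring would distort the rescue-wait distribution)
  p <- spindle_params(dynamic_instability = list(
    growth_speed = 0.2, shrinking_speed = 0.05,
    catastrophe_frequency = 0.3, rescue_frequency = 0.5))
  ens <- simulate_mt_ensemble(p, n_mt = 200, t_measure = 1500, t_burn = 50,
                              dt = 0.01, seed = 21, max_events = 20000)
  cw <- ens$catastrophe_waits
  rw <- ens$rescue_waits
  expect_gte(length(cw), 10000)
  # dither within the step interval: events are resolved to one timestep
  dith <- function(x, dt) x - runif(length(x), 0, dt)
  withr::with_seed(1, {
    kc <- stats::ks.test(dith(cw, 0.01), "pexp", rate = 0.3)
    kr <- stats::ks.test(dith(rw, 0.01), "pexp", rate = 0.5)
  })
  expect_gt(kc$p.value, 0.01)
  expect_gt(kr$p.value, 0.01)
})

test_that("bounded-regime mean length converges to the closed form", {
  sets <- list(
    list(growth_speed = 0.064, shrinking_speed = 0.1,
         catastrophe_frequency = 0.132, rescue_frequency = 0.05),
    list(growth_speed = 0.03, shrinking_speed = 0.15,
         catastrophe_frequency = 0.2, rescue_frequency = 0.1),
    list(growth_speed = 0.1, shrinking_speed = 0.08,
         catastrophe_frequency = 0.5, rescue_frequency = 0.05))
  for (i in seq_along(sets)) {
    p <- spindle_params(dynamic_instability = sets[[i]])
    ens <- simulate_mt_ensemble(p, n_mt = 400, t_measure = 4000, t_burn = 300,
                                dt = 0.01, seed = 30 + i)
    expect_lt(abs(ens$mean_length - ens$expected_mean) / ens$expected_mean,
              0.05)
  }
})

test_that("stabilized reference parameters are in the unbounded regime", {
  p <- reference_params()
  st <- p$stabilization
  di <- p$dynamic_instability
  # after scaling, f_c v_s < f_r v_g: no bounded mean exists
  expect_identical(mt_mean_length_bounded(list(
    growth_speed = di$growth_speed * st$growth_factor,
    shrinking_speed = di$shrinking_speed / st$shrink_factor,
    catastrophe_frequency = di$catastrophe_frequency / st$catastrophe_factor,
    rescue_frequency = di$rescue_frequency * st$rescue_factor)), Inf)

  # mean length grows linearly in time
  ens <- simulate_mt_ensemble(p, n_mt = 100, t_measure = 500, t_burn = 0,
                              dt = 0.01, seed = 5, stabilized = TRUE,
                              ts_interval = 10)
  ts <- ens$mean_length_series
  tt <- seq_along(ts) * 10
  fit <- stats::lm(ts ~ tt)
  # slope close to the stabilized net growth speed (all MTs growing)
  v_net <- di$growth_speed * st$growth_factor
  expect_gt(coef(fit)[2], 0.8 * v_net)
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("shrinkage renucleates at the floor in the growing state", {
  # shrink-dominated parameters: lengths pile near the floor, never below
  p <- spindle_params(dynamic_instability = list(
    growth_speed = 0.005, shrinking_speed = 0.5,
    catastrophe_frequency = 2, rescue_frequency = 0.01))
  ens <- simulate_mt_ensemble(p, n_mt = 100, t_measure = 200, t_burn = 10,
                              dt = 0.005, seed = 9)
  expect_true(all(ens$final_lengths >= p$geometry$min_mt_length - 1e-12))
  expect_lt(ens$mean_length, 0.05)
})
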