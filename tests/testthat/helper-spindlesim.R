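# shared helpers for the test suite

# coarse-timestep control profile used for whole-spindle simulations in the
# suite; the methods vignette documents the convergence check behind it
fast_control <- function(total_time = 600, ...) {
  c(list(timestep = 2e-3, total_time = total_time), list(...))
}

# a small, fully valid parameter set for unit tests that never run the clock
tiny_params <- function(...) {
  spindle_params(...)
}

# reference parameters with the coarse control profile
fast_reference <- function(total_time = 600, frame_interval = 1, ...) {
  spindle_params(control = fast_control(total_time = total_time,
                                        frame_interval = frame_interval),
                 ...)
}

expect_close <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("|%g - %g| <= %g", object, expected, tol))
}

# stochastic oracle: Gillespie simulation of 13 protofilaments sharing a
# compressive load; every subunit addition advances the tip by sigma and does
# work F*sigma against the load, removals are load-free
ratchet_oracle <- function(F, v_g, F_s, sigma, kT, t_end = 4000, seed = 1) {
  withr::with_seed(seed, {
    alpha <- exp(F_s * sigma / kT)
    # per-filament rates chosen so the unloaded ensemble speed is v_g
    k_off <- v_g / (13 * sigma * (alpha - 1))
    k_on <- alpha * k_off
    t <- 0
    len <- 0
    k_on_F <- k_on * exp(-F * sigma / kT) * 13  # total addition propensity
    k_off_T <- k_off * 13
    tot <- k_on_F + k_off_T
    n_events <- rpois(1, tot * t_end)
    if (n_events > 0) {
      adds <- runif(n_events) < k_on_F / tot
      len <- sigma * (sum(adds) - sum(!adds))
    }
    len / t_end
  })
}

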