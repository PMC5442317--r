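#' Crosslink-induced stabilization of dynamic-instability parameters
#'
#' When a crosslink (a doubly bound crosslinker head) sits within the
#' stabilization length \code{s} of a microtubule's plus end, that MT's
#' dynamic instability is stabilized: catastrophe frequency divided by its
#' factor, rescue frequency multiplied, growth speed multiplied, shrinking
#' speed divided. The rule is binary (factors saturate; multiple nearby
#' crosslinks do not stack) and acts only through the plus end.
#'
#' @param mt_length length of the microtubule, um.
#' @param head_positions arc coordinates (um, from the minus end) of every
#'   crosslink head bound to this MT; may be empty.
#' @param params a \code{spindle_params} object.
#' @param enabled logical; when \code{FALSE} (the crosslinker-without-rescue
#'   mimic) the base parameters are returned unchanged regardless of
#'   crosslinks.
#' @return A named list with \code{growth_speed}, \code{shrinking_speed},
#'   \code{catastrophe_frequency}, \code{rescue_frequency} and the logical
#'   \code{stabilized}.
#' @export
stabilization_scaling <- function(mt_length, head_positions, params,
                                  enabled = params$control$stabilization_enabled) {
  di <- params$dynamic_instability
  st <- params$stabilization
  if (length(head_positions) > 0 &&
      any(head_positions < 0 | head_positions > mt_length))
    stop("crosslink attachment coordinate outside [0, length]", call. = FALSE)
  stab <- isTRUE(enabled) && length(head_positions) > 0 &&
    any(mt_length - head_positions <= st$stabilization_length)
  if (stab) {
    list(growth_speed = di$growth_speed * st$growth_factor,
         shrinking_speed = di$shrinking_speed / st$shrink_factor,
         catastrophe_frequency = di$catastrophe_frequency /
           st$catastrophe_factor,
         rescue_frequency = di$rescue_frequency * st$rescue_factor,
         stabilized = TRUE)
  } else {
    list(growth_speed = di$growth_speed,
         shrinking_speed = di$shrinking_speed,
         catastrophe_frequency = di$catastrophe_frequency,
         rescue_frequency = di$rescue_frequency,
         stabilized = FALSE)
  }
}

#' Closed-form mean length in the bounded-growth regime
#'
#' For unstabilized four-parameter dynamic instability with renucleation at
#' zero length, the stationary length distribution is exponential with mean
#' \deqn{\langle L \rangle = v_g v_s / (f_c v_s - f_r v_g),}
#' defined when \eqn{f_c v_s > f_r v_g} (the bounded regime). Returns
#' \code{Inf} in the unbounded regime, where the mean length grows linearly
#' in time instead.
#'
#' @param params a \code{spindle_params} object, or a list with the four
#'   dynamic-instability fields.
#' @return Mean length in um (\code{Inf} if growth is unbounded).
#' @examples
#' mt_mean_length_bounded(reference_params()) # 0.64
#' @export
mt_mean_length_bounded <- function(params) {
  di <- if (inherits(params, "spindle_params")) params$dynamic_instability
        else params
  denom <- di$catastrophe_frequency * di$shrinking_speed -
    di$rescue_frequency * di$growth_speed
  if (denom <= 0) return(Inf)
  di$growth_speed * di$shrinking_speed / denom
}

#' Simulate an ensemble of independent dynamic microtubules
#'
#' Runs \code{n_mt} independent plus ends under four-parameter dynamic
#' instability with no boundary, no forces and no crosslinkers: the
#' calibration workhorse for the mean-length check and for waiting-time
#' statistics. Catastrophes and rescues are single Bernoulli draws per MT per
#' step with probabilities \eqn{1 - e^{-f dt}}; shrinkage below the minimum
#' length renucleates the MT (length reset to the floor, state growing).
#'
#' @param params a \code{spindle_params} object; the dynamic-instability
#'   section, initial/minimum lengths and (optionally) stabilization define
#'   the ensemble.
#' @param n_mt ensemble size.
#' @param t_measure measured simulated time (s) after burn-in.
#' @param t_burn burn-in time (s) excluded from averages.
#' @param dt timestep (s); defaults to 0.01 s, ample for rates of order
#'   0.1/s.
#' @param seed integer seed.
#' @param stabilized simulate the stabilized parameter set instead (all four
#'   factors applied), e.g. to demonstrate unbounded growth.
#' @param ts_interval spacing (s) of the recorded mean-length series.
#' @param max_events cap on recorded switching waiting times.
#' @return A list: \code{mean_length} (ensemble/time average),
#'   \code{final_lengths}, \code{mean_length_series},
#'   \code{catastrophe_waits}, \code{rescue_waits}, and the closed-form
#'   \code{expected_mean}.
#' @export
simulate_mt_ensemble <- function(params, n_mt = 500, t_measure = 1e4,
                                 t_burn = 200, dt = 0.01, seed = 1,
                                 stabilized = FALSE, ts_interval = 10,
                                 max_events = 50000) {
  stopifnot(inherits(params, "spindle_params"))
  di <- params$dynamic_instability
  if (stabilized) {
    st <- params$stabilization
    di <- list(growth_speed = di$growth_speed * st$growth_factor,
               shrinking_speed = di$shrinking_speed / st$shrink_factor,
               catastrophe_frequency = di$catastrophe_frequency /
                 st$catastrophe_factor,
               rescue_frequency = di$rescue_frequency * st$rescue_factor)
  }
  rate_max <- max(di$catastrophe_frequency, di$rescue_frequency)
  if (rate_max * dt > 0.1)
    warning("switching rate * dt = ", signif(rate_max * dt, 3),
            " > 0.1; waiting-time statistics will be coarse", call. = FALSE)
  out <- cpp_mt_ensemble(di$growth_speed, di$shrinking_speed,
                         di$catastrophe_frequency, di$rescue_frequency,
                         dt, t_burn, t_measure, as.integer(n_mt),
                         params$geometry$initial_mt_length,
                         params$geometry$min_mt_length,
                         ts_interval, as.integer(max_events),
                         as.integer(seed))
  out$expected_mean <- mt_mean_length_bounded(di)
  out
}
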