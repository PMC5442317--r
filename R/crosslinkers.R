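#' Antiparallel test for a microtubule pair
#'
#' Crosslinking in this model is restricted to antiparallel MT pairs:
#' a pair is crosslinkable iff the dot product of the orientation unit
#' vectors is below the threshold (default 0, the strict hemisphere rule).
#'
#' @param orientation_a,orientation_b length-3 orientation unit vectors.
#' @param threshold crosslink allowed iff \code{dot < threshold}.
#' @return logical.
#' @examples
#' is_antiparallel(c(1, 0, 0), c(-1, 0, 0)) # TRUE
#' is_antiparallel(c(1, 0, 0), c(1, 0, 0))  # FALSE
#' @export
is_antiparallel <- function(orientation_a, orientation_b, threshold = 0) {
  sum(orientation_a * orientation_b) < threshold
}

#' Harmonic crosslink force between two bound heads
#'
#' A doubly bound crosslinker acts as a harmonic spring between its two
#' attachment points: magnitude \eqn{k_{xl}(|d| - r_0)} along the
#' head-to-head vector, attractive when stretched, repulsive when
#' compressed; the two filaments receive equal and opposite forces.
#'
#' @param head_a,head_b attachment points (length-3, um).
#' @param params a \code{spindle_params} object.
#' @return list with \code{force_on_a}, \code{force_on_b} (pN) and the scalar
#'   \code{extension} (um, signed relative to rest length).
#' @export
crosslink_force <- function(head_a, head_b, params) {
  xl <- params$crosslinkers
  d <- head_b - head_a
  dist <- sqrt(sum(d^2))
  if (dist < 1e-12)
    return(list(force_on_a = c(0, 0, 0), force_on_b = c(0, 0, 0),
                extension = -xl$rest_length))
  ext <- dist - xl$rest_length
  f <- xl$spring_constant * ext * d / dist
  list(force_on_a = f, force_on_b = -f, extension = ext)
}

#' Crosslink spring energy at a given head separation
#'
#' @param separation head-to-head distance(s), um.
#' @param params a \code{spindle_params} object.
#' @return energy in kT units.
#' @export
crosslink_energy_kt <- function(separation, params) {
  xl <- params$crosslinkers
  kT <- params$ratchet$thermal_energy * 1e-3
  0.5 * xl$spring_constant * (separation - xl$rest_length)^2 / kT
}

#' Crosslinker kinetics on frozen filaments
#'
#' Runs only the crosslinker kinetic Monte Carlo and head/free diffusion on a
#' frozen system state (filaments and SPBs never move), sampling the
#' crosslinker population at fixed intervals. This is the surface on which
#' the binding/unbinding rules are validated against direct Boltzmann
#' integration: for static filaments the sampled occupancy of the
#' free/one-bound/two-bound states and the attachment-position density along
#' the filaments must match the equilibrium distribution implied by the same
#' energies and rates.
#'
#' @param state a \code{spindle_state} (typically from
#'   \code{\link{make_fixture}}).
#' @param params a \code{spindle_params} object; \code{control$timestep} is
#'   the kMC timestep.
#' @param t_burn equilibration time, s.
#' @param n_samples number of population snapshots.
#' @param sample_interval time between snapshots, s.
#' @param seed integer seed.
#' @return list: \code{occupancy} (total counts over snapshots for 0/1/2
#'   heads bound), \code{one_bound_pos}/\code{one_bound_mt}, and
#'   \code{two_bound_pos_a}/\code{two_bound_pos_b} (arc coordinates, the
#'   lower-indexed MT first).
#' @export
simulate_crosslink_equilibrium <- function(state, params, t_burn = 50,
                                           n_samples = 10000,
                                           sample_interval = 0.5, seed = 1) {
  stopifnot(inherits(state, "spindle_state"),
            inherits(params, "spindle_params"))
  cpp_xl_equilibrium(unclass(params), unclass(state), t_burn,
                     as.integer(n_samples), sample_interval,
                     as.integer(seed))
}
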