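#' Initialize a side-by-side spindle configuration
#'
#' Places the two SPBs adjacent on the nuclear envelope (centre separation =
#' one SPB diameter), nucleates \code{sites_per_spb} MTs per SPB at the
#' initial length with inward-pointing orientations given a small random
#' tilt, and scatters all crosslinkers unbound and uniformly through the
#' envelope interior. Bitwise deterministic given the seed.
#'
#' @param params a \code{spindle_params} object.
#' @param seed integer seed.
#' @return a \code{spindle_state}.
#' @export
initialize_spindle <- function(params, seed) {
  validate_params(params)
  st <- cpp_sim_init(unclass(params), as.integer(seed))
  class(st) <- "spindle_state"
  st
}

#' Run one spindle assembly simulation
#'
#' The full time-stepping loop. Each step: deterministic forces (minus-end
#' tethers, rod-rod sterics, crosslink springs, envelope wall force), then
#' crosslink-induced stabilization and the dynamic-instability update with
#' force-dependent growth, then crosslinker kinetic Monte Carlo and head
#' diffusion, then the overdamped Brownian move of rods and SPBs. Frames are
#' recorded every \code{frame_interval} and the run is classified with the
#' interpolar-fraction criterion.
#'
#' @param params a \code{spindle_params} object.
#' @param seed integer seed; a run is fully reproducible from
#'   \code{(params, seed)}.
#' @return An object of class \code{spindle_run}: list with
#'   \code{trajectory} (data frame: time, separation, interpolar_fraction,
#'   mean_mt_length, crosslinker state counts, SPB coordinates),
#'   \code{summary} (success flag, formation start time, late-time
#'   separation, mean MT length), \code{final_state}, \code{params},
#'   \code{seed}.
#' @examples
#' \donttest{
#' p <- spindle_params(control = list(timestep = 2e-3, total_time = 60))
#' r <- run_simulation(p, seed = 7)
#' tail(r$trajectory$separation, 3)
#' }
#' @export
run_simulation <- function(params, seed) {
  validate_params(params)
  warn_rates(params)
  raw <- cpp_sim_run(unclass(params), as.integer(seed))
  traj <- data.frame(
    time = raw$time,
    separation = raw$separation,
    interpolar_fraction = raw$interpolar_fraction,
    interpolar_fraction_length = raw$interpolar_fraction_length,
    mean_mt_length = raw$mean_mt_length,
    n_free = raw$n_free,
    n_one_bound = raw$n_one_bound,
    n_two_bound = raw$n_two_bound,
    spb1_x = raw$spb1[, 1], spb1_y = raw$spb1[, 2], spb1_z = raw$spb1[, 3],
    spb2_x = raw$spb2[, 1], spb2_y = raw$spb2[, 2], spb2_z = raw$spb2[, 3]
  )
  cls <- if (max(traj$time) >= 120) {
    classify_success(traj$interpolar_fraction, params$control$frame_interval)
  } else {
    list(success = NA, start_time = NA_real_)  # too short to classify
  }
  smry <- list(
    success = cls$success,
    start_time = cls$start_time,
    late_separation = late_time_separation(traj),
    mean_mt_length = mean(traj$mean_mt_length),
    cap_events = raw$cap_events
  )
  out <- list(trajectory = traj, summary = smry, params = params,
              seed = seed, final_state = structure(raw$final_state,
                                                   class = "spindle_state"))
  if (!is.null(raw$mt_lengths)) {
    out$mt_lengths <- raw$mt_lengths
    out$mt_states <- raw$mt_states
  }
  class(out) <- "spindle_run"
  out
}

#' @export
print.spindle_run <- function(x, ...) {
  s <- x$summary
  cat("<spindle_run> seed", x$seed, "\n")
  cat(sprintf("  success: %s%s\n", s$success,
              if (s$success) sprintf(" (formed at %.0f s)", s$start_time)
              else ""))
  cat(sprintf("  late-time SPB separation: %.3f um\n", s$late_separation))
  cat(sprintf("  mean MT length: %.3f um\n", s$mean_mt_length))
  invisible(x)
}

warn_rates <- function(params) {
  di <- params$dynamic_instability
  st <- params$stabilization
  xl <- params$crosslinkers
  ct <- params$control
  r <- max(di$catastrophe_frequency, di$rescue_frequency * st$rescue_factor,
           xl$one_head_off_rate, 2 * xl$two_head_off_rate)
  if (r * ct$timestep * max(ct$xl_pair_interval, 1) > 0.1)
    warning("max kinetic rate * effective timestep exceeds 0.1; ",
            "first-order kMC splitting is coarse at these settings",
            call. = FALSE)
  invisible(NULL)
}

#' Deterministic forces and torques for a given state
#'
#' Computes the tether, steric, crosslink and wall contributions separately
#' for every MT (forces and torques about the rod centre) and the tether /
#' disk-repulsion forces and spin torques on the SPBs, without advancing the
#' system: the inspection surface used by the force-closure and wall-force
#' tests and for debugging fixtures.
#'
#' @param state a \code{spindle_state}.
#' @param params a \code{spindle_params} object.
#' @return list of per-component force/torque matrices (one row per MT), the
#'   per-MT axial plus-tip load, and per-SPB contributions.
#' @export
spindle_forces <- function(state, params) {
  stopifnot(inherits(state, "spindle_state"))
  validate_params(params)
  cpp_sim_forces(unclass(params), unclass(state))
}

#' Write a run's outputs to a directory
#'
#' Writes \code{trajectory.csv}, \code{summary.json} and the canonicalized
#' resolved configuration \code{config.yaml} (plus the seed) so a run can be
#' reproduced exactly from its output directory.
#'
#' @param run a \code{spindle_run}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
save_run <- function(run, dir) {
  stopifnot(inherits(run, "spindle_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$trajectory, file.path(dir, "trajectory.csv"),
                   row.names = FALSE)
  jsonlite::write_json(c(run$summary, list(seed = run$seed)),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_config(run$params, file.path(dir, "config.yaml"))
  invisible(dir)
}
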