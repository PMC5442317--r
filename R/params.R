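#' Build a full simulation parameter set
#'
#' Constructs the complete, validated parameter object for the spindle
#' assembly model. Units throughout: lengths in micrometres, time in seconds,
#' force in piconewtons; the thermal energy is given in pN nm (the community
#' convention kT = 4.11 pN nm is the default). Any subset of fields can be
#' overridden per section; everything else takes the documented reference
#' value (see \code{\link{reference_params}} and the methods vignette for the
#' full defaults table and its rationale).
#'
#' @param geometry,dynamic_instability,stabilization,crosslinkers,wall_force,ratchet,control
#'   named lists of overrides for the corresponding parameter section.
#' @return An object of class \code{spindle_params}: a named list of the seven
#'   parameter sections.
#' @examples
#' p <- spindle_params(crosslinkers = list(number = 200))
#' p$crosslinkers$number
#' @export
spindle_params <- function(geometry = list(), dynamic_instability = list(),
                           stabilization = list(), crosslinkers = list(),
                           wall_force = list(), ratchet = list(),
                           control = list()) {
  d <- param_defaults()
  p <- list(
    geometry = merge_section(d$geometry, geometry, "geometry"),
    dynamic_instability = merge_section(d$dynamic_instability,
                                        dynamic_instability,
                                        "dynamic_instability"),
    stabilization = merge_section(d$stabilization, stabilization,
                                  "stabilization"),
    crosslinkers = merge_section(d$crosslinkers, crosslinkers, "crosslinkers"),
    wall_force = merge_section(d$wall_force, wall_force, "wall_force"),
    ratchet = merge_section(d$ratchet, ratchet, "ratchet"),
    control = merge_section(d$control, control, "control")
  )
  class(p) <- "spindle_params"
  validate_params(p)
  p
}

#' The reference parameter set
#'
#' Returns the model's reference parameters: fission-yeast-scale geometry
#' (2.75 um nuclear envelope, 0.18 um spindle pole bodies with 14 nucleation
#' sites each, 25 nm microtubules), dynamic-instability parameters chosen so
#' that the unstabilized bounded-growth mean length
#' \eqn{v_g v_s / (f_c v_s - f_r v_g)} equals 0.64 um exactly, and
#' crosslink-induced stabilization factors in the regime where bipolar
#' spindles assemble (rescue stabilized >= 10-fold, shrinking slowed >=
#' 5-fold). A pure function: repeated calls return identical values.
#'
#' @return A \code{spindle_params} object.
#' @examples
#' p <- reference_params()
#' di <- p$dynamic_instability
#' with(di, growth_speed * shrinking_speed /
#'   (catastrophe_frequency * shrinking_speed -
#'    rescue_frequency * growth_speed)) # 0.64
#' @export
reference_params <- function() {
  spindle_params()
}

param_defaults <- function() {
  list(
    geometry = list(
      envelope_diameter = 2.75,
      spb_diameter = 0.18,
      spb_diffusion_coefficient = 1.5e-3,
      spb_rotational_diffusion = 0.185,
      mt_diameter = 0.025,
      sites_per_spb = 14,
      tether_spring_constant = 100,
      tether_rest_length = 0,
      initial_mt_length = 0.1,
      min_mt_length = 8 / 13 * 1e-3,
      viscosity = 1.0,
      nucleation_stiffness = 0.1,
      nucleation_cone = 0.8
    ),
    dynamic_instability = list(
      growth_speed = 0.064,
      shrinking_speed = 0.1,
      catastrophe_frequency = 0.132,
      rescue_frequency = 0.05,
      force_catastrophe = TRUE,
      force_catastrophe_cap = 20
    ),
    stabilization = list(
      growth_factor = 1.5,
      shrink_factor = 8,
      catastrophe_factor = 8,
      rescue_factor = 15,
      stabilization_length = 0.1
    ),
    crosslinkers = list(
      number = 160,
      spring_constant = 207,
      rest_length = 0.053,
      one_head_on_rate = 800,
      one_head_off_rate = 1,
      two_head_on_rate_scale = 3000,
      two_head_off_rate = 0.08,
      bound_diffusion_coefficient = 0.1,
      free_diffusion_coefficient = 1.0,
      antiparallel_only = TRUE,
      antiparallel_threshold = -0.5,
      characteristic_binding_energy = 6.0,
      bell_parameter = 0.001,
      capture_radius = 0.053,
      quadrature_bin = 0.01,
      energy_cutoff_kt = 20,
      end_release = FALSE,
      minus_exclusion = 0
    ),
    wall_force = list(
      asymptotic_force = 7.6,
      tube_radius = 0.05,
      euler_gamma = 0.5772156649,
      const_a = 0.5416,
      const_c = 4.038,
      blend_length = 1.0
    ),
    ratchet = list(
      protofilament_count = 13,
      subunit_increment = 8 / 13 * 1e-3,
      stall_scale = 5.0,
      thermal_energy = 4.11
    ),
    control = list(
      timestep = 5e-5,
      total_time = 600,
      frame_interval = 1,
      initial_pole_angle = 0,
      rng_seed = 1,
      stabilization_enabled = TRUE,
      record_mt_detail = FALSE,
      xl_free_interval = 10,
      xl_pair_interval = 5,
      neighbor_interval = 20,
      max_step_translation = 0.005,
      max_step_rotation = 0.05,
      steric_strength = 1
    )
  )
}

merge_section <- function(defaults, overrides, section) {
  if (length(overrides) == 0) return(defaults)
  if (is.null(names(overrides)) || any(names(overrides) == ""))
    stop("all overrides in section '", section, "' must be named",
         call. = FALSE)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0)
    stop("unknown parameter field(s) in section '", section, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  defaults[names(overrides)] <- overrides
  defaults
}

#' Validate a parameter object
#'
#' Checks every model invariant (positivity, factor bounds, fixed constants,
#' geometric consistency) and fails with an informative message naming the
#' offending value. Called automatically by \code{\link{spindle_params}}.
#'
#' @param p a \code{spindle_params} object.
#' @return \code{p}, invisibly, if valid.
#' @export
validate_params <- function(p) {
  g <- p$geometry; di <- p$dynamic_instability; st <- p$stabilization
  xl <- p$crosslinkers; wf <- p$wall_force; rt <- p$ratchet; ct <- p$control

  need_pos <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
      stop("validation error: ", what, " must be a positive number, got ",
           format(x), call. = FALSE)
  }
  need_nonneg <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0)
      stop("validation error: ", what, " must be >= 0, got ", format(x),
           call. = FALSE)
  }

  need_pos(di$growth_speed, "growth_speed")
  need_pos(di$shrinking_speed, "shrinking_speed")
  need_pos(di$catastrophe_frequency, "catastrophe_frequency")
  need_pos(di$rescue_frequency, "rescue_frequency")

  for (f in c("growth_factor", "shrink_factor", "catastrophe_factor",
              "rescue_factor")) {
    if (!is.numeric(st[[f]]) || st[[f]] < 1)
      stop("validation error: stabilization ", f, " must be >= 1, got ",
           format(st[[f]]), call. = FALSE)
  }
  need_pos(st$stabilization_length, "stabilization_length")

  need_nonneg(xl$number, "crosslinker number")
  need_pos(xl$rest_length, "crosslinker rest_length")
  for (f in c("spring_constant", "one_head_on_rate", "one_head_off_rate",
              "two_head_on_rate_scale", "two_head_off_rate",
              "bound_diffusion_coefficient", "free_diffusion_coefficient",
              "bell_parameter"))
    need_nonneg(xl[[f]], paste0("crosslinker ", f))
  if (!isTRUE(xl$antiparallel_only))
    stop("validation error: antiparallel_only is fixed TRUE in this model",
         call. = FALSE)
  need_pos(xl$capture_radius, "capture_radius")
  need_pos(xl$quadrature_bin, "quadrature_bin")

  need_nonneg(wf$asymptotic_force, "asymptotic wall force")
  need_pos(wf$tube_radius, "tube_radius")
  need_pos(wf$blend_length, "blend_length")

  if (rt$protofilament_count != 13)
    stop("validation error: protofilament_count is fixed at 13", call. = FALSE)
  if (abs(rt$subunit_increment - 8 / 13 * 1e-3) > 1e-12)
    stop("validation error: subunit_increment is fixed at 8/13 nm",
         call. = FALSE)
  need_pos(rt$stall_scale, "stall_scale")
  need_pos(rt$thermal_energy, "thermal_energy")

  need_pos(g$envelope_diameter, "envelope_diameter")
  need_pos(g$spb_diameter, "spb_diameter")
  need_pos(g$mt_diameter, "mt_diameter")
  need_pos(g$initial_mt_length, "initial_mt_length")
  need_pos(g$viscosity, "viscosity")
  need_nonneg(g$tether_rest_length, "tether_rest_length")
  if (g$sites_per_spb < 1)
    stop("validation error: sites_per_spb must be >= 1", call. = FALSE)
  if (g$envelope_diameter <= 2 * g$initial_mt_length)
    stop("validation error: envelope_diameter (", g$envelope_diameter,
         ") must exceed twice the initial MT length", call. = FALSE)

  need_pos(ct$timestep, "timestep")
  if (ct$frame_interval < ct$timestep)
    stop("validation error: frame_interval must be >= timestep",
         call. = FALSE)
  if (ct$total_time < ct$frame_interval)
    stop("validation error: total_time must be >= frame_interval",
         call. = FALSE)
  invisible(p)
}

#' @export
print.spindle_params <- function(x, ...) {
  cat("<spindle_params>\n")
  for (s in names(x)) {
    v <- vapply(x[[s]], function(e) format(e), "")
    cat("  [", s, "] ", paste0(names(x[[s]]), "=", v, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Read a configuration file
#'
#' Loads a YAML configuration with any subset of the sections
#' \code{geometry}, \code{dynamic_instability}, \code{stabilization},
#' \code{crosslinkers}, \code{wall_force}, \code{ratchet}, \code{control};
#' absent fields take the reference defaults and the result is validated.
#'
#' @param path path to a YAML config file.
#' @return A \code{spindle_params} object.
#' @seealso \code{\link{write_config}}
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("configuration error: file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw))
    stop("configuration error: ", path, " does not parse to a mapping",
         call. = FALSE)
  known <- names(param_defaults())
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("configuration error: unknown section(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  do.call(spindle_params, raw[intersect(names(raw), known)])
}

#' Write a canonicalized configuration file
#'
#' Serializes the fully resolved parameter object (every field explicit) so a
#' run's exact inputs can be archived next to its outputs and re-loaded with
#' \code{\link{load_config}}.
#'
#' @param params a \code{spindle_params} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(params, path) {
  validate_params(params)
  x <- unclass(params)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' Default sampling ranges for the nine-parameter scan
#'
#' The nine sampled quantities are the crosslinker number, the four
#' dynamic-instability parameters, and the four stabilization factors.
#' Defaults: one order of magnitude either side of the reference
#' dynamic-instability values, 0 to twice the reference crosslinker number,
#' and 1 to 50 for the stabilization factors. Every entry can be overridden,
#' or a full set read from JSON with \code{\link{load_sampling_ranges}}.
#'
#' @param ... named \code{c(min, max)} overrides for any of the nine entries.
#' @return A named list of length-2 numeric vectors, class
#'   \code{sampling_ranges}.
#' @export
sampling_ranges <- function(...) {
  ref <- param_defaults()
  di <- ref$dynamic_instability
  r <- list(
    number = c(0, 2 * ref$crosslinkers$number),
    growth_speed = c(di$growth_speed / 10, di$growth_speed * 10),
    shrinking_speed = c(di$shrinking_speed / 10, di$shrinking_speed * 10),
    catastrophe_frequency = c(di$catastrophe_frequency / 10,
                              di$catastrophe_frequency * 10),
    rescue_frequency = c(di$rescue_frequency / 10, di$rescue_frequency * 10),
    growth_factor = c(1, 50),
    shrink_factor = c(1, 50),
    catastrophe_factor = c(1, 50),
    rescue_factor = c(1, 50)
  )
  ov <- list(...)
  if (length(ov) > 0) {
    unknown <- setdiff(names(ov), names(r))
    if (length(unknown) > 0)
      stop("unknown sampled parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    r[names(ov)] <- ov
  }
  for (nm in names(r)) {
    v <- r[[nm]]
    if (length(v) != 2 || !all(is.finite(v)) || v[1] > v[2])
      stop("validation error: range for ", nm,
           " must be c(min, max) with min <= max", call. = FALSE)
  }
  class(r) <- "sampling_ranges"
  r
}

#' Read sampling ranges from a JSON file
#'
#' @param path JSON file mapping each of the nine sampled parameters to a
#'   two-element \code{[min, max]} array.
#' @return A \code{sampling_ranges} object.
#' @export
load_sampling_ranges <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(sampling_ranges, as.list(raw))
}

#' Randomly sample parameter sets for a scan
#'
#' Draws \code{n_sets} parameter sets, each of the nine scanned quantities
#' independently and uniformly from its range. With
#' \code{stabilization_enabled = FALSE} all four stabilization factors are
#' pinned at exactly 1 (the crosslinkers can still bind but no longer
#' stabilize dynamics) and only the remaining five parameters vary.
#' Deterministic given \code{seed}; R's global RNG state is left untouched.
#'
#' @param ranges a \code{\link{sampling_ranges}} object.
#' @param n_sets number of parameter sets to draw.
#' @param seed integer seed.
#' @param stabilization_enabled logical; see above.
#' @param base base \code{spindle_params} the samples override.
#' @return A list of \code{parameter_sample} objects, each with elements
#'   \code{id}, \code{values} (the nine sampled values) and \code{params}
#'   (the full parameter object).
#' @export
sample_parameter_sets <- function(ranges, n_sets, seed,
                                  stabilization_enabled = TRUE,
                                  base = reference_params()) {
  stopifnot(inherits(ranges, "sampling_ranges"), n_sets >= 1)
  draws <- with_local_seed(seed, {
    vapply(names(unclass(ranges)), function(nm) {
      v <- ranges[[nm]]
      stats::runif(n_sets, v[1], v[2])
    }, numeric(n_sets))
  })
  draws <- matrix(draws, nrow = n_sets,
                  dimnames = list(NULL, names(unclass(ranges))))
  factors <- c("growth_factor", "shrink_factor", "catastrophe_factor",
               "rescue_factor")
  if (!stabilization_enabled) draws[, factors] <- 1
  draws[, "number"] <- round(draws[, "number"])
  lapply(seq_len(n_sets), function(i) {
    v <- draws[i, ]
    p <- base
    p$crosslinkers$number <- unname(v[["number"]])
    p$dynamic_instability$growth_speed <- unname(v[["growth_speed"]])
    p$dynamic_instability$shrinking_speed <- unname(v[["shrinking_speed"]])
    p$dynamic_instability$catastrophe_frequency <-
      unname(v[["catastrophe_frequency"]])
    p$dynamic_instability$rescue_frequency <- unname(v[["rescue_frequency"]])
    for (f in factors) p$stabilization[[f]] <- unname(v[[f]])
    p$control$stabilization_enabled <- stabilization_enabled
    validate_params(p)
    structure(list(id = i, values = v, params = p,
                   stabilization_enabled = stabilization_enabled),
              class = "parameter_sample")
  })
}

# run code under a temporary RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive per-run seeds for a scan: drawn up-front under the master seed so
# scheduling order cannot change any run's stream
derive_seeds <- function(master_seed, n) {
  with_local_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}
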