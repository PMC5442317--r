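#' Nuclear-envelope wall force on a protruding microtubule tip
#'
#' Inward radial force exerted by the deforming nuclear envelope on a
#' microtubule plus end that protrudes a distance \code{L} past the envelope
#' sphere. The force law blends the small-deformation (linear) membrane
#' response with the non-monotonic membrane-tube regime: the linear term is
#' the point-load response of a tense membrane,
#' \deqn{F_{lin}(L) = F_w L / (2 R_{tube} (\ln(2\sqrt{2}R_{tube}/r_{mt}) - \gamma)),}
#' with \eqn{\gamma = 0.5772...} Euler's constant, and the tube regime is the
#' damped oscillatory approach
#' \deqn{F_{nm}(L) = F_w (1 + a e^{-cL/b} \cos(cL/b)),}
#' with \eqn{a = 0.5416}, \eqn{c = 4.038} and \eqn{b = \sqrt{2} R_{tube}}.
#' The non-monotonic term carries the boundary-condition factor
#' \eqn{1 - e^{-L/\lambda}} (\eqn{\lambda} = \code{blend_length}) and the
#' linear term a complementary short-range weight \eqn{e^{-L/b}}, so that
#' \eqn{F(0) = 0} exactly and \eqn{F \to F_w} as the protrusion grows.
#'
#' @param L protrusion distance(s) past the envelope, um, \code{>= 0}.
#' @param params a \code{spindle_params} object (only the \code{wall_force}
#'   and \code{geometry$mt_diameter} fields are used).
#' @return Force in pN, same length as \code{L}, directed radially inward at
#'   the plus tip.
#' @examples
#' p <- spindle_params(wall_force = list(asymptotic_force = 14.8))
#' wall_force(c(0, 0.1, 5), p) # 0 at contact, ~14.8 pN asymptotically
#' @export
wall_force <- function(L, params) {
  stopifnot(inherits(params, "spindle_params"))
  if (any(L < 0)) stop("protrusion distance must be >= 0", call. = FALSE)
  wf <- params$wall_force
  cpp_wall_force(as.numeric(L), wf$asymptotic_force, wf$tube_radius,
                 wf$euler_gamma, wf$const_a, wf$const_c, wf$blend_length,
                 params$geometry$mt_diameter / 2)
}

#' Derived wall-force constant b
#'
#' \eqn{b = \sqrt{2} R_{tube}}; recomputed from the current tube radius, never
#' stored, so it can not go stale when \code{tube_radius} changes.
#'
#' @param params a \code{spindle_params} object.
#' @return b in um.
#' @export
wall_const_b <- function(params) {
  sqrt(2) * params$wall_force$tube_radius
}

#' Force-dependent microtubule growth speed (multi-filament Brownian ratchet)
#'
#' Growth speed of a 13-protofilament microtubule polymerizing against an
#' axial compressive load \code{F}. Each polymerization event advances the
#' tip by the per-protofilament increment \eqn{\sigma = 8/13} nm and does
#' work \eqn{F\sigma} against the load; with \eqn{\alpha = e^{F_s\sigma/kT}}
#' and \eqn{\beta = F\sigma/kT} the speed is
#' \deqn{v(F) = v_+ e^{-\beta} - (v_+ - v_g), \quad v_+ = v_g \alpha/(\alpha-1),}
#' i.e. \eqn{v(F) = v_g(\alpha e^{-\beta} - 1)/(\alpha - 1)}: the zero-force
#' limit is exactly the unloaded growth speed and the filament stalls at
#' \eqn{F = F_s} (clamped at zero beyond stall; shrinkage only occurs through
#' catastrophe).
#'
#' @param F axial compressive load(s), pN; tensile (negative) values clamp
#'   to 0.
#' @param v_g unloaded growth speed, um/s.
#' @param params a \code{spindle_params} object (\code{ratchet} section).
#' @return Growth speed(s) in um/s.
#' @examples
#' p <- reference_params()
#' growth_speed_under_load(0, 0.064, p) # = 0.064
#' growth_speed_under_load(p$ratchet$stall_scale, 0.064, p) # = 0 (stall)
#' @export
growth_speed_under_load <- function(F, v_g, params) {
  stopifnot(inherits(params, "spindle_params"))
  rt <- params$ratchet
  cpp_ratchet_speed(as.numeric(F), v_g, rt$stall_scale, rt$subunit_increment,
                    rt$thermal_energy)
}
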