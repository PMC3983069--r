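# The five protocols of intra-membrane stress generation.
#
# All pre-insertion states are represented on the flat reference domain:
# membrane curvature enters through the residual per-monolayer stress
# profiles and the external loads that maintain them (small-deformation
# kinematics).  Profiles combine
#   * a composition-driven ("chemical") three-zone modulation carrying the
#     frustration moment kappa * J_s of a monolayer whose spontaneous
#     curvature differs from its actual curvature, and
#   * the elastic stress E'(z) * eps(z) of mechanically strained material
#     (bending/stretching), whose depth profile follows the moduli profile.
#
# Sign conventions: bilayer curvature J > 0 bulges towards the outer
# monolayer; a monolayer's own curvature is +J (outer) or -J (inner); own
# bending strain is eps = c (z - z_n).

#' Scenario specification
#'
#' @param kind one of `"outer_Js"`, `"inner_Js"`, `"symmetric_Js"`,
#'   `"external_torque"`, `"stretch"`.
#' @param magnitude scenario magnitude: spontaneous curvature (nm^-1) for
#'   the `*_Js` kinds, torque (kT nm^-1) for `external_torque`,
#'   per-monolayer tension (kT nm^-2) for `stretch`.
#' @param coupling `"uncoupled"` or `"coupled"` (see [fem_reduce()]).
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(kind = c("outer_Js", "inner_Js", "symmetric_Js",
                                   "external_torque", "stretch"),
                          magnitude = 0,
                          coupling = c("uncoupled", "coupled")) {
  kind <- match.arg(kind)
  coupling <- match.arg(coupling)
  stopifnot(is.numeric(magnitude), length(magnitude) == 1L,
            is.finite(magnitude))
  structure(list(kind = kind, magnitude = magnitude, coupling = coupling),
            class = "scenario_spec")
}

# lateral stretching modulus of one monolayer, kT/nm^2 (plane strain)
.stretch_modulus <- function(moduli) {
  (moduli$E_tail * moduli$z_break +
     moduli$E_head * (moduli$h - moduli$z_break)) / (1 - moduli$poisson^2)
}

# effective bending modulus per monolayer seen by the flat-reference
# coupled representation (bending strain referenced to the bilayer
# midplane, per-monolayer lipid number fixed)
.kappa_ade <- function(moduli) {
  gA <- .stretch_modulus(moduli)
  z0 <- moduli$z0; h <- moduli$h
  moduli$kappa + z0^2 * gA
}

#' Pre-insertion membrane state for a stress-generation scenario
#'
#' Returns the equilibrium state preceding the insertion: the bilayer
#' curvature and the per-monolayer stress profiles.
#'
#' Closed forms of the curvature (monolayers of equal bending modulus
#' `kappa`, spontaneous curvatures small compared to `1/h`):
#' * `outer_Js`: `J = J_s/2` (uncoupled); each monolayer carries a bending
#'   moment of magnitude `kappa*|J_s|/2`.
#' * `inner_Js`: `J = -J_s/2` (uncoupled), moments of magnitude
#'   `kappa*|J_s|/2`.
#' * `symmetric_Js`: `J = 0`, each monolayer frustrated with moment
#'   `kappa*J_s`.
#' * `external_torque`: `J = M/(2*kappa)` (uncoupled).
#' * `stretch`: `J = 0`, per-monolayer tension in the zeroth moment.
#'
#' Under lateral coupling the bending strain is referenced to the bilayer
#' midplane (per-monolayer lipid numbers fixed, as on a closed liposome
#' formed from a flat bilayer), which adds an area-difference penalty: the
#' curvature responses above are reduced accordingly and bent states carry
#' per-monolayer tensions of opposite sign.
#'
#' @param spec a [scenario_spec()].
#' @param membrane a [monolayer_spec()] (both monolayers identical before
#'   the scenario modification).
#' @param moduli a [moduli_profile()] for the membrane.
#' @param shape [profile_shape()] parameters of the chemical modulation.
#' @return Object of class `membrane_state` with fields `J`, `profiles`
#'   (`$outer`, `$inner`), `spec`, `membrane`, `moduli`.
#' @export
scenario_state <- function(spec, membrane = monolayer_spec(),
                           moduli = moduli_profile(membrane),
                           shape = profile_shape()) {
  stopifnot(inherits(spec, "scenario_spec"))
  m <- spec$magnitude
  kap <- membrane$kappa
  h <- membrane$h; z0 <- membrane$z0
  coupled <- spec$coupling == "coupled"
  kade <- .kappa_ade(moduli)
  zn <- if (coupled) 0 else z0

  chem <- function(tau) {
    ms <- membrane; ms$J_s <- 0; ms$gamma <- 0
    sp <- monolayer_spec(h = h, kappa = kap, J_s = 0, gamma = 0, z0 = z0)
    build_stress_profile(sp, shape, tau = tau)
  }
  bend <- function(c) elastic_stress_profile(moduli, 0, c, z_neutral = zn)
  zerop <- zero_profile(h, z0)

  J <- 0
  outer <- zerop; inner <- zerop
  if (spec$kind == "outer_Js") {
    J <- if (coupled) kap * m / (2 * kade) else m / 2
    outer <- add_profiles(chem(kap * m), bend(J))
    inner <- bend(-J)
  } else if (spec$kind == "inner_Js") {
    J <- if (coupled) -kap * m / (2 * kade) else -m / 2
    inner <- add_profiles(chem(kap * m), bend(-J))
    outer <- bend(J)
  } else if (spec$kind == "symmetric_Js") {
    J <- 0
    outer <- chem(kap * m)
    inner <- chem(kap * m)
  } else if (spec$kind == "external_torque") {
    keff <- if (coupled) {
      gA <- .stretch_modulus(moduli)
      kap + z0 * gA * (z0 - h / 2)
    } else kap
    J <- m / (2 * keff)
    outer <- bend(J)
    inner <- bend(-J)
  } else if (spec$kind == "stretch") {
    J <- 0
    gA <- .stretch_modulus(moduli)
    outer <- elastic_stress_profile(moduli, strain0 = m / gA)
    inner <- outer
  }
  if (abs(J) * h >= 0.5)
    stop("scenario magnitude outside the linear regime: |J|*h = ",
         format(abs(J) * h, digits = 3), " >= 0.5")
  structure(list(J = J, profiles = list(outer = outer, inner = inner),
                 spec = spec, membrane = membrane, moduli = moduli,
                 shape = shape),
            class = "membrane_state")
}

#' Curvature of a scenario per unit magnitude
#'
#' @param kind,coupling as in [scenario_spec()].
#' @param membrane,moduli membrane description.
#' @return dJ/d(magnitude), in the scenario's magnitude units.
#' @export
scenario_curvature_gain <- function(kind, coupling = "uncoupled",
                                    membrane = monolayer_spec(),
                                    moduli = moduli_profile(membrane)) {
  st <- scenario_state(scenario_spec(kind, 1e-4, coupling), membrane, moduli)
  st$J / 1e-4
}

#' Sweep a scenario over a set of magnitudes
#'
#' @param spec a [scenario_spec()] used as template (its magnitude is
#'   ignored).
#' @param magnitudes numeric vector.
#' @param ... passed to [scenario_state()].
#' @return list of `membrane_state`, ordered as `magnitudes`.
#' @export
scenario_sweep <- function(spec, magnitudes, ...) {
  lapply(magnitudes, function(m) {
    s <- spec; s$magnitude <- m
    scenario_state(s, ...)
  })
}

#' Mean lateral stress over the void region
#'
#' Average of the outer-monolayer pre-insertion stress over the void
#' cross-section (the region the insertion will occupy); its sign
#' determines whether embedding is opposed (pressure, negative) or
#' assisted (tension, positive).
#'
#' @param state a `membrane_state`.
#' @param geom an [insertion_geometry()].
#' @return mean stress, kT nm^-3.
#' @export
void_mean_stress <- function(state, geom = insertion_geometry()) {
  h <- state$membrane$h
  vc <- void_cross_section(geom, h)
  if (vc$area <= 0) return(0)
  -void_energy(state, geom) / (geom$L_ins * vc$area)
}

#' @export
print.membrane_state <- function(x, ...) {
  cat("Membrane state [", x$spec$kind, ", magnitude ",
      format(x$spec$magnitude, digits = 4), ", ", x$spec$coupling,
      "]: J = ", format(x$J, digits = 4), " nm^-1\n", sep = "")
  mo <- profile_moments(x$profiles$outer)
  mi <- profile_moments(x$profiles$inner)
  cat("  outer: gamma = ", format(mo[1], digits = 4), ", tau = ",
      format(mo[2], digits = 4), "; inner: gamma = ",
      format(mi[1], digits = 4), ", tau = ", format(mi[2], digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' Write a scenario sweep summary as CSV
#'
#' @param states list of `membrane_state` (e.g. from [scenario_sweep()]).
#' @param path output CSV.
#' @return the summary data.frame, invisibly.
#' @export
write_sweep_csv <- function(states, path) {
  rows <- lapply(states, function(s) {
    mo <- profile_moments(s$profiles$outer)
    mi <- profile_moments(s$profiles$inner)
    data.frame(kind = s$spec$kind, magnitude = s$spec$magnitude,
               coupling = s$spec$coupling, J = s$J,
               gamma_out = mo[1], tau_out = mo[2],
               gamma_in = mi[1], tau_in = mi[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
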