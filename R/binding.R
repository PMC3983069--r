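# Binding thermodynamics: from elastic binding energies to relative
# binding constants.
#
# The absolute binding constant contains a stress-independent prefactor
# (hydrophobic, electrostatic and hydrogen-bonding contributions) that the
# elastic model cannot evaluate; only ratios are ever emitted.

#' Binding model parameters
#'
#' @param delta monolayer thickness, nm (enters the finite-size
#'   correction).
#' @param correction small-vesicle correction `g(R)`: `"offset"` (default,
#'   `g = 1 - delta/R`), `"none"` (`g = 1`), or `"area"` (outer-area
#'   fraction of the two monolayers, normalised to 1 for a flat membrane).
#' @param kT energy scale of the exponent (energies are expressed in kT,
#'   so 1).
#' @return Object of class `binding_model`.
#' @export
binding_model <- function(delta = 2,
                          correction = c("offset", "none", "area"),
                          kT = 1) {
  correction <- match.arg(correction)
  stopifnot(delta > 0, kT > 0)
  structure(list(delta = delta, correction = correction, kT = kT),
            class = "binding_model")
}

#' Small-vesicle geometric correction
#'
#' @param R vesicle mid-plane radius, nm (`Inf` for a flat membrane).
#' @param model a [binding_model()].
#' @return `g(R)`, with `g(Inf) = 1`.
#' @export
size_correction <- function(R, model = binding_model()) {
  if (any(R <= model$delta))
    stop("vesicle radius must exceed the monolayer thickness delta = ",
         model$delta, " nm")
  if (model$correction == "none") return(rep(1, length(R)))
  if (model$correction == "offset") return(1 - model$delta / R)
  x <- model$delta / (2 * R)                  # outer-area fraction form
  2 * (1 + x)^2 / ((1 + x)^2 + (1 - x)^2)
}

#' Relative binding constant
#'
#' `K_rel = exp(-(eps_el - eps_el0)/kT) * g(R)`: the binding constant of
#' the stressed (possibly curved) membrane relative to the initial
#' unstressed flat membrane, with the unknown stress-independent prefactor
#' cancelled.
#'
#' @param eps_el elastic binding energy of the stressed membrane, kT.
#' @param eps_el0 elastic binding energy of the unstressed flat membrane,
#'   kT.
#' @param R vesicle mid-plane radius, nm (`Inf` for flat).
#' @param model a [binding_model()].
#' @return dimensionless `K_rel > 0`.
#' @export
relative_binding_constant <- function(eps_el, eps_el0, R = Inf,
                                      model = binding_model()) {
  exp(-(eps_el - eps_el0) / model$kT) * size_correction(R, model)
}

#' Ratio of binding constants between two vesicle radii
#'
#' `K_B(R1)/K_B(R2)` for the same insertion geometry; the prefactor and
#' the unstressed reference cancel.
#'
#' @param eps_el_1,eps_el_2 elastic binding energies at the two radii, kT.
#' @param R1,R2 vesicle radii, nm.
#' @param model a [binding_model()].
#' @param geom1,geom2 optional [insertion_geometry()] descriptions used to
#'   verify that the two energies belong to the same insertion.
#' @return dimensionless ratio.
#' @export
ratio_between_radii <- function(eps_el_1, eps_el_2, R1, R2,
                                model = binding_model(),
                                geom1 = NULL, geom2 = NULL) {
  if (!is.null(geom1) && !is.null(geom2) &&
      !isTRUE(all.equal(geom1[c("r", "d", "L_ins")],
                        geom2[c("r", "d", "L_ins")])))
    stop("binding-constant ratios require identical insertion geometry")
  exp(-(eps_el_1 - eps_el_2) / model$kT) *
    size_correction(R1, model) / size_correction(R2, model)
}

#' Absolute binding constant (not available)
#'
#' The stress-independent prefactor of the binding constant combines
#' hydrophobic, electrostatic and hydrogen-bonding contributions that are
#' outside the elastic model; any request for an absolute constant fails.
#'
#' @param ... ignored.
#' @export
absolute_binding_constant <- function(...) {
  stop("the stress-independent prefactor of the binding constant is ",
       "unknown by construction; only relative binding constants ",
       "(ratios) can be computed")
}
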