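# Embedding energetics: the two-step decomposition of the elastic binding
# energy.
#
#   eps_el = eps_V0 + delta_eps_V + eps_R
#
# Step 1 carves the void while the membrane shape (far-boundary rotation)
# is frozen: its energy is eps_V0 (work against the pre-insertion stress,
# computed by direct quadrature over the void) plus the stress-perturbation
# energy delta_eps_V.  Step 2 releases the shape relaxation and lowers the
# energy by eps_R <= 0.

#' Energy budget of one embedding computation
#'
#' @param eps_V0 void energy, kT.
#' @param delta_eps_V stress-perturbation energy, kT.
#' @param eps_R shape-relaxation energy, kT (non-positive).
#' @return Object of class `energy_budget`; `eps_el` is the exact sum of
#'   the three contributions.
#' @export
energy_budget <- function(eps_V0, delta_eps_V, eps_R) {
  structure(list(eps_V0 = eps_V0, delta_eps_V = delta_eps_V,
                 eps_R = eps_R, eps_el = eps_V0 + delta_eps_V + eps_R),
            class = "energy_budget")
}

#' @export
print.energy_budget <- function(x, ...) {
  cat(sprintf(
    "Embedding energy budget (kT): eps_V0 = %.4f, delta_eps_V = %.4f, eps_R = %.4f, eps_el = %.4f\n",
    x$eps_V0, x$delta_eps_V, x$eps_R, x$eps_el))
  invisible(x)
}

#' Void energy of a pre-stressed membrane
#'
#' Thermodynamic work performed against the pre-insertion stress profile
#' when the void is carved:
#' `eps_V0 = -L_ins * \int_void sigma0(z) dA`, evaluated by high-resolution
#' quadrature of the chord-reduced integral over the void cross-section.
#'
#' @param state a `membrane_state` (or `NULL` for an unstressed membrane).
#' @param geom an [insertion_geometry()].
#' @param n_quad quadrature resolution.
#' @return void energy, kT.
#' @export
void_energy <- function(state, geom = insertion_geometry(), n_quad = 4001) {
  if (is.null(state)) return(0)
  h <- state$membrane$h
  vc <- void_cross_section(geom, h)           # errors if d > h
  if (vc$area <= 0) return(0)
  # substitute z = z_c + r sin(phi): the chord 2*sqrt(r^2 - (z - z_c)^2)
  # becomes 2 r^2 cos^2(phi), removing the square-root edge at the void
  # bottom (the lower integration limit is always phi = -pi/2)
  r <- geom$r
  phi_hi <- asin(min(1, (vc$z_hi - vc$z_center) / r))
  phi <- seq(-pi / 2, phi_hi, length.out = n_quad)
  z <- vc$z_center + r * sin(phi)
  w <- 2 * r^2 * cos(phi)^2
  sig <- profile_at(state$profiles$outer, z)
  -geom$L_ins * .trapz(phi, sig * w)
}

#' Embedding solver for a fixed insertion geometry
#'
#' Builds the mesh, refines it adaptively towards the insertion (using the
#' strain-energy density of the unstressed embedding as error indicator,
#' until the element count reaches the refinement floor), assembles the
#' operator and factorises the frozen-shape and relaxed reductions for both
#' steps.  The returned object embeds any number of membrane states on the
#' shared factorisation (each state only changes the load vector).
#'
#' @param geom an [insertion_geometry()].
#' @param membrane a [monolayer_spec()].
#' @param moduli a [moduli_profile()].
#' @param coupling `"uncoupled"` or `"coupled"`.
#' @param control a [mesh_control()].
#' @param verbose print mesh/refinement diagnostics.
#' @return Object of class `embedding_solver`.
#' @export
embedding_solver <- function(geom = insertion_geometry(),
                             membrane = monolayer_spec(),
                             moduli = moduli_profile(membrane),
                             coupling = c("uncoupled", "coupled"),
                             control = mesh_control(),
                             verbose = FALSE) {
  coupling <- match.arg(coupling)
  mesh <- build_mesh(geom, membrane$h, control)
  pass <- 0L
  repeat {
    asm <- fem_assemble(mesh, moduli)
    bcs <- impose_insertion(asm, geom)
    opF <- fem_reduce(asm, bcs, coupling, relax_rotation = FALSE)
    if (nrow(mesh$triangles) >= control$min_elements_refined ||
        pass >= control$max_refine_passes) break
    ind <- element_fields(solve_equilibrium(opF))$energy_density
    mesh <- refine_adaptive(mesh, ind, control$refine_fraction)
    pass <- pass + 1L
    if (verbose)
      message("refinement pass ", pass, ": ", nrow(mesh$triangles),
              " elements")
  }
  opR <- fem_reduce(asm, bcs, coupling, relax_rotation = TRUE)
  if (verbose)
    message("solver ready: ", nrow(mesh$triangles), " elements, ",
            ncol(opR$G), " reduced dofs")
  structure(list(geom = geom, membrane = membrane, moduli = moduli,
                 coupling = coupling, control = control,
                 mesh = mesh, asm = asm, bcs = bcs,
                 op_frozen = opF, op_relaxed = opR),
            class = "embedding_solver")
}

#' Embed an insertion into a prepared membrane state
#'
#' Runs the two-step embedding on a solver: step 1 (shape frozen) gives
#' `eps_V0 + delta_eps_V`, step 2 (shape relaxation released) adds
#' `eps_R`.
#'
#' @param solver an [embedding_solver()].
#' @param state a `membrane_state` from [scenario_state()], or `NULL` for
#'   the unstressed membrane.
#' @return list with the `energy_budget`, the relaxed `elastic_state` and
#'   the insertion-induced curvature change `dJ` (far-boundary rotation
#'   over the domain length).
#' @export
embed_state <- function(solver, state = NULL) {
  stopifnot(inherits(solver, "embedding_solver"))
  if (!is.null(state) && state$spec$coupling != solver$coupling)
    stop("state coupling '", state$spec$coupling,
         "' does not match solver coupling '", solver$coupling, "'")
  prestress <- if (is.null(state)) NULL else state$profiles
  L <- solver$geom$L_ins
  s1 <- solve_equilibrium(solver$op_frozen, prestress)
  s2 <- solve_equilibrium(solver$op_relaxed, prestress)
  E1 <- 2 * L * s1$energy_half
  E2 <- 2 * L * s2$energy_half
  eV0 <- void_energy(state, solver$geom)
  budget <- energy_budget(eps_V0 = eV0, delta_eps_V = E1 - eV0,
                          eps_R = E2 - E1)
  list(budget = budget, state = s2, dJ = s2$theta / solver$mesh$L_dom)
}

#' Two-step embedding for a single membrane state
#'
#' Convenience wrapper building an [embedding_solver()] for one state.
#'
#' @param state a `membrane_state`, or `NULL` (unstressed).
#' @param geom an [insertion_geometry()].
#' @param control a [mesh_control()].
#' @param ... passed to [embedding_solver()].
#' @return As [embed_state()].
#' @export
embed_insertion <- function(state = NULL, geom = insertion_geometry(),
                            control = mesh_control(), ...) {
  membrane <- if (is.null(state)) monolayer_spec() else state$membrane
  moduli <- if (is.null(state)) moduli_profile(membrane) else state$moduli
  coupling <- if (is.null(state)) "uncoupled" else state$spec$coupling
  solver <- embedding_solver(geom, membrane, moduli, coupling, control, ...)
  embed_state(solver, state)
}

#' Magnitudes spanning a target void-energy range
#'
#' The void energy is linear in the scenario magnitude; this calibrates the
#' magnitude interval over which a sweep spans the requested `eps_V0`
#' range.
#'
#' @param kind,coupling scenario kind and coupling.
#' @param geom insertion geometry.
#' @param membrane,moduli,shape membrane description.
#' @param span target void-energy interval, kT.
#' @param n number of magnitudes.
#' @return numeric vector of magnitudes.
#' @export
calibrate_magnitudes <- function(kind, coupling = "uncoupled",
                                 geom = insertion_geometry(),
                                 membrane = monolayer_spec(),
                                 moduli = moduli_profile(membrane),
                                 shape = profile_shape(),
                                 span = c(-2, 2), n = 9) {
  m0 <- 1e-3
  st <- scenario_state(scenario_spec(kind, m0, coupling), membrane, moduli,
                       shape)
  slope <- void_energy(st, geom) / m0
  if (abs(slope) < 1e-12)
    stop("void energy insensitive to scenario '", kind, "'")
  seq(span[1] / slope, span[2] / slope, length.out = n)
}

#' Sweep scenarios and tabulate embedding budgets
#'
#' Runs the full embedding computation for each scenario kind over
#' magnitudes spanning the requested void-energy range, sharing one solver
#' factorisation across all states.
#'
#' @param kinds character vector of scenario kinds.
#' @param coupling coupling mode.
#' @param geom insertion geometry.
#' @param membrane,moduli,shape membrane description.
#' @param span void-energy range, kT.
#' @param n magnitudes per scenario.
#' @param control mesh controls.
#' @param solver optional pre-built [embedding_solver()] (matching `geom`
#'   and `coupling`).
#' @return data.frame: scenario, magnitude, J, eps_V0, delta_eps_V, eps_R,
#'   eps_el.
#' @export
embed_sweep <- function(kinds = c("outer_Js", "inner_Js", "symmetric_Js",
                                  "external_torque", "stretch"),
                        coupling = "uncoupled",
                        geom = insertion_geometry(),
                        membrane = monolayer_spec(),
                        moduli = moduli_profile(membrane),
                        shape = profile_shape(),
                        span = c(-2, 2), n = 9,
                        control = mesh_control(),
                        solver = NULL) {
  if (is.null(solver))
    solver <- embedding_solver(geom, membrane, moduli, coupling, control)
  rows <- list()
  for (kind in kinds) {
    mags <- calibrate_magnitudes(kind, coupling, geom, membrane, moduli,
                                 shape, span, n)
    for (m in mags) {
      st <- scenario_state(scenario_spec(kind, m, coupling), membrane,
                           moduli, shape)
      em <- embed_state(solver, st)
      b <- em$budget
      rows[[length(rows) + 1L]] <-
        data.frame(scenario = kind, magnitude = m, J = st$J,
                   eps_V0 = b$eps_V0, delta_eps_V = b$delta_eps_V,
                   eps_R = b$eps_R, eps_el = b$eps_el)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Curvature sensitivity of the elastic binding energy
#'
#' Least-squares slope of `eps_el` versus the pre-insertion curvature `J`,
#' in the convention `eps_el ~ eps_el(0) - xi * J`: positive `xi` means
#' stronger binding to more curved membranes.
#'
#' @param series data.frame (or list of pairs) with columns `J` and
#'   `eps_el`.
#' @return Object of class `sensitivity_fit`: `xi` (kT nm), `intercept`
#'   (kT), `r_squared` and the `J` range.
#' @export
curvature_sensitivity <- function(series) {
  if (is.list(series) && !is.data.frame(series))
    series <- do.call(rbind, lapply(series, function(p)
      data.frame(J = p[[1]], eps_el = p[[2]])))
  stopifnot(all(c("J", "eps_el") %in% names(series)))
  if (nrow(series) < 3L)
    stop("need at least 3 points to fit the curvature sensitivity")
  if (diff(range(series$J)) < 1e-12)
    stop("degenerate curvature range: all J values coincide")
  fit <- stats::lm(eps_el ~ J, data = series)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits are fine
  structure(list(xi = -unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, J_range = range(series$J),
                 n = nrow(series)),
            class = "sensitivity_fit")
}

#' @export
print.sensitivity_fit <- function(x, ...) {
  cat(sprintf(
    "Curvature sensitivity: xi = %.4f kT nm (intercept %.4f kT, R^2 = %.5f, n = %d)\n",
    x$xi, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Write an embedding budget table as CSV
#'
#' @param budgets data.frame from [embed_sweep()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_budget_csv <- function(budgets, path) {
  utils::write.csv(budgets, path, row.names = FALSE)
  invisible(path)
}
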