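# Analytic verification fixtures: each case carries a closed-form
# expectation computed within the fixture itself, and is used both by the
# test suite and by the command-line `validate` entry point.

#' Analytic solver-verification fixtures
#'
#' Four cases with closed-form expectations:
#' * `zero_load`: unloaded, unstressed, no insertion; zero energy.
#' * `uniform_tension`: homogeneous bonded slab (uniform Young's modulus)
#'   under an in-plane end force; plane-strain closed form for the end
#'   displacement and stored energy.
#' * `pure_bending`: the same slab under an end moment; Euler/plate closed
#'   form `theta = M L / D`, `D = E H^3 / (12 (1 - nu^2))`.
#' * `void_quadrature`: uniform lateral pre-stress over the void of the
#'   default insertion; `eps_V0 = -sigma * A_void * L_ins` with the
#'   circular-segment closed form for the area.
#'
#' @param E,nu slab modulus (kT nm^-3) and Poisson ratio of the
#'   mechanical fixtures.
#' @param control mesh controls (smaller meshes are fine: the mechanical
#'   fixtures are exactly representable).
#' @return list of fixture cases: `name`, `expected`, `tol` (relative),
#'   and a `compute()` closure returning the named quantities.
#' @export
generate_fixtures <- function(E = 10, nu = 0.3,
                              control = mesh_control()) {
  h <- 2; L <- control$L_dom; H <- 2 * h
  slab_env <- new.env(parent = emptyenv())
  slab_op <- function() {
    if (is.null(slab_env$op)) {
      mesh <- build_mesh(insertion_geometry(d = 0), h, control)
      asm <- fem_assemble(mesh, uniform_moduli(E, nu, h),
                          interface = "bonded")
      slab_env$op <- fem_reduce(asm, NULL, "uncoupled")
    }
    slab_env$op
  }

  list(
    list(name = "zero_load", expected = c(energy = 0), tol = 1e-10,
         absolute = TRUE,
         compute = function() {
           st <- solve_equilibrium(slab_op(), NULL,
                                   load_spec(maintain = FALSE))
           c(energy = st$energy_half)
         }),
    list(name = "uniform_tension",
         expected = local({
           F <- 1; sig <- F / H; eps <- sig * (1 - nu^2) / E
           c(end_displacement = eps * L,
             strain_energy = 0.5 * sig * eps * H * L)
         }),
         tol = 0.01, absolute = FALSE,
         compute = function() {
           st <- solve_equilibrium(slab_op(), NULL,
                                   load_spec(force_out = 0.5,
                                             force_in = 0.5,
                                             maintain = FALSE))
           c(end_displacement = st$Ux_out, strain_energy = st$E_strain)
         }),
    list(name = "pure_bending",
         expected = local({
           M <- 1; D <- E * H^3 / (12 * (1 - nu^2))
           c(rotation = M * L / D, strain_energy = 0.5 * M^2 * L / D)
         }),
         tol = 0.02, absolute = FALSE,
         compute = function() {
           st <- solve_equilibrium(slab_op(), NULL,
                                   load_spec(torque = 1, maintain = FALSE))
           c(rotation = st$theta, strain_energy = st$E_strain)
         }),
    list(name = "void_quadrature",
         expected = local({
           geom <- insertion_geometry()     # r = 0.5, d = 0.8, L_ins = 2
           sig <- -0.5
           c(eps_V0 = -sig * void_cross_section(geom, h)$area * geom$L_ins)
         }),
         tol = 1e-6, absolute = FALSE,
         compute = function() {
           geom <- insertion_geometry()
           z <- seq(0, h, length.out = 2001)
           unif <- structure(list(z_grid = z, sigma = rep(-0.5, 2001),
                                  z0 = 2 * h / 3, h = h,
                                  gamma = -1, tau = NA),
                             class = "stress_profile")
           state <- list(membrane = monolayer_spec(h = h),
                         profiles = list(outer = unif, inner = unif))
           c(eps_V0 = void_energy(state, geom))
         })
  )
}

#' Run all verification fixtures
#'
#' @param fixtures from [generate_fixtures()].
#' @param verbose print a line per fixture.
#' @return data.frame with one row per checked quantity: fixture, quantity,
#'   expected, computed, error, tol, pass.
#' @export
validate_fixtures <- function(fixtures = generate_fixtures(),
                              verbose = TRUE) {
  rows <- list()
  for (fx in fixtures) {
    got <- fx$compute()
    for (nm in names(fx$expected)) {
      exp_v <- fx$expected[[nm]]; got_v <- got[[nm]]
      err <- if (isTRUE(fx$absolute) || exp_v == 0) abs(got_v - exp_v)
             else abs(got_v / exp_v - 1)
      pass <- err <= fx$tol
      if (verbose)
        message(sprintf("%-18s %-18s expected %.6g got %.6g  %s",
                        fx$name, nm, exp_v, got_v,
                        if (pass) "ok" else "FAIL"))
      rows[[length(rows) + 1L]] <-
        data.frame(fixture = fx$name, quantity = nm, expected = exp_v,
                   computed = got_v, error = err, tol = fx$tol,
                   pass = pass)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
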