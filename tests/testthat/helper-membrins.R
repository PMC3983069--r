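# Shared fixtures for the test suite.  Unit tests that do not probe the
# production mesh density use smaller meshes for speed; the full-scale
# defaults are exercised in the acceptance tests.

quick_control <- function() {
  mesh_control(L_dom = 20, dz_fine = 0.15, min_elements = 600,
               min_elements_refined = 2200, refine_fraction = 0.25,
               max_refine_passes = 2)
}

default_membrane <- function() monolayer_spec()
default_moduli <- function(ms = default_membrane()) moduli_profile(ms)

# memoised quick solver for the default geometry (built once per run)
.test_env <- new.env(parent = emptyenv())
quick_solver <- function(coupling = "uncoupled") {
  key <- paste0("solver_", coupling)
  if (is.null(.test_env[[key]])) {
    ms <- default_membrane()
    .test_env[[key]] <- embedding_solver(insertion_geometry(), ms,
                                         default_moduli(ms), coupling,
                                         quick_control())
  }
  .test_env[[key]]
}

# uniform slab operator shared by the closed-form solver tests
slab_operator <- function(E = 10, nu = 0.3) {
  key <- sprintf("slab_%g_%g", E, nu)
  if (is.null(.test_env[[key]])) {
    mesh <- build_mesh(insertion_geometry(d = 0), 2, quick_control())
    asm <- fem_assemble(mesh, uniform_moduli(E, nu, 2),
                        interface = "bonded")
    .test_env[[key]] <- fem_reduce(asm, NULL, "uncoupled")
  }
  .test_env[[key]]
}
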