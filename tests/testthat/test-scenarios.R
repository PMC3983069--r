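# Stress-generation scenarios: curvature closed forms, profile moments and
# the sign structure of the void-region stress.

test_that("scenario curvatures follow the closed forms", {
  ms <- default_membrane(); mod <- default_moduli(ms)
  # symmetric generation leaves the bilayer flat
  st <- scenario_state(scenario_spec("symmetric_Js", 0.2), ms, mod)
  expect_equal(st$J, 0)
  # outer-monolayer spontaneous curvature: J = Js/2
  st <- scenario_state(scenario_spec("outer_Js", 0.2), ms, mod)
  expect_equal(st$J, 0.1, tolerance = 1e-12)
  # inner-monolayer: J = -Js/2
  st <- scenario_state(scenario_spec("inner_Js", 0.2), ms, mod)
  expect_equal(st$J, -0.1, tolerance = 1e-12)
  # torque balance: J = M/(2 kappa)
  st <- scenario_state(scenario_spec("external_torque", 1), ms, mod)
  expect_equal(st$J, 1 / 20, tolerance = 1e-12)
  # stretching does not bend
  st <- scenario_state(scenario_spec("stretch", 0.5), ms, mod)
  expect_equal(st$J, 0)
  expect_error(scenario_spec("bogus", 1), "arg")
})

test_that("per-monolayer moments carry the prescribed magnitudes", {
  ms <- default_membrane(); mod <- default_moduli(ms)
  kap <- ms$kappa
  tol <- 0.02 * kap
  m <- 0.2
  st <- scenario_state(scenario_spec("outer_Js", m), ms, mod)
  expect_equal(unname(profile_moments(st$profiles$outer)["tau"]),
               kap * m / 2, tolerance = tol)
  expect_equal(unname(profile_moments(st$profiles$inner)["tau"]),
               kap * m / 2, tolerance = tol)
  st <- scenario_state(scenario_spec("symmetric_Js", m), ms, mod)
  expect_equal(unname(profile_moments(st$profiles$outer)["tau"]),
               kap * m, tolerance = tol)
  M <- 1
  st <- scenario_state(scenario_spec("external_torque", M), ms, mod)
  expect_equal(unname(profile_moments(st$profiles$outer)["tau"]),
               -M / 2, tolerance = 0.02)
  expect_equal(unname(profile_moments(st$profiles$inner)["tau"]),
               M / 2, tolerance = 0.02)
  g <- 0.5
  st <- scenario_state(scenario_spec("stretch", g), ms, mod)
  expect_equal(unname(profile_moments(st$profiles$outer)["gamma"]), g,
               tolerance = 1e-6)
})

test_that("all scenarios reduce to one unstressed state at zero magnitude", {
  ms <- default_membrane(); mod <- default_moduli(ms)
  for (kind in c("outer_Js", "inner_Js", "symmetric_Js",
                 "external_torque", "stretch")) {
    st <- scenario_state(scenario_spec(kind, 0), ms, mod)
    expect_equal(st$J, 0)
    expect_lt(max(abs(st$profiles$outer$sigma)), 1e-12)
    expect_lt(max(abs(st$profiles$inner$sigma)), 1e-12)
  }
})

test_that("curvature is linear in the scenario magnitude", {
  ms <- default_membrane(); mod <- default_moduli(ms)
  for (kind in c("outer_Js", "inner_Js", "external_torque")) {
    for (coupling in c("uncoupled", "coupled")) {
      J1 <- scenario_state(scenario_spec(kind, 0.05, coupling), ms, mod)$J
      J2 <- scenario_state(scenario_spec(kind, 0.10, coupling), ms, mod)$J
      expect_equal(J2 / J1, 2, tolerance = 1e-9)
    }
  }
})

test_that("void-region stress has the expected sign per scenario", {
  ms <- default_membrane(); mod <- default_moduli(ms)
  geom <- insertion_geometry()
  sgn <- function(kind, m) {
    st <- scenario_state(scenario_spec(kind, m), ms, mod)
    void_mean_stress(st, geom)
  }
  expect_lt(sgn("outer_Js", 0.2), 0)        # compression opposes embedding
  expect_lt(sgn("symmetric_Js", 0.2), 0)
  expect_gt(sgn("inner_Js", -0.2), 0)       # tension assists embedding
  expect_gt(sgn("external_torque", 1), 0)
  expect_gt(sgn("stretch", 0.5), 0)
})

test_that("matched curvature from torque and outer lipids stresses differ", {
  ms <- default_membrane(); mod <- default_moduli(ms)
  geom <- insertion_geometry()
  J <- 0.05
  st_t <- scenario_state(scenario_spec("external_torque", 2 * ms$kappa * J),
                         ms, mod)
  st_o <- scenario_state(scenario_spec("outer_Js", 2 * J), ms, mod)
  expect_equal(st_t$J, st_o$J, tolerance = 1e-12)
  eV_t <- void_energy(st_t, geom)
  eV_o <- void_energy(st_o, geom)
  # same curvature, opposite void energetics: the distinguishability at the
  # heart of stress (not curvature) sensing
  expect_true(sign(eV_t) != sign(eV_o))
  expect_gt(abs(eV_t - eV_o), 0.5)
})

test_that("magnitude sweeps are ordered and validated", {
  ms <- default_membrane(); mod <- default_moduli(ms)
  expect_equal(scenario_sweep(scenario_spec("stretch", 0), numeric(0)),
               list())
  sts <- scenario_sweep(scenario_spec("outer_Js", 0), c(-0.1, 0, 0.1),
                        membrane = ms, moduli = mod)
  expect_equal(sapply(sts, function(s) s$spec$magnitude), c(-0.1, 0, 0.1))
  expect_error(scenario_state(scenario_spec("external_torque", 200), ms,
                              mod), "linear regime")
})

test_that("sweep summaries export to CSV", {
  ms <- default_membrane(); mod <- default_moduli(ms)
  sts <- scenario_sweep(scenario_spec("symmetric_Js", 0), c(-0.1, 0.1),
                        membrane = ms, moduli = mod)
  path <- tempfile(fileext = ".csv")
  out <- write_sweep_csv(sts, path)
  expect_true(file.exists(path))
  expect_equal(nrow(read.csv(path)), 2)
  expect_equal(out$tau_out[2], ms$kappa * 0.1, tolerance = 1e-6)
})
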