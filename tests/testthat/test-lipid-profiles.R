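# Stress profiles, moments and the composition -> spontaneous-curvature map.

test_that("composition rule reproduces measured mixture curvatures", {
  # identity case
  expect_equal(composition_to_spontaneous_curvature(
    list(lipid_species("X", -0.2, 1))), -0.2)
  # quaternary mixture printed in the composition table
  expect_lt(abs(composition_to_spontaneous_curvature(
    c(DOPC = 0.60, DOPE = 0, DOPS = 0.30, DAG = 0.10)) - (-0.147)), 0.002)
  # all six tabulated mixtures, to the stated 0.002 nm^-1
  tab <- arfgap1_composition_table()$data
  fr <- do.call(rbind, lapply(strsplit(tab$composition, ":"),
                              function(x) as.numeric(x) / 100))
  colnames(fr) <- c("DOPC", "DOPE", "DOPS", "DAG")
  for (i in seq_len(nrow(fr))) {
    expect_lt(abs(composition_to_spontaneous_curvature(fr[i, ]) -
                    tab$Js[i]), 0.002)
  }
})

test_that("composition map is linear in area fractions", {
  zt <- lipid_zeta_table()
  a <- c(DOPC = 0.5, DOPE = 0.2, DOPS = 0.3, DAG = 0)
  b <- c(DOPC = 0.2, DOPE = 0.4, DOPS = 0.3, DAG = 0.1)
  lam <- 0.3
  mix <- lam * a + (1 - lam) * b
  expect_equal(composition_to_spontaneous_curvature(mix),
               lam * composition_to_spontaneous_curvature(a) +
                 (1 - lam) * composition_to_spontaneous_curvature(b))
})

test_that("lipid curvature contributions are recovered by least squares", {
  # The six (composition, Js) rows determine only three combinations of
  # the four zeta values (fractions sum to 1 and the DOPS fraction is the
  # same in every mixture), so the solve is performed in the identifiable
  # parametrisation Js = c0 + phi_E * (zE - zC) + phi_D * (zD - zC).
  tab <- arfgap1_composition_table()$data
  fr <- do.call(rbind, lapply(strsplit(tab$composition, ":"),
                              function(x) as.numeric(x) / 100))
  X <- cbind(1, fr[, 2], fr[, 4])
  fit <- stats::lsfit(X, tab$Js, intercept = FALSE)
  expect_lt(max(abs(resid(fit))), 0.002)
  z <- lipid_zeta_table()$zeta_per_nm
  names(z) <- lipid_zeta_table()$name
  truth <- c(0.7 * z["DOPC"] + 0.3 * z["DOPS"],
             z["DOPE"] - z["DOPC"], z["DAG"] - z["DOPC"])
  expect_equal(unname(coef(fit)), unname(truth), tolerance = 0.02)
})

test_that("invalid compositions are rejected with the residual named", {
  bad <- c(DOPC = 0.6, DOPS = 0.3)
  expect_error(composition_to_spontaneous_curvature(bad), "residual")
  expect_error(composition_to_spontaneous_curvature(c(BAD = 1)), "unknown")
})

test_that("built profiles satisfy both moment constraints exactly", {
  # pure moment
  p <- build_stress_profile(monolayer_spec(J_s = -0.1, kappa = 10))
  m <- profile_moments(p)
  expect_equal(unname(m["gamma"]), 0, tolerance = 1e-8)
  expect_equal(unname(m["tau"]), -1, tolerance = 1e-8)
  # pure tension
  p2 <- build_stress_profile(monolayer_spec(gamma = 0.5))
  m2 <- profile_moments(p2)
  expect_equal(unname(m2["gamma"]), 0.5, tolerance = 1e-8)
  expect_equal(unname(m2["tau"]), 0, tolerance = 1e-8)
  # zero-stress spec with a frustration component: moments still zero but
  # the profile is nonzero pointwise
  p3 <- build_stress_profile(monolayer_spec(),
                             profile_shape(frustration_amp = 1))
  m3 <- profile_moments(p3)
  expect_equal(unname(m3["gamma"]), 0, tolerance = 1e-8)
  expect_equal(unname(m3["tau"]), 0, tolerance = 1e-8)
  expect_gt(max(abs(p3$sigma)), 0.5)
})

test_that("moment round trip holds for random feasible specs", {
  set.seed(42)
  for (i in 1:10) {
    gam <- runif(1, -1, 1); Js <- runif(1, -0.3, 0.3)
    p <- build_stress_profile(monolayer_spec(J_s = Js, gamma = gam))
    m <- profile_moments(p)
    expect_equal(unname(m["gamma"]), gam, tolerance = 1e-8)
    expect_equal(unname(m["tau"]), 10 * Js, tolerance = 1e-8)
  }
})

test_that("profile moments agree with closed forms and a fine oracle", {
  # uniform stress on [0, 2] with z0 = 4/3: gamma = 2, |tau| = 2/3
  z <- seq(0, 2, length.out = 2001)
  p <- structure(list(z_grid = z, sigma = rep(1, 2001), z0 = 4 / 3, h = 2),
                 class = "stress_profile")
  m <- profile_moments(p)
  expect_equal(unname(m["gamma"]), 2, tolerance = 1e-9)
  expect_equal(abs(unname(m["tau"])), 2 / 3, tolerance = 1e-9)
  # random piecewise-linear profile vs dense trapezoid oracle
  set.seed(7)
  zk <- sort(c(0, runif(6, 0, 2), 2)); vk <- rnorm(8)
  pw <- structure(list(z_grid = zk, sigma = vk, z0 = 4 / 3, h = 2),
                  class = "stress_profile")
  zf <- sort(unique(c(zk, seq(0, 2, length.out = 10001))))
  sf <- approx(zk, vk, zf)$y
  nf <- length(zf)
  g_oracle <- sum((sf[-1] + sf[-nf]) / 2 * diff(zf))
  t_oracle <- -sum((((zf - 4 / 3) * sf)[-1] + ((zf - 4 / 3) * sf)[-nf]) /
                     2 * diff(zf))
  m2 <- profile_moments(pw)
  expect_lt(abs(unname(m2["gamma"]) - g_oracle), 1e-8)
  expect_lt(abs(unname(m2["tau"]) - t_oracle), 1e-8)
  # non-monotone grid rejected
  bad <- structure(list(z_grid = c(0, 1, 0.5), sigma = 1:3, z0 = 1),
                   class = "stress_profile")
  expect_error(profile_moments(bad), "increasing")
})

test_that("frustrated monolayers carry the expected sign structure", {
  # Js > 0 (lysolipid-like): lateral pressure in the headgroup region
  p <- build_stress_profile(monolayer_spec(J_s = 0.2))
  head <- p$z_grid > 1.5
  expect_lt(mean(p$sigma[head]), 0)
  expect_equal(unname(profile_moments(p)["tau"]), 2, tolerance = 1e-8)
})

test_that("infeasible shape parameters raise explicit errors", {
  expect_error(build_stress_profile(monolayer_spec(J_s = 0.1),
                                    profile_shape(head_width = -1)),
               "infeasible")
  # head zone centered on the neutral plane: degenerate lever arms
  expect_error(build_stress_profile(monolayer_spec(J_s = 0.1),
                                    profile_shape(head_center = 4 / 3,
                                                  interface_width = 0.5)),
               "infeasible|degenerate")
})

test_that("moduli profile calibrates bending stiffness and neutral plane", {
  ms <- monolayer_spec()
  mp <- moduli_profile(ms)
  expect_lt(abs(bending_stiffness(mp) / ms$kappa - 1), 0.02)
  expect_true(all(mp$poisson < 0.5))
  # neutral plane: first moment of E about z0 vanishes
  first <- sum(diff(mp$z_grid) *
                 (((mp$z_grid - mp$z0) * mp$youngs)[-1] +
                    ((mp$z_grid - mp$z0) * mp$youngs)[-length(mp$z_grid)]) / 2)
  expect_lt(abs(first) / (ms$kappa / ms$h), 0.05)
  # headgroup region stiffer than the chains
  expect_gt(mp$E_head, mp$E_tail)
})

test_that("zeta table round-trips through CSV", {
  path <- tempfile(fileext = ".csv")
  write.csv(lipid_zeta_table(), path, row.names = FALSE)
  expect_equal(read_zeta_table(path), lipid_zeta_table())
})
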