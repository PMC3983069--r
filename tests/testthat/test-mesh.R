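# Void geometry, meshing and adaptive refinement.

test_that("void cross-section follows the circular-segment closed form", {
  h <- 2
  expect_equal(void_cross_section(insertion_geometry(d = 0), h)$area, 0)
  # default insertion: r = 0.5, d = 0.8
  vc <- void_cross_section(insertion_geometry(), h)
  t <- 0.3; r <- 0.5
  expect_equal(vc$area,
               pi * r^2 - (r^2 * acos(t / r) - t * sqrt(r^2 - t^2)),
               tolerance = 1e-12)
  # rod exactly submerged: full circle
  expect_equal(void_cross_section(insertion_geometry(d = 1), h)$area,
               pi * 0.25, tolerance = 1e-12)
  expect_error(void_cross_section(insertion_geometry(d = 2.5), h),
               "exceeds")
})

test_that("void area agrees with Monte-Carlo point counting", {
  set.seed(11)
  geom <- insertion_geometry()
  vc <- void_cross_section(geom, 2)
  n <- 2e5
  x <- runif(n, -0.5, 0.5); z <- runif(n, 1.2, 2.2)
  inside <- (x^2 + (z - vc$z_center)^2 < 0.25) & (z < 2)
  expect_equal(vc$area, mean(inside), tolerance = 0.02)
})

test_that("void area is continuous and strictly increasing in depth", {
  h <- 2
  ds <- seq(0.05, 1, by = 0.05)
  areas <- sapply(ds, function(d)
    void_cross_section(insertion_geometry(d = d), h)$area)
  expect_true(all(diff(areas) > 0))
  # continuity at d -> 0
  expect_lt(void_cross_section(insertion_geometry(d = 1e-4), h)$area, 1e-4)
})

test_that("default mesh respects the element-count floors", {
  mesh <- build_mesh()
  expect_gte(nrow(mesh$triangles), 1908)
  expect_true(all(triangle_areas(mesh) > 0))
  expect_gte(min(triangle_min_angles(mesh)), 20)
  solver <- quick_solver()   # refinement floor honoured for its control
  expect_gte(nrow(solver$mesh$triangles),
             quick_control()$min_elements_refined)
})

test_that("boundary edges are tagged exactly once with the five labels", {
  mesh <- build_mesh()
  bt <- boundary_tags(mesh)
  expect_setequal(unique(bt$tag),
                  c("insertion_arc", "outer_surface", "inner_surface",
                    "left_symmetry", "right_relax"))
  key <- paste(pmin(bt$n1, bt$n2), pmax(bt$n1, bt$n2))
  expect_equal(anyDuplicated(key), 0L)
  # without insertion there is no arc
  bt0 <- boundary_tags(build_mesh(insertion_geometry(d = 0)))
  expect_false("insertion_arc" %in% bt0$tag)
})

test_that("meshes are simply connected triangulated disks", {
  expect_equal(euler_characteristic(build_mesh(insertion_geometry(d = 0))), 1)
  mesh <- refine_adaptive(build_mesh(), NULL, 1)
  expect_equal(euler_characteristic(mesh), 1)
})

test_that("refinement preserves conformity, orientation and quality", {
  mesh <- build_mesh(control = quick_control())
  set.seed(3)
  for (i in 1:2) {
    mesh <- refine_adaptive(mesh, runif(nrow(mesh$triangles)), 0.3)
    expect_true(all(triangle_areas(mesh) > 0))
    expect_equal(euler_characteristic(mesh), 1)
    expect_gte(min(triangle_min_angles(mesh)), 20)
  }
})

test_that("uniform refinement reduces the maximum element size", {
  mesh <- build_mesh(control = quick_control())
  h0 <- sqrt(max(triangle_areas(mesh)))
  m1 <- refine_adaptive(mesh, NULL, 1)
  m2 <- refine_adaptive(m1, NULL, 1)
  expect_lt(sqrt(max(triangle_areas(m1))), h0 + 1e-12)
  expect_lt(sqrt(max(triangle_areas(m2))), sqrt(max(triangle_areas(m1))))
})

test_that("energies decrease under nested refinement", {
  # the refined P2 space contains the coarse one, so the constrained
  # minimum cannot increase (smooth imposed-displacement fixture)
  ms <- default_membrane(); mod <- default_moduli(ms)
  ctrl <- mesh_control(L_dom = 10, dz_fine = 0.25, min_elements = 200,
                       min_elements_refined = 200, max_refine_passes = 0)
  mesh <- build_mesh(insertion_geometry(d = 0), ms$h, ctrl)
  energy_on <- function(mesh) {
    asm <- fem_assemble(mesh, mod)
    left <- which(abs(asm$coords[, 1]) < 1e-9)
    zs <- asm$coords[left, 2]
    ord <- order(zs); left <- left[ord]; zs <- zs[ord]
    vals <- 0.2 * exp(-((zs - 1) / 0.5)^2)     # smooth imposed profile
    iv <- seq(1L, length(left) - 2L, by = 2L)
    influx <- sum((zs[iv + 2] - zs[iv]) / 6 *
                    (vals[iv] + 4 * vals[iv + 1] + vals[iv + 2]))
    bcs <- structure(list(nodes = left, values = vals, scale = 1,
                          influx = influx, geom = insertion_geometry(d = 0)),
                     class = "insertion_bc")
    op <- fem_reduce(asm, bcs, "uncoupled")
    solve_equilibrium(op)$energy_half
  }
  e0 <- energy_on(mesh)
  m1 <- refine_adaptive(mesh, NULL, 1)
  e1 <- energy_on(m1)
  m2 <- refine_adaptive(m1, NULL, 1)
  e2 <- energy_on(m2)
  expect_lte(e1, e0 + 1e-6)
  expect_lte(e2, e1 + 1e-6)
  # successive energy decrements form a contracting Cauchy sequence
  d1 <- e0 - e1; d2 <- e1 - e2
  expect_gt(d1, 1e-12); expect_gt(d2, 0)
  expect_lt(d2 / d1, 0.5)
})

test_that("mesh export formats are readable text", {
  mesh <- build_mesh(control = quick_control())
  v <- tempfile(fileext = ".vtk")
  write_mesh_vtk(mesh, v, cell_data = list(a = triangle_areas(mesh)))
  lines <- readLines(v)
  expect_equal(lines[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("^CELL_DATA", lines)))
  np <- tempfile(fileext = ".csv"); ep <- tempfile(fileext = ".csv")
  write_mesh_csv(mesh, np, ep)
  expect_equal(nrow(read.csv(np)), nrow(mesh$nodes))
  expect_equal(nrow(read.csv(ep)), nrow(mesh$triangles))
})
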