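test_that("cell volumes follow the annulus formula", {
  # single annular cell: r centre 10 mm, dr 2 mm, dz 5 mm
  sc <- bottle_scenario("bottle1")
  m <- quick_mesh()
  v <- cell_volumes(m)
  rc <- (m$redge[-1] + m$redge[-length(m$redge)]) / 2
  i <- 5; j <- 3
  expect_equal(v[i, j], 2 * pi * rc[i] * diff(m$redge)[i] * diff(m$zedge)[j])
  # the worked annulus example, directly
  expect_equal(2 * pi * 0.010 * 0.002 * 0.005, 6.283185e-7, tolerance = 1e-6)
})

test_that("meshing hits the requested cell count and region volumes", {
  m <- build_mesh(bottle_scenario("bottle1"), target_cells = 4300)
  expect_lt(abs(m$n_active - 4300) / 4300, 0.15)
  expect_equal(region_volume(m, "milk"), 60e-6, tolerance = 0.01)
  m2 <- build_mesh(bottle_scenario("bottle2"), target_cells = 4300)
  expect_equal(region_volume(m2, "milk"), 178e-6, tolerance = 0.01)
  expect_error(region_volume(m, "beer"), "unknown region")
  expect_error(build_mesh(bottle_scenario("bottle1"), target_cells = 50),
               ">= 100")
})

test_that("region volumes are stable under 4x refinement", {
  sc <- bottle_scenario("bottle1")
  m1 <- build_mesh(sc, 700)
  m2 <- build_mesh(sc, 2800)
  for (rg in m1$region_names) {
    v1 <- region_volume(m1, rg); v2 <- region_volume(m2, rg)
    expect_lt(abs(v1 - v2) / v2, 0.005)
  }
})

test_that("regions partition the active mesh", {
  m <- quick_mesh()
  v <- cell_volumes(m)
  tot <- sum(v[!is.na(m$region)])
  by_region <- sum(vapply(m$region_names, function(rg)
    region_volume(m, rg), 0))
  expect_equal(by_region, tot)
  # no cell spans two materials: every active cell has exactly one region id
  expect_true(all(m$region[!is.na(m$region)] %in%
                    seq_along(m$region_names)))
})

test_that("boundary faces tile the exterior surface exactly once", {
  m <- quick_mesh("bottle2", 900)
  bf <- boundary_faces(m)
  sc <- m$scenario
  tags <- vapply(sc$boundaries, `[[`, "", "tag")
  expect_true(all(bf$tag %in% tags))          # every face covered
  expect_false(any(duplicated(bf[c("i", "j", "side")])))  # exactly once
  # total area matches the analytic exterior surface of the composite
  d <- sc$dims
  analytic <- pi * d$R_out^2 +                      # bottom (bottle + bath)
    2 * pi * d$R_out * d$z_bath +                   # heated outer wall
    pi * (d$R_out^2 - d$R_wall^2) +                 # bath surface
    2 * pi * d$R_wall * (d$H - d$z_bath) +          # wall above bath level
    pi * d$R_wall^2                                 # top (nipple + wall rim)
  expect_equal(sum(bf$area), analytic, tolerance = 0.01)
})

test_that("thermal diffusivity derives from the material table", {
  tab <- make_material_table()
  expect_equal(thermal_diffusivity(tab$milk), 0.5369 / (1030 * 3930))
  expect_equal(thermal_diffusivity(tab$milk), 1.33e-7, tolerance = 0.005)
  expect_equal(thermal_diffusivity(tab$water), 0.6 / (998.2 * 4182))
  expect_equal(thermal_diffusivity(tab$water), 1.44e-7, tolerance = 0.005)
  expect_equal(thermal_diffusivity(
    material("unit", rho = 1, cp = 1, k = 1, phase = "solid")), 1)
})
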