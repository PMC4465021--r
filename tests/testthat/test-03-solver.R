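test_that("uniform state with matching boundaries is a fixed point", {
  # whole system at 80 C, bath at 80 C, ambient convection replaced by an
  # 80 C environment: nothing may change
  sc <- cylinder_scenario(60, 107, 49, bath_temperature = 80,
                          initial_temperature = 80,
                          ambient_temperature = 80)
  mesh <- build_mesh(sc, 600)
  op <- quick_options()
  st0 <- init_state(mesh, op)
  st <- advance(st0, mesh, op, 3)
  act <- !is.na(mesh$region)
  expect_equal(max(abs(st$T[act] - 80)), 0, tolerance = 1e-8)
  expect_lt(max(abs(st$ur)) + max(abs(st$uz)), 1e-12)
})

test_that("solid cells never acquire velocity", {
  mesh <- quick_mesh()
  op <- quick_options()
  st <- advance(init_state(mesh, op), mesh, op, 5)
  solid <- which(mesh$region %in% match(c("bottle_wall", "nipple"),
                                        mesh$region_names))
  expect_identical(unname(st$ur[solid]), rep(0, length(solid)))
  expect_identical(unname(st$uz[solid]), rep(0, length(solid)))
  expect_false(any(!is.finite(st$T)) || any(!is.finite(st$ur)))
})

test_that("advance is deterministic", {
  mesh <- quick_mesh()
  op <- quick_options()
  st0 <- init_state(mesh, op)
  a <- advance(st0, mesh, op, 4)
  b <- advance(st0, mesh, op, 4)
  expect_identical(a$T, b$T)
  expect_identical(a$ur, b$ur)
  expect_identical(a$p, b$p)
})

test_that("isothermal fluid at its reference temperature stays at rest", {
  sc <- cylinder_scenario(60, 107, 49, bath_temperature = 20,
                          initial_temperature = 20,
                          ambient_temperature = 20)
  mesh <- build_mesh(sc, 600)
  op <- quick_options()
  st <- advance(init_state(mesh, op), mesh, op, 3)
  expect_lt(max(abs(st$ur)) + max(abs(st$uz)), 1e-12)
})

test_that("adiabatic conduction conserves total enthalpy per step", {
  tab <- make_material_table()
  g <- milkwarm:::manual_grid(redge = seq(0, 0.02, length.out = 11),
                              zedge = seq(0, 0.03, length.out = 13),
                              mat = tab$plastic)   # all sides adiabatic
  st <- milkwarm:::manual_state(10, 12, 4)
  # nonuniform initial field
  st$T <- matrix(4 + 40 * stats::dnorm(seq_len(120), 40, 25) /
                   stats::dnorm(40, 40, 25), 10, 12)
  st$T_prev <- st$T
  dr <- diff(g$redge); rc <- (g$redge[-1] + g$redge[-11]) / 2
  vols <- outer(2 * pi * rc * dr, diff(g$zedge))
  H0 <- sum(vols * st$T)
  for (k in 1:5) {
    st <- milkwarm:::run_manual(g, st, 1, dt = 0.5)
    H <- sum(vols * st$T)
    expect_lt(abs(H - H0) / abs(H0), 1e-8)
    H0 <- H
  }
})

test_that("converged steps satisfy discrete continuity to 1e-6", {
  mesh <- quick_mesh()
  op <- quick_options()
  st <- advance(init_state(mesh, op), mesh, op, 10)
  expect_lte(st$diag$div_scaled, 1e-6)
})

test_that("temperatures stay within the boundary range on a short run", {
  mesh <- quick_mesh()
  op <- quick_options()
  st <- advance(init_state(mesh, op), mesh, op, 25)
  expect_gte(st$diag$T_min_seen, 4 - 1e-6)
  expect_lte(st$diag$T_max_seen, 80 + 1e-6)
})

test_that("milk warms monotonically while the heater is on", {
  run <- simulate_warming(bottle_scenario("bottle1"), quick_options(),
                          end_time = 20, sample_interval = 2,
                          target_cells = 700)
  expect_true(all(diff(run$metrics$pat_C) >= -1e-9))
})

test_that("a zero-length simulation reports the initial condition", {
  run <- simulate_warming(bottle_scenario("bottle1"), quick_options(),
                          end_time = 0, sample_interval = 5,
                          target_cells = 700)
  expect_equal(nrow(run$metrics), 1)
  expect_equal(run$metrics$pat_C, 4)
  expect_equal(run$metrics$frac_above_40, 0)
})

test_that("random scenarios run stably for a few steps", {
  for (s in c(2, 11)) {
    sc <- random_scenario(s)
    mesh <- build_mesh(sc, 600)
    op <- quick_options()
    st <- advance(init_state(mesh, op), mesh, op, 5)
    lo <- min(sc$params$initial_temperature, sc$params$ambient_temperature)
    hi <- max(sc$params$bath_temperature, sc$params$ambient_temperature)
    expect_gte(st$diag$T_min_seen, lo - 1e-6)
    expect_lte(st$diag$T_max_seen, hi + 1e-6)
    expect_lte(st$diag$div_scaled, 1e-6)
  }
})
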