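test_that("slab series solution satisfies its limits and matches a brute-force
           finite-difference solution", {
  pb <- list(L = 0.01, alpha = 1.3e-7, T_init = 4, T_wall = 80, n = 400)
  # at t = 0 the alternating series converges like 1/(2n+1): with 400 terms
  # the truncation error on a 76 C step is about 0.06 C
  expect_equal(slab_conduction_profile(pb, 0, 0), 4, tolerance = 0.02)
  expect_equal(slab_conduction_profile(pb, 0, 1e9), 80, tolerance = 1e-9)

  # independent explicit finite-difference oracle on a fine grid
  fo <- 0.2                           # alpha t / L^2
  t_end <- fo * pb$L^2 / pb$alpha
  nx <- 401
  x <- seq(-pb$L, pb$L, length.out = nx)
  dx <- x[2] - x[1]
  dt <- 0.2 * dx^2 / pb$alpha
  nt <- ceiling(t_end / dt); dt <- t_end / nt
  Tn <- rep(4, nx); Tn[c(1, nx)] <- 80
  lam <- pb$alpha * dt / dx^2
  for (k in seq_len(nt)) {
    Tn[2:(nx - 1)] <- Tn[2:(nx - 1)] +
      lam * (Tn[1:(nx - 2)] - 2 * Tn[2:(nx - 1)] + Tn[3:nx])
    Tn[c(1, nx)] <- 80
  }
  centre_fd <- Tn[(nx + 1) / 2]
  centre_series <- slab_conduction_profile(pb, 0, t_end)
  expect_equal(centre_series, centre_fd, tolerance = 1e-4)
})

test_that("lumped capacitance closed form behaves at its limits", {
  expect_equal(lumped_capacitance_temperature(0, 10, 1e-2, 1000, 4000,
                                              1e-4, 4, 80), 4)
  # one time constant from 4 to 80: 80 - 76/e
  tc <- 1000 * 4000 * 1e-4 / (10 * 1e-2)
  expect_equal(lumped_capacitance_temperature(tc, 10, 1e-2, 1000, 4000,
                                              1e-4, 4, 80),
               80 - 76 / exp(1), tolerance = 1e-12)
  expect_equal(80 - 76 / exp(1), 52.0, tolerance = 1e-3)
  # h -> 0: stays at the initial temperature
  expect_equal(lumped_capacitance_temperature(1e6, 1e-12, 1e-2, 1000, 4000,
                                              1e-4, 4, 80), 4,
               tolerance = 1e-3)
})

test_that("flow-disabled solver matches the slab series to under 1% L2", {
  milk <- make_material_table()$milk
  alpha <- thermal_diffusivity(milk)
  L <- 0.01
  t_end <- 0.2 * L^2 / alpha
  pr <- slab_fv_profile(200, L, milk, 4, 80, t_end, t_end / 4000)
  l2 <- sqrt(mean((pr$T_fv - pr$T_exact)^2)) / (80 - 4)
  expect_lt(l2, 0.01)
})

test_that("slab discretization converges at second order in space", {
  milk <- make_material_table()$milk
  alpha <- thermal_diffusivity(milk)
  L <- 0.01
  t_end <- 0.2 * L^2 / alpha
  ns <- c(25, 50, 100)
  errs <- vapply(ns, function(n) {
    pr <- slab_fv_profile(n, L, milk, 4, 80, t_end, t_end / (40 * n))
    sqrt(mean((pr$T_fv - pr$T_exact)^2)) / (80 - 4)
  }, 0)
  orders <- diff(-log(errs)) / diff(log(ns))
  expect_true(all(orders >= 1.8))
})

test_that("a low-Biot solid tracks the lumped-capacitance curve within 2%", {
  lf <- lumped_fv_temperature(times = c(300, 900, 1800, 3600))
  rel <- abs(lf$T_fv - lf$T_exact) / (80 - 4)
  expect_true(all(rel < 0.02))
})

test_that("refinement factor 1 reproduces the base run exactly", {
  sc <- bottle_scenario("bottle1")
  op <- quick_options()
  base <- simulate_warming(sc, op, end_time = 4, sample_interval = 2,
                           target_cells = 700)
  ref1 <- refined_reference_metrics(sc, op, 1, end_time = 4,
                                    sample_interval = 2, target_cells = 700)
  expect_identical(base$metrics, ref1$metrics)
})

test_that("verification suite passes end to end", {
  res <- run_verification(quiet = TRUE)
  expect_true(all(res$pass))
})
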