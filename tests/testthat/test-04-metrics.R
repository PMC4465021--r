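test_that("mass-weighted mean reduces to the volume-weighted mean", {
  mesh <- quick_mesh()
  st <- fake_state(mesh, function(r, z) 36)
  expect_equal(mass_weighted_mean_temperature(st, mesh, "milk"), 36)
  # two equal-volume halves at 30 and 50 -> 40 (symmetry in z within milk)
  zt <- mesh$scenario$dims$t_wall + mesh$scenario$dims$h_milk / 2
  st2 <- fake_state(mesh, function(r, z) ifelse(z < zt, 30, 50))
  v <- cell_volumes(mesh)
  idx <- which(mesh$region == match("milk", mesh$region_names))
  manual <- sum(v[idx] * st2$T[idx]) / sum(v[idx])
  expect_equal(mass_weighted_mean_temperature(st2, mesh, "milk"), manual)
  expect_equal(manual, 40, tolerance = 0.02)  # mesh snaps mid-milk closely
  expect_error(mass_weighted_mean_temperature(st, mesh, "froth"), "unknown")
})

test_that("fraction_in_range is a half-open, additive partition", {
  mesh <- quick_mesh()
  set.seed(1)
  st <- fake_state(mesh, function(r, z) 4 + 76 * (z / max(z)))
  expect_equal(fraction_in_range(st, mesh, "milk", -Inf, Inf), 1)
  f1 <- fraction_in_range(st, mesh, "milk", -Inf, 20)
  f2 <- fraction_in_range(st, mesh, "milk", 20, 40)
  f3 <- fraction_in_range(st, mesh, "milk", 40, Inf)
  expect_equal(f1 + f2 + f3, 1, tolerance = 1e-12)
  # monotone in the lower limit
  lo <- seq(0, 60, by = 5)
  fr <- vapply(lo, function(l) fraction_in_range(st, mesh, "milk", l), 0)
  expect_true(all(diff(fr) <= 1e-15))
  st36 <- fake_state(mesh, function(r, z) 36)
  expect_equal(fraction_in_range(st36, mesh, "milk", 40), 0)
  expect_error(fraction_in_range(st36, mesh, "milk", 50, 40), "t_lo")
})

test_that("extrema bracket the mean for any field", {
  mesh <- quick_mesh()
  set.seed(2)
  st <- fake_state(mesh, function(r, z) 4 + 76 * abs(sin(500 * r + 300 * z)))
  ex <- region_extrema(st, mesh, "milk")
  pat <- mass_weighted_mean_temperature(st, mesh, "milk")
  expect_lte(ex["t_min"], pat)
  expect_gte(ex["t_max"], pat)
  stc <- fake_state(mesh, function(r, z) 21.5)
  expect_equal(unname(region_extrema(stc, mesh, "milk")), c(21.5, 21.5))
})

test_that("time_to_threshold interpolates the first crossing", {
  ser <- data.frame(time_s = c(0, 10, 20, 30),
                    pat_C = c(4, 30, 50, 70),
                    t_max_C = c(10, 45, 60, 75))
  # brute force: 40 is crossed between 10 s (30 C) and 20 s (50 C)
  expect_equal(time_to_threshold(ser, 40, "pat"), 10 + 10 * (40 - 30) / 20)
  expect_equal(time_to_threshold(ser, 40, "t_max"), 10 * (40 - 10) / 35)
  expect_equal(time_to_threshold(ser, 5, "t_max"), 0)     # starts above
  expect_true(is.na(time_to_threshold(ser, 90, "pat")))   # never reached
})

test_that("stream function reconstructs an analytic solenoidal vortex", {
  err <- vapply(c(16, 32), function(n) {
    R <- 0.03; H <- 0.04
    redge <- seq(0, R, length.out = n + 1)
    zedge <- seq(0, H, length.out = n + 1)
    mesh <- structure(list(redge = redge, zedge = zedge, nr = n, nz = n,
                           region = matrix(1L, n, n), region_names = "fluid"),
                      class = "aximesh")
    rc <- (redge[-1] + redge[-(n + 1)]) / 2
    zc <- (zedge[-1] + zedge[-(n + 1)]) / 2
    # psi = r^2 (1 - r/R)^2 sin(pi z/H):  u_z = (1/r) dpsi/dr
    st <- list(time = 0,
               uz = outer(rc, zc, function(r, z)
                 (2 * r * (1 - r / R)^2 - 2 * r^2 * (1 - r / R) / R) *
                   sin(pi * z / H) / r),
               ur = outer(rc, zc, function(r, z)
                 -r * (1 - r / R)^2 * pi / H * cos(pi * z / H)))
    psi <- stream_function(st, mesh)
    psi_exact <- outer(redge, zedge, function(r, z)
      r^2 * (1 - r / R)^2 * sin(pi * z / H))
    max(abs(psi - psi_exact)) / max(abs(psi_exact))
  }, 0)
  expect_lt(err[1], 0.15)
  expect_lt(err[2], err[1] / 2)   # vanishes under refinement
})

test_that("stream function of a quiescent field is identically zero", {
  mesh <- quick_mesh()
  st <- init_state(mesh)
  expect_identical(unique(as.numeric(stream_function(st, mesh))), 0)
})

test_that("differentiating psi recovers the axial velocity", {
  mesh <- quick_mesh()
  op <- quick_options()
  st <- advance(init_state(mesh, op), mesh, op, 10)
  psi <- stream_function(st, mesh)
  r2 <- mesh$redge^2
  # invert the radial integration row by row at interior node rows
  uz_rec <- (psi[-1, ] - psi[-(mesh$nr + 1), ]) /
    ((r2[-1] - r2[-(mesh$nr + 1)]) / 2)
  uzn <- cbind(st$uz[, 1],
               (st$uz[, -mesh$nz] + st$uz[, -1]) / 2, st$uz[, mesh$nz])
  expect_equal(uz_rec, uzn, tolerance = 1e-12)
})
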