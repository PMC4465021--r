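test_that("material table carries the reference properties", {
  tab <- make_material_table()
  expect_equal(tab$milk$cp, 3930)
  expect_equal(tab$milk$rho, 1030)
  expect_equal(tab$milk$k, 0.5369)
  expect_equal(tab$water$mu, 1e-3)
  expect_equal(tab$air$beta, 3.43e-3)
  expect_equal(tab$plastic$phase, "solid")
  expect_true(is.na(tab$plastic$mu) && is.na(tab$plastic$beta))
})

test_that("material constructor enforces the phase invariants", {
  expect_error(material("x", rho = -1, cp = 1, k = 1, phase = "solid"), "rho")
  expect_error(material("x", rho = 1, cp = 1, k = 1, phase = "liquid"), "mu")
  expect_error(material("x", rho = 1, cp = 1, k = 1, mu = 1, beta = 1,
                        phase = "solid"), "solids")
  m <- material("x", rho = 1, cp = 1, k = 1, mu = 1, beta = 0,
                phase = "gas")
  expect_s3_class(m, "milk_material")
})

test_that("bottle presets reproduce the preset dimensions", {
  b1 <- bottle_scenario("bottle1")
  expect_equal(b1$milk_volume, 60)
  expect_equal(b1$bottle_height, 49)
  expect_equal(b1$total_bottle_volume, 107)
  # inner radius from total volume and height as a plain cylinder
  expect_equal(b1$dims$R_in, sqrt(107e-6 / (pi * 0.049)), tolerance = 1e-12)
  expect_equal(b1$dims$R_in * 1000, 26.4, tolerance = 2e-3)

  b2 <- bottle_scenario("bottle2")
  expect_equal(b2$milk_volume, 178)
  expect_equal(b2$bottle_height, 140)
  expect_equal(b2$total_bottle_volume, 324)

  expect_equal(unname(b1$initial_temperatures["milk"]), 4)
  expect_equal(unname(b1$initial_temperatures["bath_water"]), 80)
  expect_error(bottle_scenario("bottle3"), "bottle1, bottle2")
})

test_that("scenario extents integrate to the declared milk volume", {
  for (sc in list(bottle_scenario("bottle1"), bottle_scenario("bottle2"))) {
    milk <- sc$regions[[which(vapply(sc$regions, `[[`, "", "name") == "milk")]]
    v <- milkwarm:::extent_volume(milk$extent)
    expect_equal(v, sc$milk_volume * 1e-6, tolerance = 0.01)
  }
})

test_that("random scenarios are deterministic in the seed and valid", {
  expect_identical(random_scenario(7), random_scenario(7))
  vols <- vapply(1:100, function(s) random_scenario(s)$milk_volume, 0)
  expect_true(all(vols >= 30 & vols <= 250))
  for (s in c(1, 17, 99)) {
    sc <- random_scenario(s)
    expect_silent(validate_scenario(sc))
    expect_true(sc$params$bath_temperature >= 40 &&
                  sc$params$bath_temperature <= 90)
    expect_true(sc$params$initial_temperature >= 2 &&
                  sc$params$initial_temperature <= 25)
    expect_true(sc$params$wall_mm >= 1 && sc$params$wall_mm <= 3)
  }
})

test_that("random_scenario leaves the caller's RNG stream untouched", {
  set.seed(42)
  a <- runif(1)
  set.seed(42)
  invisible(random_scenario(3))
  expect_identical(runif(1), a)
})
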