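test_that("resistance-conductance conversion is the reciprocal in mS", {
  expect_equal(resistance_to_conductance(1.11), 0.90, tolerance = 0.005)
  expect_equal(resistance_to_conductance(0.56), 1.79, tolerance = 0.005)
  expect_equal(resistance_to_conductance(1), 1)
  expect_error(resistance_to_conductance(0), "positive")
  expect_error(resistance_to_conductance(-2), "positive")
})

test_that("packaged calibration table is self-consistent", {
  tab <- fhsa_calibration()
  loaded <- tab[tab$conductance > 0, ] # baseline row is zeroed by convention
  expect_equal(resistance_to_conductance(loaded$resistance_kohm),
               loaded$conductance, tolerance = 0.005)
  expect_true(all(diff(tab$pressure) > 0))
})

test_that("calibration curve evaluates the quadratic through the origin", {
  curve <- calibration_curve(0.022, 0.106)
  expect_equal(pressure_from_conductance(0, curve), 0)
  # 0.022 * 0.9^2 + 0.106 * 0.9
  expect_equal(pressure_from_conductance(0.9, curve), 0.11322,
               tolerance = 1e-9)
  p <- pressure_from_conductance(1.79, curve)
  expect_equal(p, 0.2602302, tolerance = 1e-9)
  expect_lt(abs(p - 0.25), 0.02) # close to the tabulated pressure
  # strictly increasing for positive coefficients
  g <- seq(0, 3, by = 0.05)
  expect_true(all(diff(pressure_from_conductance(g, curve)) > 0))
  expect_error(pressure_from_conductance(-0.1, curve), "non-negative")
})

test_that("curve inversion returns the non-negative root and round-trips", {
  curve <- calibration_curve(0.022, 0.106)
  expect_equal(conductance_from_pressure(0, curve), 0)
  expect_equal(conductance_from_pressure(0.1132, curve), 0.9, tolerance = 1e-3)
  lin <- calibration_curve(0, 0.106)
  expect_equal(conductance_from_pressure(0.106, lin), 1.0)
  expect_error(conductance_from_pressure(-0.1, curve), "non-negative")
  expect_error(conductance_from_pressure(0.1, calibration_curve(0, 0)),
               "degenerate")
  set.seed(7)
  p <- runif(100, 0, 0.25)
  back <- pressure_from_conductance(conductance_from_pressure(p, curve), curve)
  expect_equal(back, p, tolerance = 1e-9)
})

test_that("calibration fit recovers exact data and matches the table", {
  g <- seq(0.1, 2, length.out = 8)
  exact <- fit_calibration(data.frame(pressure = 0.022 * g^2 + 0.106 * g,
                                      conductance = g))
  expect_equal(exact$a, 0.022, tolerance = 1e-10)
  expect_equal(exact$b, 0.106, tolerance = 1e-10)

  fitted <- fit_calibration(fhsa_calibration())
  expect_equal(fitted$a, 0.022, tolerance = 0.03)
  expect_equal(fitted$b, 0.106, tolerance = 0.03)

  # analytic linear solution from two points on p = g
  line <- fit_calibration(data.frame(pressure = c(1, 2), conductance = c(1, 2)))
  expect_equal(line$a, 0, tolerance = 1e-10)
  expect_equal(line$b, 1, tolerance = 1e-10)

  expect_error(fit_calibration(data.frame(pressure = 1, conductance = 1)),
               "at least two")
})

test_that("least-squares fit attains the grid-search minimum RSS", {
  set.seed(11)
  for (i in 1:3) {
    g <- sort(runif(5, 0.1, 2))
    p <- 0.03 * g^2 + 0.09 * g + rnorm(5, sd = 0.01)
    fit <- fit_calibration(data.frame(pressure = p, conductance = g))
    rss_fit <- calib_rss(fit$a, fit$b, g, p)
    rss_grid <- grid_search_calibration(g, p, fit$a + c(-0.05, 0.05),
                                        fit$b + c(-0.05, 0.05))
    expect_lte(rss_fit, rss_grid + 1e-6)
  }
})

test_that("piezoresistive response is linear in the in-plane forces", {
  expect_equal(relative_resistance_change(0, 0, 0.01, 0.02), 0)
  expect_equal(relative_resistance_change(10, 5, 0.01, 0.02), 0.2)
  one <- relative_resistance_change(3, 4, 0.01, 0.02)
  expect_equal(relative_resistance_change(6, 8, 0.01, 0.02), 2 * one)
  expect_error(relative_resistance_change(Inf, 0, 0.01, 0.02), "finite")
})

test_that("surface stress follows the point-load field", {
  z <- surface_stress(1, 1, 0, 0)
  expect_equal(z$sigma_x, 0)
  expect_equal(z$sigma_y, 0)
  s <- surface_stress(1, 0, 1, 0)
  expect_equal(s$sigma_x, 2 / pi)
  expect_equal(s$sigma_y, 0)
  sym <- surface_stress(1, 1, 1, 1)
  expect_equal(sym$sigma_x, 1 / pi)
  expect_equal(sym$sigma_y, 1 / pi)
  # sigma_x / sigma_y = x^2 / y^2 under a shared load factor
  sx <- surface_stress(2, 3, 1, 1)
  expect_equal(sx$sigma_x / sx$sigma_y, 4 / 9)
  expect_error(surface_stress(0, 0, 1, 1), "singular")
})

test_that("geometric resistance change applies the design rule", {
  expect_equal(geometric_resistance_change(0.42, 0.1, 50, 50, 1), 1.184)
  expect_equal(geometric_resistance_change(0.3, 0, 0, 1, 1), 0)
  eps <- seq(0, 1, by = 0.1)
  out <- sapply(eps, geometric_resistance_change,
                poisson = 0.42, length_mm = 50, width_mm = 50,
                thickness_mm = 1)
  expect_true(all(diff(out) > 0))
  expect_error(geometric_resistance_change(0.42, 0.1, 50, 0, 1), "positive")
})

test_that("position stress check is linear in the load", {
  expect_equal(strain_at_position(10, 10, 1, 0), 0)
  expect_equal(strain_at_position(0, 0, 1, 1), 3 / (4 * pi))
  full <- strain_at_position(5, 5, 1, 2)
  expect_equal(strain_at_position(5, 5, 1, 1), full / 2)
  expect_error(strain_at_position(5, 5, 0, 1), "positive")
})

test_that("force-pressure unit helpers invert each other", {
  f <- pressure_to_force(0.25)
  expect_equal(force_to_pressure(f), 0.25)
  expect_equal(force_to_pressure(9.80665 * 25), 1)
})

test_that("calibration table and curve round-trip through disk", {
  tab <- fhsa_calibration()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_calibration_table(tab, path)
  expect_equal(read_calibration_table(path), tab)

  curve <- fit_calibration(tab)
  jpath <- withr::local_tempfile(fileext = ".json")
  write_calibration_curve(curve, jpath)
  back <- read_calibration_curve(jpath)
  expect_equal(back$a, curve$a)
  expect_equal(back$b, curve$b)
})

test_that("array spec validates its geometry", {
  spec <- fhsa_spec()
  expect_equal(spec$n_units, 36L)
  expect_error(fhsa_spec(poisson = 0.6), "poisson")
  expect_error(fhsa_spec(thickness_mm = 0), "positive")
})
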