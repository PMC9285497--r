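test_that("registry holds the seven materials with the documented baselines", {
  reg <- tissue_registry()
  expect_setequal(reg$tissue, c("electrode", "plastic", "nidus", "sclerotic",
                                "trabecular", "cortical", "muscle"))
  pick <- function(t, f) reg[reg$tissue == t, f]
  expect_equal(pick("nidus", "sigma"), 0.22)
  expect_equal(pick("nidus", "density"), 1046)
  expect_equal(pick("cortical", "thermal_conductivity"), 0.32)
  expect_equal(pick("cortical", "perfusion"), 0)
  expect_equal(pick("muscle", "sigma"), 0.446)
  expect_equal(pick("trabecular", "perfusion"), 5.9e-4)
  expect_equal(pick("sclerotic", "water_fraction"), 0.23)
  expect_equal(pick("electrode", "water_fraction"), 0)
  expect_true(all(reg$water_fraction <= 1 & reg$water_fraction >= 0))
})

test_that("registry overrides are applied and validated", {
  reg <- tissue_registry(list(nidus = list(sigma = 0.5)))
  expect_equal(reg$sigma[reg$tissue == "nidus"], 0.5)
  expect_error(tissue_registry(list(bone = list(sigma = 1))), "unknown tissue")
  expect_error(tissue_registry(list(nidus = list(conductivity = 1))),
               "unknown property field")
  expect_error(tissue_registry(list(nidus = list(sigma = -1))), "nonnegative")
})

test_that("electrical conductivity follows the linear rise and vaporization drop", {
  expect_equal(electrical_conductivity("nidus", 37), 0.22)
  expect_equal(electrical_conductivity("muscle", 57), 0.446 * 1.30)
  ## vaporized plateau
  expect_equal(electrical_conductivity("nidus", 110), 0.01)
  expect_equal(electrical_conductivity("muscle", 200), 0.01)
  ## midpoint of the (100, 105] ramp
  s100 <- 0.22 * (1 + 0.015 * 63)
  expect_equal(electrical_conductivity("nidus", 102.5), (s100 + 0.01) / 2,
               tolerance = 1e-12)
  expect_error(electrical_conductivity("bone", 37), "unknown tissue")
  expect_error(electrical_conductivity("nidus", -5), "below 0")
})

test_that("thermal conductivity rises linearly and caps at 100 C", {
  expect_equal(thermal_conductivity("cortical", 37), 0.32)
  expect_equal(thermal_conductivity("cortical", 100), 0.32 + 0.003 * 63)
  expect_equal(thermal_conductivity("cortical", 130), 0.32 + 0.003 * 63)
  ## relative reading available as a configuration switch
  cst <- model_constants(d_k_relative = TRUE)
  expect_equal(thermal_conductivity("cortical", 47, constants = cst),
               0.32 * (1 + 0.003 * 10))
  Ts <- seq(0, 150, by = 0.5)
  k <- thermal_conductivity(rep("muscle", length(Ts)), Ts)
  expect_true(all(diff(k) >= 0))
})

test_that("enthalpy has the sensible/latent/vapor branches and is strictly increasing", {
  expect_equal(enthalpy("nidus", 37), 0)
  expect_equal(enthalpy("nidus", 50), 1046 * 2726 * 13)
  ## latent jump over the (99, 100] ramp includes the density factor
  expect_equal(enthalpy("nidus", 100) - enthalpy("nidus", 99),
               1046 * 2.25e6 * 0.60)
  ## vapor branch slope
  expect_equal(enthalpy("nidus", 101) - enthalpy("nidus", 100), 370 * 2156)
  Ts <- seq(35, 130, by = 0.25)
  h <- enthalpy("muscle", Ts)
  expect_true(all(diff(h) > 0))
  capacity <- enthalpy("muscle", Ts, derivative = TRUE)
  expect_true(all(capacity >= 1090 * 3421 - 1e-9 | Ts > 100))
})

test_that("all property models are continuous at the branch points", {
  eps <- 1e-6
  for (Tb in c(99, 100, 105)) {
    for (tis in c("nidus", "muscle", "cortical")) {
      expect_equal(electrical_conductivity(tis, Tb - eps),
                   electrical_conductivity(tis, Tb + eps), tolerance = 1e-4)
      expect_equal(thermal_conductivity(tis, Tb - eps),
                   thermal_conductivity(tis, Tb + eps), tolerance = 1e-4)
      expect_equal(enthalpy(tis, Tb - eps), enthalpy(tis, Tb + eps),
                   tolerance = 1e-3)
    }
  }
  ## sigma rises on [0, 100] and falls on [100, 105]
  Ts <- seq(37, 100, by = 0.5)
  expect_true(all(diff(electrical_conductivity(rep("nidus", length(Ts)), Ts)) >= 0))
  Ts <- seq(100, 105, by = 0.1)
  expect_true(all(diff(electrical_conductivity(rep("nidus", length(Ts)), Ts)) <= 0))
})

test_that("perfusion sink is proportional to the temperature excess and gated by death", {
  cst <- model_constants()
  expect_equal(perfusion_sink("nidus", 47, alive = TRUE),
               48e-4 * 1050 * 3617 * 10)
  expect_identical(perfusion_sink("nidus", 47, alive = FALSE), 0)
  expect_identical(perfusion_sink("cortical", 80, alive = TRUE), 0)
  expect_identical(perfusion_sink("electrode", 80, alive = TRUE), 0)
  expect_equal(perfusion_sink("muscle", 37, alive = TRUE), 0)
})
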