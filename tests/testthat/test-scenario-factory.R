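test_that("scenarios carry the documented region sets", {
  expect_setequal(build_scenario("a")$regions$label,
                  c("electrode", "plastic", "nidus", "sclerotic",
                    "trabecular", "cortical", "muscle"))
  expect_setequal(build_scenario("b")$regions$label,
                  c("electrode", "plastic", "nidus", "trabecular",
                    "cortical", "muscle"))
  ## intracortical nidus: direct nidus-cortical contact, no trabecular rim
  gc <- build_scenario("c")
  expect_setequal(gc$regions$label,
                  c("electrode", "plastic", "nidus", "cortical", "muscle"))
  expect_equal(gc$classify(5.05, 0), "cortical")
  expect_equal(gc$classify(4.9, 0), "nidus")
  expect_error(build_scenario("x"), "unknown scenario_id")
})

test_that("region areas tile the bounding box and match closed forms", {
  for (sc in c("a", "b", "c", "validation")) {
    g <- build_scenario(sc)
    expect_equal(sum(g$regions$area_mm2),
                 g$bbox["r_max"] * (g$bbox["z_max"] - g$bbox["z_min"]),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_true(all(g$regions$area_mm2 > 0))
  }
  ## nidus half-disc of radius 5 mm minus the embedded electrode column
  ## (tip plus the shaft crossing the upper cap); overlap via independent
  ## 1-D quadrature of the column/disc cross-section
  g <- build_scenario("a")
  re <- g$params$electrode_radius
  col_disc <- function(R) stats::integrate(
    function(z) pmin(re, sqrt(pmax(R^2 - z^2, 0))), -3.75, R,
    rel.tol = 1e-12)$value
  expect_equal(g$regions$area_mm2[g$regions$label == "nidus"],
               pi * 25 / 2 - col_disc(5), tolerance = 1e-8)
  ## with an override the half-disc formula follows the new radius
  g8 <- build_scenario("a", list(nidus_radius = 8))
  expect_equal(g8$regions$area_mm2[g8$regions$label == "nidus"],
               pi * 64 / 2 - col_disc(8), tolerance = 1e-8)
})

test_that("geometry overrides are validated with the offending parameter named", {
  expect_error(build_scenario("a", list(nidus_radius = -2)), "nidus_radius")
  expect_error(build_scenario("a", list(wall = 3)), "unknown geometry parameter")
  expect_error(build_scenario("a", list(electrode_radius = 6)),
               "electrode_radius")
  expect_error(build_scenario("a", list(cortical_thickness = 60)),
               "cortical")
  expect_error(build_scenario("validation", list(lamella_thickness = 50)),
               "lamella")
})

test_that("classifier partitions the half-plane with every label in the registry", {
  reg <- tissue_registry()
  set.seed(42)
  r <- runif(4000, 0, 40); z <- runif(4000, -40, 40)
  for (sc in c("a", "b", "c", "validation")) {
    g <- build_scenario(sc)
    lab <- g$classify(r, z)
    expect_true(all(lab %in% reg$tissue))
    expect_true(all(!is.na(lab)))
  }
})

test_that("validation scenario places three probes in soft tissue below the periosteum", {
  g <- build_scenario("validation")
  expect_equal(nrow(g$probe_points), 3L)
  expect_equal(g$probe_points[, "z"], c(-8, -13, -18))
  ## probe 1 on the periosteum plane, others in muscle
  expect_equal(unname(g$classify(g$probe_points[2, 1], g$probe_points[2, 2])),
               "muscle")
  ## lamella thickness on the axis below the nidus
  expect_equal(unname(g$classify(0, -6.5)), "cortical")
  expect_equal(unname(g$classify(0, -8.5)), "muscle")
})
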