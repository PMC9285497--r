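# The solver's log-space Arrhenius evaluation is checked against the direct
# product A * exp(-dE/(R T)), an independent double-precision route that is
# exact in the physiological range.

test_that("damage rate matches the direct-product oracle and is increasing", {
  cst <- arrhenius_constants()
  direct <- function(Tk) cst$A * exp(-cst$dE / (cst$R * Tk))
  for (Tc in c(37, 50, 60, 70, 80, 90, 99)) {
    Tk <- Tc + 273.15
    expect_equal(arrhenius_rate(Tk), direct(Tk), tolerance = 1e-12)
  }
  ## magnitudes: negligible at body temperature, ~3e-2/s at 50 C
  expect_lt(arrhenius_rate(310.15), 1e-6)
  expect_equal(arrhenius_rate(323.15), direct(323.15))
  expect_true(direct(323.15) > 0.025 && direct(323.15) < 0.04)
  Tk <- seq(300, 400, by = 1)
  expect_true(all(diff(arrhenius_rate(Tk)) > 0))
  expect_error(arrhenius_rate(-3), "non-physical")
})

test_that("damage integration is additive and matches fine quadrature to < 0.5%", {
  m <- coarse_mesh("a")
  nsel <- 20L
  ## prescribed nodal temperature history: ramp then plateau
  trace_T <- function(t) pmin(37 + 1.5 * t, 80)
  times <- seq(0, 60, by = 0.5)
  omega <- numeric(m$n_nodes); alive <- rep(TRUE, m$n_tris)
  for (k in seq_len(length(times) - 1)) {
    T1 <- rep(trace_T(times[k]), m$n_nodes)
    T2 <- rep(trace_T(times[k + 1]), m$n_nodes)
    up <- integrate_damage(omega, alive, T1, T2, diff(times)[1], m)
    omega <- up$omega; alive <- up$alive
  }
  ora <- arrhenius_quadrature_oracle(times, trace_T(times), dt_fine = 0.005)
  expect_equal(omega[1], ora, tolerance = 0.005)
  ## additivity: two half-integrations equal one full integration exactly
  om1 <- integrate_damage(numeric(m$n_nodes), alive,
                          rep(60, m$n_nodes), rep(60, m$n_nodes), 10, m)$omega
  om2 <- integrate_damage(om1, alive,
                          rep(60, m$n_nodes), rep(60, m$n_nodes), 10, m)$omega
  om_full <- integrate_damage(numeric(m$n_nodes), alive,
                              rep(60, m$n_nodes), rep(60, m$n_nodes), 20, m)$omega
  expect_equal(om2, om_full, tolerance = 1e-12)
})

test_that("constant 50 C reaches the death threshold at the closed-form time", {
  rate <- arrhenius_constants()$A *
    exp(-arrhenius_constants()$dE / (arrhenius_constants()$R * 323.15))
  t_death <- 4.6 / rate
  m <- coarse_mesh("a")
  om <- integrate_damage(numeric(m$n_nodes), rep(TRUE, m$n_tris),
                         rep(50, m$n_nodes), rep(50, m$n_nodes),
                         t_death, m)$omega
  expect_equal(om[1], 4.6, tolerance = 1e-9)
  ## body temperature for 15 minutes: nowhere near death
  om37 <- integrate_damage(numeric(m$n_nodes), rep(TRUE, m$n_tris),
                           rep(37, m$n_nodes), rep(37, m$n_nodes), 900, m)$omega
  expect_lt(om37[1], 1e-3)
})

test_that("death probability transform behaves at the anchors", {
  expect_equal(death_probability(4.6), 1 - exp(-4.6))
  expect_equal(round(100 * death_probability(4.6)), 99)
  expect_identical(death_probability(0), 0)
  expect_equal(death_probability(1e6), 1)
  expect_error(death_probability(-1), "nonnegative")
  ## monotone
  om <- seq(0, 10, by = 0.1)
  expect_true(all(diff(death_probability(om)) > 0))
})

test_that("dead elements never revive and their perfusion is exactly zero", {
  r <- study_run("a", 90)
  expect_true(all(r$final_omega >= 0))
  ## alive mask is consistent with the threshold on element means
  tris <- r$mesh$tris
  om_e <- (r$final_omega[tris[, 1]] + r$final_omega[tris[, 2]] +
           r$final_omega[tris[, 3]]) / 3
  expect_true(all(xor(om_e >= 4.6, r$final_alive)))
  ## the sink coefficient used downstream is bitwise zero for dead elements
  fem <- r$fem
  coef <- fem$wperf * fem$constants$rho_blood * fem$constants$c_blood *
    as.numeric(r$final_alive)
  expect_true(all(coef[!r$final_alive] == 0))
})

test_that("ablation radius finds the outermost linear crossing", {
  m <- coarse_mesh("a")
  d_mm <- sqrt(rowSums(m$nodes^2)) * 1000
  ## synthetic cone: Omega = 9.2 (1 - d/10), crossing 4.6 at exactly 5 mm
  om <- 9.2 * pmax(0, 1 - d_mm / 10)
  expect_equal(ablation_radius(om, m, "perpendicular"), 5, tolerance = 0.01)
  expect_equal(ablation_radius(om, m, "parallel"), 5, tolerance = 0.01)
  ## zero field: zero radius
  expect_identical(ablation_radius(numeric(m$n_nodes), m), 0)
  ## pointwise increase never shrinks the radius
  om2 <- om * 1.5
  expect_gte(ablation_radius(om2, m), ablation_radius(om, m))
})

test_that("radius series are monotone in time including during cooldown", {
  for (sc in c("a", "c")) {
    r <- study_run(sc, 90)
    expect_true(all(diff(r$r_perp) >= -1e-9))
    expect_true(all(diff(r$r_par) >= -1e-9))
    ## damage keeps accruing while hot: the radius still grows after
    ## the electrode is switched off
    i_off <- which.min(abs(r$times - 240))
    expect_gt(r$r_perp[length(r$r_perp)], r$r_perp[i_off])
  }
})
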