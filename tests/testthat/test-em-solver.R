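# The electric solver is certified against the closed-form annulus problem:
# concentric cylinders, inner radius a at V0, outer radius b grounded,
# flux-free axial ends, V(r) = V0 ln(b/r)/ln(b/a).

annulus_fem <- function(nr = 40, nz = 9, a = 1, b = 20, L = 10) {
  rl <- exp(seq(log(a), log(b), length.out = nr))
  zl <- seq(0, L, length.out = nz)
  msh <- structured_mesh(rl, zl)
  fem <- fem_setup(msh)
  list(msh = msh, fem = fem,
       inner = which(abs(msh$nodes[, 1] - a / 1000) < 1e-12),
       outer = which(abs(msh$nodes[, 1] - b / 1000) < 1e-12))
}

test_that("annulus potential matches the closed form to < 0.5%", {
  an <- annulus_fem()
  pf <- solve_potential(an$fem, sigma = rep(0.5, an$fem$m),
                        electrode_voltage = 10,
                        electrode_nodes = an$inner, outer_nodes = an$outer)
  ora <- annulus_potential_oracle(1e-3, 20e-3, V0 = 10, sigma = 0.5, L = 10e-3)
  r <- an$msh$nodes[, 1]
  expect_lt(max(abs(pf$V - ora$potential(r))), 0.005 * 10)
  ## delivered power against the analytic conductance, within 1%
  expect_equal(delivered_power(an$fem, pf), ora$power, tolerance = 0.01)
  ## boundary current x voltage equals the volume integral of Q_RF
  K <- assemble_conductivity_system(an$fem, rep(0.5, an$fem$m))
  I_in <- sum((K %*% pf$V)[an$inner])
  expect_equal(10 * I_in, delivered_power(an$fem, pf), tolerance = 0.01)
})

test_that("annulus error decreases at the expected second-order rate", {
  errs <- sapply(c(20, 40, 80), function(nr) {
    an <- annulus_fem(nr = nr)
    pf <- solve_potential(an$fem, sigma = rep(1, an$fem$m),
                          electrode_voltage = 1,
                          electrode_nodes = an$inner, outer_nodes = an$outer)
    ora <- annulus_potential_oracle(1e-3, 20e-3)
    max(abs(pf$V - ora$potential(an$msh$nodes[, 1])))
  })
  ## roughly quartered per halving of h
  expect_gt(errs[1] / errs[2], 3)
  expect_gt(errs[2] / errs[3], 3)
})

test_that("potential obeys linearity, scaling invariance and the maximum principle", {
  m <- coarse_mesh("a")
  fem <- fem_setup(m)
  pf1 <- solve_potential(fem, electrode_voltage = 20)
  pf2 <- solve_potential(fem, electrode_voltage = 40)
  expect_equal(2 * pf1$V, pf2$V, tolerance = 1e-9)
  expect_equal(4 * pf1$Q_RF, pf2$Q_RF, tolerance = 1e-9)
  ## discrete maximum principle
  expect_true(all(pf1$V >= -1e-9 & pf1$V <= 20 + 1e-9))
  expect_true(all(pf1$Q_RF >= 0))
  expect_gt(delivered_power(fem, pf1), 0)
  ## conductivity scaling leaves the potential unchanged
  sig <- element_property(fem, rep(37, fem$n), "sigma")
  pf3 <- solve_potential(fem, sigma = 3 * sig, electrode_voltage = 20)
  expect_equal(pf1$V, pf3$V, tolerance = 1e-8)
  ## zero boundary data
  pf0 <- solve_potential(fem, electrode_voltage = 0)
  expect_identical(max(abs(pf0$V)), 0)
  expect_identical(max(pf0$Q_RF), 0)
})

test_that("assembled system is symmetric and rejects bad conductivities", {
  m <- coarse_mesh("a")
  fem <- fem_setup(m)
  sig <- element_property(fem, rep(37, fem$n), "sigma")
  K <- assemble_conductivity_system(fem, sig)
  expect_equal(Matrix::norm(K - Matrix::t(K), "I"), 0)
  expect_error(assemble_conductivity_system(fem, -sig), "negative")
  sig0 <- sig; sig0[which(!fem$is_electrode)[1]] <- 0
  expect_error(assemble_conductivity_system(fem, sig0), "non-positive")
})

test_that("Joule heating follows sigma E^2 with the element gradient", {
  ## uniform axial field on a rectangle: V linear in z
  msh <- structured_mesh(seq(1, 5, length.out = 5), seq(0, 10, length.out = 11))
  fem <- fem_setup(msh)
  V <- 7 * msh$nodes[, 2] / 0.010            # 7 V over 10 mm -> 700 V/m
  q <- joule_heating(fem, V, rep(0.22, fem$m))
  expect_equal(unname(attr(q, "E_mag")), rep(700, fem$m), tolerance = 1e-9)
  expect_equal(as.numeric(q), rep(0.22 * 700^2, fem$m), tolerance = 1e-9)
  ## constant potential: no heating
  expect_equal(max(abs(joule_heating(fem, rep(3, fem$n), rep(1, fem$m)))), 0)
})
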