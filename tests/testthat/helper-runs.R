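# Shared scaled-down simulation runs, memoised across test files so the
# behavioural suites (controller regulation, radius orderings, profile
# shapes, early/late growth) reuse the same closed-loop solutions.

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, ...) {
  if (is.null(.run_cache[[key]])) {
    cfg <- simulation_config(...)
    .run_cache[[key]] <- run_simulation(cfg)
  }
  .run_cache[[key]]
}

# standard scaled study runs: coarse mesh, 0.5 s step, 240 s heat + 120 s
# cooldown; long enough for the controller to settle and the cell-death
# radius to clear the nidus
study_run <- function(scenario, control_temp) {
  cached_run(paste0("study_", scenario, "_", control_temp),
             scenario = scenario, control_temp = control_temp,
             heat_time = 240, cool_time = 120,
             resolution = "coarse", dt_heat = 0.5)
}

coarse_mesh <- function(scenario = "a") {
  key <- paste0("mesh_", scenario)
  if (is.null(.run_cache[[key]]))
    .run_cache[[key]] <- generate_mesh(build_scenario(scenario), "coarse")
  .run_cache[[key]]
}

# Fundamental conduction eigenmode on a homogeneous cylinder (R = L = 20 mm,
# rim clamped): numeric decay constant from the implicit solver vs the
# Bessel-zero closed form. Memoised: shared between the thermal unit test
# and the acceptance property suite.
eigenmode_decay <- function() {
  if (!is.null(.run_cache$eigenmode)) return(.run_cache$eigenmode)
  R <- 0.020; L <- 0.020
  msh <- structured_mesh(seq(0, 20, by = 0.5), seq(0, 20, by = 0.5))
  msh$outer_nodes <- which(abs(msh$nodes[, 1] - R) < 1e-12 |
                           abs(msh$nodes[, 2]) < 1e-12 |
                           abs(msh$nodes[, 2] - L) < 1e-12)
  reg <- tissue_registry(list(muscle = list(perfusion = 0)))
  cst <- model_constants(d_k_abs = 0)   # constant-coefficient conduction
  fem <- fem_setup(msh, reg, cst)
  k <- reg$thermal_conductivity[reg$tissue == "muscle"]
  rhoc <- reg$density[reg$tissue == "muscle"] *
    reg$specific_heat[reg$tissue == "muscle"]
  ora <- conduction_eigenmode_oracle(R, L, alpha = k / rhoc)
  st <- thermal_state(fem)
  st$T <- 37 + 5 * ora$mode(msh$nodes[, 1], msh$nodes[, 2])
  centre <- which.min((msh$nodes[, 1])^2 + (msh$nodes[, 2] - L / 2)^2)
  dt <- 0.2; nsteps <- 150
  amp0 <- st$T[centre] - 37
  for (i in seq_len(nsteps))
    st <- step_temperature(fem, st, numeric(fem$m), dt = dt,
                           picard_tol = 1e-6)
  out <- c(numeric_lambda = -log((st$T[centre] - 37) / amp0) / (nsteps * dt),
           analytic_lambda = ora$lambda)
  .run_cache$eigenmode <- out
  out
}
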