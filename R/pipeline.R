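## Closed-loop simulation pipeline: scenario -> mesh -> per-step controller
## update -> electric solve with sigma(T) -> implicit thermal step -> damage
## integration -> cell-death radius extraction, followed by a voltage-off
## cooldown with continued thermal and damage stepping. Fully deterministic
## for a fixed configuration.

#' Simulation configuration
#'
#' Collects every knob of a closed-loop ablation run. Defaults follow the
#' study protocol: control temperatures in {70, 80, 90} degrees C, 15 min
#' (900 s) of active heating, 5 min (300 s) of cooldown, 0.25 s controller
#' and thermal step during heating, 1 s during cooldown, output every 5 s.
#'
#' @param scenario One of `"a"`, `"b"`, `"c"`, `"validation"`.
#' @param control_temp Tip target temperature (degrees C), must be below
#'   the vaporization point (100).
#' @param heat_time,cool_time Phase durations (s); `heat_time = 0` gives a
#'   cooldown-only run.
#' @param resolution Mesh resolution level (see [generate_mesh()]).
#' @param dt_heat,dt_cool Time steps (s) for the two phases.
#' @param overrides Tissue-property overrides, e.g.
#'   `list(nidus = list(sigma = 0.5))`.
#' @param geometry_overrides Geometry parameter overrides (mm).
#' @param body_temp Initial, boundary and blood temperature (degrees C);
#'   37 by default, 35 for the validation layout.
#' @param Kp,Ki PI controller gains (V/K, V/K/s).
#' @param output_every Output cadence for radii and traces (s).
#' @param profile_time Heating-phase time (s) at which an early field
#'   snapshot is stored for profile extraction.
#' @param seed Integer recorded in the provenance; the model is
#'   deterministic, so the seed does not alter results.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(scenario, control_temp = 90, heat_time = 900,
                              cool_time = 300, resolution = "fine",
                              dt_heat = 0.25, dt_cool = 1,
                              overrides = list(), geometry_overrides = list(),
                              body_temp = if (scenario == "validation") 35 else 37,
                              Kp = 1.15, Ki = 0.06, output_every = 5,
                              profile_time = 30, seed = 1L) {
  if (control_temp >= 100)
    stop("control_temp must be below the vaporization point (100 C)")
  if (heat_time < 0 || cool_time < 0) stop("phase durations must be >= 0")
  if (heat_time + cool_time <= 0) stop("nothing to simulate")
  if (dt_heat <= 0 || dt_cool <= 0) stop("time steps must be positive")
  ## fail early on bad overrides so grid runs report the offending cell
  invisible(tissue_registry(overrides))
  structure(list(scenario = scenario, control_temp = control_temp,
                 heat_time = heat_time, cool_time = cool_time,
                 resolution = resolution, dt_heat = dt_heat,
                 dt_cool = dt_cool, overrides = overrides,
                 geometry_overrides = geometry_overrides,
                 body_temp = body_temp, Kp = Kp, Ki = Ki,
                 output_every = output_every, profile_time = profile_time,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Run a closed-loop ablation simulation
#'
#' Executes the full coupled electric-thermal-damage simulation defined by
#' a [simulation_config()]: per heating step the controller reads the tip
#' temperature and sets the electrode r.m.s. voltage, the quasi-static
#' potential is re-solved with the current sigma(T), one implicit bioheat
#' step is taken, and the Arrhenius damage and per-element perfusion mask
#' are updated; the electrode is then switched off and the model cools
#' down with damage still accruing.
#'
#' @param config A [simulation_config()].
#' @param mesh Optionally a pre-built mesh (to share meshes across runs);
#'   must match the config's scenario and resolution.
#' @param verbose Print a one-line summary when done.
#' @return Object of class `ablation_result`: output-cadence series of
#'   voltage, tip/maximum temperature and perpendicular/parallel cell-death
#'   radii; the per-step controller trace; final temperature and damage
#'   fields; snapshots for profile extraction; probe traces (validation
#'   layout); configuration echo and provenance.
#' @export
run_simulation <- function(config, mesh = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  registry <- tissue_registry(config$overrides)
  constants <- model_constants(body_temp_C = config$body_temp)
  geometry <- build_scenario(config$scenario, config$geometry_overrides)
  if (is.null(mesh)) mesh <- generate_mesh(geometry, config$resolution,
                                           seed = config$seed)
  fem <- fem_setup(mesh, registry, constants)
  ctrl <- pi_controller(config$control_temp, config$Kp, config$Ki)

  probe_nodes <- NULL
  if (!is.null(geometry$probe_points))
    probe_nodes <- probe_indices(mesh, geometry$probe_points)

  th_asm <- .make_assembler(fem, mesh$outer_nodes)
  em_fixed <- c(mesh$electrode_nodes,
                setdiff(mesh$outer_nodes, mesh$electrode_nodes))
  n_elec <- length(mesh$electrode_nodes)
  em_asm <- .make_assembler(fem, em_fixed)

  state <- thermal_state(fem, config$body_temp)
  T_extrap <- NULL
  omega <- numeric(fem$n)
  max_T_overall <- config$body_temp
  qrf <- numeric(fem$m)

  rec <- list(t = c(), V = c(), tip = c(), maxT = c(), rp = c(), rpar = c())
  step_trace <- list(t = c(), V = c(), tip = c())
  probe_T <- NULL
  if (!is.null(probe_nodes)) probe_T <- list()
  snapshots <- list()

  record <- function(t) {
    rec$t <<- c(rec$t, t)
    rec$V <<- c(rec$V, ctrl$V)
    rec$tip <<- c(rec$tip, tip_temperature(state, mesh))
    rec$maxT <<- c(rec$maxT, max(state$T))
    rec$rp <<- c(rec$rp, ablation_radius(omega, mesh, "perpendicular"))
    rec$rpar <<- c(rec$rpar, ablation_radius(omega, mesh, "parallel"))
    if (!is.null(probe_nodes))
      probe_T[[length(probe_T) + 1L]] <<- c(t, state$T[probe_nodes])
  }
  record(0)

  solve_em <- function(V0, T_nodal) {
    if (V0 <= 0) return(list(q = numeric(fem$m), sig = NULL))
    sig <- element_property(fem, T_nodal, "sigma")
    .asm_update(em_asm, fem, sig)
    vals <- c(rep(V0, n_elec), rep(0, length(em_fixed) - n_elec))
    rhs <- -as.numeric(em_asm$Kfc %*% vals)
    V <- numeric(fem$n)
    V[em_fixed] <- vals
    V[em_asm$free] <- .asm_solve(em_asm, rhs)
    list(q = as.numeric(joule_heating(fem, V, sig)), V = V, sig = sig)
  }

  advance <- function(duration, dt, heating) {
    if (duration <= 0) return(invisible())
    n <- max(1L, as.integer(round(duration / dt)))
    dt <- duration / n
    t0 <- state$t
    T_extrap <<- NULL  # step size changes between phases
    for (k in seq_len(n)) {
      tipT <- tip_temperature(state, mesh)
      if (heating) {
        ctrl <<- update_controller(ctrl, tipT, dt)
        em <- solve_em(ctrl$V, state$T)
        qrf <<- em$q
      } else {
        qrf <<- numeric(fem$m)
      }
      T_prev <- state$T
      ## linear extrapolation from the previous step as the Picard start:
      ## most steps then converge in a single solve
      guess <- if (is.null(T_extrap)) NULL else pmin(2 * state$T - T_extrap, 130)
      T_extrap <<- state$T
      state <<- step_temperature(fem, state, qrf, dt,
                                 boundary_temp = config$body_temp,
                                 assembler = th_asm, T_guess = guess)
      dmg <- integrate_damage(omega, state$alive, T_prev, state$T, dt, mesh)
      omega <<- dmg$omega
      state$alive <<- dmg$alive
      max_T_overall <<- max(max_T_overall, max(state$T))
      t_now <- t0 + k * dt
      state$t <<- t_now
      step_trace$t <<- c(step_trace$t, t_now)
      step_trace$V <<- c(step_trace$V, ctrl$V)
      step_trace$tip <<- c(step_trace$tip, tipT)
      near <- function(x) abs(t_now / x - round(t_now / x)) < 1e-9
      if (near(config$output_every) || k == n) record(t_now)
      if (heating && is.null(snapshots$early) &&
          t_now >= min(config$profile_time, duration) - 1e-9)
        snapshots$early <<- list(t = t_now, T = state$T, Q_RF = qrf)
    }
    invisible()
  }

  advance(config$heat_time, config$dt_heat, heating = TRUE)
  snapshots$end_heat <- list(t = state$t, T = state$T, Q_RF = qrf)
  ctrl <- cooldown_mode(ctrl)
  advance(config$cool_time, config$dt_cool, heating = FALSE)
  snapshots$end_cool <- list(t = state$t, T = state$T,
                             Q_RF = numeric(fem$m))

  if (!is.null(probe_T)) {
    probe_T <- do.call(rbind, probe_T)
    colnames(probe_T) <- c("time_s", paste0("probe_", seq_along(probe_nodes)))
  }

  out <- structure(list(
    times = rec$t, voltage = rec$V, tip_T = rec$tip, max_T = rec$maxT,
    r_perp = rec$rp, r_par = rec$rpar,
    step_trace = data.frame(time_s = step_trace$t, voltage_V = step_trace$V,
                            tip_temp_C = step_trace$tip),
    final_T = state$T, final_omega = omega, final_alive = state$alive,
    max_T_overall = max_T_overall,
    final_r_perp = rec$rp[length(rec$rp)],
    final_r_par = rec$rpar[length(rec$rpar)],
    probe_T = probe_T, probe_nodes = probe_nodes,
    snapshots = snapshots, mesh = mesh, fem = fem, config = config,
    provenance = list(
      package_version = as.character(utils::packageVersion("ooablate")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      n_nodes = mesh$n_nodes, n_tris = mesh$n_tris,
      h_near_electrode_mm = unname(mesh$h_params["h_near_electrode"]),
      seed = config$seed)
  ), class = "ablation_result")
  if (verbose)
    cat(sprintf("scenario %s @ %g C: r_perp %.2f mm, r_par %.2f mm, max T %.1f C\n",
                config$scenario, config$control_temp, out$final_r_perp,
                out$final_r_par, max_T_overall))
  out
}

#' @exportS3Method base::print
print.ablation_result <- function(x, ...) {
  cfg <- x$config
  cat("Ablation run: scenario '", cfg$scenario, "', ", cfg$control_temp,
      " C control, ", cfg$heat_time, " s heating + ", cfg$cool_time,
      " s cooldown\n", sep = "")
  cat("  mesh: ", x$provenance$n_nodes, " nodes (", cfg$resolution, ")\n",
      sep = "")
  cat(sprintf("  final cell-death radius: %.2f mm perpendicular, %.2f mm parallel\n",
              x$final_r_perp, x$final_r_par))
  cat(sprintf("  maximum temperature reached anywhere: %.1f C\n",
              x$max_T_overall))
  invisible(x)
}

#' Scenario x control-temperature study
#'
#' Runs the full grid of scenarios and control temperatures and collects
#' the cell-death radius time series in tidy form. Failures are isolated
#' per grid cell.
#'
#' @param scenarios Character vector of scenario ids.
#' @param temperatures Control temperatures (degrees C).
#' @param heat_time,cool_time Phase durations (s).
#' @param ... Further arguments to [simulation_config()].
#' @return List with `radii` (tidy data.frame: scenario, control_temp,
#'   time_s, direction, radius_mm), `results` (named list of
#'   `ablation_result`s) and `failures`.
#' @export
run_temperature_time_grid <- function(scenarios = c("a", "b", "c"),
                                      temperatures = c(70, 80, 90),
                                      heat_time = 900, cool_time = 300, ...) {
  stopifnot(length(scenarios) > 0, length(temperatures) > 0)
  results <- list(); failures <- list(); rows <- list()
  meshes <- list()
  for (sc in scenarios) for (tc in temperatures) {
    key <- paste0(sc, "_", tc)
    res <- tryCatch({
      cfg <- simulation_config(sc, control_temp = tc, heat_time = heat_time,
                               cool_time = cool_time, ...)
      if (is.null(meshes[[sc]]))
        meshes[[sc]] <- generate_mesh(
          build_scenario(sc, cfg$geometry_overrides), cfg$resolution,
          seed = cfg$seed)
      run_simulation(cfg, mesh = meshes[[sc]])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[key]] <- conditionMessage(res)
      next
    }
    results[[key]] <- res
    rows[[key]] <- data.frame(
      scenario = sc, control_temp = tc,
      time_s = rep(res$times, 2),
      direction = rep(c("perpendicular", "parallel"), each = length(res$times)),
      radius_mm = c(res$r_perp, res$r_par))
  }
  list(radii = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       results = results, failures = failures)
}

#' Nidus-property sensitivity study
#'
#' Re-runs a configuration over combinations of nidus electrical
#' conductivity and blood-perfusion coefficient and reports the percent
#' change of the final cell-death radii against the baseline tissue table.
#'
#' @param config Baseline [simulation_config()] (its own nidus overrides,
#'   if any, are replaced by the sweep values).
#' @param sigma_values Nidus conductivities (S/m) to test.
#' @param omega_values Nidus perfusion coefficients (1/s) to test.
#' @return data.frame with one row per combination: radii and percent
#'   changes relative to the baseline (sigma = 0.22 S/m,
#'   omega = 48e-4 1/s).
#' @export
run_sensitivity <- function(config,
                            sigma_values = c(0.08, 0.22, 0.5),
                            omega_values = c(26e-4, 48e-4, 70e-4)) {
  base <- tissue_registry()
  s0 <- base$sigma[base$tissue == "nidus"]
  w0 <- base$perfusion[base$tissue == "nidus"]
  grid <- expand.grid(sigma = sigma_values, omega = omega_values)
  mesh <- generate_mesh(build_scenario(config$scenario,
                                       config$geometry_overrides),
                        config$resolution, seed = config$seed)
  run1 <- function(sig, om) {
    cfg <- config
    cfg$overrides$nidus <- list(sigma = sig, perfusion = om)
    run_simulation(cfg, mesh = mesh)
  }
  ## baseline must be part of the comparison even if not in the grid
  if (!any(grid$sigma == s0 & grid$omega == w0))
    grid <- rbind(data.frame(sigma = s0, omega = w0), grid)
  out <- vector("list", nrow(grid))
  rb_perp <- rb_par <- NA_real_
  for (k in order(!(grid$sigma == s0 & grid$omega == w0))) {
    res <- run1(grid$sigma[k], grid$omega[k])
    if (grid$sigma[k] == s0 && grid$omega[k] == w0) {
      rb_perp <- res$final_r_perp; rb_par <- res$final_r_par
    }
    out[[k]] <- data.frame(
      sigma = grid$sigma[k], omega = grid$omega[k],
      r_perp_mm = res$final_r_perp, r_par_mm = res$final_r_par)
  }
  out <- do.call(rbind, out)
  out$pct_change_perp <- 100 * (out$r_perp_mm - rb_perp) / rb_perp
  out$pct_change_par <- 100 * (out$r_par_mm - rb_par) / rb_par
  out$baseline <- out$sigma == s0 & out$omega == w0
  out
}

#' Mesh-convergence study
#'
#' Runs the same configuration across the resolution ladder and reports
#' the relative change of the final cell-death radii between successive
#' levels; converged when the change between the two finest levels is
#' below 1%.
#'
#' @param config A [simulation_config()] (its `resolution` is ignored).
#' @param levels Ladder levels, coarsest first; at least two.
#' @return data.frame (level, nodes, radii, successive relative changes in
#'   percent) with attribute `converged`.
#' @export
mesh_convergence_study <- function(config,
                                   levels = c("coarse", "medium", "fine",
                                              "finest")) {
  if (length(levels) < 2L)
    stop("the resolution ladder needs at least two levels")
  rows <- vector("list", length(levels))
  for (k in seq_along(levels)) {
    cfg <- config
    cfg$resolution <- levels[k]
    res <- run_simulation(cfg)
    rows[[k]] <- data.frame(level = levels[k],
                            nodes = res$provenance$n_nodes,
                            r_perp_mm = res$final_r_perp,
                            r_par_mm = res$final_r_par)
  }
  out <- do.call(rbind, rows)
  out$rel_change_perp_pct <- c(NA, abs(diff(out$r_perp_mm)) /
                                 out$r_perp_mm[-1] * 100)
  out$rel_change_par_pct <- c(NA, abs(diff(out$r_par_mm)) /
                                out$r_par_mm[-1] * 100)
  attr(out, "converged") <- out$rel_change_perp_pct[nrow(out)] < 1
  out
}

#' Resistive-heating and temperature line profiles
#'
#' Samples the Joule source and the temperature along a ray from the
#' centre of the electrode, at the early snapshot time and at the end of
#' heating, and locates the local maxima of the resistive heating beyond
#' the electrode surface (the electrode-tissue peak and, where the
#' background is cortical bone, the secondary peak at the tumour-bone
#' interface).
#'
#' @param result An [run_simulation()] result (with stored snapshots).
#' @param ray `"perpendicular"` or `"parallel"`.
#' @return data.frame (s_mm, Q_RF_W_m3, T_early_C, T_end_C) with attribute
#'   `peaks`: positions (mm) of local Q_RF maxima in decreasing height
#'   order.
#' @export
extract_profiles <- function(result, ray = "perpendicular") {
  sn <- result$snapshots
  if (is.null(sn$end_heat) || is.null(sn$early))
    stop("result does not carry the required field snapshots")
  sampler <- .ray_sampler(result$mesh, ray)
  qr <- sn$end_heat$Q_RF[sampler$elem]
  prof <- data.frame(
    s_mm = sampler$s_mm,
    Q_RF_W_m3 = qr,
    T_early_C = .sample_nodal(sampler, sn$early$T),
    T_end_C = .sample_nodal(sampler, sn$end_heat$T))
  ## local maxima on the per-element plateaus beyond the electrode radius
  re <- result$mesh$geometry$electrode["radius"]
  run <- rle(sampler$elem)
  ends <- cumsum(run$lengths); starts <- ends - run$lengths + 1L
  mid <- (sampler$s_mm[starts] + sampler$s_mm[ends]) / 2
  val <- qr[starts]
  keep <- mid > re * 0.5
  mid <- mid[keep]; val <- val[keep]
  nb <- length(val)
  ispeak <- val > c(-Inf, val[-nb]) & val >= c(val[-1], -Inf)
  peaks <- data.frame(s_mm = mid[ispeak], Q_RF_W_m3 = val[ispeak])
  peaks <- peaks[order(-peaks$Q_RF_W_m3), , drop = FALSE]
  attr(prof, "peaks") <- peaks
  prof
}

#' Ex-vivo style validation run
#'
#' Replicates the validation protocol: the nidus sits behind a cortical
#' lamella, the specimen starts at 35 degrees C, and ablation runs for
#' 400 s with a 95-degree control temperature. Temperature traces at the
#' three probes (0, 5 and 10 mm from the periosteum in soft tissue) are
#' returned for qualitative comparison.
#'
#' @param lamella_mm Cortical lamella thickness (mm).
#' @param control_temp Control temperature (degrees C).
#' @param heat_time Heating duration (s).
#' @param ... Further arguments to [simulation_config()].
#' @return The `ablation_result`, whose `$probe_T` matrix holds the probe
#'   traces.
#' @export
run_validation_scenario <- function(lamella_mm = 3, control_temp = 95,
                                    heat_time = 400, ...) {
  cfg <- simulation_config("validation", control_temp = control_temp,
                           heat_time = heat_time, cool_time = 0,
                           geometry_overrides = list(
                             lamella_thickness = lamella_mm), ...)
  run_simulation(cfg)
}
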