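## Time integration of the bioheat equation in enthalpy form:
##   dh/dt = div(k(T) grad T) + Q_RF - Q_p
## One implicit (backward Euler) step with the apparent volumetric heat
## capacity as the mass coefficient, Picard iteration on the
## temperature-dependent coefficients, lumped mass/perfusion, Dirichlet
## body temperature on the outer boundary and a natural condition on the
## symmetry axis.

#' Initialize a thermal state
#'
#' @param fem A [fem_setup()] result.
#' @param T_init Uniform initial temperature (degrees C); defaults to the
#'   model's body temperature.
#' @return List of class `thermal_state` with nodal temperature `T`, clock
#'   `t` (s) and the per-element alive mask.
#' @export
thermal_state <- function(fem, T_init = fem$constants$body_temp) {
  structure(list(T = rep(T_init, fem$n), t = 0,
                 alive = rep(TRUE, fem$m)), class = "thermal_state")
}

#' One implicit step of the enthalpy bioheat equation
#'
#' Advances the nodal temperature by `dt` seconds under the given Joule
#' source and per-element alive mask. Nonlinearity (apparent heat capacity,
#' thermal conductivity) is resolved by Picard iteration at the element
#' mean temperature; the perfusion sink uses lumped weights and contributes
#' exactly zero on dead or non-perfused elements.
#'
#' @param fem A [fem_setup()] result.
#' @param state A [thermal_state()].
#' @param Q_RF Per-element heat source (W/m^3); zero inside the electrode.
#' @param dt Time step (s), > 0.
#' @param alive Per-element alive mask; defaults to the state's mask.
#' @param boundary_temp Dirichlet temperature on the outer boundary
#'   (degrees C); defaults to body temperature.
#' @param picard_tol Convergence tolerance on max |dT| between Picard
#'   iterates (degrees C).
#' @param max_picard Maximum Picard iterations.
#' @param assembler Internal assembler cache (created on first use when a
#'   persistent environment is supplied via `attr(state, "asm")`); `NULL`
#'   rebuilds from scratch.
#' @param diagnostics If `TRUE`, attach the discrete energy-balance terms
#'   (enthalpy change, source, sink and boundary-flux integrals in joules)
#'   as attribute `energy`.
#' @return Updated `thermal_state`.
#' @export
step_temperature <- function(fem, state, Q_RF, dt, alive = state$alive,
                             boundary_temp = fem$constants$body_temp,
                             picard_tol = 1e-3, max_picard = 5L,
                             assembler = NULL, diagnostics = FALSE,
                             T_guess = NULL) {
  if (dt <= 0) stop("dt must be positive")
  stopifnot(length(Q_RF) == fem$m)
  mesh <- fem$mesh
  fixed <- mesh$outer_nodes
  ## reuse the assembler cached on the state during sequential stepping
  if (is.null(assembler)) assembler <- attr(state, "assembler")
  if (is.null(assembler) || !identical(assembler$fixed, fixed))
    assembler <- .make_assembler(fem, fixed)
  free <- assembler$free
  cst <- fem$constants

  T_old <- state$T
  F_src <- .lump_nodal(fem, Q_RF)
  perf_coef <- fem$wperf * cst$rho_blood * cst$c_blood * as.numeric(alive)

  ## initial Picard iterate: caller-provided extrapolation if available
  T_new <- if (is.null(T_guess)) T_old else T_guess
  err_prev <- Inf
  iters <- 0L
  for (it in seq_len(max_picard)) {
    iters <- it
    k_e <- element_property(fem, T_new, "k")
    c_e <- element_property(fem, T_new, "capacity")
    Cd <- .lump_nodal(fem, c_e)
    Pd <- .lump_nodal(fem, perf_coef)
    .asm_update(assembler, fem, k_e,
                diag_add = Cd[free] / dt + Pd[free])
    rhs <- Cd[free] / dt * T_old[free] + F_src[free] +
      Pd[free] * cst$T_blood -
      as.numeric(assembler$Kfc %*% rep(boundary_temp, length(fixed)))
    T_prev <- T_new
    T_new <- T_old
    T_new[fixed] <- boundary_temp
    T_new[free] <- .asm_solve(assembler, rhs)
    if (!all(is.finite(T_new)))
      stop("non-finite temperature at t = ", state$t, " s")
    err <- max(abs(T_new - T_prev))
    if (err < picard_tol) break
    if (err > 10 * err_prev + picard_tol)
      stop("Picard iteration diverging at t = ", state$t,
           " s (dT = ", signif(err, 3), " C)")
    err_prev <- err
  }

  out <- structure(list(T = T_new, t = state$t + dt, alive = alive),
                   class = "thermal_state")
  attr(out, "picard_iterations") <- iters

  if (diagnostics) {
    ## independent evaluation of each energy term over the step
    h_old <- .enthalpy_T(fem$rho, fem$cp, fem$Cw, .elem_T(fem, T_old), cst)
    h_new <- .enthalpy_T(fem$rho, fem$cp, fem$Cw, .elem_T(fem, T_new), cst)
    dH <- sum((h_new - h_old) * fem$volume)
    E_src <- dt * sum(Q_RF * fem$volume)
    Qp_e <- perf_coef * (.elem_T(fem, T_new) - cst$T_blood)
    E_sink <- dt * sum(Qp_e * fem$volume)
    ## boundary conduction flux: residual of the full discrete operator at
    ## the Dirichlet rows
    K_full <- assemble_stiffness(fem, element_property(fem, T_new, "k"))
    Cd <- .lump_nodal(fem, element_property(fem, T_new, "capacity"))
    Pd <- .lump_nodal(fem, perf_coef)
    res <- Cd / dt * (T_new - T_old) +
      as.numeric(K_full %*% T_new) + Pd * (T_new - cst$T_blood) - F_src
    E_flux <- dt * sum(res[fixed])
    attr(out, "energy") <- c(enthalpy_change = dH, source = E_src,
                             sink = E_sink, boundary_flux = E_flux)
  }
  out
}

#' Electrode tip temperature
#'
#' Temperature at the designated sensor node: the node at the distal apex
#' of the active tip on the symmetry axis (the thermocouple position of a
#' non-cooled temperature-controlled electrode).
#'
#' @param state A [thermal_state()] (or a bare nodal temperature vector).
#' @param mesh The mesh that defines the sensor node.
#' @return Temperature in degrees C.
#' @export
tip_temperature <- function(state, mesh) {
  T <- if (inherits(state, "thermal_state")) state$T else state
  T[mesh$tip_sensor]
}
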