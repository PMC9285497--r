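## Independent closed-form / fine-discretization references used to certify
## the solver numerics. These share no code with the FEM or damage paths
## they check.

#' Annulus potential oracle
#'
#' Closed form for the potential between concentric cylinders (inner radius
#' `a` at `V0`, outer radius `b` grounded, flux-free axial ends):
#' `V(r) = V0 ln(b/r) / ln(b/a)`, with per-unit-length conductance
#' `G = 2 pi sigma L / ln(b/a)`.
#'
#' @param a,b Inner and outer radii (m), `0 < a < b`.
#' @param V0 Applied voltage (V).
#' @param sigma Conductivity (S/m).
#' @param L Axial length (m).
#' @return List with `potential(r)` function, `conductance` (S) and
#'   `power` (W) for the given voltage.
#' @export
annulus_potential_oracle <- function(a, b, V0 = 1, sigma = 1, L = 1) {
  if (a <= 0 || a >= b) stop("need 0 < a < b")
  G <- 2 * pi * sigma * L / log(b / a)
  list(potential = function(r) V0 * log(b / r) / log(b / a),
       conductance = G,
       power = G * V0^2)
}

#' Conduction eigenmode oracle
#'
#' Fundamental decay constant of pure conduction in a homogeneous cylinder
#' of radius `R` and length `L` with zero boundary data: the product mode
#' `J0(j01 r / R) sin(pi z / L)` decays as `exp(-lambda t)` with
#' `lambda = alpha (j01^2 / R^2 + pi^2 / L^2)`, `alpha = k / (rho c)` and
#' `j01` the first zero of the Bessel function J0 (located here by root
#' bracketing of [base::besselJ()], an independent route).
#'
#' @param R Cylinder radius (m).
#' @param L Cylinder length (m); `Inf` gives the purely radial mode.
#' @param alpha Thermal diffusivity (m^2/s).
#' @return List with `lambda` (1/s), `j01`, and the `mode(r, z)` shape.
#' @export
conduction_eigenmode_oracle <- function(R, L = Inf, alpha) {
  j01 <- stats::uniroot(function(x) besselJ(x, 0), c(2, 3),
                        tol = 1e-12)$root
  lam <- alpha * (j01^2 / R^2 + if (is.finite(L)) pi^2 / L^2 else 0)
  list(lambda = lam, j01 = j01,
       mode = function(r, z = NULL) {
         m <- besselJ(j01 * r / R, 0)
         if (is.finite(L) && !is.null(z)) m <- m * sin(pi * z / L)
         m
       })
}

#' Radial finite-difference decay reference
#'
#' Independent 1-D radial finite-difference estimate of the fundamental
#' conduction decay constant in a disc (zero Dirichlet rim), used to
#' cross-check the Bessel-zero eigenvalue: implicit stepping of
#' `u_t = alpha (u_rr + u_r / r)` on a fine radial grid, with the decay
#' rate read off from successive step ratios after burn-in.
#'
#' @param R Disc radius (m).
#' @param alpha Diffusivity (m^2/s).
#' @param nr Radial grid points.
#' @param dt Time step (s).
#' @param nsteps Steps to integrate.
#' @return Estimated decay constant (1/s).
#' @export
radial_fd_decay <- function(R, alpha, nr = 400, dt = NULL, nsteps = 60) {
  r <- seq(0, R, length.out = nr)
  h <- r[2] - r[1]
  if (is.null(dt)) dt <- 0.002 * R^2 / alpha / nsteps
  ## implicit Laplacian with the r=0 symmetry condition (u_rr term doubled)
  main <- rep(1 + 2 * alpha * dt / h^2, nr)
  lower <- upper <- rep(-alpha * dt / h^2, nr - 1)
  ri <- r[2:(nr - 1)]
  upper[2:(nr - 1)] <- -alpha * dt / h^2 * (1 + h / (2 * ri))
  lower[1:(nr - 2)] <- -alpha * dt / h^2 * (1 - h / (2 * ri))
  upper[1] <- -2 * alpha * dt / h^2
  Amat <- diag(main)
  Amat[cbind(1:(nr - 1), 2:nr)] <- upper
  Amat[cbind(2:nr, 1:(nr - 1))] <- lower
  Amat[nr, ] <- 0; Amat[nr, nr] <- 1  # Dirichlet rim
  u <- 1 - (r / R)^2                   # smooth start, rim-compatible
  u[nr] <- 0
  ratios <- numeric(nsteps)
  for (k in seq_len(nsteps)) {
    u_new <- solve(Amat, u)
    ratios[k] <- u_new[1] / u[1]
    u <- u_new
  }
  ## after burn-in only the fundamental mode remains
  -log(mean(ratios[(nsteps %/% 2):nsteps])) / dt
}

#' Fine-quadrature Arrhenius damage reference
#'
#' Direct rectangle-rule integration of the damage integral over a
#' piecewise-linear temperature trace at a fine internal resolution, with
#' the rate evaluated as the direct product `A * exp(-dE/(R T))` (a route
#' independent of the solver's log-space evaluation; both are exact to
#' double precision in the physiological range).
#'
#' @param times Trace times (s), increasing from 0.
#' @param T_celsius Temperatures at `times` (degrees C).
#' @param dt_fine Quadrature step (s).
#' @param constants An [arrhenius_constants()] list.
#' @return Total damage Omega.
#' @export
arrhenius_quadrature_oracle <- function(times, T_celsius, dt_fine = 0.01,
                                        constants = arrhenius_constants()) {
  stopifnot(length(times) == length(T_celsius), !is.unsorted(times))
  tq <- seq(times[1], times[length(times)], by = dt_fine)
  Tq <- stats::approx(times, T_celsius, xout = tq, ties = "ordered")$y
  Tk <- (Tq[-1] + Tq[-length(Tq)]) / 2 + 273.15
  rate <- constants$A * exp(-constants$dE / (constants$R * Tk))
  sum(rate * diff(tq))
}
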