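## Quasi-static electric problem: div(sigma(T) grad V) = 0 on the
## axisymmetric mesh, Dirichlet r.m.s. voltage on the electrode surface
## (enforced on every metal node; the metal itself is excluded from the
## weak form), zero voltage on the outer boundary (grounding pad), natural
## zero-flux condition on the symmetry axis.

#' Assemble the conductivity system
#'
#' Axisymmetric weak form of the quasi-static potential equation with
#' per-element electrical conductivity. Symmetric positive semidefinite;
#' the symmetry axis needs no explicit constraint.
#'
#' @param fem A [fem_setup()] result.
#' @param sigma Per-element conductivity (S/m); must be nonnegative, with
#'   zeros only on electrode-metal elements (excluded from the solve).
#' @return Sparse symmetric matrix.
#' @export
assemble_conductivity_system <- function(fem, sigma) {
  if (any(sigma < 0)) stop("negative electrical conductivity")
  if (any(sigma[!fem$is_electrode] <= 0))
    stop("non-positive conductivity on a tissue element")
  assemble_stiffness(fem, sigma)
}

#' Solve the electric potential
#'
#' Applies the Dirichlet data (applied r.m.s. voltage on the electrode node
#' set, reference voltage on the outer boundary) and solves the reduced
#' symmetric system by sparse Cholesky. Also evaluates the element electric
#' field magnitude and the Joule heat source Q_RF = sigma |grad V|^2.
#'
#' @param fem A [fem_setup()] result.
#' @param sigma Per-element conductivity (S/m); defaults to the baseline
#'   37-degree values.
#' @param electrode_voltage Applied r.m.s. voltage (V), >= 0.
#' @param outer_voltage Grounding-pad voltage (V), default 0.
#' @param electrode_nodes,outer_nodes Dirichlet node sets; default to the
#'   mesh's electrode-metal and outer-boundary node sets (overridable for
#'   oracle problems on custom meshes).
#' @return Object of class `potential_field`: nodal `V`, per-element
#'   `E_mag` and `Q_RF`, and the applied voltage.
#' @export
solve_potential <- function(fem, sigma = NULL, electrode_voltage,
                            outer_voltage = 0,
                            electrode_nodes = fem$mesh$electrode_nodes,
                            outer_nodes = fem$mesh$outer_nodes) {
  if (electrode_voltage < 0) stop("electrode_voltage must be >= 0")
  if (is.null(sigma)) {
    sigma <- fem$sigma0
    sigma[fem$is_electrode] <- 0
  }
  n <- fem$n
  fixed <- c(electrode_nodes, setdiff(outer_nodes, electrode_nodes))
  if (!length(electrode_nodes) || !length(outer_nodes))
    stop("both Dirichlet sets (electrode, outer boundary) must be nonempty")
  vals <- c(rep(electrode_voltage, length(electrode_nodes)),
            rep(outer_voltage, length(setdiff(outer_nodes, electrode_nodes))))
  K <- assemble_conductivity_system(fem, sigma)
  V <- numeric(n)
  V[fixed] <- vals
  free <- setdiff(seq_len(n), fixed)
  if (electrode_voltage == 0 && outer_voltage == 0) {
    ## zero boundary data: V identically zero
  } else {
    rhs <- -as.numeric(K[free, fixed, drop = FALSE] %*% vals)
    A <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
    V[free] <- as.numeric(Matrix::solve(A, rhs))
  }
  qe <- joule_heating(fem, V, sigma)
  structure(list(V = V, E_mag = attr(qe, "E_mag"), Q_RF = as.numeric(qe),
                 applied_voltage = electrode_voltage), class = "potential_field")
}

#' Joule heat source
#'
#' Q_RF = sigma |grad V|^2 per element, with the P1 element gradient.
#'
#' @param fem A [fem_setup()] result.
#' @param V Nodal potential (V r.m.s.).
#' @param sigma Per-element conductivity (S/m).
#' @return Per-element heat source (W/m^3) with the field magnitude (V/m)
#'   attached as attribute `E_mag`.
#' @export
joule_heating <- function(fem, V, sigma) {
  tris <- fem$mesh$tris
  v1 <- V[tris[, 1]]; v2 <- V[tris[, 2]]; v3 <- V[tris[, 3]]
  gr <- (fem$gb[, 1] * v1 + fem$gb[, 2] * v2 + fem$gb[, 3] * v3) / (2 * fem$area)
  gz <- (fem$gc[, 1] * v1 + fem$gc[, 2] * v2 + fem$gc[, 3] * v3) / (2 * fem$area)
  E <- sqrt(gr^2 + gz^2)
  q <- sigma * E^2
  attr(q, "E_mag") <- E
  q
}

#' Total delivered power
#'
#' Volume integral of the Joule source, `int Q_RF 2 pi r dA`, in watts.
#' Equals applied voltage times boundary current by the discrete energy
#' identity.
#'
#' @param fem A [fem_setup()] result.
#' @param field A `potential_field` (or a per-element Q_RF vector).
#' @return Power in W.
#' @export
delivered_power <- function(fem, field) {
  q <- if (inherits(field, "potential_field")) field$Q_RF else field
  sum(q * fem$volume)
}
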