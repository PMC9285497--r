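## Arrhenius cell-death model: cumulative damage
##   Omega(t) = int_0^t A exp(-dE / (R T(tau))) dtau
## with osteocyte kinetics A = 8.99e133 1/s, dE = 838 kJ/mol. A node is
## dead at Omega >= 4.6 (99% probability of cell death); a dead element's
## perfusion is exactly zero thereafter. Rates are evaluated in log space
## so the enormous frequency factor never enters intermediate arithmetic.

#' Arrhenius damage constants
#'
#' @param A Frequency factor (1/s).
#' @param dE Activation energy (J/mol).
#' @param threshold Damage threshold defining cell death.
#' @return Named list, including the precomputed log frequency factor.
#' @export
arrhenius_constants <- function(A = 8.99e133, dE = 838e3, threshold = 4.6) {
  list(A = A, dE = dE, threshold = threshold,
       logA = log(A), R = 8.314462618)
}

#' Arrhenius damage rate
#'
#' d Omega / dt = A exp(-dE / (R T)) at absolute temperature T, evaluated
#' as exp(log A - dE/(R T)). Strictly increasing in T.
#'
#' @param T_kelvin Absolute temperature(s) (K), > 0.
#' @param constants An [arrhenius_constants()] list.
#' @return Rate in 1/s.
#' @examples
#' arrhenius_rate(323.15)  # ~3.2e-2 /s at 50 degrees C
#' @export
arrhenius_rate <- function(T_kelvin, constants = arrhenius_constants()) {
  if (any(T_kelvin <= 0)) stop("non-physical absolute temperature <= 0 K")
  exp(constants$logA - constants$dE / (constants$R * T_kelvin))
}

#' Advance the damage field over one time step
#'
#' Adds `dt` times the Arrhenius rate at the trapezoidal mean of the
#' endpoint temperatures (converted to kelvin) to the nodal damage, and
#' updates the per-element alive mask: an element dies when its mean nodal
#' damage reaches the threshold, and death is one-way.
#'
#' @param omega Nodal damage (dimensionless, nonnegative).
#' @param alive Per-element alive mask.
#' @param T_old_C,T_new_C Nodal temperatures at the step endpoints
#'   (degrees C).
#' @param dt Time step (s), > 0.
#' @param mesh The mesh (for the element-node incidence).
#' @param constants An [arrhenius_constants()] list.
#' @return List with updated `omega` and `alive`.
#' @export
integrate_damage <- function(omega, alive, T_old_C, T_new_C, dt, mesh,
                             constants = arrhenius_constants()) {
  if (dt <= 0) stop("dt must be positive")
  Tbar <- (T_old_C + T_new_C) / 2 + 273.15
  omega <- omega + dt * arrhenius_rate(Tbar, constants)
  tris <- mesh$tris
  om_e <- (omega[tris[, 1]] + omega[tris[, 2]] + omega[tris[, 3]]) / 3
  alive <- alive & om_e < constants$threshold
  list(omega = omega, alive = alive)
}

#' Probability of cell death implied by a damage value
#'
#' First-order kinetics: P = 1 - exp(-Omega). The threshold Omega = 4.6
#' corresponds to 99% probability of cell death.
#'
#' @param omega Damage value(s), >= 0.
#' @return Death probability in `[0, 1]`.
#' @export
death_probability <- function(omega) {
  if (any(omega < 0)) stop("damage must be nonnegative")
  1 - exp(-omega)
}

## ---- ray sampling ------------------------------------------------------

## Precompute a sub-element sampler along a ray from the active-tip centre:
## sample positions every ds_mm with P1 interpolation weights (containing
## triangle + barycentric coordinates).
.ray_cache <- new.env(parent = emptyenv())

.ray_sampler <- function(mesh, direction = c("perpendicular", "parallel"),
                         ds_mm = 0.05) {
  direction <- match.arg(direction)
  key <- paste(direction, ds_mm, mesh$n_nodes, mesh$n_tris,
               signif(sum(mesh$nodes), 12), sep = "|")
  hit <- .ray_cache[[key]]
  if (!is.null(hit)) return(hit)

  rmax <- max(mesh$nodes[, 1]); zmax <- max(mesh$nodes[, 2])
  smax <- if (direction == "perpendicular") rmax else zmax
  s <- seq(0, smax * 1000 - 1e-6, by = ds_mm)  # mm
  pts <- if (direction == "perpendicular")
    cbind(s / 1000, 0) else cbind(0, s / 1000)

  tris <- mesh$tris; nodes <- mesh$nodes
  ## candidate triangles: bounding box straddles the ray line
  if (direction == "perpendicular") {
    zt <- matrix(nodes[tris, 2], nrow(tris))
    cand <- which(apply(zt, 1, min) <= 1e-12 & apply(zt, 1, max) >= -1e-12)
  } else {
    rt <- matrix(nodes[tris, 1], nrow(tris))
    cand <- which(apply(rt, 1, min) <= 1e-12)
  }
  elem <- integer(length(s)); w <- matrix(0, length(s), 3L)
  un <- seq_along(s)
  for (t in cand) {
    if (!length(un)) break
    v <- tris[t, ]
    x1 <- nodes[v[1], 1]; y1 <- nodes[v[1], 2]
    x2 <- nodes[v[2], 1]; y2 <- nodes[v[2], 2]
    x3 <- nodes[v[3], 1]; y3 <- nodes[v[3], 2]
    det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
    px <- pts[un, 1]; py <- pts[un, 2]
    l1 <- ((y2 - y3) * (px - x3) + (x3 - x2) * (py - y3)) / det
    l2 <- ((y3 - y1) * (px - x3) + (x1 - x3) * (py - y3)) / det
    l3 <- 1 - l1 - l2
    inside <- l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9
    if (any(inside)) {
      hitk <- un[inside]
      elem[hitk] <- t
      w[hitk, ] <- cbind(l1[inside], l2[inside], l3[inside])
      un <- un[!inside]
    }
  }
  ok <- elem > 0L
  sampler <- list(s_mm = s[ok], elem = elem[ok],
                  tris = tris[elem[ok], , drop = FALSE],
                  w = w[ok, , drop = FALSE], direction = direction)
  .ray_cache[[key]] <- sampler
  sampler
}

.sample_nodal <- function(sampler, field) {
  rowSums(sampler$w * cbind(field[sampler$tris[, 1]],
                            field[sampler$tris[, 2]],
                            field[sampler$tris[, 3]]))
}

#' Cell-death radius along a ray
#'
#' Distance from the centre of the electrode active tip to the farthest
#' point where the interpolated damage reaches the death threshold, along
#' the ray perpendicular (+r) or parallel (+z) to the electrode. The
#' nodal damage field is sampled at sub-element resolution and the
#' outermost threshold crossing is located by linear interpolation; zero
#' if the threshold is nowhere reached on the ray.
#'
#' @param omega Nodal damage field.
#' @param mesh The mesh carrying the field.
#' @param direction `"perpendicular"` or `"parallel"`.
#' @param threshold Damage threshold (default 4.6).
#' @param ds_mm Sampling resolution along the ray (mm).
#' @return Radius in millimetres.
#' @examples
#' # a synthetic cone-shaped field crossing 4.6 at 5 mm
#' @export
ablation_radius <- function(omega, mesh, direction = "perpendicular",
                            threshold = 4.6, ds_mm = 0.05) {
  sampler <- .ray_sampler(mesh, direction, ds_mm)
  vals <- .sample_nodal(sampler, omega)
  above <- vals >= threshold
  if (!any(above)) return(0)
  k <- max(which(above))
  if (k == length(vals)) return(sampler$s_mm[k])
  ## linear crossing between samples k (>= thr) and k+1 (< thr)
  s1 <- sampler$s_mm[k]; s2 <- sampler$s_mm[k + 1L]
  v1 <- vals[k]; v2 <- vals[k + 1L]
  s1 + (v1 - threshold) / (v1 - v2) * (s2 - s1)
}
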