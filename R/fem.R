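## Axisymmetric P1 finite-element plumbing shared by the electric and
## thermal solvers. Element integrals carry the 2*pi*r volume weight with
## one-point (centroid) quadrature for the stiffness and a row-sum lumped
## mass: int r phi_a dA = A (2 r_a + r_b + r_c) / 12.

#' Precompute finite-element structures for a mesh
#'
#' Computes per-element geometry (areas, centroid radii, P1 shape-function
#' gradients), the sparse-assembly index vectors, lumped volume weights and
#' per-element baseline tissue properties. The result backs both the
#' electric and the thermal solver.
#'
#' @param mesh An [generate_mesh()] result (or [structured_mesh()]).
#' @param registry A [tissue_registry()] (possibly with overrides).
#' @param constants A [model_constants()] list.
#' @return List of class `fem_model`.
#' @export
fem_setup <- function(mesh, registry = tissue_registry(),
                      constants = model_constants()) {
  tris <- mesh$tris
  r1 <- mesh$nodes[tris[, 1], 1]; z1 <- mesh$nodes[tris[, 1], 2]
  r2 <- mesh$nodes[tris[, 2], 1]; z2 <- mesh$nodes[tris[, 2], 2]
  r3 <- mesh$nodes[tris[, 3], 1]; z3 <- mesh$nodes[tris[, 3], 2]
  A <- 0.5 * ((r2 - r1) * (z3 - z1) - (r3 - r1) * (z2 - z1))
  stopifnot(all(A > 0))
  rbar <- (r1 + r2 + r3) / 3
  ## P1 gradient coefficients: grad phi_a = (b_a, c_a) / (2A)
  b <- cbind(z2 - z3, z3 - z1, z1 - z2)
  cc <- cbind(r3 - r2, r1 - r3, r2 - r1)

  ## stiffness in local pair order (a,b) column-major over 3x3
  pairs <- expand.grid(a = 1:3, b = 1:3)
  m <- nrow(tris)
  Kgeo <- matrix(0, m, 9L)
  for (k in 1:9) {
    a <- pairs$a[k]; bb <- pairs$b[k]
    Kgeo[, k] <- 2 * pi * rbar * (b[, a] * b[, bb] + cc[, a] * cc[, bb]) / (4 * A)
  }
  I9 <- tris[, pairs$a]; J9 <- tris[, pairs$b]  # m x 9 matrices

  ## lumped volume weights per local node (m^3)
  rloc <- cbind(r1, r2, r3)
  Wl <- 2 * pi * A * (2 * rloc + rloc[, c(2, 3, 1)] + rloc[, c(3, 1, 2)]) / 12

  ## aggregation operator scattering 3m element-node weights to the n nodes
  Lagg <- Matrix::sparseMatrix(i = as.vector(tris), j = seq_len(3L * m),
                               x = rep(1, 3L * m), dims = c(nrow(mesh$nodes), 3L * m))

  i <- .tissue_row(registry, mesh$region)
  fem <- list(
    Lagg = Lagg,
    mesh = mesh, registry = registry, constants = constants,
    n = nrow(mesh$nodes), m = m,
    area = A, rbar = rbar, gb = b, gc = cc,
    I9 = I9, J9 = J9, Kgeo = Kgeo, Wlump = Wl,
    sigma0 = registry$sigma[i], k0 = registry$thermal_conductivity[i],
    rho = registry$density[i], cp = registry$specific_heat[i],
    Cw = registry$water_fraction[i], wperf = registry$perfusion[i],
    is_electrode = mesh$region == "electrode",
    is_plastic = mesh$region == "plastic",
    volume = 2 * pi * rbar * A
  )
  class(fem) <- "fem_model"
  fem
}

## element mean nodal temperature
.elem_T <- function(fem, T_nodal) {
  (T_nodal[fem$mesh$tris[, 1]] + T_nodal[fem$mesh$tris[, 2]] +
   T_nodal[fem$mesh$tris[, 3]]) / 3
}

#' Per-element temperature-dependent properties
#'
#' Evaluate electrical conductivity, thermal conductivity or apparent
#' volumetric heat capacity per element from the element-mean nodal
#' temperature. For `"sigma"` the electrode metal is excluded (coefficient
#' zero): metal nodes enter the electric problem as Dirichlet values.
#'
#' @param fem A [fem_setup()] result.
#' @param T_nodal Nodal temperature (degrees C).
#' @param what One of `"sigma"`, `"k"`, `"capacity"`.
#' @return Numeric vector, one value per element.
#' @export
element_property <- function(fem, T_nodal, what = c("sigma", "k", "capacity")) {
  what <- match.arg(what)
  Te <- .elem_T(fem, T_nodal)
  cst <- fem$constants
  switch(what,
    sigma = {
      s <- .sigma_T(fem$sigma0, Te, cst)
      s[fem$is_electrode] <- 0
      s
    },
    k = .k_T(fem$k0, Te, cst),
    capacity = .heat_capacity_T(fem$rho, fem$cp, fem$Cw, Te, cst))
}

## Assemble the full axisymmetric stiffness matrix sum_e coef_e * 2 pi rbar
## int grad phi_a . grad phi_b dA as a dgCMatrix.
#' Assemble an axisymmetric stiffness matrix
#'
#' Weak form of div(coef grad u) with 2*pi*r volume weighting; symmetric
#' positive semidefinite. Used with the per-element electrical conductivity
#' for the potential problem and with the thermal conductivity for heat
#' conduction.
#'
#' @param fem A [fem_setup()] result.
#' @param coef Per-element coefficient (length `fem$m`).
#' @return Sparse symmetric matrix (`dgCMatrix`).
#' @export
assemble_stiffness <- function(fem, coef) {
  stopifnot(length(coef) == fem$m)
  Matrix::sparseMatrix(i = as.vector(fem$I9), j = as.vector(fem$J9),
                       x = as.vector(fem$Kgeo * coef),
                       dims = c(fem$n, fem$n))
}

## nodal accumulation of per-element lumped weights times a coefficient
.lump_nodal <- function(fem, coef) {
  as.numeric(fem$Lagg %*% as.vector(fem$Wlump * coef))
}

## ---- fast pattern-reusing Dirichlet assembler -------------------------
## Precomputes the mapping from element triplets into the compressed slots
## of (i) the symmetric free-free block and (ii) the free-fixed coupling
## block, so per-step assembly is a single rowsum() plus slot assignment,
## and the CHOLMOD symbolic factorisation can be reused via update().
.make_assembler <- function(fem, fixed) {
  n <- fem$n
  free <- setdiff(seq_len(n), fixed)
  gmap <- integer(n); gmap[free] <- seq_along(free)       # global -> free idx
  fmap <- integer(n); fmap[fixed] <- seq_along(fixed)
  I <- as.vector(fem$I9); J <- as.vector(fem$J9)
  nf <- length(free)

  ff <- gmap[I] > 0L & gmap[J] > 0L & gmap[I] <= gmap[J]  # upper triangle
  key_ff <- (gmap[J[ff]] - 1) * nf + gmap[I[ff]]
  uk_ff <- sort(unique(key_ff))
  pos_ff <- match(key_ff, uk_ff)
  Kff <- Matrix::sparseMatrix(i = as.integer((uk_ff - 1) %% nf + 1),
                              j = as.integer((uk_ff - 1) %/% nf + 1),
                              x = rep(1, length(uk_ff)), dims = c(nf, nf),
                              symmetric = TRUE)
  diag_pos <- match((seq_len(nf) - 1) * nf + seq_len(nf), uk_ff)

  fc <- gmap[I] > 0L & fmap[J] > 0L
  key_fc <- (fmap[J[fc]] - 1) * nf + gmap[I[fc]]
  uk_fc <- sort(unique(key_fc))
  pos_fc <- match(key_fc, uk_fc)
  Kfc <- Matrix::sparseMatrix(i = as.integer((uk_fc - 1) %% nf + 1),
                              j = as.integer((uk_fc - 1) %/% nf + 1),
                              x = rep(1, length(uk_fc)),
                              dims = c(nf, length(fixed)))

  env <- new.env(parent = emptyenv())
  env$free <- free; env$fixed <- fixed; env$nf <- nf
  env$Kff <- Kff; env$Kfc <- Kfc
  env$sel_ff <- which(ff); env$pos_ff <- pos_ff
  env$sel_fc <- which(fc); env$pos_fc <- pos_fc
  env$diag_pos <- diag_pos
  ## aggregation operators: compressed-slot value <- sum of triplet values
  env$Aff <- Matrix::sparseMatrix(i = pos_ff, j = seq_along(pos_ff),
                                  x = rep(1, length(pos_ff)),
                                  dims = c(length(uk_ff), length(pos_ff)))
  env$Afc <- Matrix::sparseMatrix(i = pos_fc, j = seq_along(pos_fc),
                                  x = rep(1, length(pos_fc)),
                                  dims = c(length(uk_fc), length(pos_fc)))
  env$chol <- NULL
  env
}

## assemble the two blocks for a per-element coefficient; optionally add a
## nodal diagonal term (lumped capacity / perfusion)
.asm_update <- function(asm, fem, coef, diag_add = NULL) {
  vals <- as.vector(fem$Kgeo * coef)
  xff <- as.numeric(asm$Aff %*% vals[asm$sel_ff])
  if (!is.null(diag_add)) xff[asm$diag_pos] <- xff[asm$diag_pos] + diag_add
  asm$Kff@x <- xff
  asm$Kfc@x <- as.numeric(asm$Afc %*% vals[asm$sel_fc])
  invisible(asm)
}

## Solve Kff x = rhs to a relative residual of rtol. The Cholesky factor of
## a recent matrix with the same pattern is kept and reused as a
## preconditioner via iterative refinement (the coefficients drift slowly
## between time steps); the factor is refreshed only when refinement stalls.
.asm_solve <- function(asm, rhs_free, rtol = 1e-10) {
  bnorm <- sqrt(sum(rhs_free^2))
  if (bnorm == 0) return(numeric(length(rhs_free)))
  if (is.null(asm$chol)) {
    asm$chol <- Matrix::Cholesky(asm$Kff, LDL = FALSE)
    asm$fresh <- TRUE
  }
  x <- as.numeric(Matrix::solve(asm$chol, rhs_free, system = "A"))
  for (it in 1:6) {
    r <- rhs_free - as.numeric(asm$Kff %*% x)
    if (sqrt(sum(r^2)) <= rtol * bnorm) return(x)
    x <- x + as.numeric(Matrix::solve(asm$chol, r, system = "A"))
  }
  ## stale factor: refresh and solve directly
  asm$chol <- Matrix::update(asm$chol, asm$Kff)
  x <- as.numeric(Matrix::solve(asm$chol, rhs_free, system = "A"))
  r <- rhs_free - as.numeric(asm$Kff %*% x)
  x + as.numeric(Matrix::solve(asm$chol, r, system = "A"))
}

#' Build a plain structured triangular mesh on a rectangle
#'
#' Tensor-product triangulation of `[min(r), max(r)] x [min(z), max(z)]`
#' with a uniform tissue label; used by the closed-form oracle problems
#' (annulus potential, conduction eigenmode) and available for tests.
#'
#' @param r_mm,z_mm Grid lines in millimetres.
#' @param label Tissue label applied to every element.
#' @return A minimal `oo_mesh`-compatible object.
#' @export
structured_mesh <- function(r_mm, z_mm, label = "muscle") {
  rl <- sort(unique(r_mm)); zl <- sort(unique(z_mm))
  nr <- length(rl); nz <- length(zl)
  stopifnot(nr >= 2L, nz >= 2L, all(rl >= 0))
  nodes <- cbind(rep(rl, times = nz), rep(zl, each = nr)) / 1000
  id <- function(i, j) (j - 1L) * nr + i
  i <- rep(seq_len(nr - 1L), times = nz - 1L)
  j <- rep(seq_len(nz - 1L), each = nr - 1L)
  n1 <- id(i, j); n2 <- id(i + 1L, j); n3 <- id(i + 1L, j + 1L); n4 <- id(i, j + 1L)
  even <- (i + j) %% 2L == 0L
  tris <- rbind(
    cbind(n1[even], n2[even], n3[even]), cbind(n1[even], n3[even], n4[even]),
    cbind(n1[!even], n2[!even], n4[!even]), cbind(n2[!even], n3[!even], n4[!even]))
  structure(list(
    nodes = nodes, tris = tris, region = rep(label, nrow(tris)),
    areas = .tri_areas(nodes, tris),
    n_nodes = nrow(nodes), n_tris = nrow(tris),
    outer_nodes = integer(0), electrode_nodes = integer(0),
    axis_nodes = which(nodes[, 1] < 1e-12),
    tip_sensor = 1L, resolution_level = "custom",
    geometry = NULL
  ), class = "oo_mesh")
}
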