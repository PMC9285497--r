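## Graded triangular meshing of the scenario geometries.
##
## Strategy: a graded tensor-product grid in (r, z) whose lines contain every
## straight interface of the geometry exactly, split into triangles
## (union-jack diagonals), then made conforming to the circular
## nidus/sclerosis interfaces by snapping near-circle vertices onto the
## circle and chord-splitting the triangles the circle still crosses.
## Deterministic: identical (geometry, level) always yields the same mesh.

.resolution_ladder <- function() {
  ## near-electrode / interface-band / far-field characteristic lengths (mm)
  list(coarse  = c(h_min = 0.4, h_mid = 1.0, h_max = 4.0),
       medium  = c(h_min = 0.3, h_mid = 0.7, h_max = 3.0),
       fine    = c(h_min = 0.2, h_mid = 0.5, h_max = 2.5),
       finest  = c(h_min = 0.1, h_mid = 0.45, h_max = 2.5))
}

## Graded point distribution on [a, b] with local target spacing hfun(x):
## equidistribute the integral of 1/h so anchors stay exact and grading is
## smooth.
.spaced_points <- function(a, b, hfun) {
  if (b - a <= 0) return(numeric(0))
  xs <- seq(a, b, length.out = 801)
  invh <- 1 / pmax(hfun(xs), 1e-9)
  cum <- c(0, cumsum(diff(xs) * (invh[-1] + invh[-length(invh)]) / 2))
  n <- max(1L, as.integer(round(cum[length(cum)])))
  targ <- seq(0, cum[length(cum)], length.out = n + 1L)
  pts <- stats::approx(cum, xs, xout = targ, ties = "ordered")$y
  pts[1] <- a; pts[length(pts)] <- b
  pts
}

.grid_axis <- function(anchors, lo, hi, hfun) {
  anchors <- sort(unique(c(lo, hi, anchors[anchors > lo & anchors < hi])))
  out <- anchors[1]
  for (k in seq_len(length(anchors) - 1L)) {
    seg <- .spaced_points(anchors[k], anchors[k + 1L], hfun)
    out <- c(out, seg[-1])
  }
  out
}

## minimum incident edge length per node
.node_min_edge <- function(nodes, tris) {
  ed <- rbind(tris[, c(1L, 2L)], tris[, c(2L, 3L)], tris[, c(3L, 1L)])
  len <- sqrt((nodes[ed[, 1], 1] - nodes[ed[, 2], 1])^2 +
              (nodes[ed[, 1], 2] - nodes[ed[, 2], 2])^2)
  minlen <- rep(Inf, nrow(nodes))
  idx <- c(ed[, 1], ed[, 2]); ll <- c(len, len)
  agg <- tapply(ll, idx, min)
  minlen[as.integer(names(agg))] <- agg
  minlen
}

.tri_areas <- function(nodes, tris) {
  r1 <- nodes[tris[, 1], 1]; z1 <- nodes[tris[, 1], 2]
  r2 <- nodes[tris[, 2], 1]; z2 <- nodes[tris[, 2], 2]
  r3 <- nodes[tris[, 3], 1]; z3 <- nodes[tris[, 3], 2]
  0.5 * ((r2 - r1) * (z3 - z1) - (r3 - r1) * (z2 - z1))
}

## Make the triangulation conform to the circle of radius Rc centred at the
## origin: snap vertices lying within a fraction of their local edge length
## onto the circle, then split every triangle whose edges still cross it.
.cut_circle <- function(nodes, tris, Rc) {
  for (pass in 1:12) {
    d <- sqrt(nodes[, 1]^2 + nodes[, 2]^2)
    minlen <- .node_min_edge(nodes, tris)
    snap <- d > 0 & abs(d - Rc) < 0.22 * minlen & abs(d - Rc) > 0
    if (any(snap))
      nodes[snap, ] <- nodes[snap, , drop = FALSE] * (Rc / d[snap])
    d <- sqrt(nodes[, 1]^2 + nodes[, 2]^2)
    s <- d - Rc
    s[abs(s) < 1e-9 * Rc] <- 0

    ## unique undirected edges with strictly opposite signs
    ed <- rbind(tris[, c(1L, 2L)], tris[, c(2L, 3L)], tris[, c(3L, 1L)])
    ekey <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
    keep <- !duplicated(ekey)
    ed <- ed[keep, , drop = FALSE]; ekey <- ekey[keep]
    crossing <- s[ed[, 1]] * s[ed[, 2]] < 0
    if (!any(crossing)) {
      cross_ed <- ed[0, , drop = FALSE]; tpar <- numeric(0); ckey <- character(0)
      break
    }
    cross_ed <- ed[crossing, , drop = FALSE]
    ckey <- ekey[crossing]
    A <- nodes[cross_ed[, 1], , drop = FALSE]
    B <- nodes[cross_ed[, 2], , drop = FALSE]
    dAB <- B - A
    qa <- rowSums(dAB^2); qb <- 2 * rowSums(A * dAB); qc <- rowSums(A^2) - Rc^2
    disc <- sqrt(pmax(qb^2 - 4 * qa * qc, 0))
    t1 <- (-qb - disc) / (2 * qa); t2 <- (-qb + disc) / (2 * qa)
    tpar <- ifelse(t1 > 0 & t1 < 1, t1, t2)
    near0 <- tpar < 0.12; near1 <- tpar > 0.88
    if (!any(near0 | near1)) break
    ## crossing too close to an endpoint: snap that endpoint instead
    sn <- unique(c(cross_ed[near0, 1], cross_ed[near1, 2]))
    sn <- sn[d[sn] > 0]
    nodes[sn, ] <- nodes[sn, , drop = FALSE] * (Rc / d[sn])
  }
  if (nrow(cross_ed) == 0L) return(list(nodes = nodes, tris = tris))

  ## create one new node per crossed edge
  newpts <- nodes[cross_ed[, 1], , drop = FALSE] +
    tpar * (nodes[cross_ed[, 2], , drop = FALSE] -
            nodes[cross_ed[, 1], , drop = FALSE])
  ## project exactly onto the circle
  dn <- sqrt(newpts[, 1]^2 + newpts[, 2]^2)
  newpts <- newpts * (Rc / dn)
  newpts[abs(newpts[, 1]) < 1e-12, 1] <- 0  # keep axis nodes on the axis
  newid <- nrow(nodes) + seq_len(nrow(newpts))
  names(newid) <- ckey
  nodes <- rbind(nodes, newpts)

  d <- sqrt(nodes[, 1]^2 + nodes[, 2]^2)
  s <- d - Rc; s[abs(s) < 1e-9 * Rc] <- 0

  out <- vector("list", nrow(tris))
  for (t in seq_len(nrow(tris))) {
    v <- tris[t, ]
    k12 <- paste(min(v[1], v[2]), max(v[1], v[2]))
    k23 <- paste(min(v[2], v[3]), max(v[2], v[3]))
    k31 <- paste(min(v[3], v[1]), max(v[3], v[1]))
    p <- newid[c(k12, k23, k31)]
    ncross <- sum(!is.na(p))
    if (ncross == 0L) {
      out[[t]] <- matrix(v, 1L)
    } else if (ncross == 1L) {
      ## one crossed edge, opposite vertex sits on the circle
      e <- which(!is.na(p))          # 1 = (v1,v2), 2 = (v2,v3), 3 = (v3,v1)
      w <- c(3L, 1L, 2L)[e]          # vertex not on the crossed edge
      u <- c(1L, 2L, 3L)[e]; x <- c(2L, 3L, 1L)[e]
      out[[t]] <- rbind(c(v[w], v[u], p[e]), c(v[w], p[e], v[x]))
    } else if (ncross == 2L) {
      e <- which(!is.na(p))
      ## apex vertex shared by the two crossed edges
      vert_of_edge <- list(c(1L, 2L), c(2L, 3L), c(3L, 1L))
      shared <- intersect(vert_of_edge[[e[1]]], vert_of_edge[[e[2]]])
      others <- setdiff(1:3, shared)
      p1 <- p[e[1]]; p2 <- p[e[2]]
      ## p1 lies on edge (shared, a1) where a1 is the other vertex of e[1]
      a1 <- setdiff(vert_of_edge[[e[1]]], shared)
      a2 <- setdiff(vert_of_edge[[e[2]]], shared)
      out[[t]] <- rbind(c(v[shared], p1, p2),
                        c(p1, v[a1], v[a2]),
                        c(p1, v[a2], p2))
    } else {
      stop("circle crosses all three edges of a triangle; refine the mesh")
    }
  }
  tris <- do.call(rbind, out)
  ## restore counter-clockwise orientation where splitting flipped it
  ar <- .tri_areas(nodes, tris)
  flip <- ar < 0
  if (any(flip)) tris[flip, 2:3] <- tris[flip, 3:2, drop = FALSE]
  list(nodes = nodes, tris = tris)
}

#' Generate a graded triangular mesh for a scenario geometry
#'
#' Builds a graded tensor-product triangulation of the axisymmetric domain
#' with the smallest elements adjacent to the electrode active tip, exact
#' grid lines on every straight tissue interface, and chord-conforming
#' refinement along the circular nidus/sclerosis interfaces. Elements carry
#' the tissue label of the region containing their centroid; boundary edges
#' are tagged `symmetry_axis`, `outer_boundary` and (internal)
#' `electrode_active_tip`.
#'
#' @param geometry A [build_scenario()] result.
#' @param resolution_level One of `"coarse"`, `"medium"`, `"fine"`,
#'   `"finest"` (near-electrode characteristic lengths 0.4 / 0.3 / 0.2 /
#'   0.1 mm).
#' @param seed Integer recorded for provenance; mesh construction is fully
#'   deterministic, so the seed does not alter the result.
#' @return An object of class `oo_mesh`: node coordinates in metres,
#'   triangle node triples, per-triangle region labels and areas, tagged
#'   boundary edge sets, node index sets (axis, outer boundary, electrode),
#'   the tip sensor node and characteristic-length bookkeeping.
#' @export
generate_mesh <- function(geometry, resolution_level = "fine", seed = 1L) {
  stopifnot(inherits(geometry, "region_geometry"))
  ladder <- .resolution_ladder()
  if (!resolution_level %in% names(ladder))
    stop("resolution_level must be one of: ",
         paste(names(ladder), collapse = ", "))
  h <- ladder[[resolution_level]]

  re <- geometry$electrode["radius"]; th <- geometry$electrode["tip_half"]
  D <- geometry$bbox["r_max"]
  ## mid-resolution band: covers the nidus interfaces and the region the
  ## cell-death isoline can plausibly reach (~12 mm), not far interfaces
  band_r <- min(max(geometry$circles) + 7, D - 1)
  band_z <- band_r

  hfun_r <- function(x) stats::approx(
    c(0, re + 1.2, band_r, D), c(h["h_min"], h["h_min"], h["h_mid"], h["h_max"]),
    xout = pmin(x, D), rule = 2, ties = "ordered")$y
  hfun_z <- function(z) stats::approx(
    c(0, th + 1.2, band_z, D), c(h["h_min"], h["h_min"], h["h_mid"], h["h_max"]),
    xout = pmin(abs(z), D), rule = 2, ties = "ordered")$y

  r_anch <- c(0, re, geometry$r_lines, geometry$circles, D)
  z_anch <- c(geometry$z_lines, 0, geometry$circles, -geometry$circles, -D, D)
  rl <- .grid_axis(r_anch, 0, D, hfun_r)
  zl <- .grid_axis(z_anch, -D, D, hfun_z)

  nr <- length(rl); nz <- length(zl)
  nodes <- cbind(rep(rl, times = nz), rep(zl, each = nr)) / 1000  # mm -> m
  id <- function(i, j) (j - 1L) * nr + i
  i <- rep(seq_len(nr - 1L), times = nz - 1L)
  j <- rep(seq_len(nz - 1L), each = nr - 1L)
  n1 <- id(i, j); n2 <- id(i + 1L, j); n3 <- id(i + 1L, j + 1L); n4 <- id(i, j + 1L)
  even <- (i + j) %% 2L == 0L
  tris <- rbind(
    cbind(n1[even], n2[even], n3[even]), cbind(n1[even], n3[even], n4[even]),
    cbind(n1[!even], n2[!even], n4[!even]), cbind(n2[!even], n3[!even], n4[!even]))

  for (Rc in sort(geometry$circles)) {
    cut <- .cut_circle(nodes, tris, Rc / 1000)
    nodes <- cut$nodes; tris <- cut$tris
  }

  areas <- .tri_areas(nodes, tris)
  if (any(areas <= 0))
    stop("mesh generation produced ", sum(areas <= 0),
         " degenerate element(s) for scenario '", geometry$scenario_id,
         "' at level '", resolution_level, "'")

  ## classify elements by centroid (back to mm for the classifier)
  cr <- (nodes[tris[, 1], 1] + nodes[tris[, 2], 1] + nodes[tris[, 3], 1]) / 3
  cz <- (nodes[tris[, 1], 2] + nodes[tris[, 2], 2] + nodes[tris[, 3], 2]) / 3
  region <- geometry$classify(cr * 1000, cz * 1000)

  ## boundary edges: edges used by exactly one triangle
  ed <- rbind(tris[, c(1L, 2L)], tris[, c(2L, 3L)], tris[, c(3L, 1L)])
  etri <- rep(seq_len(nrow(tris)), 3L)
  ekey <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  tab <- table(ekey)
  bkey <- names(tab)[tab == 1L]
  isb <- ekey %in% bkey
  bed <- ed[isb, , drop = FALSE]
  tol <- 1e-9
  on_axis <- nodes[bed[, 1], 1] < tol & nodes[bed[, 2], 1] < tol
  Dm <- D / 1000
  on_outer <- !on_axis
  if (!all(abs(pmax(nodes[bed[on_outer, 1], 1], abs(nodes[bed[on_outer, 1], 2])) - Dm) < 1e-6 |
           abs(pmax(nodes[bed[on_outer, 2], 1], abs(nodes[bed[on_outer, 2], 2])) - Dm) < 1e-6))
    stop("untagged boundary edge found off the domain boundary")

  ## internal electrode-tissue interface (active tip surface)
  first_seen <- match(ekey, ekey)
  twin <- which(first_seen != seq_along(ekey))
  tip_ed <- NULL
  if (length(twin)) {
    lab1 <- region[etri[first_seen[twin]]]
    lab2 <- region[etri[twin]]
    mix <- (lab1 == "electrode") != (lab2 == "electrode")
    tip_ed <- ed[twin[mix], , drop = FALSE]
  }

  electrode_nodes <- sort(unique(as.vector(tris[region == "electrode", ])))
  outer_nodes <- which(abs(nodes[, 1] - Dm) < 1e-6 |
                       abs(nodes[, 2] - Dm) < 1e-6 |
                       abs(nodes[, 2] + Dm) < 1e-6)
  axis_nodes <- which(nodes[, 1] < tol)
  tip_sensor <- which.min(nodes[, 1]^2 + (nodes[, 2] + th / 1000)^2)

  ## characteristic length adjacent to the electrode active tip
  near <- tris[region != "electrode" & region != "plastic", , drop = FALSE]
  touch <- matrix(near %in% electrode_nodes, nrow(near))
  near <- near[rowSums(touch) > 0, , drop = FALSE]
  h_near <- if (nrow(near)) {
    ne <- rbind(near[, c(1L, 2L)], near[, c(2L, 3L)], near[, c(3L, 1L)])
    min(sqrt((nodes[ne[, 1], 1] - nodes[ne[, 2], 1])^2 +
             (nodes[ne[, 1], 2] - nodes[ne[, 2], 2])^2)) * 1000
  } else NA_real_

  structure(list(
    nodes = nodes, tris = tris, region = region, areas = areas,
    n_nodes = nrow(nodes), n_tris = nrow(tris),
    boundary = list(symmetry_axis = bed[on_axis, , drop = FALSE],
                    outer_boundary = bed[!on_axis, , drop = FALSE],
                    electrode_active_tip = tip_ed),
    outer_nodes = outer_nodes, axis_nodes = axis_nodes,
    electrode_nodes = electrode_nodes, tip_sensor = tip_sensor,
    h_params = c(h, h_near_electrode = h_near),
    resolution_level = resolution_level, seed = as.integer(seed),
    geometry = geometry
  ), class = "oo_mesh")
}

#' Per-region mesh areas
#'
#' Sums planar triangle areas by region label, in mm^2, for comparison with
#' the geometry's analytic region areas.
#'
#' @param mesh An [generate_mesh()] result.
#' @return Named numeric vector of areas (mm^2).
#' @export
mesh_region_areas <- function(mesh) {
  a <- tapply(mesh$areas, mesh$region, sum) * 1e6
  out <- as.numeric(a); names(out) <- names(a)
  out
}

#' Nearest mesh nodes to probe points
#'
#' @param mesh An `oo_mesh`.
#' @param probe_points Matrix with columns (r, z) in millimetres.
#' @return Integer node indices, one per probe.
#' @export
probe_indices <- function(mesh, probe_points) {
  probe_points <- matrix(probe_points, ncol = 2L)
  bb <- mesh$geometry$bbox
  idx <- integer(nrow(probe_points))
  for (k in seq_len(nrow(probe_points))) {
    p <- probe_points[k, ]
    if (p[1] < 0 || p[1] > bb["r_max"] || p[2] < bb["z_min"] || p[2] > bb["z_max"])
      stop("probe point (", p[1], ", ", p[2], ") mm lies outside the domain")
    idx[k] <- which.min((mesh$nodes[, 1] - p[1] / 1000)^2 +
                        (mesh$nodes[, 2] - p[2] / 1000)^2)
  }
  idx
}

#' @exportS3Method base::print
print.oo_mesh <- function(x, ...) {
  cat("Axisymmetric triangular mesh (scenario '",
      x$geometry$scenario_id, "', level '", x$resolution_level, "')\n",
      sep = "")
  cat("  ", x$n_nodes, " nodes, ", x$n_tris, " triangles\n", sep = "")
  cat("  characteristic length near electrode: ",
      signif(x$h_params["h_near_electrode"], 3), " mm\n", sep = "")
  cat("  per-region areas (mm^2):\n")
  print(round(mesh_region_areas(x), 2))
  invisible(x)
}
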