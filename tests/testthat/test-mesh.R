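test_that("meshes are valid, conforming and resolve each region area to < 1%", {
  for (sc in c("a", "c", "validation")) {
    g <- build_scenario(sc)
    m <- generate_mesh(g, "coarse")
    expect_true(all(m$areas > 0))
    ma <- mesh_region_areas(m)
    an <- setNames(g$regions$area_mm2, g$regions$label)
    expect_setequal(names(ma), names(an))
    expect_lt(max(abs(ma[names(an)] - an) / an), 0.01)
    ## symmetry-axis edges sit on r = 0, outer edges on the domain boundary
    ax <- m$boundary$symmetry_axis
    expect_true(all(m$nodes[as.vector(ax), 1] < 1e-9))
    D <- g$bbox["r_max"] / 1000
    ob <- unique(as.vector(m$boundary$outer_boundary))
    expect_true(all(abs(m$nodes[ob, 1] - D) < 1e-6 |
                    abs(abs(m$nodes[ob, 2]) - D) < 1e-6))
    ## active-tip interface edges separate metal from tissue
    expect_gt(nrow(m$boundary$electrode_active_tip), 0)
  }
})

test_that("refinement ladder is monotone and reaches 0.1 mm near the electrode", {
  g <- build_scenario("a")
  n_nodes <- sapply(c("coarse", "medium", "fine"), function(l)
    generate_mesh(g, l)$n_nodes)
  expect_true(all(diff(n_nodes) > 0))
  mf <- generate_mesh(g, "finest")
  expect_lte(mf$h_params[["h_near_electrode"]], 0.1 + 1e-6)
  expect_gt(mf$n_nodes, n_nodes["fine"])
})

test_that("meshes are bit-reproducible for identical inputs", {
  g <- build_scenario("b")
  m1 <- generate_mesh(g, "coarse")
  m2 <- generate_mesh(g, "coarse")
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$tris, m2$tris)
  expect_identical(m1$region, m2$region)
})

test_that("probe lookup returns nearby distinct nodes and rejects outside points", {
  g <- build_scenario("validation")
  m <- generate_mesh(g, "coarse")
  idx <- probe_indices(m, g$probe_points)
  expect_length(unique(idx), 3L)
  d_mm <- sqrt(rowSums((m$nodes[idx, ] * 1000 - g$probe_points)^2))
  expect_true(all(d_mm < 2 * m$h_params[["h_max"]]))
  ## a probe that coincides with a node comes back exactly
  p <- m$nodes[500, , drop = FALSE] * 1000
  expect_equal(probe_indices(m, p), 500L)
  expect_error(probe_indices(m, cbind(400, 0)), "outside the domain")
})

test_that("the tip sensor sits at the distal apex of the active tip", {
  m <- coarse_mesh("a")
  p <- m$nodes[m$tip_sensor, ] * 1000
  expect_equal(unname(p[1]), 0)
  expect_equal(unname(p[2]), -3.75, tolerance = 1e-6)
})
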