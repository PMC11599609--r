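# Dual surface construction: triangulated RAG -> dual polygons ->
# refinement -> smoothing.

octahedron_graph <- function(r = 10) {
  nodes <- tibble::tibble(scute_id = 1:6,
                          x = c(1, -1, 0, 0, 0, 0) * r,
                          y = c(0, 0, 1, -1, 0, 0) * r,
                          z = c(0, 0, 0, 0, 1, -1) * r)
  edges <- tibble::tibble(from = c(1, 1, 1, 1, 2, 2, 2, 2, 3, 4, 3, 4),
                          to   = c(3, 4, 5, 6, 3, 4, 5, 6, 5, 5, 6, 6))
  new_adjacency_graph(nodes, edges)
}

test_that("octahedron regions dualize to quadrilaterals", {
  s <- build_dual_surface(octahedron_graph(), refine = 0, smooth_iterations = 0)
  # 8 RAG triangles -> 8 dual vertices; each node surrounded by 4
  # triangles -> quadrilateral patch (2 fan triangles)
  expect_identical(nrow(s$mesh$vertices), 8L)
  expect_true(all(lengths(s$scute_patch) == 2))
  expect_true(all(s$fully_surrounded))
})

test_that("refinement multiplies faces by 64 after three passes", {
  s0 <- build_dual_surface(octahedron_graph(), refine = 0, smooth_iterations = 0)
  s3 <- build_dual_surface(octahedron_graph(), refine = 3, smooth_iterations = 0)
  expect_identical(nrow(s3$mesh$faces), 64L * nrow(s0$mesh$faces))
})

test_that("boundary nodes of a planar tiling are not fully surrounded", {
  g <- hex_tiling_graph(n_ring = 3, d = 2)
  s <- build_dual_surface(g, refine = 0, smooth_iterations = 0)
  # interior nodes (6 neighbors) are surrounded; the outer ring is not
  deg <- count_neighbors(g)
  expect_true(all(s$fully_surrounded[deg == 6]))
  expect_false(any(s$fully_surrounded[deg < 6]))
})

test_that("interior hexagon patch area matches the analytic hexagon", {
  d <- 2
  g <- hex_tiling_graph(n_ring = 4, d = d)
  # hexagonal tile of a triangular lattice with spacing d has edge
  # a = d / sqrt(3) and area (3 sqrt(3) / 2) a^2
  a <- d / sqrt(3)
  A_hex <- 3 * sqrt(3) / 2 * a^2
  center <- g$nodes$scute_id[abs(g$nodes$x) < 1e-9 & abs(g$nodes$y) < 1e-9]
  s0 <- build_dual_surface(g, refine = 0, smooth_iterations = 0)
  expect_equal(scute_plane_area(s0, center), A_hex, tolerance = 1e-9)
  # with refinement + smoothing the planar patch area changes only a little
  s <- build_dual_surface(g)
  expect_lt(abs(scute_plane_area(s, center) - A_hex) / A_hex, 0.05)
})

test_that("dual surface area scales quadratically with the RAG scale", {
  fx <- small_specimen()
  g <- fx$measured$rag
  a1 <- surface_area(build_dual_surface(g, refine = 1, smooth_iterations = 3))
  for (s in c(0.5, 2)) {
    g2 <- g
    g2$nodes$x <- g$nodes$x * s
    g2$nodes$y <- g$nodes$y * s
    g2$nodes$z <- g$nodes$z * s
    a2 <- surface_area(build_dual_surface(g2, refine = 1, smooth_iterations = 3))
    expect_equal(a2, a1 * s^2, tolerance = 1e-6)
  }
})

test_that("a triangle-free graph is rejected", {
  nodes <- tibble::tibble(scute_id = 1:4, x = rnorm(4), y = rnorm(4), z = 0)
  edges <- tibble::tibble(from = c(1, 2, 3, 4), to = c(2, 3, 4, 1))
  expect_error(build_dual_surface(new_adjacency_graph(nodes, edges)),
               "no triangles")
})
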