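# Centroidal Voronoi tessellation of carapace surfaces.

test_that("two regions on a sphere are mutual neighbors", {
  m <- icosphere(10, 3)
  p <- tessellate(m, 2, 0, seed = 1, lloyd_iterations = 10)
  adj <- partition_adjacency(p)
  expect_identical(nrow(adj), 1L)
  expect_equal(as.vector(adj), c(1, 2))
})

test_that("region areas conserve the total mesh area minus openings", {
  m <- icosphere(12, 4)
  p <- tessellate(m, 60, 3, seed = 2, lloyd_iterations = 15)
  A_open <- sum(face_areas(m)[p$face_label == 0])
  expect_equal(sum(partition_region_areas(p)) + A_open, surface_area(m),
               tolerance = 1e-9)
})

test_that("sphere tessellation honors Euler's neighbor-count bound", {
  m <- get_fixture("sphere_fine", icosphere(20, 5))
  p <- tessellate(m, 400, 0, seed = 5, lloyd_iterations = 40)
  adj <- partition_adjacency(p)
  deg <- tabulate(c(adj[, 1], adj[, 2]), nbins = nrow(p$generator_points))
  # trivalent genus-0 tessellation: mean degree 6 - 12/n, discretization
  # noise shifts it slightly below
  expect_lt(mean(deg), 6)
  expect_lt(abs(mean(deg) - (6 - 12 / 400)), 0.2)
  # mode at 6 neighbors, flanked by 5s and 7s
  tab <- table(deg)
  expect_identical(names(which.max(tab)), "6")
  expect_gt(mean(deg == 6), 0.4)
})

test_that("tessellation is deterministic given the seed and rejects bad input", {
  m <- icosphere(5, 3)
  p1 <- tessellate(m, 40, 2, seed = 9, lloyd_iterations = 8)
  p2 <- tessellate(m, 40, 2, seed = 9, lloyd_iterations = 8)
  expect_identical(p1$face_label, p2$face_label)
  expect_identical(p1$generator_points, p2$generator_points)
  expect_error(tessellate(m, 1, 0), "n_scutes")
  expect_error(tessellate(m, nrow(m$faces) + 1, 0), "exceeds")
})

test_that("regions are edge-connected on the mesh", {
  m <- icosphere(10, 4)
  p <- tessellate(m, 80, 0, seed = 3, lloyd_iterations = 15)
  adjp <- carapace:::face_adjacency_pairs(m)
  for (lab in sample(seq_len(nrow(p$generator_points)), 10)) {
    faces <- which(p$face_label == lab)
    sub <- adjp[p$face_label[adjp[, 1]] == lab & p$face_label[adjp[, 2]] == lab, ,
                drop = FALSE]
    g <- igraph::graph_from_edgelist(
      matrix(match(as.vector(sub), faces), ncol = 2), directed = FALSE)
    g <- igraph::add_vertices(g, length(faces) - igraph::vcount(g))
    expect_equal(igraph::components(g)$no, 1)
  }
})
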