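# Region-adjacency graph construction from label volumes.

test_that("planar 3x3 grid has rook adjacency only", {
  g <- build_rag(grid9_volume())
  # labels laid out row-major: 1..9 on a 3x3 grid
  deg <- count_neighbors(g)
  expect_identical(unname(deg[c("1", "3", "7", "9")]), rep(2L, 4))  # corners
  expect_identical(unname(deg["5"]), 4L)                            # center
  expect_identical(unname(deg[c("2", "4", "6", "8")]), rep(3L, 4))  # sides
})

test_that("face contact makes an edge, corner contact does not", {
  arr <- array(0L, dim = c(4, 4, 4))
  arr[1, 1, 1] <- 1L; arr[2, 1, 1] <- 2L          # share a face
  arr[3, 3, 3] <- 3L; arr[4, 4, 4] <- 4L          # touch only at a corner
  g <- build_rag(label_volume(arr, 1))
  expect_identical(nrow(g$edges), 1L)
  expect_identical(c(g$edges$from, g$edges$to), c(1L, 2L))
})

test_that("RAG equals the brute-force adjacency oracle on random Voronoi labels", {
  vol <- voronoi_volume(n_labels = 12, dim3 = 24, seed = 5)
  g <- build_rag(vol)
  got <- cbind(g$edges$from, g$edges$to)
  want <- brute_force_adjacency(vol)
  expect_identical(got, matrix(as.integer(want), ncol = 2))
})

test_that("RAG commutes with label permutation", {
  vol <- voronoi_volume(n_labels = 8, dim3 = 16, seed = 3)
  g1 <- build_rag(vol)
  set.seed(1)
  perm <- sample(8)
  vol2 <- vol
  vol2$labels <- array(ifelse(vol$labels > 0, perm[vol$labels], 0L),
                       dim = dim(vol$labels))
  g2 <- build_rag(vol2)
  e1 <- apply(cbind(perm[g1$edges$from], perm[g1$edges$to]), 1,
              function(r) paste(sort(r), collapse = "-"))
  e2 <- paste(g2$edges$from, g2$edges$to, sep = "-")
  expect_setequal(e1, e2)
})

test_that("handshake identity holds and unknown ids are rejected", {
  fx <- small_specimen()
  g <- fx$measured$rag
  deg <- count_neighbors(g)
  expect_identical(sum(deg), 2L * nrow(g$edges))
  expect_error(count_neighbors(g, max(g$nodes$scute_id) + 10), "unknown")
  expect_error(build_rag(label_volume(array(0L, c(3, 3, 3)), 1)), "empty|non-zero")
})

test_that("min_contact filters weak contacts", {
  arr <- array(0L, dim = c(4, 2, 1))
  arr[1:2, 1, 1] <- 1L
  arr[3:4, 1, 1] <- 2L
  arr[1:2, 2, 1] <- 1L                             # 1 contacts 2 via one face
  g1 <- build_rag(label_volume(arr, 1), min_contact = 1)
  g2 <- build_rag(label_volume(arr, 1), min_contact = 2)
  expect_identical(nrow(g1$edges), 1L)
  expect_identical(nrow(g2$edges), 0L)
})
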