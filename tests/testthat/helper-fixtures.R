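# Shared fixtures, memoized so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

get_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# A small complete synthetic specimen (tetragonal, ~220 scutes),
# reused across module tests.
small_specimen <- function() {
  get_fixture("small_specimen", {
    sp <- carapace_spec("tetragonal", length_mm = 60, height_mm = 28,
                        width_mm = 26, n_scutes = 220, n_openings = 4,
                        seed = 7)
    obj <- synthesize_carapace(sp, mesh_res = list(n_theta = 96, n_axial = 80))
    m <- measure_scutes(obj$volume, "fix1")
    list(obj = obj, measured = m)
  })
}

# A moderately fine icosphere (radius 20 mm).
sphere_mesh <- function() get_fixture("sphere20", icosphere(20, 4))

# Planar 3x3 grid of one-voxel-thick square labels (for RAG tests):
# each label is a 3x3 voxel square in a single z-slice.
grid9_volume <- function() {
  arr <- array(0L, dim = c(9, 9, 3))
  lab <- 0L
  for (gy in 0:2) for (gx in 0:2) {
    lab <- lab + 1L
    arr[gx * 3 + 1:3, gy * 3 + 1:3, 2] <- lab
  }
  label_volume(arr, 1)
}

# Random 3D Voronoi labeling of a small volume.
voronoi_volume <- function(n_labels = 12, dim3 = 24, seed = 5) {
  set.seed(seed)
  seeds <- matrix(runif(n_labels * 3, 1, dim3), ncol = 3)
  idx <- as.matrix(expand.grid(i = 1:dim3, j = 1:dim3, k = 1:dim3))
  d2 <- matrix(0, nrow(idx), n_labels)
  for (s in 1:n_labels)
    d2[, s] <- rowSums(sweep(idx, 2, seeds[s, ])^2)
  arr <- array(as.integer(max.col(-d2)), dim = c(dim3, dim3, dim3))
  label_volume(arr, 0.5)
}

# Brute-force 6-connectivity adjacency oracle: scans every voxel pair.
brute_force_adjacency <- function(volume) {
  arr <- volume$labels
  d <- dim(arr)
  pairs <- c()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    a <- arr[i, j, k]
    if (a == 0) next
    for (off in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
      ii <- i + off[1]; jj <- j + off[2]; kk <- k + off[3]
      if (ii > d[1] || jj > d[2] || kk > d[3]) next
      b <- arr[ii, jj, kk]
      if (b != 0 && b != a)
        pairs <- rbind(pairs, c(min(a, b), max(a, b)))
    }
  }
  unique(pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE])
}

# RAG of a regular planar hexagonal tiling (triangular lattice of
# centers with spacing d), n_ring rings around a central node.
hex_tiling_graph <- function(n_ring = 4, d = 2) {
  pts <- c()
  for (q in -n_ring:n_ring) for (r in -n_ring:n_ring) {
    if (abs(q + r) > n_ring) next
    x <- d * (q + r / 2); y <- d * r * sqrt(3) / 2
    pts <- rbind(pts, c(x, y, 0))
  }
  nodes <- tibble::tibble(scute_id = seq_len(nrow(pts)),
                          x = pts[, 1], y = pts[, 2], z = pts[, 3])
  # edges: all pairs at distance d
  e <- c()
  for (i in seq_len(nrow(pts) - 1)) for (j in (i + 1):nrow(pts)) {
    if (abs(sqrt(sum((pts[i, ] - pts[j, ])^2)) - d) < 1e-9)
      e <- rbind(e, c(i, j))
  }
  new_adjacency_graph(nodes, tibble::tibble(from = e[, 1], to = e[, 2]))
}
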