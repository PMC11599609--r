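# Triangle-mesh container and the small set of mesh operations the
# carapace pipeline needs: areas, normals, orientation repair, midpoint
# subdivision and Laplacian smoothing. Vertices are in mm throughout.

#' Construct a triangle mesh
#'
#' @param vertices numeric matrix, one row per vertex (x, y, z) in mm.
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @return an object of class `carapace_mesh` with elements `vertices`
#'   and `faces`.
#' @export
new_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3,
                  dimnames = NULL, byrow = FALSE,
                  nrow = nrow(as.matrix(faces)))
  assert_that(ncol(vertices) == 3, "vertices must be an n x 3 matrix")
  assert_that(ncol(faces) == 3, "faces must be an m x 3 matrix")
  assert_that(all(is.finite(vertices)), "vertex coordinates must be finite")
  assert_that(min(faces) >= 1 && max(faces) <= nrow(vertices),
              "face indices out of range")
  structure(list(vertices = vertices, faces = faces),
            class = "carapace_mesh")
}

#' @export
print.carapace_mesh <- function(x, ...) {
  cat(sprintf("<carapace_mesh> %d vertices, %d faces, area %.4g mm^2\n",
              nrow(x$vertices), nrow(x$faces), sum(face_areas(x))))
  invisible(x)
}

face_corners <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  list(a = V[F[, 1], , drop = FALSE],
       b = V[F[, 2], , drop = FALSE],
       c = V[F[, 3], , drop = FALSE])
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Per-face areas of a triangle mesh
#' @param mesh a `carapace_mesh`.
#' @return numeric vector of face areas (mm^2).
#' @export
face_areas <- function(mesh) {
  fc <- face_corners(mesh)
  cr <- cross3(fc$b - fc$a, fc$c - fc$a)
  0.5 * sqrt(rowSums(cr^2))
}

face_normals <- function(mesh, normalize = TRUE) {
  fc <- face_corners(mesh)
  cr <- cross3(fc$b - fc$a, fc$c - fc$a)
  if (normalize) {
    len <- sqrt(rowSums(cr^2))
    len[len == 0] <- 1
    cr <- cr / len
  }
  cr
}

face_centroids <- function(mesh) {
  fc <- face_corners(mesh)
  (fc$a + fc$b + fc$c) / 3
}

#' Area-weighted vertex normals
#' @param mesh a `carapace_mesh` with consistent outward orientation.
#' @return n x 3 matrix of unit normals.
#' @keywords internal
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh, normalize = FALSE)  # length ~ 2 * area
  n <- nrow(mesh$vertices)
  vn <- matrix(0, n, 3)
  for (k in 1:3) {
    idx <- mesh$faces[, k]
    for (d in 1:3) {
      acc <- rowsum(fn[, d], idx)
      vn[as.integer(rownames(acc)), d] <- vn[as.integer(rownames(acc)), d] + acc
    }
  }
  len <- sqrt(rowSums(vn^2))
  len[len == 0] <- 1
  vn / len
}

edge_table <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

edge_keys <- function(edges, n) (edges[, 1] - 1) * n + edges[, 2]

#' Euler characteristic V - E + F
#' @param mesh a `carapace_mesh`.
#' @return integer; 2 for a closed genus-0 surface.
#' @export
euler_characteristic <- function(mesh) {
  n <- nrow(mesh$vertices)
  e <- length(unique(edge_keys(edge_table(mesh$faces), n)))
  nrow(mesh$vertices) - e + nrow(mesh$faces)
}

#' Is every edge shared by exactly two faces?
#' @param mesh a `carapace_mesh`.
#' @return logical.
#' @export
is_watertight <- function(mesh) {
  n <- nrow(mesh$vertices)
  tab <- table(edge_keys(edge_table(mesh$faces), n))
  all(tab == 2)
}

#' Signed volume enclosed by a closed oriented mesh
#' @keywords internal
mesh_volume <- function(mesh) {
  fc <- face_corners(mesh)
  sum(rowSums(fc$a * cross3(fc$b, fc$c))) / 6
}

#' Repair face orientation
#'
#' Propagates a consistent winding over the face-adjacency graph and, for
#' closed meshes, flips globally so normals point outward (positive
#' enclosed volume).
#'
#' @param mesh a `carapace_mesh`.
#' @return the mesh with consistently wound faces.
#' @export
orient_mesh <- function(mesh) {
  F <- mesh$faces
  nf <- nrow(F)
  nv <- nrow(mesh$vertices)
  # directed edges per face
  und <- edge_table(F)
  key <- edge_keys(und, nv)
  ord <- order(key)
  key_s <- key[ord]
  face_s <- rep(seq_len(nf), 3)[ord]
  # adjacency pairs: consecutive equal keys
  same <- which(key_s[-1] == key_s[-length(key_s)])
  pa <- face_s[same]; pb <- face_s[same + 1]
  adj <- vector("list", nf)
  for (i in seq_along(pa)) {
    adj[[pa[i]]] <- c(adj[[pa[i]]], pb[i])
    adj[[pb[i]]] <- c(adj[[pb[i]]], pa[i])
  }
  # directed edge sets for agreement testing
  dir_edges <- function(f) {
    rbind(f[c(1, 2)], f[c(2, 3)], f[c(3, 1)])
  }
  flipped <- rep(FALSE, nf)
  visited <- rep(FALSE, nf)
  queue <- integer(nf)
  for (root in seq_len(nf)) {
    if (visited[root]) next
    qhead <- 1L; qtail <- 1L
    queue[1] <- root
    visited[root] <- TRUE
    while (qhead <= qtail) {
      f <- queue[qhead]; qhead <- qhead + 1L
      fe <- dir_edges(if (flipped[f]) F[f, c(1, 3, 2)] else F[f, ])
      fe_key <- (fe[, 1] - 1) * nv + fe[, 2]
      for (g in adj[[f]]) {
        if (visited[g]) next
        ge <- dir_edges(F[g, ])
        ge_key <- (ge[, 1] - 1) * nv + ge[, 2]
        # consistent orientation: shared edge traversed in opposite senses,
        # so g's directed edges must NOT repeat f's
        flipped[g] <- any(ge_key %in% fe_key)
        visited[g] <- TRUE
        qtail <- qtail + 1L
        queue[qtail] <- g
      }
    }
  }
  if (any(flipped)) F[flipped, ] <- F[flipped, c(1, 3, 2)]
  out <- mesh
  out$faces <- F
  if (is_watertight(out) && mesh_volume(out) < 0)
    out$faces <- F[, c(1, 3, 2)]
  out
}

#' Midpoint (1-to-4) subdivision
#'
#' Each refinement pass splits every triangle into four by inserting edge
#' midpoints; face count multiplies by 4 per pass.
#'
#' @param mesh a `carapace_mesh`.
#' @param times number of passes.
#' @param face_parent optionally track provenance: if TRUE, the result
#'   carries an attribute `parent` mapping each face to its ancestral face
#'   in the input mesh.
#' @return refined `carapace_mesh`.
#' @export
subdivide_midpoint <- function(mesh, times = 1, face_parent = FALSE) {
  parent <- seq_len(nrow(mesh$faces))
  for (t in seq_len(times)) {
    V <- mesh$vertices; F <- mesh$faces
    nv <- nrow(V)
    e <- edge_table(F)
    key <- edge_keys(e, nv)
    ukey <- unique(key)
    eid <- match(key, ukey)              # edge id per face-edge slot
    ue <- e[match(ukey, key), , drop = FALSE]
    mid <- (V[ue[, 1], , drop = FALSE] + V[ue[, 2], , drop = FALSE]) / 2
    mv <- nv + seq_along(ukey)
    m12 <- mv[eid[seq_len(nrow(F))]]
    m23 <- mv[eid[nrow(F) + seq_len(nrow(F))]]
    m31 <- mv[eid[2 * nrow(F) + seq_len(nrow(F))]]
    newF <- rbind(cbind(F[, 1], m12, m31),
                  cbind(F[, 2], m23, m12),
                  cbind(F[, 3], m31, m23),
                  cbind(m12, m23, m31))
    parent <- rep(parent, 4)
    mesh <- new_mesh(rbind(V, mid), newF)
  }
  if (face_parent) attr(mesh, "parent") <- parent
  mesh
}

#' Laplacian (umbrella-operator) smoothing
#'
#' Moves each vertex toward the mean of its neighbors:
#' v <- v + lambda * (mean(neighbors) - v), repeated `iterations` times.
#'
#' @param mesh a `carapace_mesh`.
#' @param iterations number of smoothing sweeps (default 10).
#' @param lambda relaxation factor in (0, 1] (default 0.7).
#' @return smoothed `carapace_mesh` (connectivity unchanged).
#' @export
smooth_laplacian <- function(mesh, iterations = 10, lambda = 0.7) {
  V <- mesh$vertices
  nv <- nrow(V)
  e <- unique(edge_keys(edge_table(mesh$faces), nv))
  i <- (e - 1) %/% nv + 1
  j <- (e - 1) %% nv + 1
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1, dims = c(nv, nv))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  for (k in seq_len(iterations)) {
    V <- V + lambda * (as.matrix(A %*% V) / deg - V)
  }
  out <- mesh
  out$vertices <- V
  out
}

#' Total surface area of a mesh or carapace surface
#'
#' Sum of triangle areas. Degenerate (zero-area) triangles contribute 0
#' and trigger a warning. For a surface built by [build_dual_surface()]
#' this is the carapace surface area (SA), the body-size variable of the
#' scaling analyses.
#'
#' @param surface a `carapace_mesh` or `carapace_surface`.
#' @return area in mm^2.
#' @export
surface_area <- function(surface) {
  mesh <- if (inherits(surface, "carapace_surface")) surface$mesh else surface
  assert_that(inherits(mesh, "carapace_mesh"), "not a mesh or surface")
  assert_that(nrow(mesh$faces) > 0, "empty mesh")
  a <- face_areas(mesh)
  if (any(a == 0)) warning("degenerate triangles contribute zero area")
  sum(a)
}

#' Icosphere test mesh
#'
#' @param radius sphere radius (mm).
#' @param subdivisions midpoint-subdivision passes applied to an icosahedron.
#' @return a `carapace_mesh` with vertices projected onto the sphere.
#' @export
icosphere <- function(radius = 1, subdivisions = 3) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  m <- new_mesh(V, F)
  if (subdivisions > 0) m <- subdivide_midpoint(m, subdivisions)
  v <- m$vertices
  v <- v / sqrt(rowSums(v^2)) * radius
  m$vertices <- v
  orient_mesh(m)
}
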