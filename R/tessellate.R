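# Centroidal Voronoi tessellation of a closed triangle mesh into scute
# regions. Distances between face centroids and generator points are
# Euclidean, which approximates geodesic distance at the scute scale
# (nearest-seed assignments only involve distances of one scute
# diameter). An optional per-face density field produces locally smaller
# scutes where the density is high.

face_adjacency_pairs <- function(mesh) {
  nv <- nrow(mesh$vertices)
  key <- edge_keys(edge_table(mesh$faces), nv)
  fidx <- rep(seq_len(nrow(mesh$faces)), 3)
  ord <- order(key)
  ks <- key[ord]; fs <- fidx[ord]
  same <- which(ks[-1] == ks[-length(ks)])
  cbind(fs[same], fs[same + 1])
}

assign_nearest <- function(C, S, chunk = 20000L) {
  # argmin over seeds of |c - s|^2 = argmax of c.s - |s|^2/2
  n <- nrow(C)
  out <- integer(n)
  Saug <- t(cbind(S, -rowSums(S^2) / 2))   # fold -|s|^2/2 into one GEMM
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    P <- cbind(C[lo:hi, , drop = FALSE], 1) %*% Saug
    out[lo:hi] <- max.col(P, ties.method = "first")
  }
  out
}

min_dist2_to_seeds <- function(C, S, chunk = 20000L) {
  n <- nrow(C)
  out <- numeric(n)
  St <- t(S)
  s2 <- colSums(St^2)
  c2 <- rowSums(C^2)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    P <- -2 * (C[lo:hi, , drop = FALSE] %*% St)
    P <- P + rep(s2, each = hi - lo + 1L)
    out[lo:hi] <- c2[lo:hi] + apply(P, 1, min)
  }
  out
}

# Reassign edge-disconnected fragments of each region to the neighboring
# region with which they share the most mesh edges.
enforce_connected <- function(assignment, adj_pairs, max_rounds = 5) {
  for (round in seq_len(max_rounds)) {
    changed <- FALSE
    g <- igraph::graph_from_edgelist(adj_pairs, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(assignment) - igraph::vcount(g)))
    same <- assignment[adj_pairs[, 1]] == assignment[adj_pairs[, 2]]
    gs <- igraph::subgraph_from_edges(g, which(same), delete.vertices = FALSE)
    comp <- igraph::components(gs)$membership
    for (lab in unique(assignment)) {
      faces <- which(assignment == lab)
      comps <- comp[faces]
      tab <- table(comps)
      if (length(tab) <= 1) next
      main <- as.integer(names(tab)[which.max(tab)])
      for (cid in as.integer(names(tab))) {
        if (cid == main) next
        frag <- faces[comps == cid]
        # neighboring labels across fragment boundary
        sel <- adj_pairs[, 1] %in% frag | adj_pairs[, 2] %in% frag
        nb <- c(assignment[adj_pairs[sel, 1]], assignment[adj_pairs[sel, 2]])
        nb <- nb[nb != lab]
        if (!length(nb)) next
        assignment[frag] <- as.integer(names(which.max(table(nb))))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  assignment
}

#' Tessellate a carapace surface into scute regions
#'
#' Partitions the mesh faces into `n_scutes` regions by Lloyd-relaxed
#' (centroidal) Voronoi tessellation, then relabels `n_openings` regions
#' to 0 to create carapace openings. Deterministic given `seed`.
#'
#' @param mesh a closed `carapace_mesh`.
#' @param n_scutes number of Voronoi regions (>= 2).
#' @param n_openings number of regions converted to openings (label 0).
#' @param seed integer seed.
#' @param density optional per-face density (numeric vector of length
#'   `nrow(mesh$faces)`): regions shrink where density is high.
#' @param lloyd_iterations Lloyd relaxation sweeps (default 60).
#' @param opening_sites optional k x 3 matrix of points; the regions
#'   nearest these points become openings. By default openings are placed
#'   in the anterior third of the carapace (head/pectoral region).
#' @return a `surface_partition`: the mesh, a per-face region label
#'   (`face_label`, 0 = opening), and one `generator_points` row per
#'   retained scute (rownames = scute id).
#' @export
tessellate <- function(mesh, n_scutes, n_openings = 0, seed = 42,
                       density = NULL, lloyd_iterations = 60,
                       opening_sites = NULL) {
  assert_that(inherits(mesh, "carapace_mesh"), "mesh must be a carapace_mesh")
  assert_that(n_scutes >= 2, "n_scutes must be >= 2")
  nf <- nrow(mesh$faces)
  if (n_scutes > nf) stop_carapace("n_scutes exceeds the number of mesh faces")
  C <- face_centroids(mesh)
  A <- face_areas(mesh)
  dens <- if (is.null(density)) rep(1, nf) else {
    assert_that(length(density) == nf && all(density > 0),
                "density must be positive, one value per face")
    density
  }
  w <- A * dens
  with_seed(seed, {
    seeds_idx <- sample.int(nf, n_scutes, prob = w)
    S <- C[seeds_idx, , drop = FALSE]
    for (it in seq_len(lloyd_iterations)) {
      asg <- assign_nearest(C, S)
      # weighted centroid per region, projected back to a member face centroid
      sw <- rowsum(w, asg)
      cx <- rowsum(w * C[, 1], asg) / sw
      cy <- rowsum(w * C[, 2], asg) / sw
      cz <- rowsum(w * C[, 3], asg) / sw
      present <- as.integer(rownames(sw))
      Snew <- S
      Snew[present, ] <- cbind(cx, cy, cz)
      empty <- setdiff(seq_len(n_scutes), present)
      if (length(empty)) {
        # reseed empty regions at the faces farthest from any seed
        d2min <- min_dist2_to_seeds(C, S)
        Snew[empty, ] <- C[order(d2min, decreasing = TRUE)[seq_along(empty)], ,
                           drop = FALSE]
      }
      S <- Snew
    }
    asg <- assign_nearest(C, S)
  })
  adjp <- face_adjacency_pairs(mesh)
  asg <- enforce_connected(asg, adjp)
  kept <- sort(unique(asg))
  asg <- match(asg, kept)                      # compact labels 1..K
  S <- S[kept, , drop = FALSE]
  n_regions <- length(unique(asg))
  # snap generator points to the (area-weighted) centroid of their region
  for (lab in seq_len(n_regions)) {
    faces <- which(asg == lab)
    S[lab, ] <- colSums(C[faces, , drop = FALSE] * A[faces]) / sum(A[faces])
  }
  opening_regions <- integer(0)
  if (n_openings > 0) {
    if (is.null(opening_sites)) {
      xr <- range(mesh$vertices[, 1])
      anterior <- which(S[, 1] < xr[1] + diff(xr) / 3)
      if (length(anterior) < n_openings) anterior <- order(S[, 1])[seq_len(max(n_openings, 3))]
      opening_regions <- with_seed(seed + 1L,
                                   sample(anterior, n_openings))
    } else {
      opening_regions <- unique(assign_nearest(as.matrix(opening_sites), S))
      opening_regions <- head(opening_regions, n_openings)
    }
  }
  face_label <- integer(nf)
  keep <- setdiff(seq_len(n_regions), opening_regions)
  face_label[asg %in% keep] <- match(asg[asg %in% keep], keep)
  gp <- S[keep, , drop = FALSE]
  rownames(gp) <- seq_len(nrow(gp))
  structure(list(mesh = mesh, face_label = face_label,
                 generator_points = gp,
                 opening_sites = S[opening_regions, , drop = FALSE]),
            class = "surface_partition")
}

#' @export
print.surface_partition <- function(x, ...) {
  cat(sprintf("<surface_partition> %d scutes, %d opening region(s), %d faces\n",
              nrow(x$generator_points), nrow(x$opening_sites),
              nrow(x$mesh$faces)))
  invisible(x)
}

#' Region adjacency of a surface partition
#'
#' Two regions are neighbors when they share at least one mesh edge.
#' Openings (label 0) are excluded.
#'
#' @param partition a `surface_partition`.
#' @return two-column matrix of neighboring scute-id pairs.
#' @export
partition_adjacency <- function(partition) {
  adjp <- face_adjacency_pairs(partition$mesh)
  la <- partition$face_label[adjp[, 1]]
  lb <- partition$face_label[adjp[, 2]]
  sel <- la != lb & la > 0 & lb > 0
  pairs <- unique(cbind(pmin(la[sel], lb[sel]), pmax(la[sel], lb[sel])))
  pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
}

#' Per-region areas of a partition
#' @param partition a `surface_partition`.
#' @return named numeric vector of region areas (mm^2); names are scute
#'   ids, openings excluded.
#' @export
partition_region_areas <- function(partition) {
  A <- face_areas(partition$mesh)
  sel <- partition$face_label > 0
  v <- rowsum(A[sel], partition$face_label[sel])
  setNames(as.numeric(v), rownames(v))
}
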