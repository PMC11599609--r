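# Region-adjacency graph (RAG) of a scute label field: one node per
# scute at its voxel centroid, one edge per pair of scutes in face
# (6-connectivity) contact. The RAG is the basis for neighbor counts and
# for the dual carapace surface.

#' Build the region-adjacency graph of a label volume
#'
#' Nodes sit at the voxel centroid of each scute (world mm); an edge
#' connects two scutes when they share at least `min_contact`
#' face-adjacent (6-connectivity) voxel pairs. Corner or edge contact
#' between voxels does not count.
#'
#' @param volume a `label_volume`.
#' @param min_contact minimum number of shared voxel faces for an edge
#'   (default 1).
#' @return an `adjacency_graph` with `nodes` (scute_id, x, y, z,
#'   n_voxels) and `edges` (from, to, contact).
#' @export
build_rag <- function(volume, min_contact = 1) {
  assert_that(inherits(volume, "label_volume"), "volume must be a label_volume")
  arr <- volume$labels
  assert_that(any(arr > 0), "empty volume: no labeled scutes")
  d <- dim(arr)
  pair_counts <- function(u, v) {
    sel <- u > 0 & v > 0 & u != v
    if (!any(sel)) return(NULL)
    cbind(pmin(u[sel], v[sel]), pmax(u[sel], v[sel]))
  }
  pairs <- rbind(
    pair_counts(arr[-d[1], , , drop = FALSE], arr[-1, , , drop = FALSE]),
    pair_counts(arr[, -d[2], , drop = FALSE], arr[, -1, , drop = FALSE]),
    pair_counts(arr[, , -d[3], drop = FALSE], arr[, , -1, drop = FALSE]))
  labs <- sort(setdiff(unique(as.vector(arr)), 0L))
  if (is.null(pairs)) {
    edges <- tibble::tibble(from = integer(0), to = integer(0),
                            contact = integer(0))
  } else {
    key <- (pairs[, 1] - 1) * (max(labs) + 1) + pairs[, 2]
    tab <- table(key)
    k <- as.numeric(names(tab))
    from <- (k - 1) %/% (max(labs) + 1) + 1
    to <- k - (from - 1) * (max(labs) + 1)
    keep <- as.integer(tab) >= min_contact
    edges <- tibble::tibble(from = as.integer(from[keep]),
                            to = as.integer(to[keep]),
                            contact = as.integer(tab)[keep])
    edges <- edges[order(edges$from, edges$to), ]
  }
  idx <- which(arr > 0)
  lab <- arr[idx]
  i <- (idx - 1) %% d[1] + 1
  j <- ((idx - 1) %/% d[1]) %% d[2] + 1
  k3 <- (idx - 1) %/% (d[1] * d[2]) + 1
  nv <- as.vector(rowsum(rep(1L, length(lab)), lab))
  cx <- as.vector(rowsum(as.numeric(i), lab)) / nv
  cy <- as.vector(rowsum(as.numeric(j), lab)) / nv
  cz <- as.vector(rowsum(as.numeric(k3), lab)) / nv
  nodes <- tibble::tibble(
    scute_id = labs,
    x = volume$origin[1] + (cx - 0.5) * volume$voxel_mm[1],
    y = volume$origin[2] + (cy - 0.5) * volume$voxel_mm[2],
    z = volume$origin[3] + (cz - 0.5) * volume$voxel_mm[3],
    n_voxels = as.integer(nv))
  new_adjacency_graph(nodes, edges)
}

#' Construct an adjacency graph directly from nodes and edges
#' @param nodes tibble with columns scute_id, x, y, z.
#' @param edges tibble with columns from, to (and optionally contact).
#' @return an `adjacency_graph`.
#' @export
new_adjacency_graph <- function(nodes, edges) {
  assert_that(all(c("scute_id", "x", "y", "z") %in% names(nodes)),
              "nodes needs columns scute_id, x, y, z")
  assert_that(all(c("from", "to") %in% names(edges)),
              "edges needs columns from, to")
  assert_that(all(is.finite(nodes$x)) && all(is.finite(nodes$y)) &&
                all(is.finite(nodes$z)), "node centers must be finite")
  assert_that(!any(edges$from == edges$to), "self-edges are not allowed")
  assert_that(all(c(edges$from, edges$to) %in% nodes$scute_id),
              "edge endpoints must be graph nodes")
  structure(list(nodes = tibble::as_tibble(nodes),
                 edges = tibble::as_tibble(edges)),
            class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("<adjacency_graph> %d scutes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of neighboring scutes
#'
#' Degree of a scute's node on the region-adjacency graph. A scute with
#' six neighbors corresponds to a hexagonal tile.
#'
#' @param graph an `adjacency_graph`.
#' @param scute_id one or more scute ids; default all nodes.
#' @return named integer vector of neighbor counts.
#' @export
count_neighbors <- function(graph, scute_id = graph$nodes$scute_id) {
  assert_that(inherits(graph, "adjacency_graph"), "graph must be an adjacency_graph")
  unknown <- setdiff(scute_id, graph$nodes$scute_id)
  if (length(unknown))
    stop_carapace("unknown scute id(s): ", paste(unknown, collapse = ", "))
  deg <- table(factor(c(graph$edges$from, graph$edges$to),
                      levels = graph$nodes$scute_id))
  out <- as.integer(deg[as.character(scute_id)])
  names(out) <- scute_id
  out
}

#' Write an adjacency graph as CSV node and edge tables
#' @param graph an `adjacency_graph`.
#' @param node_path,edge_path output CSV paths.
#' @export
write_graph_csv <- function(graph, node_path, edge_path) {
  utils::write.csv(graph$nodes, node_path, row.names = FALSE)
  utils::write.csv(graph$edges, edge_path, row.names = FALSE)
  invisible(c(node_path, edge_path))
}
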