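# Dual carapace surface: the RAG (scute centers + adjacency) is
# triangulated (each triangle = three mutually touching scutes), the
# dual mesh places one vertex per triangle and forms one polygon per
# scute, which is then refined by midpoint subdivision and Laplacian
# smoothing. Scutes whose RAG node is not completely surrounded by
# triangles (they border an opening) get no surface patch.

#' Build the smoothed dual carapace surface from a RAG
#'
#' Steps: (i) triangulate the RAG by enumerating mutually adjacent scute
#' triples (4-cliques are split along their shorter center-to-center
#' diagonal); (ii) repair triangle orientation; (iii) build the dual
#' surface (one vertex per RAG triangle, one polygon per fully
#' surrounded scute, fan-triangulated); (iv) repair orientation again;
#' (v) midpoint-subdivide `refine` times; (vi) Laplacian-smooth.
#'
#' @param graph an `adjacency_graph`.
#' @param refine midpoint-subdivision passes (default 3; face count
#'   multiplies by 4 per pass).
#' @param smooth_iterations Laplacian smoothing sweeps (default 10).
#' @param lambda smoothing relaxation factor (default 0.7).
#' @return a `carapace_surface`: `mesh` (the smoothed dual surface),
#'   `scute_patch` (named list mapping each fully surrounded scute id to
#'   its face indices), `fully_surrounded` (named logical per scute) and
#'   `centers` (the RAG node coordinates).
#' @export
build_dual_surface <- function(graph, refine = 3, smooth_iterations = 10,
                               lambda = 0.7) {
  assert_that(inherits(graph, "adjacency_graph"), "graph must be an adjacency_graph")
  ids <- graph$nodes$scute_id
  P <- as.matrix(graph$nodes[, c("x", "y", "z")])
  idx_of <- function(id) match(id, ids)
  ig <- igraph::graph_from_edgelist(
    cbind(idx_of(graph$edges$from), idx_of(graph$edges$to)), directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0, length(ids) - igraph::vcount(ig)))
  # split 4-cliques along the shorter diagonal: drop the longer one
  cl4 <- igraph::cliques(ig, min = 4, max = 4)
  if (length(cl4)) {
    drop_edges <- unique(do.call(rbind, lapply(cl4, function(cl) {
      v <- as.integer(cl)
      ctr <- colMeans(P[v, , drop = FALSE])
      rel <- sweep(P[v, , drop = FALSE], 2, ctr)
      # order the four nodes around their best-fit plane
      nrm <- svd(rel)$v[, 3]
      e1 <- rel[1, ] - sum(rel[1, ] * nrm) * nrm
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
              nrm[3] * e1[1] - nrm[1] * e1[3],
              nrm[1] * e1[2] - nrm[2] * e1[1])
      ang <- atan2(rel %*% e2, rel %*% e1)
      v <- v[order(ang)]
      d13 <- sum((P[v[1], ] - P[v[3], ])^2)
      d24 <- sum((P[v[2], ] - P[v[4], ])^2)
      if (d13 > d24) c(min(v[1], v[3]), max(v[1], v[3]))
      else c(min(v[2], v[4]), max(v[2], v[4]))
    })))
    eids <- igraph::get_edge_ids(ig, t(drop_edges))
    ig <- igraph::delete_edges(ig, eids[eids > 0])
  }
  tri <- matrix(as.integer(igraph::triangles(ig)), ncol = 3, byrow = TRUE)
  if (nrow(tri) == 0) stop_carapace("RAG contains no triangles; cannot build a dual surface")
  rag_mesh <- orient_mesh(new_mesh(P, tri))
  tri <- rag_mesh$faces

  # dual vertices: one per RAG triangle, at the triangle centroid
  DV <- (P[tri[, 1], , drop = FALSE] + P[tri[, 2], , drop = FALSE] +
           P[tri[, 3], , drop = FALSE]) / 3
  # incident triangles per node, with the directed link edge (winding order)
  nf <- nrow(tri)
  inc_node <- as.vector(t(tri))
  inc_tri <- rep(seq_len(nf), each = 3)
  slot <- rep(1:3, nf)
  nxt1 <- tri[cbind(inc_tri, slot %% 3 + 1)]          # successor vertex in face
  nxt2 <- tri[cbind(inc_tri, (slot + 1) %% 3 + 1)]    # the third vertex
  ordn <- order(inc_node)
  faces <- list()
  patch <- list()
  surrounded <- setNames(rep(FALSE, length(ids)), ids)
  fidx <- 0L
  bounds <- c(0, cumsum(tabulate(inc_node, nbins = length(ids))))
  inc_tri_s <- inc_tri[ordn]; nxt1_s <- nxt1[ordn]; nxt2_s <- nxt2[ordn]
  for (vi in seq_along(ids)) {
    sel <- if (bounds[vi + 1] > bounds[vi]) (bounds[vi] + 1):bounds[vi + 1] else integer(0)
    kt <- length(sel)
    if (kt < 3) next
    t_ids <- inc_tri_s[sel]
    e_from <- nxt1_s[sel]; e_to <- nxt2_s[sel]
    # chain the link edges e_from -> e_to into a single closed cycle
    succ <- match(e_to, e_from)       # triangle whose link edge starts where this ends
    if (anyNA(succ)) next
    chain <- integer(kt)
    cur <- 1L
    ok <- TRUE
    for (s in seq_len(kt)) {
      chain[s] <- cur
      cur <- succ[cur]
      if (s < kt && cur == 1L) { ok <- FALSE; break }
    }
    if (!ok || cur != 1L || anyDuplicated(chain)) next
    poly <- t_ids[chain]
    # fan triangulation from the first polygon vertex
    newf <- cbind(poly[1], poly[2:(kt - 1)], poly[3:kt])
    faces[[length(faces) + 1]] <- newf
    patch[[as.character(ids[vi])]] <- fidx + seq_len(nrow(newf))
    fidx <- fidx + nrow(newf)
    surrounded[vi] <- TRUE
  }
  if (!length(faces)) stop_carapace("no fully surrounded scutes; dual surface is empty")
  F <- do.call(rbind, faces)
  dual <- new_mesh(DV, F)
  # outward orientation: positive enclosed volume (meaningful for closed
  # or nearly closed surfaces)
  if (mesh_volume(dual) < 0) {
    dual$faces <- dual$faces[, c(1, 3, 2)]
  }
  face_scute <- integer(nrow(F))
  for (id in names(patch)) face_scute[patch[[id]]] <- as.integer(id)
  if (refine > 0) {
    dual <- subdivide_midpoint(dual, refine, face_parent = TRUE)
    face_scute <- face_scute[attr(dual, "parent")]
    attr(dual, "parent") <- NULL
  }
  if (smooth_iterations > 0)
    dual <- smooth_laplacian(dual, smooth_iterations, lambda)
  patch <- split(seq_along(face_scute), face_scute)
  structure(list(mesh = dual,
                 scute_patch = patch,
                 fully_surrounded = surrounded,
                 nodes = graph$nodes),
            class = "carapace_surface")
}

#' @export
print.carapace_surface <- function(x, ...) {
  cat(sprintf("<carapace_surface> %d faces, %d/%d scutes with closed patches, SA %.4g mm^2\n",
              nrow(x$mesh$faces), sum(x$fully_surrounded),
              length(x$fully_surrounded), surface_area(x)))
  invisible(x)
}

#' Write a mesh or carapace surface as ASCII PLY
#'
#' Optionally attaches per-face properties (e.g. scute labels or a
#' color-coded scalar) as extra face columns.
#'
#' @param mesh a `carapace_mesh` or `carapace_surface`.
#' @param path output path.
#' @param face_props optional data.frame of per-face properties; integer
#'   columns are written as `int`, others as `float`.
#' @export
write_ply <- function(mesh, path, face_props = NULL) {
  if (inherits(mesh, "carapace_surface")) mesh <- mesh$mesh
  V <- mesh$vertices; F <- mesh$faces
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(V)),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nrow(F)),
           "property list uchar int vertex_indices")
  if (!is.null(face_props)) {
    assert_that(nrow(face_props) == nrow(F),
                "face_props must have one row per face")
    for (nm in names(face_props)) {
      typ <- if (is.integer(face_props[[nm]])) "int" else "float"
      hdr <- c(hdr, sprintf("property %s %s", typ, nm))
    }
  }
  hdr <- c(hdr, "end_header")
  flines <- paste(3, F[, 1] - 1, F[, 2] - 1, F[, 3] - 1)
  if (!is.null(face_props))
    flines <- paste(flines, do.call(paste, face_props))
  writeLines(c(hdr,
               paste(format(V[, 1], trim = TRUE, digits = 9),
                     format(V[, 2], trim = TRUE, digits = 9),
                     format(V[, 3], trim = TRUE, digits = 9)),
               flines), path)
  invisible(path)
}

#' Read an ASCII PLY written by [write_ply()]
#' @param path PLY file path.
#' @return list with `mesh` and (if present) `face_props` tibble.
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  end <- match("end_header", lines)
  hdr <- lines[seq_len(end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  fprop_lines <- hdr[seq(match(grep("^element face", hdr, value = TRUE), hdr) + 1, length(hdr) - 1)]
  fprop_lines <- fprop_lines[!grepl("^property list", fprop_lines)]
  vlines <- lines[end + seq_len(nv)]
  V <- matrix(scan(text = vlines, quiet = TRUE), ncol = 3, byrow = TRUE)
  flines <- lines[end + nv + seq_len(nf)]
  fm <- matrix(scan(text = flines, quiet = TRUE), nrow = nf, byrow = TRUE)
  F <- fm[, 2:4, drop = FALSE] + 1
  out <- list(mesh = new_mesh(V, F))
  if (length(fprop_lines)) {
    props <- as.data.frame(fm[, 4 + seq_along(fprop_lines), drop = FALSE])
    names(props) <- sub("^property \\S+ ", "", fprop_lines)
    types <- sub("^property (\\S+) .*$", "\\1", fprop_lines)
    for (i in seq_along(types)) if (types[i] == "int")
      props[[i]] <- as.integer(props[[i]])
    out$face_props <- tibble::as_tibble(props)
  }
  out
}
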