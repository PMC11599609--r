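# Per-scute variables: neighbor count, volume, plane-based area,
# thickness, width, aspect ratio, and Gaussian/mean surface curvature,
# plus per-specimen carapace dimensions. All lengths in mm.

#' Scute volume from the label field
#'
#' Number of voxels times the volume of one voxel.
#'
#' @param volume a `label_volume`.
#' @param scute_id one or more scute ids.
#' @return volume(s) in mm^3.
#' @export
scute_volume <- function(volume, scute_id) {
  assert_that(inherits(volume, "label_volume"), "volume must be a label_volume")
  counts <- tabulate(volume$labels, nbins = max(volume$labels))
  absent <- scute_id[scute_id > length(counts) | scute_id < 1 |
                       counts[pmax(1, pmin(scute_id, length(counts)))] == 0]
  if (length(absent))
    stop_carapace("label(s) absent from volume: ", paste(absent, collapse = ", "))
  counts[scute_id] * prod(volume$voxel_mm)
}

#' Plane-based scute area
#'
#' Area of the scute's dual-surface patch. Scutes whose RAG node is not
#' completely surrounded by triangles (they border a carapace opening)
#' have no closed patch; their area is the missing flag -1000.
#'
#' @param surface a `carapace_surface`.
#' @param scute_id one or more scute ids.
#' @return area(s) in mm^2, or -1000 where missing.
#' @export
scute_plane_area <- function(surface, scute_id) {
  assert_that(inherits(surface, "carapace_surface"), "surface must be a carapace_surface")
  fa <- face_areas(surface$mesh)
  vapply(as.character(scute_id), function(id) {
    p <- surface$scute_patch[[id]]
    if (is.null(p)) MISSING_FLAG else sum(fa[p])
  }, numeric(1), USE.NAMES = FALSE)
}

pca_extents <- function(X, voxel_mm) {
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  ev <- eigen(crossprod(Xc) / nrow(Xc), symmetric = TRUE)
  proj <- Xc %*% ev$vectors
  ext <- apply(proj, 2, function(v) diff(range(v)))
  # +1 voxel accounts for the extent of the voxels themselves
  ext + mean(voxel_mm)
}

#' Scute thickness and maximum width
#'
#' Principal-axes (covariance-aligned) bounding cuboid of the scute's
#' voxel coordinates; thickness is the shortest cuboid dimension, width
#' the largest. One voxel is added to each peak-to-peak extent to
#' account for voxel size (disable via `add_voxel = FALSE`).
#'
#' @param volume a `label_volume`.
#' @param scute_id a single scute id.
#' @param add_voxel add one voxel to the projected extents (default TRUE).
#' @return named numeric vector `c(thickness =, width =)` in mm.
#' @export
scute_thickness_width <- function(volume, scute_id, add_voxel = TRUE) {
  X <- voxel_world_coords(volume, scute_id)
  if (nrow(X) < 4) {
    warning(sprintf("scute %s has < 4 voxels; extents floored at voxel size", scute_id))
    return(c(thickness = mean(volume$voxel_mm), width = mean(volume$voxel_mm)))
  }
  ext <- pca_extents(X, if (add_voxel) volume$voxel_mm else 0)
  ext <- pmax(ext, mean(volume$voxel_mm))   # degenerate (planar/linear) floor
  c(thickness = min(ext), width = max(ext))
}

#' Scute aspect ratio
#'
#' Thickness divided by maximum width; an index of a plate's bending
#' resistance. In (0, 1] by construction.
#'
#' @param thickness,width scute thickness and width (mm).
#' @return dimensionless ratio.
#' @export
aspect_ratio <- function(thickness, width) {
  assert_that(all(width > 0), "width must be positive")
  thickness / width
}

#' Gaussian and mean surface curvature at scute centers
#'
#' Principal curvatures are estimated at the surface point nearest each
#' center by fitting a quadric over a neighborhood of radius
#' `2 * median inter-center spacing`. Sign convention: outward normals,
#' convex regions have positive mean curvature. CGS is the product and
#' CMS the mean of the two principal curvatures.
#'
#' @param surface a `carapace_surface` (or `carapace_mesh`).
#' @param centers n x 3 matrix of query points (mm); defaults to the
#'   surface's RAG node centers.
#' @param radius neighborhood radius (mm); default 2 x median
#'   nearest-center spacing.
#' @param max_points cap on neighborhood size used in each fit.
#' @return tibble with columns `cgs` (mm^-2) and `cms` (mm^-1); NA with
#'   a warning where the neighborhood is too small to fit.
#' @export
surface_curvatures <- function(surface, centers = NULL, radius = NULL,
                               max_points = 400) {
  mesh <- if (inherits(surface, "carapace_surface")) surface$mesh else surface
  if (is.null(centers)) {
    assert_that(inherits(surface, "carapace_surface"),
                "centers must be given for a bare mesh")
    centers <- as.matrix(surface$nodes[, c("x", "y", "z")])
  }
  centers <- matrix(as.numeric(centers), ncol = 3)
  if (is.null(radius)) {
    # median nearest-neighbor spacing among the query centers
    nn <- sqrt(min_dist2_to_seeds_excl(centers))
    radius <- 2 * median(nn)
  }
  V <- mesh$vertices
  VN <- vertex_normals(mesh)
  n <- nrow(centers)
  cgs <- cms <- rep(NA_real_, n)
  too_small <- 0L
  chunk <- max(1L, floor(4e6 / nrow(V)))
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    Cc <- centers[lo:hi, , drop = FALSE]
    D2 <- outer(rowSums(Cc^2), rowSums(V^2), "+") - 2 * (Cc %*% t(V))
    for (r in seq_len(hi - lo + 1L)) {
      i <- lo + r - 1L
      d2 <- D2[r, ]
      p0i <- which.min(d2)
      nb <- which(d2 <= radius^2)
      if (length(nb) < 8) { too_small <- too_small + 1L; next }
      if (length(nb) > max_points)
        nb <- nb[seq(1, length(nb), length.out = max_points)]
      nrm <- VN[p0i, ]
      e1 <- c(-nrm[2], nrm[1], 0)
      if (sum(e1^2) < 1e-12) e1 <- c(1, 0, 0)
      e1 <- e1 - sum(e1 * nrm) * nrm
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
              nrm[3] * e1[1] - nrm[1] * e1[3],
              nrm[1] * e1[2] - nrm[2] * e1[1])
      rel <- sweep(V[nb, , drop = FALSE], 2, V[p0i, ])
      u <- rel %*% e1; v <- rel %*% e2; h <- rel %*% nrm
      Xd <- cbind(u^2, u * v, v^2, u, v, 1)
      cf <- tryCatch(qr.solve(crossprod(Xd), crossprod(Xd, h)),
                     error = function(e) NULL)
      if (is.null(cf)) { too_small <- too_small + 1L; next }
      a <- cf[1]; b <- cf[2]; cc <- cf[3]; dd <- cf[4]; ee <- cf[5]
      W <- sqrt(1 + dd^2 + ee^2)
      E <- 1 + dd^2; Fm <- dd * ee; G <- 1 + ee^2
      L <- 2 * a / W; M <- b / W; N <- 2 * cc / W
      den <- E * G - Fm^2
      cgs[i] <- (L * N - M^2) / den
      # height h is along the outward normal; a convex surface bends
      # toward -n, so flip to make convex CMS positive
      cms[i] <- -(E * N - 2 * Fm * M + G * L) / (2 * den)
    }
  }
  if (too_small > 0)
    warning(sprintf("%d center(s) had neighborhoods too small to fit; curvature set to NA",
                    too_small))
  tibble::tibble(cgs = cgs, cms = cms)
}

# nearest-neighbor distance within one point set
min_dist2_to_seeds_excl <- function(P) {
  n <- nrow(P)
  out <- numeric(n)
  chunk <- max(1L, floor(4e6 / n))
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    D2 <- outer(rowSums(P[lo:hi, , drop = FALSE]^2), rowSums(P^2), "+") -
      2 * (P[lo:hi, , drop = FALSE] %*% t(P))
    D2[cbind(seq_len(hi - lo + 1L), lo:hi)] <- Inf
    out[lo:hi] <- apply(D2, 1, min)
  }
  pmax(out, 0)
}

#' Carapace length, height and width from scute centers
#'
#' Principal component analysis of the scute center coordinates; the
#' carapace length is the coordinate range along PC1 (the anteroposterior
#' axis), and of the PC2/PC3 ranges the one whose axis aligns better
#' with the dorsoventral direction is reported as height.
#'
#' @param centers n x 3 matrix of scute centers (mm), or a tibble with
#'   x, y, z columns.
#' @param dorsoventral world-space dorsoventral axis used to tell height
#'   from width (default +z). If NULL, the larger of the two transverse
#'   ranges is reported as height with a warning.
#' @return named vector `c(length =, height =, width =)` in mm.
#' @export
carapace_dimensions <- function(centers, dorsoventral = c(0, 0, 1)) {
  if (is.data.frame(centers)) centers <- as.matrix(centers[, c("x", "y", "z")])
  centers <- matrix(as.numeric(centers), ncol = 3)
  assert_that(nrow(centers) >= 2, "need at least two scute centers")
  pc <- prcomp(centers, center = TRUE, scale. = FALSE)
  rng <- apply(pc$x, 2, function(v) diff(range(v)))
  rot <- pc$rotation
  if (length(rng) < 3) {
    # degenerate configurations (collinear or planar centers) have
    # fewer than three components; missing transverse ranges are 0
    rng <- c(rng, rep(0, 3 - length(rng)))
    rot <- cbind(rot, matrix(0, 3, 3 - ncol(rot)))
  }
  if (is.null(dorsoventral)) {
    warning("no dorsoventral axis given; reporting the larger transverse range as height")
    hw <- sort(rng[2:3], decreasing = TRUE)
  } else {
    al <- abs(t(rot[, 2:3]) %*% (dorsoventral / sqrt(sum(dorsoventral^2))))
    hw <- if (al[1] >= al[2]) rng[2:3] else rng[c(3, 2)]
  }
  c(length = unname(rng[1]), height = unname(hw[1]), width = unname(hw[2]))
}

# bulk thickness/width: one pass over the nonzero voxels
thickness_width_all <- function(volume, add_voxel = TRUE) {
  arr <- volume$labels
  d <- dim(arr)
  idx <- which(arr > 0)
  lab <- arr[idx]
  i <- (idx - 1) %% d[1] + 1
  j <- ((idx - 1) %/% d[1]) %% d[2] + 1
  k <- (idx - 1) %/% (d[1] * d[2]) + 1
  X <- cbind(volume$origin[1] + (i - 0.5) * volume$voxel_mm[1],
             volume$origin[2] + (j - 0.5) * volume$voxel_mm[2],
             volume$origin[3] + (k - 0.5) * volume$voxel_mm[3])
  groups <- split(seq_along(lab), lab)
  vx <- mean(volume$voxel_mm)
  out <- t(vapply(groups, function(g) {
    if (length(g) < 4) return(c(vx, vx))
    ext <- pca_extents(X[g, , drop = FALSE], if (add_voxel) volume$voxel_mm else 0)
    ext <- pmax(ext, vx)
    c(min(ext), max(ext))
  }, numeric(2)))
  tibble::tibble(scute_id = as.integer(names(groups)),
                 thickness = out[, 1], width = out[, 2])
}

#' Measure all scutes of one specimen
#'
#' Runs the full measurement pipeline on a label volume: RAG, dual
#' surface, and the eight per-scute variables, returning a per-scute
#' table in the standard schema (columns specimen, scute_id, x, y, z,
#' n_neighbors, volume, area, thickness, width, aspect_ratio, cgs, cms).
#'
#' @param volume a `label_volume`.
#' @param specimen_id identifier stored in the `specimen` column.
#' @param min_contact RAG contact threshold (see [build_rag()]).
#' @param rag,surface optionally precomputed RAG / dual surface.
#' @return list with `records` (per-scute tibble), `surface`, `rag` and
#'   `summary` (one-row tibble: specimen, surface_area, length, height,
#'   width, n_scutes).
#' @export
measure_scutes <- function(volume, specimen_id = "specimen", min_contact = 1,
                           rag = NULL, surface = NULL) {
  rag <- rag %||% build_rag(volume, min_contact = min_contact)
  surface <- surface %||% build_dual_surface(rag)
  ids <- rag$nodes$scute_id
  nb <- count_neighbors(rag)
  vol <- scute_volume(volume, ids)
  area <- scute_plane_area(surface, ids)
  tw <- thickness_width_all(volume)
  tw <- tw[match(ids, tw$scute_id), ]
  curv <- surface_curvatures(surface)
  rec <- tibble::tibble(
    specimen = specimen_id,
    scute_id = ids,
    x = rag$nodes$x, y = rag$nodes$y, z = rag$nodes$z,
    n_neighbors = as.integer(nb),
    volume = vol,
    area = area,
    thickness = tw$thickness,
    width = tw$width,
    aspect_ratio = aspect_ratio(tw$thickness, tw$width),
    cgs = curv$cgs,
    cms = curv$cms,
    is_opening_scute = area == MISSING_FLAG)
  dims <- carapace_dimensions(rec)
  summary <- tibble::tibble(
    specimen = specimen_id,
    surface_area = surface_area(surface),
    length = dims["length"], height = dims["height"], width = dims["width"],
    n_scutes = nrow(rec))
  list(records = rec, summary = summary, surface = surface, rag = rag)
}
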