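# Voxelization of a labeled surface partition into a shell-like label
# field, emulating a microCT segmentation: each scute becomes a layer of
# labeled voxels of prescribed local thickness grown inward from the
# surface, openings leave background gaps.

#' Construct a label volume
#'
#' @param labels 3D integer array; 0 is background, positive values are
#'   scute ids.
#' @param voxel_mm voxel spacing in mm (scalar isotropic or length-3).
#' @param origin world coordinate (mm) of the corner of voxel (1,1,1);
#'   the center of voxel (i,j,k) is `origin + (c(i,j,k) - 0.5) * voxel_mm`.
#' @return a `label_volume`.
#' @export
label_volume <- function(labels, voxel_mm, origin = c(0, 0, 0)) {
  assert_that(length(dim(labels)) == 3, "labels must be a 3D array")
  assert_that(all(labels >= 0), "labels must be non-negative")
  voxel_mm <- rep(voxel_mm, length.out = 3)
  assert_that(all(voxel_mm > 0), "voxel spacing must be positive")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, voxel_mm = voxel_mm,
                 origin = as.numeric(origin)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %d x %d x %d voxels @ %.3g mm, %d labels\n",
              d[1], d[2], d[3], x$voxel_mm[1],
              length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}

# Deterministic barycentric lattice samples for one subdivision level m.
bary_lattice <- function(m) {
  ij <- expand.grid(i = 0:m, j = 0:m)
  ij <- ij[ij$i + ij$j <= m, ]
  # offset to cell interiors so samples avoid shared edges
  b1 <- (ij$i + 1 / 3) / (m + 1)
  b2 <- (ij$j + 1 / 3) / (m + 1)
  cbind(b1, b2, 1 - b1 - b2)
}

#' Voxelize a surface partition into a label volume
#'
#' Each scute's faces are sampled on a regular barycentric lattice at
#' sub-voxel spacing and grown inward along the face normal over the
#' scute's local shell thickness, producing a closed shell of labeled
#' voxels with background gaps at openings.
#'
#' @param partition a `surface_partition`.
#' @param spec the `carapace_spec` (provides `base_thickness_mm` and
#'   `voxel_mm`).
#' @param thickness optional per-scute thickness vector (mm), named or
#'   ordered by scute id; defaults to `base_thickness_mm` everywhere.
#'   Curvature-correlated edge thickening is applied by
#'   [synthesize_carapace()], which passes its thickness field here.
#' @return a `label_volume`.
#' @export
voxelize <- function(partition, spec, thickness = NULL) {
  assert_that(inherits(partition, "surface_partition"),
              "partition must be a surface_partition")
  vox <- spec$voxel_mm
  if (spec$base_thickness_mm / vox < 2)
    stop_carapace(sprintf(
      "resolution too coarse: voxel %.3g mm resolves base thickness %.3g mm with < 2 voxels",
      vox, spec$base_thickness_mm))
  mesh <- partition$mesh
  n_scutes <- nrow(partition$generator_points)
  th <- if (is.null(thickness)) rep(spec$base_thickness_mm, n_scutes)
        else rep(thickness, length.out = n_scutes)
  h <- vox / 2
  V <- mesh$vertices
  tmax <- max(th)
  origin <- apply(V, 2, min) - tmax - 2 * vox
  upper <- apply(V, 2, max) + 2 * vox
  dims <- ceiling((upper - origin) / vox)
  arr <- array(0L, dim = dims)

  # each voxel is claimed by the nearest surface sample, so suture
  # boundaries between scutes are deterministic and free of
  # salt-and-pepper interleaving
  claim_lin <- list()
  claim_lab <- list()
  claim_d2 <- list()
  lab <- partition$face_label
  keep <- which(lab > 0)
  fc <- face_corners(mesh)
  A <- face_areas(mesh)[keep]
  nrm <- face_normals(mesh)[keep, , drop = FALSE]
  a <- fc$a[keep, , drop = FALSE]
  b <- fc$b[keep, , drop = FALSE]
  cc <- fc$c[keep, , drop = FALSE]
  labk <- lab[keep]
  thk <- th[labk]
  # lattice level per face: edge length relative to sample spacing h
  emax <- sqrt(pmax(rowSums((a - b)^2), rowSums((b - cc)^2),
                    rowSums((cc - a)^2)))
  m <- pmax(1L, as.integer(ceiling(emax / h)))
  nx <- dims[1]; nxy <- dims[1] * dims[2]
  for (mm in sort(unique(m))) {
    fsel <- which(m == mm)
    B <- bary_lattice(mm)                      # k x 3
    k <- nrow(B)
    px <- B %*% rbind(a[fsel, 1], b[fsel, 1], cc[fsel, 1])  # k x g
    py <- B %*% rbind(a[fsel, 2], b[fsel, 2], cc[fsel, 2])
    pz <- B %*% rbind(a[fsel, 3], b[fsel, 3], cc[fsel, 3])
    nxv <- rep(nrm[fsel, 1], each = k)
    nyv <- rep(nrm[fsel, 2], each = k)
    nzv <- rep(nrm[fsel, 3], each = k)
    lv <- rep(labk[fsel], each = k)
    tv <- rep(thk[fsel], each = k)
    px <- as.vector(px); py <- as.vector(py); pz <- as.vector(pz)
    max_steps <- ceiling(max(tv) / h)
    for (d in 0:max_steps) {
      depth <- d * h
      sel <- which(tv >= depth - h / 2 - 1e-9)
      if (!length(sel)) break
      qx <- px[sel] - depth * nxv[sel]
      qy <- py[sel] - depth * nyv[sel]
      qz <- pz[sel] - depth * nzv[sel]
      i <- floor((qx - origin[1]) / vox) + 1
      j <- floor((qy - origin[2]) / vox) + 1
      kk <- floor((qz - origin[3]) / vox) + 1
      ok <- i >= 1 & i <= dims[1] & j >= 1 & j <= dims[2] &
        kk >= 1 & kk <= dims[3]
      lin <- (kk[ok] - 1) * nxy + (j[ok] - 1) * nx + i[ok]
      # voxel centers claimed by this sample
      cx <- origin[1] + (i[ok] - 0.5) * vox
      cy <- origin[2] + (j[ok] - 0.5) * vox
      cz <- origin[3] + (kk[ok] - 0.5) * vox
      # keep only voxels whose center lies within the shell: the center
      # depth is the sample depth minus the offset along the normal
      dd <- depth - ((cx - qx[ok]) * nxv[sel][ok] +
                       (cy - qy[ok]) * nyv[sel][ok] +
                       (cz - qz[ok]) * nzv[sel][ok])
      inside <- dd >= -1e-9 & dd <= tv[sel][ok] + 1e-9
      d2 <- (qx[ok] - cx)^2 + (qy[ok] - cy)^2 + (qz[ok] - cz)^2
      claim_lin[[length(claim_lin) + 1]] <- lin[inside]
      claim_lab[[length(claim_lab) + 1]] <- (lv[sel][ok])[inside]
      claim_d2[[length(claim_d2) + 1]] <- d2[inside]
    }
  }
  claim_lin <- unlist(claim_lin, use.names = FALSE)
  claim_lab <- unlist(claim_lab, use.names = FALSE)
  claim_d2 <- unlist(claim_d2, use.names = FALSE)
  # resolve competing claims: nearest sample wins (ties by claim order)
  ord <- order(claim_d2, decreasing = TRUE)
  arr[claim_lin[ord]] <- claim_lab[ord]
  label_volume(arr, vox, origin)
}

#' Centers of all voxels of one label, in mm
#' @keywords internal
voxel_world_coords <- function(volume, scute_id) {
  idx <- which(volume$labels == scute_id)
  if (!length(idx)) stop_carapace(sprintf("label %s absent from volume", scute_id))
  d <- dim(volume$labels)
  i <- (idx - 1) %% d[1] + 1
  j <- ((idx - 1) %/% d[1]) %% d[2] + 1
  k <- (idx - 1) %/% (d[1] * d[2]) + 1
  sweep(sweep(cbind(i, j, k) - 0.5, 2, volume$voxel_mm, "*"),
        2, volume$origin, "+")
}

#' Write / read a label volume
#'
#' NRRD files (`.nrrd`) carry the voxel spacing and origin in their
#' header (`raw` little-endian or `ascii` encodings). Multi-page TIFF
#' (`.tif`/`.tiff`) stores one z-slice per page as 16-bit; spacing must
#' then be supplied again on read.
#'
#' @param volume a `label_volume`.
#' @param path output file; format chosen by extension.
#' @param encoding for NRRD: `"raw"` (default) or `"ascii"`.
#' @export
write_label_volume <- function(volume, path, encoding = c("raw", "ascii")) {
  encoding <- match.arg(encoding)
  ext <- tolower(tools::file_ext(path))
  if (ext == "nrrd") {
    d <- dim(volume$labels)
    hdr <- c("NRRD0004",
             "# label field written by the carapace package",
             "type: int32",
             "dimension: 3",
             sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
             sprintf("spacings: %.10g %.10g %.10g",
                     volume$voxel_mm[1], volume$voxel_mm[2], volume$voxel_mm[3]),
             sprintf("axis mins: %.10g %.10g %.10g",
                     volume$origin[1], volume$origin[2], volume$origin[3]),
             "endian: little",
             sprintf("encoding: %s", encoding),
             "")
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    if (encoding == "raw") {
      writeBin(as.vector(volume$labels), con, size = 4, endian = "little")
    } else {
      writeLines(paste(as.vector(volume$labels), collapse = " "), con)
    }
  } else if (ext %in% c("tif", "tiff")) {
    mx <- max(volume$labels)
    assert_that(mx <= 65535, "TIFF export supports at most 65535 labels")
    pages <- lapply(seq_len(dim(volume$labels)[3]), function(k)
      t(volume$labels[, , k]) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16)
  } else stop_carapace("unsupported volume format: ", ext)
  invisible(path)
}

#' @rdname write_label_volume
#' @param voxel_mm,origin spacing/origin override (required for TIFF,
#'   optional for NRRD).
#' @export
read_label_volume <- function(path, voxel_mm = NULL, origin = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "nrrd") {
    con <- file(path, "rb")
    on.exit(close(con))
    hdr <- character(0)
    repeat {
      line <- readLines(con, 1)
      if (!length(line) || line == "") break
      hdr <- c(hdr, line)
    }
    gethdr <- function(key) {
      ln <- grep(paste0("^", key, ": "), hdr, value = TRUE)
      if (!length(ln)) return(NULL)
      strsplit(sub(paste0("^", key, ": "), "", ln[1]), " +")[[1]]
    }
    sizes <- as.integer(gethdr("sizes"))
    spac <- as.numeric(gethdr("spacings") %||% "1 1 1")
    mins <- as.numeric(gethdr("axis mins") %||% "0 0 0")
    enc <- gethdr("encoding")[1]
    n <- prod(sizes)
    vals <- if (identical(enc, "raw")) {
      readBin(con, "integer", n = n, size = 4, endian = "little")
    } else {
      as.integer(scan(con, what = integer(), n = n, quiet = TRUE))
    }
    label_volume(array(vals, dim = sizes),
                 voxel_mm %||% spac, origin %||% mins)
  } else if (ext %in% c("tif", "tiff")) {
    assert_that(!is.null(voxel_mm), "voxel_mm must be given when reading TIFF")
    pages <- tiff::readTIFF(path, all = TRUE)
    arr <- array(0L, dim = c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) arr[, , k] <- as.integer(round(t(pages[[k]]) * 65535))
    label_volume(arr, voxel_mm, origin %||% c(0, 0, 0))
  } else stop_carapace("unsupported volume format: ", ext)
}
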