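# Closed boxfish-like surfaces: a rounded-polygon (or elliptic)
# cross-section swept along the anteroposterior axis with a smooth
# nose/tail taper. This is a 3-parameter shape family (polygon order,
# corner rounding, taper), not a measured outline.

# Unit cross-section boundary: rounded regular n-gon, resampled to
# n_theta points by arc length, then normalized so y and z ranges are
# exactly [-1, 1]. A rounded polygon is the Minkowski sum of a shrunk
# polygon with a disc of radius rounding * inradius; rounding = 1 gives
# a circle exactly.
cross_section_profile <- function(geometry_class, corner_rounding, n_theta) {
  if (geometry_class == "elliptic" || corner_rounding >= 1) {
    th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
    prof <- cbind(cos(th), sin(th))
  } else {
    n <- if (geometry_class == "triangular") 3L else 4L
    phi0 <- if (n == 3L) pi / 2 else pi / 4   # apex dorsal / sides axis-aligned
    r_in <- cos(pi / n)
    rho <- corner_rounding * r_in
    shrink <- 1 - rho / r_in                  # circumradius factor of core polygon
    corners <- phi0 + 2 * pi * (0:(n - 1)) / n
    dense <- list()
    arc_pts <- 64L
    for (k in seq_len(n)) {
      ctr <- shrink * c(cos(corners[k]), sin(corners[k]))
      psi <- seq(corners[k] - pi / n, corners[k] + pi / n, length.out = arc_pts)
      arc <- cbind(ctr[1] + rho * cos(psi), ctr[2] + rho * sin(psi))
      # straight edge toward next corner's arc start
      k2 <- if (k == n) 1L else k + 1L
      ctr2 <- shrink * c(cos(corners[k2]), sin(corners[k2]))
      psi2 <- corners[k2] - pi / n
      p_end <- arc[arc_pts, ]
      p_next <- c(ctr2[1] + rho * cos(psi2), ctr2[2] + rho * sin(psi2))
      tt <- seq(0, 1, length.out = 48L)[-c(1, 48)]
      edge <- cbind(p_end[1] + tt * (p_next[1] - p_end[1]),
                    p_end[2] + tt * (p_next[2] - p_end[2]))
      dense[[2 * k - 1]] <- arc
      dense[[2 * k]] <- edge
    }
    dense <- do.call(rbind, dense)
    # resample uniformly by arc length
    seg <- sqrt(rowSums((dense - dense[c(2:nrow(dense), 1), ])^2))
    s <- cumsum(c(0, seg[-length(seg)]))
    total <- s[length(s)] + seg[length(seg)]
    target <- seq(0, total, length.out = n_theta + 1)[-(n_theta + 1)]
    idx <- findInterval(target, s)
    frac <- (target - s[idx]) / pmax(seg[idx], 1e-12)
    nxt <- ifelse(idx == nrow(dense), 1L, idx + 1L)
    prof <- dense[idx, , drop = FALSE] +
      frac * (dense[nxt, , drop = FALSE] - dense[idx, , drop = FALSE])
  }
  # normalize extents to [-1, 1] in both axes
  prof[, 1] <- 2 * (prof[, 1] - min(prof[, 1])) / diff(range(prof[, 1])) - 1
  prof[, 2] <- 2 * (prof[, 2] - min(prof[, 2])) / diff(range(prof[, 2])) - 1
  prof
}

#' Generate a closed boxfish-like carapace surface
#'
#' Sweeps the spec's cross-section (ellipse or rounded 3-/4-gon) along
#' the anteroposterior (x) axis with an elliptical nose/tail taper,
#' producing a watertight, outward-oriented triangle mesh whose bounding
#' extents match the spec's length/height/width.
#'
#' @param spec a [carapace_spec()].
#' @param n_theta cross-section resolution (default 96).
#' @param n_axial number of axial stations (default 80).
#' @param taper `"ellipsoid"` (smooth closed nose/tail, the default) or
#'   `"none"` (straight prism with flat end caps; used for limiting-case
#'   checks).
#' @param taper_exponent shape of the longitudinal profile
#'   `(1 - |2u-1|^p)^(1/p)`: 2 is an ellipse; values below 2 give a
#'   pointier nose/tail with more uniform meridian curvature along the
#'   mid-body.
#' @return a `carapace_mesh`.
#' @export
generate_surface <- function(spec, n_theta = 96, n_axial = 80,
                             taper = c("ellipsoid", "none"),
                             taper_exponent = 2) {
  assert_that(inherits(spec, "carapace_spec"), "spec must be a carapace_spec")
  taper <- match.arg(taper)
  prof <- cross_section_profile(spec$geometry_class, spec$corner_rounding,
                                n_theta)
  L <- spec$length_mm; H <- spec$height_mm; W <- spec$width_mm
  if (taper == "ellipsoid") {
    # cosine-spaced axial stations cluster rings near the poles
    t <- seq_len(n_axial - 1) / n_axial
    u <- (1 - cos(pi * t)) / 2
    f <- (pmax(0, 1 - abs(2 * u - 1)^taper_exponent))^(1 / taper_exponent)
    x <- (u - 0.5) * L
    nv_ring <- length(x)
    V <- do.call(rbind, lapply(seq_len(nv_ring), function(i)
      cbind(x[i], W / 2 * f[i] * prof[, 1], H / 2 * f[i] * prof[, 2])))
    pole1 <- c(-L / 2, 0, 0)
    pole2 <- c(L / 2, 0, 0)
    V <- rbind(V, pole1, pole2)
    ip1 <- nrow(V) - 1L; ip2 <- nrow(V)
    ring <- function(i) (i - 1L) * n_theta + seq_len(n_theta)
    F <- list()
    for (i in seq_len(nv_ring - 1)) {
      a <- ring(i); b <- ring(i + 1)
      a2 <- c(a[-1], a[1]); b2 <- c(b[-1], b[1])
      F[[i]] <- rbind(cbind(a, b, b2), cbind(a, b2, a2))
    }
    a <- ring(1)
    F[[nv_ring]] <- cbind(ip1, a, c(a[-1], a[1]))
    b <- ring(nv_ring)
    F[[nv_ring + 1]] <- cbind(ip2, c(b[-1], b[1]), b)
    mesh <- new_mesh(V, do.call(rbind, F))
  } else {
    u <- seq(0, 1, length.out = n_axial)
    x <- (u - 0.5) * L
    V <- do.call(rbind, lapply(seq_along(x), function(i)
      cbind(x[i], W / 2 * prof[, 1], H / 2 * prof[, 2])))
    c1 <- c(-L / 2, 0, 0); c2 <- c(L / 2, 0, 0)
    V <- rbind(V, c1, c2)
    ic1 <- nrow(V) - 1L; ic2 <- nrow(V)
    ring <- function(i) (i - 1L) * n_theta + seq_len(n_theta)
    F <- list()
    for (i in seq_len(n_axial - 1)) {
      a <- ring(i); b <- ring(i + 1)
      a2 <- c(a[-1], a[1]); b2 <- c(b[-1], b[1])
      F[[i]] <- rbind(cbind(a, b, b2), cbind(a, b2, a2))
    }
    a <- ring(1)
    F[[n_axial]] <- cbind(ic1, a, c(a[-1], a[1]))
    b <- ring(n_axial)
    F[[n_axial + 1]] <- cbind(ic2, c(b[-1], b[1]), b)
    mesh <- new_mesh(V, do.call(rbind, F))
  }
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  if (!is_watertight(mesh))
    stop_carapace("internal error: generated surface is not watertight")
  mesh
}
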