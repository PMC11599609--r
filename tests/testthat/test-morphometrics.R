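# Per-scute variables and carapace dimensions.

test_that("scute volume is voxel count times voxel volume and is conserved", {
  arr <- array(0L, dim = c(5, 5, 5))
  arr[1:5, 1, 1] <- 1L
  arr[1:5, 2, 1] <- 1L
  vol <- label_volume(arr, 0.1)
  expect_equal(scute_volume(vol, 1), 10 * 0.001)
  # splitting the scute into two labels conserves summed volume exactly
  arr2 <- arr
  arr2[1:5, 2, 1] <- 2L
  vol2 <- label_volume(arr2, 0.1)
  expect_identical(sum(scute_volume(vol2, c(1, 2))), scute_volume(vol, 1))
  expect_error(scute_volume(vol, 7), "absent")
})

test_that("spherical shell scute volume is near the analytic value", {
  m <- icosphere(10, 4)
  p <- tessellate(m, 2, 0, seed = 1, lloyd_iterations = 5)
  sp <- carapace_spec("elliptic", 20.001, 20, 20, base_thickness_mm = 1,
                      voxel_mm = 0.2)
  vol <- voxelize(p, sp)
  v <- sum(scute_volume(vol, c(1, 2)))
  v_true <- 4 / 3 * pi * (1000 - 729)
  expect_lt(abs(v - v_true) / v_true, 0.05)
})

test_that("thickness and width recover an axis-aligned slab", {
  arr <- array(0L, dim = c(24, 14, 6))
  arr[3:22, 3:12, 3:4] <- 1L          # 20 x 10 x 2 voxels at 1 mm
  vol <- label_volume(arr, 1)
  tw <- scute_thickness_width(vol, 1)
  expect_equal(unname(tw["thickness"]), 2, tolerance = 0.5)
  expect_equal(unname(tw["width"]), 20, tolerance = 0.5)
})

test_that("thickness and width recover a rotated slab within half a voxel", {
  # 20 x 10 x 2 mm slab rotated 45 deg about its long axis, re-voxelized
  vox <- 0.25
  th <- pi / 4
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  gr <- expand.grid(x = seq(-12, 12, vox), y = seq(-9, 9, vox),
                    z = seq(-9, 9, vox))
  P <- as.matrix(gr) %*% R           # rotate the grid into slab frame
  inside <- abs(P[, 1]) <= 10 & abs(P[, 2]) <= 5 & abs(P[, 3]) <= 1
  d <- c(length(seq(-12, 12, vox)), length(seq(-9, 9, vox)),
         length(seq(-9, 9, vox)))
  arr <- array(0L, dim = d)
  arr[which(inside)] <- 1L
  vol <- label_volume(arr, vox)
  tw <- scute_thickness_width(vol, 1)
  expect_equal(unname(tw["thickness"]), 2, tolerance = 0.5)
  expect_equal(unname(tw["width"]), 20, tolerance = 0.5)
})

test_that("a solid ball is isotropic: thickness equals width within one voxel", {
  vox <- 0.5
  g <- seq(-6, 6, vox)
  gr <- as.matrix(expand.grid(g, g, g))
  arr <- array(0L, dim = rep(length(g), 3))
  arr[rowSums(gr^2) <= 25] <- 1L
  vol <- label_volume(arr, vox)
  tw <- scute_thickness_width(vol, 1)
  expect_lt(abs(tw["width"] - tw["thickness"]), vox + 1e-9)
  expect_equal(unname(tw["width"]), 10, tolerance = 1)
})

test_that("aspect ratio is thickness over width, bounded by 1", {
  expect_equal(aspect_ratio(2, 20), 0.1)
  expect_equal(aspect_ratio(3, 3), 1)
  expect_error(aspect_ratio(1, 0), "positive")
  fx <- small_specimen()
  rec <- fx$measured$records
  expect_true(all(rec$aspect_ratio > 0 & rec$aspect_ratio <= 1))
})

test_that("curvatures match closed forms on sphere, plane and cylinder", {
  # sphere radius 2: CGS = 1/4, CMS = 1/2
  sph <- icosphere(2, 4)
  q <- sph$vertices[seq(1, nrow(sph$vertices), length.out = 15), ] * 0.999
  cv <- surface_curvatures(sph, centers = q, radius = 0.5)
  expect_lt(max(abs(cv$cgs - 0.25) / 0.25), 0.05)
  expect_lt(max(abs(cv$cms - 0.5) / 0.5), 0.05)
  # plane: both zero
  nvx <- 41
  gx <- expand.grid(x = seq(-5, 5, 0.25), y = seq(-5, 5, 0.25))
  vid <- function(i, j) (j - 1) * nvx + i
  fr <- list()
  for (j in 1:(nvx - 1)) for (i in 1:(nvx - 1))
    fr[[length(fr) + 1]] <- rbind(c(vid(i, j), vid(i + 1, j), vid(i + 1, j + 1)),
                                  c(vid(i, j), vid(i + 1, j + 1), vid(i, j + 1)))
  pm <- new_mesh(cbind(gx$x, gx$y, 0), do.call(rbind, fr))
  cvp <- surface_curvatures(pm, centers = rbind(c(0, 0, 0), c(1, 1, 0)),
                            radius = 2)
  expect_lt(max(abs(cvp$cgs)), 1e-6)
  expect_lt(max(abs(cvp$cms)), 1e-6)
  # cylinder radius 1: CGS ~ 0, CMS = 1/2, convex positive
  nt <- 144
  thg <- seq(0, 2 * pi, length.out = nt + 1)[-(nt + 1)]
  xs <- seq(-4, 4, 0.1)
  Vc <- do.call(rbind, lapply(xs, function(x) cbind(x, cos(thg), sin(thg))))
  fcy <- list()
  for (i in 1:(length(xs) - 1)) {
    a <- (i - 1) * nt + 1:nt; b <- i * nt + 1:nt
    a2 <- c(a[-1], a[1]); b2 <- c(b[-1], b[1])
    fcy[[i]] <- rbind(cbind(a, b2, b), cbind(a, a2, b2))
  }
  cm <- new_mesh(Vc, do.call(rbind, fcy))
  cvc <- surface_curvatures(cm, centers = rbind(c(0, 1, 0), c(1, 0, 1)),
                            radius = 0.45)
  expect_lt(max(abs(cvc$cgs)), 0.025)
  expect_lt(max(abs(cvc$cms - 0.5) / 0.5), 0.05)
})

test_that("carapace dimensions recover analytic extents and rotation invariance", {
  expect_equal(
    unname(carapace_dimensions(rbind(c(0, 0, 0), c(30, 0, 0)))),
    c(30, 0, 0))
  set.seed(1)
  u <- matrix(rnorm(6000), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  E <- sweep(u, 2, c(50, 30, 20), "*")   # ellipsoid surface, semi-axes 50/30/20
  d0 <- carapace_dimensions(E, dorsoventral = c(0, 1, 0))
  expect_equal(unname(d0), c(100, 60, 40), tolerance = 0.02)
  th <- 0.61
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  d1 <- carapace_dimensions(E %*% t(R), dorsoventral = NULL)
  d0b <- suppressWarnings(carapace_dimensions(E, dorsoventral = NULL))
  expect_warning(carapace_dimensions(E, dorsoventral = NULL), "height")
  expect_equal(unname(d1), unname(d0b), tolerance = 1e-6)
})

test_that("area flag -1000 marks exactly the opening-bordering scutes", {
  fx <- small_specimen()
  rec <- fx$measured$records
  surf <- fx$measured$surface
  expect_identical(rec$area == MISSING_FLAG, rec$is_opening_scute)
  expect_identical(unname(rec$area == MISSING_FLAG),
                   unname(!surf$fully_surrounded[as.character(rec$scute_id)]))
  # patches cover at most the full surface
  ok <- rec$area != MISSING_FLAG
  expect_lte(sum(rec$area[ok]), surface_area(surf) + 1e-6)
  expect_gt(sum(rec$is_opening_scute), 0)
})

test_that("measured variables scale as their physical dimensions", {
  # two geometrically similar specimens, scale factor 2
  sp1 <- carapace_spec("tetragonal", 50, 24, 22, n_scutes = 150,
                       n_openings = 0, seed = 33)
  sp2 <- carapace_spec("tetragonal", 100, 48, 44, n_scutes = 150,
                       n_openings = 0, seed = 33)
  o1 <- synthesize_carapace(sp1, plant_types = FALSE, thickness_noise_sd = 0,
                            mesh_res = list(n_theta = 96, n_axial = 80))
  o2 <- synthesize_carapace(sp2, plant_types = FALSE, thickness_noise_sd = 0,
                            mesh_res = list(n_theta = 96, n_axial = 80))
  m1 <- measure_scutes(o1$volume, "s1")
  m2 <- measure_scutes(o2$volume, "s2")
  s <- 2
  expect_equal(median(m2$records$volume) / median(m1$records$volume), s^3,
               tolerance = 0.15)
  a1 <- m1$records$area[m1$records$area != MISSING_FLAG]
  a2 <- m2$records$area[m2$records$area != MISSING_FLAG]
  expect_equal(median(a2) / median(a1), s^2, tolerance = 0.12)
  expect_equal(median(m2$records$thickness) / median(m1$records$thickness), s,
               tolerance = 0.1)
  expect_equal(median(m2$records$width) / median(m1$records$width), s,
               tolerance = 0.1)
  expect_equal(median(m2$records$aspect_ratio) / median(m1$records$aspect_ratio),
               1, tolerance = 0.1)
  expect_equal(median(m2$records$cgs, na.rm = TRUE) /
                 median(m1$records$cgs, na.rm = TRUE), s^-2, tolerance = 0.2)
  expect_equal(median(m2$records$cms, na.rm = TRUE) /
                 median(m1$records$cms, na.rm = TRUE), s^-1, tolerance = 0.12)
  expect_equal(m2$summary$surface_area / m1$summary$surface_area, s^2,
               tolerance = 0.05)
})
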