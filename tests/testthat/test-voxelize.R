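# Voxelization of surface partitions into shell label fields.

test_that("single-scute sphere shell volume matches the analytic value", {
  m <- icosphere(10, 4)
  p <- tessellate(m, 2, 0, seed = 1, lloyd_iterations = 5)
  # treat both regions as one scute pair covering the sphere
  sp <- carapace_spec("elliptic", 20.001, 20, 20, n_scutes = 2, n_openings = 0,
                      base_thickness_mm = 1, voxel_mm = 0.2)
  vol <- voxelize(p, sp)
  v_total <- sum(scute_volume(vol, c(1, 2)))
  v_true <- 4 / 3 * pi * (10^3 - 9^3)
  expect_lt(abs(v_total - v_true) / v_true, 0.05)
})

test_that("uniform thickness yields uniform measured thickness", {
  fx <- small_specimen()
  sp <- fx$obj$spec
  part <- fx$obj$partition
  vol <- voxelize(part, sp)    # default: base thickness everywhere
  tw <- carapace:::thickness_width_all(vol)
  # voxelization tolerance: thickness spread small relative to median
  expect_lt(mad(tw$thickness) / median(tw$thickness), 0.2)
})

test_that("edge thickening doubles the measured thickness of edge scutes", {
  sp <- carapace_spec("tetragonal", 60, 28, 26, n_scutes = 220, n_openings = 0,
                      edge_thickness_factor = 2, seed = 21)
  obj <- synthesize_carapace(sp, plant_types = FALSE, thickness_noise_sd = 0,
                             mesh_res = list(n_theta = 96, n_axial = 80))
  vol <- obj$volume
  tw <- carapace:::thickness_width_all(vol)
  # compare against the generator's own thickness field
  thick_true <- obj$truth$thickness_mm[match(tw$scute_id, obj$truth$scute_id)]
  edge <- thick_true > 1.5 * sp$base_thickness_mm
  expect_gt(sum(edge), 10)
  ratio <- median(tw$thickness[edge]) / median(tw$thickness[!edge])
  expect_lt(abs(ratio - 2), 0.3)
})

test_that("coarse voxel resolution is rejected with a message", {
  m <- icosphere(5, 2)
  p <- tessellate(m, 10, 0, seed = 1, lloyd_iterations = 3)
  sp <- carapace_spec("elliptic", 10.001, 10, 10, base_thickness_mm = 0.5,
                      voxel_mm = 0.4)
  expect_error(voxelize(p, sp), "resolution too coarse")
})

test_that("label volumes round-trip through NRRD and TIFF bit-exactly", {
  arr <- array(0L, dim = c(7, 6, 5))
  arr[2:4, 2:4, 2:3] <- 3L
  arr[5:6, 1:2, 4] <- 12L
  vol <- label_volume(arr, c(0.2, 0.2, 0.3), origin = c(-1, 0, 2))
  for (enc in c("raw", "ascii")) {
    f <- tempfile(fileext = ".nrrd")
    write_label_volume(vol, f, encoding = enc)
    back <- read_label_volume(f)
    expect_identical(back$labels, vol$labels)
    expect_equal(back$voxel_mm, vol$voxel_mm)
    expect_equal(back$origin, vol$origin)
    unlink(f)
  }
  f <- tempfile(fileext = ".tif")
  write_label_volume(vol, f)
  back <- read_label_volume(f, voxel_mm = c(0.2, 0.2, 0.3))
  expect_identical(back$labels, vol$labels)
  unlink(f)
})
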