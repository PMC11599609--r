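# Parametric description of a synthetic boxfish carapace. The three
# geometry classes follow the simplified cross-sections seen across
# Ostracioidea: elliptic (Aracana-like), triangular (Tetrosomus-like,
# apex dorsal) and tetragonal (Ostracion-like, flat sides).

#' Specify a synthetic carapace
#'
#' @param geometry_class one of `"elliptic"`, `"triangular"`, `"tetragonal"`.
#' @param length_mm,height_mm,width_mm carapace extents (mm). Boxfish are
#'   longer than tall or wide; a spec violating that is accepted with a
#'   warning.
#' @param corner_rounding fraction in (0, 1] controlling how sharp the
#'   cross-section's edges are: 1 collapses the rounded polygon to an
#'   ellipse, values near 0 approach a sharp-cornered polygon.
#' @param n_scutes number of scutes to tessellate the surface into.
#' @param n_openings number of carapace openings (eye/fin/gill gaps);
#'   must stay below `n_scutes / 10`.
#' @param edge_thickness_factor multiplier (>= 1) applied to scute
#'   thickness in high-curvature zones, mimicking the thickened edge
#'   scutes of real carapaces.
#' @param base_thickness_mm scute shell thickness in flat regions (mm).
#' @param voxel_mm isotropic voxel spacing of the label field (mm); must
#'   resolve the base thickness with at least 2 voxels.
#' @param seed integer seed controlling all stochastic generation steps.
#' @return an object of class `carapace_spec`.
#' @export
carapace_spec <- function(geometry_class = c("elliptic", "triangular", "tetragonal"),
                          length_mm = 60, height_mm = 30, width_mm = 28,
                          corner_rounding = 0.35,
                          n_scutes = 450, n_openings = 7,
                          edge_thickness_factor = 1.9,
                          base_thickness_mm = 0.013 * length_mm,
                          voxel_mm = base_thickness_mm / 3,
                          seed = 42) {
  geometry_class <- match.arg(geometry_class)
  for (v in c(length_mm, height_mm, width_mm, base_thickness_mm, voxel_mm))
    assert_that(is.numeric(v) && length(v) == 1 && is.finite(v) && v > 0,
                "carapace dimensions, thickness and voxel size must be positive")
  assert_that(corner_rounding > 0 && corner_rounding <= 1,
              "corner_rounding must lie in (0, 1]")
  assert_that(n_scutes >= 1 && n_scutes == round(n_scutes),
              "n_scutes must be a positive integer")
  assert_that(n_openings >= 0 && n_openings == round(n_openings),
              "n_openings must be a non-negative integer")
  assert_that(n_openings < n_scutes / 10,
              "n_openings must be below n_scutes / 10")
  assert_that(edge_thickness_factor >= 1,
              "edge_thickness_factor must be >= 1")
  if (length_mm < height_mm || length_mm < width_mm)
    warning("unusual proportions: carapace length below height or width")
  structure(list(
    geometry_class = geometry_class,
    length_mm = length_mm, height_mm = height_mm, width_mm = width_mm,
    corner_rounding = corner_rounding,
    n_scutes = as.integer(n_scutes), n_openings = as.integer(n_openings),
    edge_thickness_factor = edge_thickness_factor,
    base_thickness_mm = base_thickness_mm,
    voxel_mm = voxel_mm, seed = as.integer(seed)
  ), class = "carapace_spec")
}

#' @export
print.carapace_spec <- function(x, ...) {
  cat(sprintf(
    "<carapace_spec> %s, L x H x W = %.3g x %.3g x %.3g mm, %d scutes, %d openings\n",
    x$geometry_class, x$length_mm, x$height_mm, x$width_mm,
    x$n_scutes, x$n_openings))
  invisible(x)
}

#' Write / read a carapace spec as YAML
#' @param spec a `carapace_spec`.
#' @param path file path.
#' @export
write_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_spec
#' @export
read_spec <- function(path) {
  do.call(carapace_spec, yaml::read_yaml(path))
}
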