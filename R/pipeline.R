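# End-to-end orchestration: simulate or load specimens, measure scutes,
# run the scaling, region, shape-frequency and clustering analyses, and
# write a reproducible report bundle.

#' Measure every specimen of a synthetic batch
#'
#' @param batch list of specimen objects from [simulate_batch()] or
#'   [simulate_isometric_batch()].
#' @return list with `records` (stacked per-scute tibble, standard schema plus
#'   planted `type` when available), `specimens` (per-specimen summary
#'   tibble with geometry_class) and `surfaces` (named list).
#' @export
measure_batch <- function(batch) {
  recs <- list(); sums <- list(); surfaces <- list()
  for (obj in batch) {
    m <- measure_scutes(obj$volume, obj$specimen_id)
    rec <- m$records
    if (!is.null(obj$truth$type) && !all(is.na(obj$truth$type)))
      rec$type <- obj$truth$type[match(rec$scute_id, obj$truth$scute_id)]
    recs[[obj$specimen_id]] <- rec
    s <- m$summary
    s$geometry_class <- obj$geometry_class %||% NA_character_
    sums[[obj$specimen_id]] <- s
    surfaces[[obj$specimen_id]] <- m$surface
  }
  list(records = dplyr::bind_rows(recs),
       specimens = dplyr::bind_rows(sums),
       surfaces = surfaces)
}

#' Full scaling / region / shape / cluster analysis of a measured batch
#'
#' Reproduces the complete statistical pipeline on a per-scute table
#' plus per-specimen summaries: fits the CGS/CMS exponents, normalizes
#' curvature, classifies edge vs flat regions (normalized CGS >=
#' `cgs_threshold`), fits the scaling table, computes shape frequencies,
#' prepares the scute matrix, and runs PCA + Ward clustering.
#'
#' @param records per-scute tibble (standard schema).
#' @param specimens per-specimen tibble (specimen, surface_area, length,
#'   height, width, n_scutes, geometry_class).
#' @param cgs_threshold edge/flat threshold on normalized CGS (default 5).
#' @param k number of scute clusters (default 5).
#' @param outlier_mads outlier rule for [prepare_matrix()] (default 8).
#' @return list with elements `exponents`, `records` (with region
#'   column), `scaling_table`, `residuals_by_geometry`,
#'   `shape_frequencies`, `matrix`, `pca`, `clusters`, `summaries`,
#'   `interaction_pvalues`.
#' @export
analyze_batch <- function(records, specimens, cgs_threshold = 5, k = 5,
                          outlier_mads = 8) {
  sa <- setNames(specimens$surface_area, specimens$specimen)
  rec <- records
  # normalized curvature and region classification
  med <- rec %>% dplyr::group_by(specimen) %>%
    dplyr::summarise(cgs = median(cgs, na.rm = TRUE),
                     cms = median(cms, na.rm = TRUE), .groups = "drop")
  sa_med <- sa[med$specimen]
  fit_cgs <- fit_loglog(sa_med, med$cgs, "cgs")
  fit_cms <- fit_loglog(sa_med, med$cms, "cms")
  rec$normalized_cgs <- normalize_by_sa(rec$cgs, sa[rec$specimen], fit_cgs$slope)
  rec$normalized_cms <- normalize_by_sa(rec$cms, sa[rec$specimen], fit_cms$slope)
  cls <- classify_region(rec$normalized_cgs, threshold = cgs_threshold,
                         scute_id = seq_len(nrow(rec)))
  rec$region <- NA_character_
  rec$region[cls$scute_id] <- cls$region
  scaling <- fit_scaling_table(specimens, rec)
  # residuals of carapace dimensions by geometry class
  res_geo <- list()
  if (!all(is.na(specimens$geometry_class))) {
    for (v in c("length", "height", "width")) {
      f <- fit_loglog(specimens$surface_area, specimens[[v]], v)
      res_geo[[v]] <- residuals_by_geometry(f, specimens$geometry_class)
    }
  }
  shapes <- shape_frequencies(rec)
  M <- prepare_matrix(rec, sa, outlier_mads = outlier_mads)
  pca <- run_pca(M)
  clus <- hierarchical_clusters(pca$scores, k = k)
  summaries <- cluster_summaries(clus, M)
  # region-interaction tests per scute dimension
  ipv <- c()
  for (v in c("volume", "area", "width", "thickness", "aspect_ratio")) {
    sub <- rec[!is.na(rec$region) & rec[[v]] != MISSING_FLAG, ]
    mm <- aggregate(sub[[v]], list(specimen = sub$specimen,
                                   region = sub$region), median)
    names(mm)[3] <- "v"
    wide <- split(mm, mm$region)
    if (length(wide) == 2 &&
        all(specimens$specimen %in% wide$flat$specimen) &&
        all(specimens$specimen %in% wide$edge$specimen)) {
      yf <- wide$flat$v[match(specimens$specimen, wide$flat$specimen)]
      ye <- wide$edge$v[match(specimens$specimen, wide$edge$specimen)]
      ipv[v] <- tryCatch(
        region_interaction_test(specimens$surface_area, yf, ye),
        error = function(e) NA_real_)
    } else ipv[v] <- NA_real_
  }
  list(exponents = attr(M, "exponents"),
       records = rec,
       scaling_table = scaling,
       residuals_by_geometry = res_geo,
       shape_frequencies = shapes,
       matrix = M, pca = pca, clusters = clus, summaries = summaries,
       interaction_pvalues = ipv)
}

#' Read / write per-scute tables in the standard per-scute schema
#'
#' Canonical columns: specimen, scute_id, x, y, z, n_neighbors, volume,
#' area, thickness, width, aspect_ratio, cgs, cms. A column mapping
#' adapts files with different headers.
#'
#' @param path CSV path.
#' @param column_map optional named character vector mapping canonical
#'   names to the file's actual headers.
#' @return tibble in canonical schema (plus `is_opening_scute`).
#' @export
read_scute_table <- function(path, column_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  canon <- c("specimen", "scute_id", "x", "y", "z", "n_neighbors", "volume",
             "area", "thickness", "width", "aspect_ratio", "cgs", "cms")
  if (!is.null(column_map)) {
    for (nm in names(column_map)) {
      if (!column_map[[nm]] %in% names(df))
        stop_carapace("mapped column not found: ", column_map[[nm]])
      names(df)[names(df) == column_map[[nm]]] <- nm
    }
  }
  missing <- setdiff(canon, names(df))
  if (length(missing))
    stop_carapace("scute table lacks column(s): ", paste(missing, collapse = ", "))
  out <- tibble::as_tibble(df[, intersect(c(canon, "region", "type"), names(df))])
  out$is_opening_scute <- out$area == MISSING_FLAG
  out
}

#' @rdname read_scute_table
#' @param records per-scute tibble.
#' @export
write_scute_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Run configuration for the end-to-end pipeline
#'
#' @param input_mode one of `"synthetic"`, `"scute_table"`,
#'   `"label_volume"`.
#' @param out_dir output directory for the report bundle.
#' @param seed batch seed.
#' @param n_specimens synthetic batch size.
#' @param scute_table path to a standard-schema CSV (mode `"scute_table"`);
#'   must contain per-specimen SA either as a `surface_area` column or
#'   via `specimen_table`.
#' @param specimen_table optional CSV with per-specimen surface_area,
#'   length, height, width, n_scutes, geometry_class.
#' @param label_volumes named character vector of volume files (mode
#'   `"label_volume"`).
#' @param column_map passed to [read_scute_table()].
#' @param cgs_threshold,k,outlier_mads,min_contact analysis options.
#' @param batch_args extra arguments for [simulate_batch()] in synthetic
#'   mode (e.g. `length_range`, `scute_range`).
#' @return a `run_config`.
#' @export
run_config <- function(input_mode = c("synthetic", "scute_table", "label_volume"),
                       out_dir = tempfile("carapace_run_"), seed = 42,
                       n_specimens = 13, scute_table = NULL,
                       specimen_table = NULL, label_volumes = NULL,
                       column_map = NULL, cgs_threshold = 5, k = 5,
                       outlier_mads = 8, min_contact = 1,
                       batch_args = list()) {
  input_mode <- match.arg(input_mode)
  if (input_mode == "scute_table")
    assert_that(file.exists(scute_table %||% ""), "scute_table file not found")
  if (input_mode == "label_volume")
    assert_that(all(file.exists(label_volumes %||% "")),
                "label volume file(s) not found")
  structure(list(input_mode = input_mode, out_dir = out_dir, seed = seed,
                 n_specimens = n_specimens, scute_table = scute_table,
                 specimen_table = specimen_table,
                 label_volumes = label_volumes, column_map = column_map,
                 cgs_threshold = cgs_threshold, k = k,
                 outlier_mads = outlier_mads, min_contact = min_contact,
                 batch_args = batch_args),
            class = "run_config")
}

#' Run the complete pipeline and write the report bundle
#'
#' Stages: obtain per-scute records (simulate + measure, load a scute
#' table, or measure label volumes), analyze (scaling, regions, shape
#' frequencies, PCA + clustering), and write all outputs plus a
#' machine-readable manifest. Outputs are deterministic given the
#' config.
#'
#' @param config a [run_config()].
#' @return (invisibly) the analysis list from [analyze_batch()], with
#'   `out_dir` attached.
#' @export
run_pipeline <- function(config) {
  assert_that(inherits(config, "run_config"), "config must be a run_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "input"
  res <- tryCatch({
    if (config$input_mode == "synthetic") {
      batch <- do.call(simulate_batch,
                       c(list(n = config$n_specimens, seed = config$seed),
                         config$batch_args))
      mb <- measure_batch(batch)
      records <- mb$records; specimens <- mb$specimens
    } else if (config$input_mode == "scute_table") {
      records <- read_scute_table(config$scute_table, config$column_map)
      if (!is.null(config$specimen_table)) {
        specimens <- tibble::as_tibble(utils::read.csv(config$specimen_table))
      } else {
        assert_that("surface_area" %in% names(records),
                    "scute table must carry surface_area or a specimen_table must be given")
        specimens <- records %>% dplyr::group_by(specimen) %>%
          dplyr::summarise(surface_area = surface_area[1],
                           n_scutes = dplyr::n(), .groups = "drop")
        dims <- do.call(rbind, lapply(split(records, records$specimen),
                                      carapace_dimensions))
        specimens$length <- dims[specimens$specimen, "length"]
        specimens$height <- dims[specimens$specimen, "height"]
        specimens$width <- dims[specimens$specimen, "width"]
        specimens$geometry_class <- NA_character_
      }
    } else {
      mb <- list()
      recs <- list(); sums <- list()
      for (nm in names(config$label_volumes)) {
        vol <- read_label_volume(config$label_volumes[[nm]])
        m <- measure_scutes(vol, nm, min_contact = config$min_contact)
        recs[[nm]] <- m$records; sums[[nm]] <- m$summary
      }
      records <- dplyr::bind_rows(recs)
      specimens <- dplyr::bind_rows(sums)
      specimens$geometry_class <- NA_character_
    }
    stage <- "analyze"
    ana <- analyze_batch(records, specimens,
                         cgs_threshold = config$cgs_threshold, k = config$k,
                         outlier_mads = config$outlier_mads)
    stage <- "report"
    od <- config$out_dir
    write_scute_table(ana$records, file.path(od, "scute_records.csv"))
    utils::write.csv(specimens, file.path(od, "specimen_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(ana$scaling_table, file.path(od, "scaling_table.csv"),
                     row.names = FALSE)
    utils::write.csv(ana$shape_frequencies,
                     file.path(od, "shape_frequencies.csv"), row.names = FALSE)
    for (v in names(ana$residuals_by_geometry))
      utils::write.csv(ana$residuals_by_geometry[[v]]$residuals,
                       file.path(od, sprintf("residuals_%s.csv", v)),
                       row.names = FALSE)
    utils::write.csv(
      tibble::tibble(row = seq_len(nrow(ana$pca$scores))) %>%
        dplyr::bind_cols(tibble::as_tibble(ana$pca$scores)),
      file.path(od, "pc_scores.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(ana$pca$loadings),
                     file.path(od, "pc_loadings.csv"))
    utils::write.csv(
      tibble::tibble(specimen = attr(ana$matrix, "specimen"),
                     scute_id = attr(ana$matrix, "scute_id"),
                     cluster = ana$clusters$assignment),
      file.path(od, "cluster_assignments.csv"), row.names = FALSE)
    utils::write.csv(ana$summaries$variable_stats,
                     file.path(od, "cluster_variable_stats.csv"),
                     row.names = FALSE)
    utils::write.csv(ana$summaries$specimen_frequencies,
                     file.path(od, "cluster_frequencies.csv"),
                     row.names = FALSE)
    write_cluster_tree(ana$clusters, file.path(od, "cluster_tree.nwk"))
    manifest <- list(
      package_version = as.character(utils::packageVersion("carapace")),
      r_version = as.character(getRversion()),
      config = unclass(config),
      exponents = as.list(ana$exponents),
      interaction_pvalues = as.list(ana$interaction_pvalues))
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    ana
  }, error = function(e) {
    stop_carapace(sprintf("pipeline failed at stage '%s': %s", stage,
                          conditionMessage(e)))
  })
  attr(res, "out_dir") <- config$out_dir
  invisible(res)
}

#' Export a mesh color-coded by a per-scute variable
#'
#' Writes a PLY whose faces carry the (optionally normalized) value of
#' one scute variable, for surface renderings of the tessellation.
#' Values outside `range` are clamped (the number of clamped scutes is
#' reported); opening scutes without a computable value carry the
#' sentinel -1000.
#'
#' @param surface a `carapace_surface`.
#' @param records per-scute tibble for this specimen.
#' @param variable column of `records` to export.
#' @param path output PLY path.
#' @param normalization optional `SA^slope` divisor: list with `sa` and
#'   `slope`.
#' @param range optional c(lo, hi) color-scale clamp.
#' @return (invisibly) the path; attribute `n_clamped` reports clamping.
#' @export
export_colored_mesh <- function(surface, records, variable, path,
                                normalization = NULL, range = NULL) {
  assert_that(variable %in% names(records),
              paste("unknown variable:", variable))
  vals <- records[[variable]]
  if (!is.null(normalization))
    vals <- ifelse(vals == MISSING_FLAG, MISSING_FLAG,
                   normalize_by_sa(vals, normalization$sa, normalization$slope))
  n_clamped <- 0L
  if (!is.null(range)) {
    ok <- vals != MISSING_FLAG & !is.na(vals)
    n_clamped <- sum(ok & (vals < range[1] | vals > range[2]))
    vals[ok] <- pmin(pmax(vals[ok], range[1]), range[2])
  }
  nf <- nrow(surface$mesh$faces)
  face_val <- rep(MISSING_FLAG, nf)
  face_lab <- rep(0L, nf)
  for (i in seq_len(nrow(records))) {
    p <- surface$scute_patch[[as.character(records$scute_id[i])]]
    if (!is.null(p)) {
      face_val[p] <- if (is.na(vals[i])) MISSING_FLAG else vals[i]
      face_lab[p] <- records$scute_id[i]
    }
  }
  write_ply(surface$mesh, path,
            face_props = data.frame(scute = face_lab, value = face_val))
  out <- invisible(path)
  attr(out, "n_clamped") <- n_clamped
  out
}
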