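# Covariation and cluster analysis of scute variables: filtering,
# size-normalization, shift-log transform, outlier removal,
# standardization, PCA, and Ward hierarchical clustering on the PC
# scores (HCPC-style).

CLUSTER_VARS <- c("n_neighbors", "volume", "area", "thickness", "width",
                  "aspect_ratio", "cgs", "cms")

#' Prepare the scute matrix for PCA and clustering
#'
#' Filtering and transformation pipeline: (i) drop scutes whose area is
#' missing (-1000) or zero; (ii) normalize each dimensioned variable by
#' SA^slope; (iii) natural-log transform all variables except the number
#' of neighbors, shifting the two curvature columns by their minimum
#' plus 0.001 so the log is finite; (iv) drop extreme outliers (any
#' transformed value beyond median +/- `outlier_mads` * MAD); (v)
#' standardize columns to mean 0, sd 1.
#'
#' @param records per-scute tibble (standard schema).
#' @param sa_by_specimen named vector of carapace surface areas, names =
#'   specimen ids.
#' @param exponents named vector of scaling exponents used for
#'   normalization (names among volume, area, thickness, width,
#'   aspect_ratio, cgs, cms). By default they are fitted from the data
#'   at hand via per-specimen medians.
#' @param outlier_mads robust outlier cutoff in MAD units (default 8;
#'   set to Inf to keep all rows).
#' @return a `scute_matrix`: standardized numeric matrix with attributes
#'   `specimen`, `scute_id`, `dropped` (tibble of dropped rows with
#'   flags area_missing / area_zero / curvature_missing / outlier) and
#'   `exponents`.
#' @export
prepare_matrix <- function(records, sa_by_specimen, exponents = NULL,
                           outlier_mads = 8) {
  assert_that(all(CLUSTER_VARS %in% names(records)),
              "records is missing scute variable columns")
  rec <- records
  no_sa <- !(rec$specimen %in% names(sa_by_specimen))
  if (any(no_sa)) {
    warning(sprintf("%d scute(s) from specimen(s) without SA excluded: %s",
                    sum(no_sa),
                    paste(unique(rec$specimen[no_sa]), collapse = ", ")))
    rec <- rec[!no_sa, ]
  }
  dropped <- tibble::tibble(specimen = character(0), scute_id = integer(0),
                            flag = character(0))
  flag_rows <- function(sel, flag) {
    if (any(sel)) {
      dropped <<- dplyr::bind_rows(dropped, tibble::tibble(
        specimen = as.character(rec$specimen[sel]),
        scute_id = rec$scute_id[sel], flag = flag))
      rec <<- rec[!sel, ]
    }
  }
  flag_rows(rec$area == MISSING_FLAG, "area_missing")
  flag_rows(rec$area == 0, "area_zero")
  flag_rows(is.na(rec$cgs) | is.na(rec$cms), "curvature_missing")

  sa <- sa_by_specimen[as.character(rec$specimen)]
  if (is.null(exponents)) {
    vars <- setdiff(CLUSTER_VARS, "n_neighbors")
    specs <- sort(unique(as.character(rec$specimen)))
    sa_med <- sa_by_specimen[specs]
    exponents <- vapply(vars, function(v) {
      med <- tapply(rec[[v]], factor(as.character(rec$specimen), specs),
                    median, na.rm = TRUE)
      fit_loglog(sa_med, as.numeric(med), v)$slope
    }, numeric(1))
  }
  M <- matrix(NA_real_, nrow(rec), length(CLUSTER_VARS),
              dimnames = list(NULL, CLUSTER_VARS))
  M[, "n_neighbors"] <- rec$n_neighbors
  for (v in setdiff(CLUSTER_VARS, "n_neighbors")) {
    x <- normalize_by_sa(rec[[v]], sa, exponents[[v]])
    if (v %in% c("cgs", "cms")) {
      x <- x - min(x) + 0.001       # shift so the minimum maps to 0.001
    }
    M[, v] <- log(x)
  }
  if (is.finite(outlier_mads)) {
    out <- rep(FALSE, nrow(M))
    for (v in colnames(M)) {
      md <- median(M[, v]); s <- mad(M[, v])
      if (s > 0) out <- out | abs(M[, v] - md) > outlier_mads * s
    }
    if (any(out)) {
      dropped <- dplyr::bind_rows(dropped, tibble::tibble(
        specimen = as.character(rec$specimen[out]),
        scute_id = rec$scute_id[out], flag = "outlier"))
      rec <- rec[!out, ]
      M <- M[!out, , drop = FALSE]
    }
  }
  M <- scale(M)
  attr(M, "scaled:center") <- NULL; attr(M, "scaled:scale") <- NULL
  structure(M, specimen = as.character(rec$specimen),
            scute_id = rec$scute_id, dropped = dropped,
            exponents = exponents, class = c("scute_matrix", "matrix"))
}

#' Principal component analysis of the scute matrix
#'
#' Eigen-decomposition of the standardized matrix. Loadings are reported
#' as variable-PC Pearson correlations; each PC's sign is fixed so its
#' largest-magnitude loading is positive.
#'
#' @param matrix a `scute_matrix` (standardized).
#' @return list with `scores`, `loadings` (correlations), and
#'   `variance_explained` (percent, sums to 100).
#' @export
run_pca <- function(matrix) {
  M <- unclass(matrix)
  attributes(M)[setdiff(names(attributes(M)), "dim")] <- NULL
  dimnames(M) <- list(NULL, colnames(matrix))
  pc <- prcomp(M, center = FALSE, scale. = FALSE)
  if (min(pc$sdev) < 1e-10)
    warning("rank-deficient matrix; some components have zero variance")
  # correlation loadings: rotation * sdev (columns standardized, unit sd)
  load <- sweep(pc$rotation, 2, pc$sdev, "*")
  flip <- apply(load, 2, function(l) l[which.max(abs(l))] < 0)
  pc$x[, flip] <- -pc$x[, flip]
  load[, flip] <- -load[, flip]
  list(scores = pc$x,
       loadings = load,
       variance_explained = 100 * pc$sdev^2 / sum(pc$sdev^2))
}

#' Pairwise Pearson correlations of the scute variables
#'
#' @param matrix a `scute_matrix` (or any numeric matrix).
#' @return list with `correlations` (symmetric coefficient table) and
#'   `scatter` (the column data for pairwise scatterplots).
#' @export
correlation_panel <- function(matrix) {
  M <- unclass(matrix)
  attributes(M)[setdiff(names(attributes(M)), c("dim", "dimnames"))] <- NULL
  list(correlations = cor(M), scatter = tibble::as_tibble(M))
}

#' Hierarchical clustering on principal component scores
#'
#' Ward-linkage agglomeration on the PC scores, cut at `k` clusters
#' (HCPC-style). Per-merge heights are reported so the relative
#' branch-length criterion for choosing k can be inspected. An optional
#' k-means consolidation pass (off by default) refines assignments from
#' the cluster centroids.
#'
#' @param scores PC score matrix (or the list from [run_pca()]).
#' @param k number of clusters (default 5).
#' @param consolidate run a k-means refinement from the hierarchical
#'   centroids (default FALSE).
#' @return a `cluster_model`: assignment, tree (`hclust`), merge
#'   heights, k, scores.
#' @export
hierarchical_clusters <- function(scores, k = 5, consolidate = FALSE) {
  if (is.list(scores) && !is.data.frame(scores)) scores <- scores$scores
  scores <- as.matrix(scores)
  assert_that(k >= 1 && k <= nrow(scores), "k must be between 1 and n")
  tree <- hclust(dist(scores), method = "ward.D2")
  assignment <- cutree(tree, k = k)
  if (consolidate && k > 1) {
    ctr <- do.call(rbind, lapply(seq_len(k), function(cl)
      colMeans(scores[assignment == cl, , drop = FALSE])))
    km <- kmeans(scores, centers = ctr, iter.max = 50)
    assignment <- km$cluster
  }
  structure(list(assignment = assignment, tree = tree,
                 heights = tree$height, k = k, scores = scores),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> %d scutes in %d clusters (sizes: %s)\n",
              length(x$assignment), x$k,
              paste(tabulate(x$assignment, x$k), collapse = ", ")))
  invisible(x)
}

#' Serialize the linkage tree as newick
#' @param model a `cluster_model`.
#' @param path output file.
#' @export
write_cluster_tree <- function(model, path) {
  ape::write.tree(ape::as.phylo(model$tree), path)
  invisible(path)
}

#' Per-cluster summaries and per-specimen cluster frequencies
#'
#' Boxplot statistics of every standardized variable per cluster (the
#' unit is the global standard deviation, so clusters with |mean z| > 2
#' are flagged as outlier clusters), plus per-specimen cluster counts
#' and proportions.
#'
#' @param model a `cluster_model`.
#' @param matrix the `scute_matrix` the model was built from.
#' @return list with `variable_stats` (cluster, variable, min, q25,
#'   median, q75, max, mean, outlier_cluster), `specimen_frequencies`
#'   (specimen, cluster, count, proportion) and `cluster_sizes`.
#' @export
cluster_summaries <- function(model, matrix) {
  asg <- model$assignment
  M <- unclass(matrix)
  vars <- colnames(matrix)
  rows <- list()
  for (cl in sort(unique(asg))) {
    sub <- M[asg == cl, , drop = FALSE]
    for (v in vars) {
      q <- quantile(sub[, v], c(0, .25, .5, .75, 1), names = FALSE)
      mn <- mean(sub[, v])
      rows[[length(rows) + 1]] <- tibble::tibble(
        cluster = cl, variable = v, min = q[1], q25 = q[2], median = q[3],
        q75 = q[4], max = q[5], mean = mn,
        outlier_cluster = abs(mn) > 2)
    }
  }
  spec <- attr(matrix, "specimen")
  freq <- NULL
  if (!is.null(spec)) {
    freq <- tibble::as_tibble(as.data.frame(table(specimen = spec,
                                                  cluster = asg),
                                            stringsAsFactors = FALSE))
    names(freq)[3] <- "count"
    freq <- freq %>% dplyr::group_by(specimen) %>%
      dplyr::mutate(proportion = count / sum(count)) %>% dplyr::ungroup()
    freq$cluster <- as.integer(freq$cluster)
  }
  list(variable_stats = dplyr::bind_rows(rows),
       specimen_frequencies = freq,
       cluster_sizes = tabulate(asg, model$k))
}
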