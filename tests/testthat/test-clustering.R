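# Scute matrix preparation, PCA, correlations, Ward clustering.

make_records <- function(n = 60, seed = 1, specimen = "s1", sa = 1000) {
  set.seed(seed)
  tibble::tibble(
    specimen = specimen, scute_id = seq_len(n),
    x = runif(n), y = runif(n), z = runif(n),
    n_neighbors = sample(4:8, n, replace = TRUE),
    volume = exp(rnorm(n, 0, 0.3)),
    area = exp(rnorm(n, 1, 0.3)),
    thickness = exp(rnorm(n, -1, 0.2)),
    width = exp(rnorm(n, 0.5, 0.2)),
    aspect_ratio = exp(rnorm(n, -1.5, 0.2)),
    cgs = rnorm(n, 0.001, 0.0005),
    cms = rnorm(n, 0.03, 0.01),
    is_opening_scute = FALSE,
    surface_area = sa)
}

zero_exp <- setNames(rep(0, 7),
                     c("volume", "area", "thickness", "width",
                       "aspect_ratio", "cgs", "cms"))

test_that("prepare_matrix drops flagged rows and standardizes columns", {
  rec <- make_records(50)
  rec$area[3] <- MISSING_FLAG
  rec$area[7] <- 0
  M <- prepare_matrix(rec, c(s1 = 1000), exponents = zero_exp)
  expect_identical(nrow(M), 48L)
  dropped <- attr(M, "dropped")
  expect_identical(dropped$flag[dropped$scute_id == 3], "area_missing")
  expect_identical(dropped$flag[dropped$scute_id == 7], "area_zero")
  expect_true(all(abs(colMeans(M)) < 1e-9))
  expect_true(all(abs(apply(M, 2, sd) - 1) < 1e-9))
})

test_that("curvature shift maps the minimum to 0.001 before the log", {
  rec <- make_records(40, seed = 2)
  rec$cgs[5] <- -0.002                      # negative curvature present
  M <- prepare_matrix(rec, c(s1 = 1000), exponents = zero_exp,
                      outlier_mads = Inf)
  # reconstruct: the minimum shifted value is 0.001, whose log is finite
  cg <- rec$cgs - min(rec$cgs) + 0.001
  z <- (log(cg) - mean(log(cg))) / sd(log(cg))
  expect_equal(unname(M[, "cgs"]), z, tolerance = 1e-9)
  expect_true(all(is.finite(M)))
})

test_that("the MAD outlier rule removes planted extremes and reports them", {
  rec <- make_records(80, seed = 3)
  rec$volume[10] <- exp(20)                 # extremely large volume
  rec$cms[20] <- 40                         # extreme curvature
  M <- prepare_matrix(rec, c(s1 = 1000), exponents = zero_exp)
  dropped <- attr(M, "dropped")
  expect_setequal(dropped$scute_id[dropped$flag == "outlier"], c(10, 20))
  expect_identical(nrow(M), 78L)
})

test_that("specimens without surface area are excluded with a warning", {
  rec <- dplyr::bind_rows(make_records(20, specimen = "a"),
                          make_records(20, seed = 9, specimen = "b"))
  expect_warning(M <- prepare_matrix(rec, c(a = 1000), exponents = zero_exp),
                 "without SA")
  expect_true(all(attr(M, "specimen") == "a"))
})

test_that("PCA loadings are correlations with sign convention and full variance", {
  rec <- make_records(100, seed = 4)
  M <- prepare_matrix(rec, c(s1 = 1000), exponents = zero_exp)
  pca <- run_pca(M)
  expect_equal(sum(pca$variance_explained), 100, tolerance = 1e-9)
  # loadings equal Pearson correlations between variables and scores
  want <- cor(unclass(M), pca$scores)
  expect_equal(unname(pca$loadings), unname(want), tolerance = 1e-6)
  # sign convention: the largest-magnitude loading of each PC is positive
  for (k in seq_len(ncol(pca$loadings))) {
    l <- pca$loadings[, k]
    expect_gte(l[which.max(abs(l))], 0)
  }
  # full-rank reconstruction: PC-space distances equal original distances
  i <- c(1, 5, 9); j <- c(2, 6, 10)
  d_orig <- sqrt(rowSums((unclass(M)[i, ] - unclass(M)[j, ])^2))
  d_pc <- sqrt(rowSums((pca$scores[i, ] - pca$scores[j, ])^2))
  expect_equal(d_pc, d_orig, tolerance = 1e-9)
})

test_that("two correlated columns load on a common first component", {
  rec <- make_records(100, seed = 5)
  rec$volume <- rec$width^3 * exp(rnorm(100, 0, 0.01))
  M <- prepare_matrix(rec, c(s1 = 1000), exponents = zero_exp)
  cp <- correlation_panel(M)
  expect_gt(cp$correlations["volume", "width"], 0.95)
  expect_equal(cp$correlations, t(cp$correlations), tolerance = 1e-12)
  expect_true(all(abs(diag(cp$correlations) - 1) < 1e-12))
})

test_that("well-separated blobs are recovered exactly at k = 2", {
  set.seed(6)
  sc <- rbind(matrix(rnorm(100, 0, 0.2), ncol = 2),
              matrix(rnorm(100, 5, 0.2), ncol = 2))
  truth <- rep(1:2, each = 50)
  cm <- hierarchical_clusters(sc, k = 2)
  agree <- max(mean(cm$assignment == truth), mean(cm$assignment == 3 - truth))
  expect_equal(agree, 1)
  cm1 <- hierarchical_clusters(sc, k = 1)
  expect_identical(unique(cm1$assignment), 1L)
  expect_error(hierarchical_clusters(sc, k = 200), "between")
})

test_that("cluster summaries flag outlier clusters and count per specimen", {
  rec <- dplyr::bind_rows(make_records(40, seed = 7, specimen = "a"),
                          make_records(40, seed = 8, specimen = "b"))
  M <- prepare_matrix(rec, c(a = 1000, b = 1200), exponents = zero_exp)
  pca <- run_pca(M)
  cm <- hierarchical_clusters(pca$scores, k = 3)
  cs <- cluster_summaries(cm, M)
  freq <- cs$specimen_frequencies
  tot <- tapply(freq$count, freq$specimen, sum)
  expect_equal(as.numeric(tot[c("a", "b")]), c(40, 40))
  props <- tapply(freq$proportion, freq$specimen, sum)
  expect_equal(as.numeric(props), c(1, 1), tolerance = 1e-9)
  expect_identical(cs$variable_stats$outlier_cluster,
                   abs(cs$variable_stats$mean) > 2)
})

test_that("clustering pipeline is deterministic and stable to duplication", {
  rec <- make_records(120, seed = 10)
  # correlated structure so the leading components are well determined
  rec$volume <- rec$width^3 * exp(rnorm(120, 0, 0.05))
  rec$area <- rec$width^2 * exp(rnorm(120, 0, 0.05))
  rec$aspect_ratio <- rec$thickness / rec$width
  M <- prepare_matrix(rec, c(s1 = 1000), exponents = zero_exp)
  p1 <- run_pca(M); p2 <- run_pca(M)
  expect_identical(hierarchical_clusters(p1$scores, 4)$assignment,
                   hierarchical_clusters(p2$scores, 4)$assignment)
  # duplicating one row barely moves the well-determined leading loadings
  rec2 <- dplyr::bind_rows(rec, rec[30, ])
  M2 <- prepare_matrix(rec2, c(s1 = 1000), exponents = zero_exp)
  p3 <- run_pca(M2)
  expect_lt(max(abs(abs(p3$loadings[, 1:2]) - abs(p1$loadings[, 1:2]))), 0.05)
})
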