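# Edge/flat region classification from normalized Gaussian curvature,
# and per-specimen scute shape (neighbor-count) frequency tables.

#' Classify scutes into edge and flat carapace regions
#'
#' Scutes whose size-normalized Gaussian surface curvature reaches the
#' threshold belong to carapace edges; smaller values represent flat
#' regions. The threshold is inclusive (>= 5 by default). Normalization
#' is expected to come from [normalize_by_sa()] with the fitted CGS
#' exponent.
#'
#' @param normalized_cgs numeric vector of normalized CGS values.
#' @param threshold classification threshold (default 5, inclusive).
#' @param scute_id optional ids carried through to the output.
#' @return tibble: scute_id, normalized_cgs, region (`"edge"`/`"flat"`).
#'   Records with missing curvature are excluded with a warning.
#' @export
classify_region <- function(normalized_cgs, threshold = 5,
                            scute_id = seq_along(normalized_cgs)) {
  keep <- !is.na(normalized_cgs)
  if (any(!keep))
    warning(sprintf("%d record(s) without curvature excluded from region classification",
                    sum(!keep)))
  tibble::tibble(
    scute_id = scute_id[keep],
    normalized_cgs = normalized_cgs[keep],
    region = ifelse(normalized_cgs[keep] >= threshold, "edge", "flat"))
}

#' Per-specimen scute shape frequencies
#'
#' Proportion of scutes with k neighbors (a 6-neighbor scute is a
#' hexagon), computed per specimen with opening scutes excluded from
#' the denominator. Classes 3..8 are reported individually and >= 9
#' pooled for display; exact counts are kept in the `counts` attribute.
#'
#' @param records per-scute tibble with columns specimen, n_neighbors
#'   and is_opening_scute.
#' @return tibble: specimen, shape class columns `n3`..`n8`, `n9plus`
#'   (proportions summing to 1) and `n_excluded_opening`.
#' @export
shape_frequencies <- function(records) {
  assert_that(all(c("specimen", "n_neighbors", "is_opening_scute") %in%
                    names(records)),
              "records needs specimen, n_neighbors, is_opening_scute columns")
  out <- list()
  counts_raw <- list()
  for (spec in unique(records$specimen)) {
    rec <- records[records$specimen == spec, ]
    inc <- rec[!rec$is_opening_scute, ]
    if (nrow(inc) == 0)
      stop_carapace("specimen ", spec, " has no non-opening scutes")
    k <- inc$n_neighbors
    cls <- pmin(pmax(k, 3L), 9L)
    tab <- table(factor(cls, levels = 3:9))
    prop <- as.numeric(tab) / nrow(inc)
    row <- tibble::tibble(specimen = spec)
    nm <- c(paste0("n", 3:8), "n9plus")
    for (i in seq_along(nm)) row[[nm[i]]] <- prop[i]
    row$n_excluded_opening <- sum(rec$is_opening_scute)
    out[[length(out) + 1]] <- row
    counts_raw[[as.character(spec)]] <- table(k)
  }
  res <- dplyr::bind_rows(out)
  attr(res, "counts") <- counts_raw
  res
}
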