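# Interspecific scaling against carapace surface area (SA): log-log OLS
# for dimensions and median scute variables, Poisson regression for
# scute counts, size normalization by fitted exponents, residual
# extraction by carapace geometry, and the region-interaction test.

#' Isometric reference slopes against an area-based size variable
#'
#' Linear dimensions scale as SA^0.5, areas as SA^1, volumes as SA^1.5,
#' dimensionless ratios as SA^0, Gaussian curvature as SA^-1 and mean
#' curvature as SA^-0.5.
#' @export
ISOMETRY_REFERENCE <- c(
  length = 0.5, height = 0.5, width = 0.5,
  volume = 1.5, area = 1.0, thickness = 0.5,
  aspect_ratio = 0, cgs = -1.0, cms = -0.5)

new_scaling_fit <- function(variable, model, slope, intercept, ci95,
                            residuals, n, fit) {
  assert_that(ci95[1] <= slope && slope <= ci95[2],
              "confidence interval must bracket the slope")
  structure(list(variable = variable, model = model, slope = slope,
                 intercept = intercept, ci95 = ci95,
                 residuals = residuals, n = n, fit = fit),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit> %s ~ SA [%s]: slope %.3f (95%% CI %.3f, %.3f), n = %d\n",
              x$variable, x$model, x$slope, x$ci95[1], x$ci95[2], x$n))
  invisible(x)
}

#' Log-log scaling regression against surface area
#'
#' Ordinary least squares of ln(y) on ln(SA); the slope is the scaling
#' exponent, with a two-sided t-based 95% confidence interval.
#'
#' @param sa per-specimen carapace surface area (mm^2).
#' @param y per-specimen response (typically a per-specimen median of a
#'   scute variable; medians are preferred over means because of extreme
#'   values from horns and ornamented scutes).
#' @param variable label stored in the fit.
#' @param level confidence level of the interval (default 0.95).
#' @return a `scaling_fit` with residuals on the ln scale.
#' @export
fit_loglog <- function(sa, y, variable = deparse(substitute(y)),
                       level = 0.95) {
  assert_that(length(sa) == length(y), "sa and y lengths differ")
  assert_that(length(y) >= 3, "need at least 3 specimens")
  bad <- which(is.na(sa) | is.na(y) | !(sa > 0) | !(y > 0))
  if (length(bad))
    stop_carapace("missing or non-positive values for specimen(s) ",
                  paste(bad, collapse = ", "),
                  "; log-log regression requires positive data")
  fit <- lm(log(y) ~ log(sa))
  ci <- suppressMessages(confint(fit, level = level))[2, ]
  new_scaling_fit(variable, "loglog_ols",
                  slope = unname(coef(fit)[2]),
                  intercept = unname(coef(fit)[1]),
                  ci95 = unname(ci),
                  residuals = unname(fit$residuals),
                  n = length(y), fit = fit)
}

#' Scaling of scute number with surface area
#'
#' Poisson generalized linear model with a log link regressing the scute
#' count on SA; the slope and its 95% confidence interval are
#' back-transformed to the response scale with `exp`. By default the
#' predictor is untransformed SA; `log_sa = TRUE` uses ln(SA) instead.
#'
#' @param sa per-specimen surface area.
#' @param counts per-specimen scute counts (non-negative integers).
#' @param ci one of `"profile"` (default, likelihood profile) or
#'   `"wald"`.
#' @param log_sa regress on ln(SA) rather than SA.
#' @param level confidence level (default 0.95).
#' @return a `scaling_fit` with the exp-transformed slope.
#' @export
fit_scute_count <- function(sa, counts, ci = c("profile", "wald"),
                            log_sa = FALSE, level = 0.95) {
  ci <- match.arg(ci)
  assert_that(all(counts >= 0) && all(counts == round(counts)),
              "counts must be non-negative integers")
  x <- if (log_sa) log(sa) else sa
  fit <- glm(counts ~ x, family = poisson())
  b <- unname(coef(fit)[2])
  cib <- if (ci == "profile") {
    suppressMessages(confint(fit, level = level))[2, ]  # MASS profile method
  } else {
    se <- sqrt(diag(vcov(fit)))[2]
    coef(fit)[2] + c(-1, 1) * qnorm(1 - (1 - level) / 2) * se
  }
  new_scaling_fit("scute_number", "poisson_loglink",
                  slope = exp(b), intercept = unname(coef(fit)[1]),
                  ci95 = unname(exp(cib)),
                  residuals = unname(fit$residuals),
                  n = length(counts), fit = fit)
}

#' Normalize values by a power of surface area
#'
#' Divides each value by SA^slope, removing the fitted allometric size
#' effect so specimens of different size become comparable.
#'
#' @param values numeric vector.
#' @param sa surface area per value (recycled per specimen as needed).
#' @param slope the scaling exponent.
#' @return normalized values.
#' @export
normalize_by_sa <- function(values, sa, slope) {
  assert_that(all(sa > 0), "surface area must be positive")
  values / sa^slope
}

#' Regression residuals grouped by carapace geometry
#'
#' @param fit a `scaling_fit`.
#' @param classes per-specimen geometry class (character/factor), in the
#'   order of the specimens used in the fit.
#' @return list with `residuals` (tibble: class, residual — the
#'   strip-plot data) and `summary` (per-class n, median, min, max).
#' @export
residuals_by_geometry <- function(fit, classes) {
  assert_that(inherits(fit, "scaling_fit"), "fit must be a scaling_fit")
  assert_that(length(classes) == fit$n,
              "classes must cover every specimen in the fit")
  known <- c("elliptic", "triangular", "tetragonal")
  unknown <- setdiff(unique(as.character(classes)), known)
  if (length(unknown))
    stop_carapace("unknown geometry class(es): ", paste(unknown, collapse = ", "))
  tab <- tibble::tibble(class = as.character(classes),
                        residual = fit$residuals)
  summ <- tab %>%
    dplyr::group_by(class) %>%
    dplyr::summarise(n = dplyr::n(), median = median(residual),
                     min = min(residual), max = max(residual),
                     .groups = "drop")
  list(residuals = tab, summary = summ)
}

#' Does the scaling exponent differ between flat and edge regions?
#'
#' Fits ln(y) ~ ln(SA) * region on the stacked per-specimen medians of
#' both regions and returns the p-value of the interaction term. A
#' non-significant interaction justifies pooling both regions into a
#' single exponent for normalization.
#'
#' @param sa per-specimen surface area.
#' @param y_flat,y_edge per-specimen medians for flat and edge regions.
#' @return interaction-term p-value (NA with a warning when the model is
#'   degenerate, e.g. noiseless data where the test is unidentified).
#' @export
region_interaction_test <- function(sa, y_flat, y_edge) {
  assert_that(length(sa) == length(y_flat) && length(sa) == length(y_edge),
              "need both region medians for every specimen")
  if (anyNA(y_flat) || anyNA(y_edge))
    stop_carapace("missing region medians")
  df <- data.frame(lsa = rep(log(sa), 2),
                   ly = log(c(y_flat, y_edge)),
                   region = rep(c("flat", "edge"), each = length(sa)))
  fit <- lm(ly ~ lsa * region, data = df)
  sm <- summary(fit)
  if (sm$sigma < 1e-12 || any(is.na(coef(fit)))) {
    warning("degenerate regression (zero residual variance); interaction p-value is NA")
    return(NA_real_)
  }
  unname(coef(sm)["lsa:regionflat", "Pr(>|t|)"])
}

#' Fit the full table of scaling exponents
#'
#' Convenience wrapper reproducing the interspecific scaling table:
#' carapace dimensions and median scute variables per region (flat,
#' edge, both) regressed on SA, plus the Poisson scute-count model.
#'
#' @param specimens per-specimen tibble with columns specimen,
#'   surface_area, length, height, width, n_scutes.
#' @param records per-scute tibble (standard schema) with a `region` column
#'   (`"flat"`/`"edge"`) and logical `is_opening_scute`.
#' @param level confidence level for every interval (default 0.95).
#' @return tibble: variable, region, slope, ci_low, ci_high, n.
#' @export
fit_scaling_table <- function(specimens, records, level = 0.95) {
  sa <- specimens$surface_area
  rows <- list()
  addrow <- function(variable, region, fit) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      variable = variable, region = region, slope = fit$slope,
      ci_low = fit$ci95[1], ci_high = fit$ci95[2], n = fit$n)
  }
  for (v in c("length", "height", "width"))
    addrow(paste0("carapace_", v), "",
           fit_loglog(sa, specimens[[v]], v, level = level))
  addrow("scute_number", "",
         fit_scute_count(sa, specimens$n_scutes, level = level))
  med_by_spec <- function(rec, var) {
    v <- tapply(rec[[var]], rec$specimen,
                function(x) median(x[x != MISSING_FLAG], na.rm = TRUE))
    as.numeric(v[as.character(specimens$specimen)])
  }
  for (v in c("cgs", "cms"))
    addrow(v, "both", fit_loglog(sa, med_by_spec(records, v), v,
                                 level = level))
  reg_subsets <- list(flat = records[records$region %in% "flat", ],
                      edge = records[records$region %in% "edge", ],
                      both = records)
  for (v in c("volume", "area", "width", "thickness", "aspect_ratio"))
    for (rg in names(reg_subsets)) {
      m <- med_by_spec(reg_subsets[[rg]], v)
      if (sum(!is.na(m)) < 3) {
        warning(sprintf("too few specimens with %s-region scutes to fit %s; row skipped",
                        rg, v))
        next
      }
      addrow(v, rg, fit_loglog(sa[!is.na(m)], m[!is.na(m)], v, level = level))
    }
  dplyr::bind_rows(rows)
}
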