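#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cov dist lm glm coef confint cutree hclust kmeans
#'   mad median prcomp qnorm quantile rnorm runif sd setNames poisson vcov
#'   complete.cases aggregate p.adjust
#' @importFrom utils head tail write.csv read.csv
#' @importFrom Matrix sparseMatrix Diagonal rowSums t
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>% group_by summarise mutate arrange filter select
#'   bind_rows left_join n ungroup
#' @importFrom igraph graph_from_edgelist triangles cliques
#' @importFrom MASS ginv
#' @importFrom ape as.phylo write.tree
#' @importFrom jsonlite write_json
#' @importFrom yaml read_yaml write_yaml
#' @importFrom tiff readTIFF writeTIFF
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's random-number state afterwards, so that seeded
#' internals do not perturb the user's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_carapace <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop_carapace(msg)

#' Missing-value flag for plane-based measures
#'
#' Scutes whose dual-surface patch is not closed (they border a carapace
#' opening) carry this sentinel in the `area` column.
#' @export
MISSING_FLAG <- -1000
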