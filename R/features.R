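# Guard against division by zero in depth and variance ratios.
FEATURE_EPS <- 1e-9

#' Compute classifier features for linked scaffold pairs
#'
#' For each pair the six features combine the Hi-C link count `R`, the two
#' scaffold lengths `l1`, `l2`, mean depths `d1`, `d2`, depth variances `v1`,
#' `v2` and connection degrees `c1`, `c2`:
#'
#' * `f1 = 1e6 * R / (l1 * l2)` — length-normalized link count (the 1e6
#'   factor keeps the value away from floating-point underflow),
#' * `f2 = 1e6 * R / (d1*l1 + d2*l2 + eps)` — coverage-normalized link count,
#' * `f3 = R / max(c1 + c2, 1)` — link count relative to how promiscuously
#'   the two scaffolds link elsewhere,
#' * `f4 = min(d1, d2) / max(d1, d2, eps)` — depth-compatibility ratio,
#' * `f5 = min(v1+eps, v2+eps) / max(v1+eps, v2+eps)` — variance ratio,
#' * `f6 = min(l1, l2)` — length of the shorter scaffold.
#'
#' All features are symmetric under swapping the two scaffolds. Features are
#' only defined for pairs with at least one Hi-C link.
#'
#' @param lm A [linkmap()].
#' @param scaffolds Scaffold data frame with `id`, `length`, `depth_mean`,
#'   `depth_var`.
#' @param pairs Optional data frame with columns `a`, `b`; defaults to every
#'   linked pair in `lm`.
#' @return Data frame with columns `a`, `b`, `f1`..`f6`.
#' @export
compute_pair_features <- function(lm, scaffolds, pairs = NULL) {
  if (is.null(pairs)) pairs <- lm$pairs[, c("a", "b")]
  ids <- unique(c(pairs$a, pairs$b))
  miss <- setdiff(ids, scaffolds$id)
  if (length(miss))
    stop("scaffold '", miss[1L], "' has no length/depth metadata")
  R <- linkmap_counts(lm, pairs$a, pairs$b)
  if (any(R < 1L)) {
    k <- which(R < 1L)[1L]
    stop("pair (", pairs$a[k], ", ", pairs$b[k],
         ") has no Hi-C links; features are only defined for linked pairs")
  }
  i <- match(pairs$a, scaffolds$id)
  j <- match(pairs$b, scaffolds$id)
  l1 <- scaffolds$length[i];      l2 <- scaffolds$length[j]
  d1 <- scaffolds$depth_mean[i];  d2 <- scaffolds$depth_mean[j]
  v1 <- scaffolds$depth_var[i];   v2 <- scaffolds$depth_var[j]
  c1 <- unname(lm$degree[pairs$a])
  c2 <- unname(lm$degree[pairs$b])
  eps <- FEATURE_EPS
  data.frame(
    a = pairs$a, b = pairs$b,
    f1 = 1e6 * R / (as.numeric(l1) * as.numeric(l2)),
    f2 = 1e6 * R / (d1 * l1 + d2 * l2 + eps),
    f3 = R / pmax(c1 + c2, 1),
    f4 = pmin(d1, d2) / pmax(d1, d2, eps),
    f5 = pmin(v1 + eps, v2 + eps) / pmax(v1 + eps, v2 + eps),
    f6 = pmin(l1, l2),
    stringsAsFactors = FALSE
  )
}

#' Export pair features as TSV (debugging aid)
#'
#' @param features Data frame from [compute_pair_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_features <- function(features, path) {
  cols <- c("a", "b", paste0("f", 1:6))
  utils::write.table(features[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("scaffold_a", "scaffold_b",
                                                      paste0("f", 1:6)))
  invisible(path)
}
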