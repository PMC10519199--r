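#' Threshold pair probabilities into a binary connectivity predicate
#'
#' `pair(a, b) = 1` iff the predicted same-genome probability is at least
#' `minscore` (default 0.5); pairs absent from `probs` (no Hi-C link) are 0.
#'
#' @param probs Data frame from [predict_pair_probs()].
#' @param minscore Probability cutoff in `[0, 1]`.
#' @return An object of class `pair_predicate`.
#' @export
pair_predicate <- function(probs, minscore = 0.5) {
  stopifnot(minscore >= 0, minscore <= 1)
  keep <- probs$prob >= minscore
  structure(list(connected = pair_key(probs$a[keep], probs$b[keep]),
                 minscore = minscore),
            class = "pair_predicate")
}

#' Link-rate score between two bins
#'
#' The fraction of cross-bin scaffold pairs the classifier deems connected:
#' `sum_m sum_n pair(s_im, s_jn) / (num(b_i) * num(b_j))`.
#'
#' @param bin_i,bin_j Character vectors of the two bins' scaffold ids
#'   (must be disjoint and non-empty).
#' @param predicate A [pair_predicate()].
#' @return Numeric in `[0, 1]`.
#' @export
lr_score <- function(bin_i, bin_j, predicate) {
  if (!length(bin_i) || !length(bin_j)) stop("empty bin")
  if (length(intersect(bin_i, bin_j)))
    stop("bins overlap: ", intersect(bin_i, bin_j)[1L])
  keys <- pair_key(rep(bin_i, times = length(bin_j)),
                   rep(bin_j, each = length(bin_i)))
  sum(keys %in% predicate$connected) / (length(bin_i) * length(bin_j))
}

#' Depth-compatibility score between two bins
#'
#' Two-sided Welch (unequal-variance) t-test p-value comparing the two bins'
#' per-scaffold mean-depth vectors; a high p-value means the bins have
#' compatible abundance. Degenerate profiles use explicit conventions:
#' two constant profiles score 1 when their means agree and 0 otherwise;
#' when one bin holds a single scaffold the test falls back to the pooled
#' (equal-variance) t-test borrowing the other bin's variance, or to 1 when
#' that too is degenerate.
#'
#' @param d_i,d_j Numeric depth profiles (one value per member scaffold).
#' @param tol Numerical tolerance used by the degeneracy checks.
#' @return p-value in `[0, 1]`.
#' @export
depth_score <- function(d_i, d_j, tol = 1e-12) {
  if (!length(d_i) || !length(d_j)) stop("empty depth profile")
  n_i <- length(d_i)
  n_j <- length(d_j)
  const_i <- n_i < 2L || stats::var(d_i) <= tol
  const_j <- n_j < 2L || stats::var(d_j) <= tol
  same_mean <- abs(mean(d_i) - mean(d_j)) <= tol
  if (n_i >= 2L && n_j >= 2L) {
    if (const_i && const_j) return(if (same_mean) 1 else 0)
    return(tryCatch(stats::t.test(d_i, d_j)$p.value,
                    error = function(e) if (same_mean) 1 else 0))
  }
  # At least one single-scaffold bin.
  if (const_i && const_j) {
    if (n_i == 1L && n_j == 1L) return(if (same_mean) 1 else 0)
    message("single-scaffold bin against a constant profile; depth score set to 1")
    return(1)
  }
  stats::t.test(d_i, d_j, var.equal = TRUE)$p.value
}

#' Composition score between two bins
#'
#' Cosine similarity of the two bins' TNF vectors.
#'
#' @param t_i,t_j Numeric TNF vectors (e.g. from [bin_tnf()]).
#' @return Cosine similarity in `[-1, 1]`.
#' @export
tnf_score <- function(t_i, t_j) {
  ni <- sqrt(sum(t_i^2))
  nj <- sqrt(sum(t_j^2))
  if (ni <= 0 || nj <= 0) stop("zero-norm TNF vector cannot be normalized")
  sum(t_i * t_j) / (ni * nj)
}

#' Score every bin pair
#'
#' Computes the link-rate, depth and composition scores for all bin pairs of
#' a binning; this table feeds [plan_merges()].
#'
#' @param bn A [binning()].
#' @param predicate A [pair_predicate()].
#' @param scaffolds Scaffold data frame.
#' @param tnfm Per-scaffold TNF matrix from [tnf_matrix()].
#' @return Data frame with columns `bin_i`, `bin_j` (`bin_i < bin_j`), `lr`,
#'   `depth_p`, `tnf_cos`.
#' @export
score_bin_pairs <- function(bn, predicate, scaffolds, tnfm) {
  bins <- sort(names(bn$bins))
  profiles <- lapply(bn$bins, function(m) {
    scaffolds$depth_mean[match(sort(m), scaffolds$id)]
  })
  tnfs <- lapply(stats::setNames(bins, bins),
                 function(b) bin_tnf(bn, scaffolds, tnfm, b))
  if (length(bins) < 2L) {
    return(data.frame(bin_i = character(0), bin_j = character(0),
                      lr = numeric(0), depth_p = numeric(0),
                      tnf_cos = numeric(0), stringsAsFactors = FALSE))
  }
  cmb <- utils::combn(bins, 2L)
  out <- data.frame(bin_i = cmb[1L, ], bin_j = cmb[2L, ],
                    lr = NA_real_, depth_p = NA_real_, tnf_cos = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(out))) {
    bi <- out$bin_i[k]
    bj <- out$bin_j[k]
    out$lr[k] <- lr_score(bn$bins[[bi]], bn$bins[[bj]], predicate)
    out$depth_p[k] <- depth_score(profiles[[bi]], profiles[[bj]])
    out$tnf_cos[k] <- tnf_score(tnfs[[bi]], tnfs[[bj]])
  }
  out
}
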