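#' Select the bins used for self-supervised training
#'
#' Large bins from the initial binning are the most trustworthy (the
#' dominant failure mode of single-sample binning is incompleteness, not
#' contamination), so the training set is drawn from the `n_bins` bins with
#' the largest total base pairs. Ties break lexicographically by bin id.
#'
#' @param bn A [binning()].
#' @param scaffolds Scaffold data frame (needs `id`, `length`).
#' @param n_bins Number of bins to select (default 10); clamped with a
#'   warning when fewer bins exist.
#' @return Character vector of bin ids, largest first.
#' @export
select_training_bins <- function(bn, scaffolds, n_bins = 10) {
  if (length(bn$bins) < 2L)
    stop("need at least 2 bins to build a training set (no negatives otherwise)")
  if (n_bins < 2L) stop("n_bins must be >= 2")
  bp <- bin_sizes_bp(bn, scaffolds)
  sel <- names(bp)[order(-bp, names(bp))]
  if (length(sel) < n_bins)
    warning(sprintf("only %d bins available; using all (requested %d)",
                    length(sel), n_bins))
  utils::head(sel, n_bins)
}

#' Build the self-supervised training set
#'
#' Positives are Hi-C-linked scaffold pairs whose two scaffolds sit in the
#' same training bin (label 1, weight 1). Negative candidates are linked
#' pairs spanning two different training bins (label 0). Because incomplete
#' bins can place two scaffolds of one genome in different bins, negative
#' labels are noisier than positive ones and get weight `neg_weight < 1`.
#' Negatives are subsampled (seeded) to match the positive count; when
#' negatives are the scarcer class, positives are subsampled instead.
#'
#' @param bn A [binning()].
#' @param lm A [linkmap()].
#' @param scaffolds Scaffold data frame.
#' @param train_bin_ids Bins from [select_training_bins()].
#' @param neg_weight Weight of negative rows, in (0, 1] (default 0.5).
#' @param seed Integer seed for the balancing subsample.
#' @return A `training_set`: data frame with `a`, `b`, `f1`..`f6`, `label`,
#'   `weight`, plus attribute `bins_used`.
#' @export
build_training_set <- function(bn, lm, scaffolds, train_bin_ids,
                               neg_weight = 0.5, seed = 42) {
  stopifnot(neg_weight > 0, neg_weight <= 1)
  asg <- bn$assignment
  p <- lm$pairs
  ba <- unname(asg[p$a])
  bb <- unname(asg[p$b])
  in_train <- ba %in% train_bin_ids & bb %in% train_bin_ids
  pos <- which(in_train & ba == bb)
  neg <- which(in_train & ba != bb)
  if (!length(pos))
    stop("no positive training pairs: the training bins contain no ",
         "Hi-C-linked intra-bin scaffold pairs (insufficient Hi-C connectivity)")
  if (!length(neg))
    stop("no negative training pairs: no Hi-C links between distinct ",
         "training bins (insufficient Hi-C connectivity)")
  n <- min(length(pos), length(neg))
  if (length(neg) > n) {
    neg <- with_seed(sub_seed(seed, 11L), sort(sample(neg, n)))
  } else if (length(pos) > n) {
    message("fewer linked negatives than positives; subsampling positives to ", n)
    pos <- with_seed(sub_seed(seed, 12L), sort(sample(pos, n)))
  }
  idx <- c(pos, neg)
  out <- compute_pair_features(lm, scaffolds, p[idx, c("a", "b")])
  out$label <- rep(c(1L, 0L), c(length(pos), length(neg)))
  out$weight <- ifelse(out$label == 1L, 1, neg_weight)
  rownames(out) <- NULL
  attr(out, "bins_used") <- train_bin_ids
  class(out) <- c("training_set", class(out))
  out
}

#' Train the random-forest pair classifier
#'
#' Rows are split (seeded, stratified by label) into train/validation/test
#' partitions; a probability random forest is fitted on the training
#' partition with per-row weights; accuracy, precision and recall of the
#' 0.5-thresholded prediction are computed on the test partition only. The
#' validation partition is reserved for optional hyperparameter tuning and
#' otherwise unused.
#'
#' @param training_set From [build_training_set()].
#' @param split Train/validation/test fractions, summing to 1.
#' @param seed Integer seed (controls both the split and the forest).
#' @param num_trees Number of trees (default 100).
#' @return A `pair_model`: list with the fitted forest (`fit`), `metrics`
#'   (`accuracy`, `precision`, `recall`, partition sizes), `split_seed`,
#'   `feature_names` and `bins_used`.
#' @export
train_pair_model <- function(training_set, split = c(0.70, 0.15, 0.15),
                             seed = 42, num_trees = 100) {
  ts <- training_set
  if (nrow(ts) < 20L)
    stop("training set too small (", nrow(ts), " rows; need >= 20)")
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  part <- with_seed(sub_seed(seed, 21L), {
    out <- character(nrow(ts))
    for (lab in sort(unique(ts$label))) {
      idx <- sample(which(ts$label == lab))
      n <- length(idx)
      n_tr <- floor(split[1L] * n)
      n_va <- floor(split[2L] * n)
      out[idx[seq_len(n_tr)]] <- "train"
      if (n_va > 0) out[idx[n_tr + seq_len(n_va)]] <- "val"
      out[idx[seq.int(n_tr + n_va + 1L, n)]] <- "test"
    }
    out
  })
  fcols <- paste0("f", 1:6)
  tr <- ts[part == "train", , drop = FALSE]
  if (length(unique(tr$label)) < 2L)
    stop("training partition contains a single class")
  fit <- ranger::ranger(
    x = tr[, fcols], y = factor(tr$label, levels = c(0L, 1L)),
    case.weights = tr$weight, probability = TRUE,
    num.trees = num_trees, seed = sub_seed(seed, 22L), num.threads = 1
  )
  te <- ts[part == "test", , drop = FALSE]
  prob <- stats::predict(fit, data = te[, fcols], num.threads = 1)$predictions[, "1"]
  pred <- as.integer(prob >= 0.5)
  tp <- sum(pred == 1L & te$label == 1L)
  fp <- sum(pred == 1L & te$label == 0L)
  fn <- sum(pred == 0L & te$label == 1L)
  metrics <- list(
    accuracy = mean(pred == te$label),
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    n_train = nrow(tr), n_val = sum(part == "val"), n_test = nrow(te)
  )
  structure(
    list(fit = fit, metrics = metrics, split_seed = seed,
         feature_names = fcols, bins_used = attr(ts, "bins_used")),
    class = "pair_model"
  )
}

#' @export
print.pair_model <- function(x, ...) {
  cat(sprintf(paste0("<pair_model> %d trees; test accuracy %.3f ",
                     "(precision %.3f, recall %.3f; n_test %d)\n"),
              x$fit$num.trees, x$metrics$accuracy, x$metrics$precision,
              x$metrics$recall, x$metrics$n_test))
  invisible(x)
}

# Predict same-genome probabilities for rows of a feature data frame.
pair_prob <- function(model, features) {
  stats::predict(model$fit, data = features[, model$feature_names, drop = FALSE],
                 num.threads = 1)$predictions[, "1"]
}

#' Predict same-genome probabilities for every linked scaffold pair
#'
#' The model is applied to every pair with at least one Hi-C link across the
#' whole assembly, whether or not the scaffolds were in the training set.
#' Pairs without any Hi-C link carry no evidence and are treated as
#' probability 0 by downstream consumers (they are simply absent here).
#'
#' @param model A [train_pair_model()] fit.
#' @param lm A [linkmap()].
#' @param scaffolds Scaffold data frame; every linked scaffold must have
#'   length/depth metadata.
#' @return Data frame with columns `a`, `b`, `prob` (symmetric by
#'   construction: each unordered pair appears once).
#' @export
predict_pair_probs <- function(model, lm, scaffolds) {
  feats <- compute_pair_features(lm, scaffolds)
  data.frame(a = feats$a, b = feats$b, prob = pair_prob(model, feats),
             stringsAsFactors = FALSE)
}
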