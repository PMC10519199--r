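#' Build a Hi-C link map
#'
#' A link map stores, for every unordered scaffold pair connected by at least
#' one informative Hi-C read pair, the number of read pairs bridging the two
#' scaffolds, together with each scaffold's connection degree (the number of
#' distinct scaffolds it links to). Self-pairs are discarded: every downstream
#' quantity is defined between two different scaffolds.
#'
#' @param a,b Character vectors of scaffold ids (one entry per link
#'   observation; repeated pairs are summed).
#' @param count Integer link counts, recycled along `a`.
#' @param scaffold_ids Optional character vector of the full scaffold universe,
#'   so that unlinked scaffolds get an explicit degree of 0.
#' @return An object of class `linkmap` with elements `pairs` (data frame with
#'   columns `a`, `b`, `count`, `a < b`) and `degree` (named integer vector).
#' @export
linkmap <- function(a, b, count = 1L, scaffold_ids = NULL) {
  a <- as.character(a)
  b <- as.character(b)
  stopifnot(length(a) == length(b))
  count <- rep_len(as.integer(count), length(a))
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  keep <- lo != hi & count > 0L
  lo <- lo[keep]
  hi <- hi[keep]
  count <- count[keep]
  if (length(lo)) {
    key <- paste(lo, hi, sep = "\x01")
    tot <- rowsum(count, key)
    first <- !duplicated(key)
    pairs <- data.frame(
      a = lo[first], b = hi[first],
      count = as.integer(tot[match(key[first], rownames(tot)), 1L]),
      stringsAsFactors = FALSE
    )
    pairs <- pairs[order(pairs$a, pairs$b), , drop = FALSE]
    rownames(pairs) <- NULL
  } else {
    pairs <- data.frame(a = character(0), b = character(0), count = integer(0),
                        stringsAsFactors = FALSE)
  }
  ids <- sort(unique(c(as.character(scaffold_ids), pairs$a, pairs$b)))
  degree <- stats::setNames(integer(length(ids)), ids)
  if (nrow(pairs)) {
    tab <- table(c(pairs$a, pairs$b))
    degree[names(tab)] <- as.integer(tab)
  }
  structure(list(pairs = pairs, degree = degree), class = "linkmap")
}

#' Look up link counts for scaffold pairs
#'
#' @param lm A [linkmap()].
#' @param a,b Character vectors of scaffold ids.
#' @return Integer vector of counts; 0 for unlinked pairs.
#' @export
linkmap_counts <- function(lm, a, b) {
  idx <- match(pair_key(a, b), pair_key(lm$pairs$a, lm$pairs$b))
  out <- lm$pairs$count[idx]
  out[is.na(out)] <- 0L
  out
}

#' Restrict a link map to a set of scaffolds
#'
#' Drops every pair touching a scaffold outside `ids` and recomputes degrees
#' over the restricted universe.
#'
#' @param lm A [linkmap()].
#' @param ids Character vector of scaffold ids to keep.
#' @return A new `linkmap`.
#' @export
linkmap_subset <- function(lm, ids) {
  p <- lm$pairs
  keep <- p$a %in% ids & p$b %in% ids
  linkmap(p$a[keep], p$b[keep], p$count[keep], scaffold_ids = ids)
}

#' @export
print.linkmap <- function(x, ...) {
  cat(sprintf("<linkmap> %d linked pairs over %d scaffolds (total links %d)\n",
              nrow(x$pairs), length(x$degree), sum(x$pairs$count)))
  invisible(x)
}
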