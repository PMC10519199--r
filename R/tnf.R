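.tnf_env <- new.env(parent = emptyenv())

# Canonical tetramer classes: each of the 256 4-mers is mapped to the
# lexicographic minimum of itself and its reverse complement, giving 136
# strand-independent classes (16 palindromes + 120 merged pairs).
tnf_classes <- function() {
  if (is.null(.tnf_env$classes)) {
    kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 4)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
    canon <- ifelse(kmers <= rc, kmers, rc)
    classes <- sort(unique(canon))
    collapse <- matrix(0, length(kmers), length(classes),
                       dimnames = list(kmers, classes))
    collapse[cbind(seq_along(kmers), match(canon, classes))] <- 1
    .tnf_env$classes <- classes
    .tnf_env$collapse <- collapse
  }
  list(classes = .tnf_env$classes, collapse = .tnf_env$collapse)
}

#' Compute a tetranucleotide-frequency (TNF) vector
#'
#' Counts every 4-mer window at stride 1 (windows containing non-ACGT
#' characters are skipped), merges each 4-mer with its reverse complement
#' into one of 136 canonical classes, and normalizes the counts to
#' frequencies. A sequence shorter than 4 bp yields the zero vector.
#'
#' @param sequence A nucleotide string or [Biostrings::DNAString].
#' @return Named numeric vector of length 136 summing to 1 (or the zero
#'   vector when no window could be counted).
#' @export
compute_tnf <- function(sequence) {
  tc <- tnf_classes()
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  if (length(sequence) < 4L) {
    message("sequence shorter than 4 bp; returning a zero TNF vector")
    return(stats::setNames(numeric(length(tc$classes)), tc$classes))
  }
  cnt <- Biostrings::oligonucleotideFrequency(sequence, width = 4)
  v <- as.numeric(cnt[rownames(tc$collapse)] %*% tc$collapse)
  names(v) <- tc$classes
  s <- sum(v)
  if (s > 0) v / s else v
}

#' Compute TNF vectors for a set of sequences
#'
#' @param seqs A named [Biostrings::DNAStringSet].
#' @return Numeric matrix (sequences x 136 canonical classes), rows
#'   normalized to sum 1 where at least one window was counted.
#' @export
tnf_matrix <- function(seqs) {
  tc <- tnf_classes()
  cnt <- Biostrings::oligonucleotideFrequency(seqs, width = 4)
  m <- cnt[, rownames(tc$collapse), drop = FALSE] %*% tc$collapse
  s <- rowSums(m)
  nz <- s > 0
  m[nz, ] <- m[nz, , drop = FALSE] / s[nz]
  rownames(m) <- names(seqs)
  m
}

#' TNF vector of a bin
#'
#' The bin TNF is the length-weighted mean of its member scaffolds' TNF
#' vectors, renormalized to sum 1.
#'
#' @param bn A [binning()].
#' @param scaffolds Scaffold data frame (needs `id` and `length`).
#' @param tnfm Per-scaffold TNF matrix from [tnf_matrix()].
#' @param bin_id Bin to summarize.
#' @return Named numeric vector of length 136.
#' @export
bin_tnf <- function(bn, scaffolds, tnfm, bin_id) {
  members <- bn$bins[[bin_id]]
  if (is.null(members) || !length(members))
    stop("empty or unknown bin: ", bin_id)
  w <- scaffolds$length[match(members, scaffolds$id)]
  if (anyNA(w)) stop("bin '", bin_id, "' has members missing from the scaffold table")
  v <- as.numeric(w %*% tnfm[members, , drop = FALSE]) / sum(w)
  s <- sum(v)
  if (s > 0) v <- v / s
  stats::setNames(v, colnames(tnfm))
}
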