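#' Recruit unbinned scaffolds by graph partitioning
#'
#' Builds a graph over all scaffolds (binned and unbinned) whose edges are
#' the pairs with predicted probability at least `minscore`, weighted by the
#' raw probability, and partitions it with label propagation (default) or
#' Louvain. An unbinned scaffold is recruited iff its partition contains
#' exactly one known bin; partitions with zero or several known bins leave
#' their unbinned members untouched. Binned scaffolds are never reassigned.
#'
#' @param bn A [binning()].
#' @param probs Data frame from [predict_pair_probs()].
#' @param minscore Edge cutoff in `[0, 1]` (default 0.5).
#' @param algorithm `"lpa"` (label propagation, default) or `"louvain"`.
#' @param seed Integer seed for the randomized partitioning.
#' @return A new [binning()] with attribute `recruited` (sorted ids of the
#'   scaffolds assigned by this step).
#' @export
recruit_unbinned <- function(bn, probs, minscore = 0.5,
                             algorithm = c("lpa", "louvain"), seed = 42) {
  algorithm <- match.arg(algorithm)
  stopifnot(minscore >= 0, minscore <= 1)
  keep <- probs$prob >= minscore
  # Canonical (sorted) vertex order so partitioning is reproducible under seed.
  all_ids <- sort(unique(c(names(bn$assignment), bn$unbinned,
                           probs$a, probs$b)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = probs$a[keep], to = probs$b[keep],
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = all_ids
  )
  igraph::E(g)$weight <- probs$prob[keep]
  comm <- with_seed(sub_seed(seed, 31L), switch(
    algorithm,
    lpa = igraph::cluster_label_prop(g, weights = igraph::E(g)$weight),
    louvain = igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  ))
  memb <- igraph::membership(comm)
  asg <- bn$assignment
  recruited <- character(0)
  for (part in split(names(memb), as.integer(memb))) {
    known <- unique(unname(asg[intersect(part, names(asg))]))
    if (length(known) == 1L) {
      u <- intersect(part, bn$unbinned)
      if (length(u)) {
        asg[u] <- known
        recruited <- c(recruited, u)
      }
    }
  }
  out <- binning(asg, scaffold_ids = c(names(asg), bn$unbinned))
  attr(out, "recruited") <- sort(recruited)
  out
}
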