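#' Plan bin merges by connected components
#'
#' Builds a graph with bins as nodes; an edge joins two bins iff their
#' link-rate, depth and composition scores all clear their thresholds
#' (`lr >= lr_min AND depth_p >= depth_min AND tnf_cos >= tnf_min`). The
#' connected components of this graph are the merge partitions; every bin in
#' a component is predicted to derive from the same genome.
#'
#' @param bn A [binning()].
#' @param scores Bin-pair score table from [score_bin_pairs()].
#' @param thresholds Named numeric vector with `lr_min`, `depth_min`,
#'   `tnf_min`.
#' @return A `merge_plan`: list with `partitions` (list of sorted bin-id
#'   vectors covering all bins), `edges` (the qualifying score rows) and
#'   `thresholds`.
#' @export
plan_merges <- function(bn, scores,
                        thresholds = c(lr_min = 0.1, depth_min = 0.05,
                                       tnf_min = 0.90)) {
  pass <- scores$lr >= thresholds[["lr_min"]] &
    scores$depth_p >= thresholds[["depth_min"]] &
    scores$tnf_cos >= thresholds[["tnf_min"]]
  edges <- scores[pass, , drop = FALSE]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(edges[, c("bin_i", "bin_j")],
                                     directed = FALSE,
                                     vertices = sort(names(bn$bins)))
  comp <- igraph::components(g)
  parts <- lapply(split(names(comp$membership), comp$membership), sort)
  parts <- parts[order(vapply(parts, `[`, character(1), 1L))]
  structure(list(partitions = unname(parts), edges = edges,
                 thresholds = thresholds),
            class = "merge_plan")
}

#' Apply a merge plan
#'
#' Each multi-bin partition's scaffolds are unioned under a new bin id
#' `merged_<k>` recording its parents; singleton partitions leave their bin
#' untouched. The unbinned set is unchanged.
#'
#' @param bn A [binning()].
#' @param plan A [plan_merges()] result over `bn`'s bin ids.
#' @return A new [binning()] with attribute `merges`, a list of
#'   `list(new_id, parents)` records.
#' @export
apply_merges <- function(bn, plan) {
  unknown <- setdiff(unlist(plan$partitions), names(bn$bins))
  if (length(unknown))
    stop("merge plan references unknown bin: ", unknown[1L])
  asg <- bn$assignment
  merges <- list()
  k <- 0L
  for (part in plan$partitions) {
    if (length(part) < 2L) next
    k <- k + 1L
    new_id <- sprintf("merged_%d", k)
    asg[asg %in% part] <- new_id
    merges[[k]] <- list(new_id = new_id, parents = part)
  }
  out <- binning(asg, scaffold_ids = c(names(asg), bn$unbinned))
  attr(out, "merges") <- merges
  out
}
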