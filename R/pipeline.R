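#' Pipeline configuration
#'
#' Collects every tunable of the refinement pipeline with its default:
#' scaffolds shorter than `min_len` (1500 bp) are excluded from all
#' computation; `minscore` (0.5) turns pair probabilities into the binary
#' connectivity predicate; the `train_bins` (10) largest bins seed the
#' self-supervised training set with negative weight `neg_weight` (0.5);
#' bins merge when the link-rate, depth-test and TNF-cosine scores clear
#' `lr_min` (0.1), `depth_min` (0.05) and `tnf_min` (0.90); unbinned
#' scaffolds are recruited with `recruit_algo` (label propagation).
#'
#' @param min_len Minimum scaffold length in bp.
#' @param minscore Pair-probability cutoff in `[0, 1]`.
#' @param train_bins Number of training bins (>= 2).
#' @param neg_weight Negative-label weight in (0, 1].
#' @param lr_min,depth_min,tnf_min Merge thresholds.
#' @param recruit_algo `"lpa"` or `"louvain"`.
#' @param mapq_min Minimum mapping quality for Hi-C records.
#' @param num_trees Random-forest size.
#' @param seed Master seed; all randomness derives from it.
#' @param outdir Optional output directory for the final binning, per-bin
#'   FASTA and report JSON.
#' @return An object of class `refine_config`.
#' @export
refine_config <- function(min_len = 1500, minscore = 0.5, train_bins = 10,
                          neg_weight = 0.5, lr_min = 0.1, depth_min = 0.05,
                          tnf_min = 0.90, recruit_algo = c("lpa", "louvain"),
                          mapq_min = 0, num_trees = 100, seed = 42,
                          outdir = NULL) {
  recruit_algo <- match.arg(recruit_algo)
  stopifnot(min_len >= 1, minscore >= 0, minscore <= 1, train_bins >= 2,
            neg_weight > 0, neg_weight <= 1, mapq_min >= 0, num_trees >= 1)
  structure(list(min_len = min_len, minscore = minscore,
                 train_bins = train_bins, neg_weight = neg_weight,
                 lr_min = lr_min, depth_min = depth_min, tnf_min = tnf_min,
                 recruit_algo = recruit_algo, mapq_min = mapq_min,
                 num_trees = num_trees, seed = as.integer(seed),
                 outdir = outdir),
            class = "refine_config")
}

#' Run the full Hi-C bin-refinement pipeline
#'
#' Executes, in order: input reading, the 1500 bp scaffold-length filter,
#' link-map construction, TNF computation, training-bin selection,
#' self-supervised model training, pair prediction, bin merging by connected
#' components, and recruitment of unbinned scaffolds (merging strictly
#' before recruitment). Each argument may be a file path or the
#' corresponding in-memory object.
#'
#' @param assembly FASTA path, or a list with `scaffolds` and `seqs` as
#'   returned by [read_fasta()] (a `community_sim` also works).
#' @param depth Depth-table path or data frame; `NULL` if `assembly` already
#'   carries depths.
#' @param hic SAM/BAM path or a [linkmap()].
#' @param bins Binning TSV path / per-bin FASTA directory, or a [binning()].
#' @param config A [refine_config()].
#' @return List with `binning` (the refined [binning()]), `report` (the
#'   machine-readable run record), `model`, `probs`, `scores`, `plan` and
#'   the filtered `scaffolds` table.
#' @export
refine_pipeline <- function(assembly, depth = NULL, hic, bins,
                            config = refine_config()) {
  asm <- with_stage("read assembly",
                    if (is.character(assembly)) read_fasta(assembly) else assembly)
  scaffolds <- asm$scaffolds
  seqs <- asm$seqs
  if (!is.null(depth)) {
    dtab <- with_stage("read depth table",
                       if (is.character(depth)) read_depth_table(depth) else depth)
    scaffolds <- with_stage("join depths", join_depths(scaffolds, dtab))
  }
  lm <- with_stage("read Hi-C alignments",
                   if (is.character(hic)) read_hic_alignments(hic, config$mapq_min)
                   else hic)
  bn <- with_stage("read binning",
                   if (is.character(bins)) read_binning(bins, scaffold_ids = scaffolds$id)
                   else bins)

  keep_ids <- scaffolds$id[scaffolds$length >= config$min_len]
  n_short <- nrow(scaffolds) - length(keep_ids)
  if (n_short > 0L)
    message(n_short, " scaffold(s) below ", config$min_len, " bp excluded")
  scaffolds <- scaffolds[scaffolds$id %in% keep_ids, , drop = FALSE]
  seqs <- seqs[intersect(names(seqs), keep_ids)]
  lm <- linkmap_subset(lm, keep_ids)
  bn <- with_stage("length filter", binning(
    bn$assignment[names(bn$assignment) %in% keep_ids],
    scaffold_ids = keep_ids
  ))

  tnfm <- with_stage("tetranucleotide frequencies", tnf_matrix(seqs))
  train_ids <- with_stage("training-bin selection",
                          select_training_bins(bn, scaffolds, config$train_bins))
  ts <- with_stage("training-set construction",
                   build_training_set(bn, lm, scaffolds, train_ids,
                                      config$neg_weight, config$seed))
  model <- with_stage("model training",
                      train_pair_model(ts, seed = config$seed,
                                       num_trees = config$num_trees))
  probs <- with_stage("pair prediction", predict_pair_probs(model, lm, scaffolds))
  pred <- pair_predicate(probs, config$minscore)

  scores <- with_stage("bin-pair scoring",
                       score_bin_pairs(bn, pred, scaffolds, tnfm))
  plan <- with_stage("merge planning", plan_merges(
    bn, scores, c(lr_min = config$lr_min, depth_min = config$depth_min,
                  tnf_min = config$tnf_min)
  ))
  merged <- with_stage("bin merging", apply_merges(bn, plan))
  final <- with_stage("scaffold recruitment",
                      recruit_unbinned(merged, probs, config$minscore,
                                       config$recruit_algo, config$seed))

  merge_records <- lapply(attr(merged, "merges") %||% list(), function(m) {
    e <- plan$edges
    e <- e[e$bin_i %in% m$parents & e$bin_j %in% m$parents, , drop = FALSE]
    list(new_id = m$new_id, parents = m$parents, edge_scores = e)
  })
  report <- list(
    schema_version = 1L,
    config = unclass(config)[setdiff(names(unclass(config)), "outdir")],
    n_scaffolds = nrow(scaffolds),
    n_short_removed = n_short,
    n_linked_pairs = nrow(lm$pairs),
    model = c(model$metrics,
              list(bins_used = model$bins_used,
                   n_training_rows = nrow(ts))),
    n_merges = length(merge_records),
    merges = merge_records,
    recruitment = list(
      algorithm = config$recruit_algo,
      n_unbinned_before = length(merged$unbinned),
      n_recruited = length(attr(final, "recruited")),
      recruited = attr(final, "recruited")
    )
  )
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    write_binning(final, file.path(config$outdir, "bins_final.tsv"),
                  seqs = seqs, fasta_dir = file.path(config$outdir, "bins"))
    writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, dataframe = "rows"),
               file.path(config$outdir, "report.json"))
  }
  list(binning = final, report = report, model = model, probs = probs,
       scores = scores, plan = plan, scaffolds = scaffolds)
}
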