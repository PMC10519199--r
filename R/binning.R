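#' Construct a binning
#'
#' A binning assigns scaffolds to bins and keeps an explicit unbinned set.
#' The bins partition the assigned scaffolds: a scaffold listed under two
#' different bins is an error.
#'
#' @param assignment Named character vector mapping scaffold id to bin id.
#'   The reserved bin id `"unbinned"` places a scaffold in the unbinned set.
#' @param scaffold_ids Optional full scaffold universe; scaffolds absent from
#'   `assignment` are placed in the unbinned set.
#' @return An object of class `binning` with elements `assignment` (named
#'   character vector, binned scaffolds only), `bins` (named list of sorted
#'   member id vectors) and `unbinned` (sorted character vector).
#' @export
binning <- function(assignment, scaffold_ids = NULL) {
  nm <- names(assignment)
  if (is.null(nm) || any(nm == ""))
    stop("assignment must be a named character vector (scaffold -> bin)")
  assignment <- as.character(stats::setNames(assignment, nm))
  names(assignment) <- nm
  if (anyDuplicated(nm)) {
    uniq <- !duplicated(paste(nm, assignment, sep = "\x01"))
    assignment <- assignment[uniq]
    nm <- names(assignment)
    if (anyDuplicated(nm)) {
      bad <- nm[duplicated(nm)][1L]
      stop("scaffold '", bad, "' is assigned to more than one bin")
    }
  }
  unbinned <- unique(c(nm[assignment == "unbinned"],
                       setdiff(as.character(scaffold_ids), nm)))
  asg <- assignment[assignment != "unbinned"]
  if (!length(asg))
    stop("empty binning: no scaffold is assigned to a bin")
  bins <- lapply(split(names(asg), unname(asg)), sort)
  structure(list(assignment = asg, bins = bins, unbinned = sort(unbinned)),
            class = "binning")
}

# Total base pairs per bin, sorted as names(bn$bins).
bin_sizes_bp <- function(bn, scaffolds) {
  vapply(bn$bins, function(m) {
    sum(scaffolds$length[match(m, scaffolds$id)])
  }, numeric(1))
}

#' @export
print.binning <- function(x, ...) {
  cat(sprintf("<binning> %d bins, %d binned scaffolds, %d unbinned\n",
              length(x$bins), length(x$assignment), length(x$unbinned)))
  invisible(x)
}
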