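#' Read assembly scaffolds from FASTA
#'
#' The scaffold id is the first whitespace-delimited token of the header.
#' Depth fields are left at 0 until joined with a depth table via
#' [join_depths()].
#'
#' @param path Path to a FASTA file.
#' @return A list with `scaffolds` (data frame: `id`, `length`, `depth_mean`,
#'   `depth_var`) and `seqs` (a named [Biostrings::DNAStringSet]).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate scaffold id in FASTA: ", ids[duplicated(ids)][1L])
  names(seqs) <- ids
  list(
    scaffolds = data.frame(id = ids, length = Biostrings::width(seqs),
                           depth_mean = 0, depth_var = 0,
                           stringsAsFactors = FALSE),
    seqs = seqs
  )
}

#' Read a metaBAT-style per-scaffold depth table
#'
#' Expects a tab-separated file with header columns `contigName`, `contigLen`,
#' `totalAvgDepth`, followed by per-sample depth / depth-variance column pairs.
#' The mean depth is `totalAvgDepth`; the variance is taken from the first
#' sample's variance column (the single-sample regime this method targets).
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `id`, `length`, `depth_mean`, `depth_var`.
#' @export
read_depth_table <- function(path) {
  if (!file.exists(path)) stop("depth table not found: ", path)
  tab <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("contigName", "contigLen", "totalAvgDepth")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("depth table is missing column '", miss[1L], "'")
  to_num <- function(x, col) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at data row %d", col, bad[1L]))
    v
  }
  if (!nrow(tab)) {
    return(data.frame(id = character(0), length = integer(0),
                      depth_mean = numeric(0), depth_var = numeric(0),
                      stringsAsFactors = FALSE))
  }
  dvar <- if (ncol(tab) >= 5L) {
    to_num(tab[[5L]], colnames(tab)[5L])
  } else {
    warning("depth table has no variance column; depth_var set to 0")
    rep(0, nrow(tab))
  }
  data.frame(
    id = tab$contigName,
    length = as.integer(to_num(tab$contigLen, "contigLen")),
    depth_mean = to_num(tab$totalAvgDepth, "totalAvgDepth"),
    depth_var = dvar,
    stringsAsFactors = FALSE
  )
}

#' Join a depth table onto a scaffold table
#'
#' @param scaffolds Scaffold data frame (as from [read_fasta()]).
#' @param depths Depth data frame (as from [read_depth_table()]).
#' @return `scaffolds` with `depth_mean` and `depth_var` filled in.
#' @export
join_depths <- function(scaffolds, depths) {
  i <- match(scaffolds$id, depths$id)
  if (anyNA(i))
    stop("no depth record for scaffold '",
         scaffolds$id[which(is.na(i))[1L]], "'")
  scaffolds$depth_mean <- depths$depth_mean[i]
  scaffolds$depth_var <- depths$depth_var[i]
  scaffolds
}

#' Read Hi-C alignments into a link map
#'
#' Consumes SAM or BAM alignments in which the two mates of each Hi-C read
#' pair were mapped independently. A record is discarded when any bit of SAM
#' flag 2316 is set (read unmapped, mate unmapped, secondary, supplementary),
#' when the duplicate bit (1024) is set, or when its mapping quality is below
#' `mapq_min` (records without a MAPQ value pass). Surviving records are
#' paired by read name; a pair whose mates map to two different scaffolds
#' contributes one link to that scaffold pair. Same-scaffold pairs carry no
#' inter-scaffold signal and are ignored. Read names without exactly two
#' surviving records are counted and reported, not fatal.
#'
#' @param path Path to a SAM (`.sam`) or BAM file.
#' @param mapq_min Minimum mapping quality (default 0, i.e. no MAPQ filter).
#' @return A [linkmap()] whose degree vector covers every scaffold declared in
#'   the alignment header.
#' @export
read_hic_alignments <- function(path, mapq_min = 0) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]
  all_ids <- names(hdr$targets)
  param <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "mapq"))
  rec <- Rsamtools::scanBam(bam, param = param)[[1L]]
  mapq_ok <- is.na(rec$mapq) | rec$mapq >= mapq_min
  keep <- bitwAnd(rec$flag, 2316L) == 0L &
    bitwAnd(rec$flag, 1024L) == 0L & mapq_ok
  qn <- rec$qname[keep]
  rn <- as.character(rec$rname)[keep]
  if (!length(qn)) return(linkmap(character(0), character(0), scaffold_ids = all_ids))
  o <- order(qn)
  qn <- qn[o]
  rn <- rn[o]
  runs <- rle(qn)
  unpaired <- sum(runs$lengths != 2L)
  if (unpaired > 0L)
    message(unpaired, " read name(s) without exactly two surviving alignments; skipped")
  ends <- cumsum(runs$lengths)[runs$lengths == 2L]
  a <- rn[ends - 1L]
  b <- rn[ends]
  inter <- a != b
  linkmap(a[inter], b[inter], 1L, scaffold_ids = all_ids)
}

#' Read an initial binning
#'
#' Accepts either a two-column TSV (`scaffold_id TAB bin_id`, `#` comment
#' lines allowed, no header) or a directory of per-bin FASTA files whose file
#' stems are the bin ids.
#'
#' @param path TSV file or directory.
#' @param scaffold_ids Optional assembly scaffold universe; scaffolds missing
#'   from the binning are placed in the unbinned set.
#' @return A [binning()].
#' @export
read_binning <- function(path, scaffold_ids = NULL) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(fa|fasta|fna)$",
                        full.names = TRUE, ignore.case = TRUE)
    if (!length(files)) stop("empty binning: no FASTA files under ", path)
    asg <- character(0)
    for (f in sort(files)) {
      ids <- sub("\\s.*$", "", names(Biostrings::fasta.seqlengths(f)))
      bin <- tools::file_path_sans_ext(basename(f))
      asg <- c(asg, stats::setNames(rep(bin, length(ids)), ids))
    }
  } else {
    if (!file.exists(path)) stop("binning file not found: ", path)
    tab <- tryCatch(
      utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                        colClasses = "character",
                        col.names = c("scaffold", "bin")),
      error = function(e) stop("empty or unreadable binning '", path, "': ",
                               conditionMessage(e), call. = FALSE)
    )
    if (!nrow(tab)) stop("empty binning: ", path)
    asg <- stats::setNames(tab$bin, tab$scaffold)
  }
  binning(asg, scaffold_ids = scaffold_ids)
}

#' Write a binning
#'
#' Writes the two-column TSV (unbinned scaffolds are emitted with bin id
#' `"unbinned"`), and, when sequences are supplied, one FASTA per bin under
#' `fasta_dir`. The TSV round-trips through [read_binning()] to an identical
#' binning.
#'
#' @param bn A [binning()].
#' @param path Output TSV path.
#' @param seqs Optional named [Biostrings::DNAStringSet] of scaffold sequences.
#' @param fasta_dir Directory for per-bin FASTA output (created if needed).
#' @return `path`, invisibly.
#' @export
write_binning <- function(bn, path, seqs = NULL, fasta_dir = NULL) {
  asg <- c(bn$assignment,
           stats::setNames(rep("unbinned", length(bn$unbinned)), bn$unbinned))
  asg <- asg[order(names(asg))]
  writeLines(paste(names(asg), unname(asg), sep = "\t"), path)
  if (!is.null(seqs) && !is.null(fasta_dir)) {
    dir.create(fasta_dir, recursive = TRUE, showWarnings = FALSE)
    for (b in names(bn$bins)) {
      members <- intersect(bn$bins[[b]], names(seqs))
      if (length(members))
        Biostrings::writeXStringSet(seqs[members],
                                    file.path(fasta_dir, paste0(b, ".fa")))
    }
  }
  invisible(path)
}

#' Write a metaBAT-style depth table
#'
#' @param scaffolds Scaffold data frame with `id`, `length`, `depth_mean`,
#'   `depth_var`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_depth_table <- function(scaffolds, path) {
  tab <- data.frame(
    contigName = scaffolds$id,
    contigLen = scaffolds$length,
    totalAvgDepth = scaffolds$depth_mean,
    sample1 = scaffolds$depth_mean,
    sample1.var = scaffolds$depth_var,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  colnames(tab)[4:5] <- c("sample1.bam", "sample1.bam-var")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a link map as mate-independent SAM alignments
#'
#' Emits, for every linked scaffold pair, `count` read pairs whose two mates
#' are mapped independently (flag 0) to the two scaffolds. Reading the file
#' back with [read_hic_alignments()] reproduces the link map.
#'
#' @param lm A [linkmap()].
#' @param scaffold_lengths Named integer vector of scaffold lengths (defines
#'   the `@SQ` header lines).
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_linkmap_sam <- function(lm, scaffold_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(scaffold_lengths),
                   as.integer(scaffold_lengths)))
  p <- lm$pairs
  idx <- rep(seq_len(nrow(p)), p$count)
  if (length(idx)) {
    qname <- sprintf("hic_%07d", seq_along(idx))
    rec <- function(rname) paste(qname, 0L, rname, 1L, 60L, "5M", "*", 0L, 0L,
                                 "ACGTA", "*", sep = "\t")
    body <- as.vector(rbind(rec(p$a[idx]), rec(p$b[idx])))
  } else {
    body <- character(0)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
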