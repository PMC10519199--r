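# Shared fixtures, all built in code.

# Write a SAM file from a record list; each record is
# list(qname, flag, rname, mapq). Unmapped records use rname "*".
write_test_sam <- function(records, sq = c(s1 = 10000L, s2 = 10000L, s3 = 10000L),
                           path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sq), sq))
  body <- vapply(records, function(r) {
    mapped <- r$rname != "*"
    paste(r$qname, r$flag, r$rname, if (mapped) 1L else 0L,
          r$mapq %||% 60L, if (mapped) "5M" else "*", "*", 0L, 0L,
          "ACGTA", "*", sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# A read pair: two mate-independent records.
sam_pair <- function(qname, r1, r2, f1 = 0L, f2 = 0L, q1 = 60L, q2 = 60L) {
  list(list(qname = qname, flag = f1, rname = r1, mapq = q1),
       list(qname = qname, flag = f2, rname = r2, mapq = q2))
}

# Small community used by module tests (fast: ~0.4 Mb of sequence).
small_sim <- function(seed = 42, ...) {
  simulate_community(sim_config(n_genomes = 4, genome_len_bp = 100000,
                                seed = seed, ...))
}

# Scaffold table for toy examples that never touch sequences.
toy_scaffolds <- function(ids, length = 10000L, depth = 10, dvar = 2) {
  data.frame(id = ids,
             length = rep_len(length, length(ids)),
             depth_mean = rep_len(depth, length(ids)),
             depth_var = rep_len(dvar, length(ids)),
             stringsAsFactors = FALSE)
}

# Independent Welch t-test oracle: closed form with Welch-Satterthwaite df.
welch_p_oracle <- function(x, y) {
  m1 <- mean(x); m2 <- mean(y)
  v1 <- var(x); v2 <- var(y)
  n1 <- length(x); n2 <- length(y)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  2 * stats::pt(-abs(t), df)
}

# Reverse complement without Biostrings (kept independent of the TNF path).
revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
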