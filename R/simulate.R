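#' Simulator configuration
#'
#' Describes a synthetic microbial community in the style of a staggered
#' mock standard: `n_genomes` genomes with genome-specific order-3 Markov
#' composition, log-spaced abundances (so no two genomes share a depth),
#' fragmentation into scaffolds, and Hi-C links whose per-pair rate decays
#' with genomic distance inside a genome and is a small uniform background
#' between genomes.
#'
#' Intra-genome links for a scaffold pair at genomic distance `d` (between
#' scaffold midpoints) are Poisson with rate
#' `intra_rate * (1 + d / decay_bp)^(-decay_power)`, the standard power-law
#' contact decay of proximity-ligation data; inter-genome pairs are Poisson
#' with constant rate `inter_rate`. Setting `intra_rate == inter_rate` and
#' `decay_power = 0` yields the null community with no within-genome link
#' enrichment.
#'
#' @param n_genomes Number of genomes.
#' @param genome_len_bp Nominal genome length in bp (each genome is jittered
#'   by +/-15%).
#' @param scaffold_len_range Min/max scaffold length in bp (min must be at
#'   least 1500, the downstream scaffold floor).
#' @param depth_range Range of genome mean depths; genome means are
#'   log-spaced across it.
#' @param depth_noise Per-scaffold relative depth noise (Gaussian sd as a
#'   fraction of the genome mean, truncated at 0).
#' @param intra_rate Expected links for a zero-distance intra-genome pair.
#' @param inter_rate Expected links for an inter-genome pair.
#' @param decay_bp,decay_power Contact-decay scale and exponent.
#' @param order3_markov Draw a genome-specific order-3 Markov composition
#'   (TRUE) or i.i.d. uniform bases (FALSE).
#' @param seed Integer seed; the whole community is a deterministic function
#'   of the configuration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genomes = 8, genome_len_bp = 300000,
                       scaffold_len_range = c(2000, 12000),
                       depth_range = c(5, 80), depth_noise = 0.1,
                       intra_rate = 10, inter_rate = 0.25,
                       decay_bp = 20000, decay_power = 2,
                       order3_markov = TRUE, seed = 42) {
  if (scaffold_len_range[1L] < 1500)
    stop("scaffold_len_range minimum must be >= 1500 bp")
  if (scaffold_len_range[2L] > genome_len_bp)
    stop("infeasible config: maximum scaffold length exceeds the genome length")
  if (!(intra_rate >= inter_rate && inter_rate >= 0))
    stop("need intra_rate >= inter_rate >= 0")
  if (n_genomes < 2L) stop("need at least 2 genomes")
  structure(list(n_genomes = n_genomes, genome_len_bp = genome_len_bp,
                 scaffold_len_range = scaffold_len_range,
                 depth_range = depth_range, depth_noise = depth_noise,
                 intra_rate = intra_rate, inter_rate = inter_rate,
                 decay_bp = decay_bp, decay_power = decay_power,
                 order3_markov = order3_markov, seed = seed),
            class = "sim_config")
}

# Generate `n` bases from an order-3 Markov chain with 64x4 transition
# probabilities P (contexts in base-4 encoding, A=0..T=3).
markov_seq <- function(n, P) {
  bases <- c("A", "C", "G", "T")
  cp1 <- P[, 1L]
  cp2 <- cp1 + P[, 2L]
  cp3 <- cp2 + P[, 3L]
  out <- integer(n)
  out[1:3] <- sample.int(4L, 3L, replace = TRUE)
  u <- stats::runif(n)
  s <- (out[1L] - 1L) * 16L + (out[2L] - 1L) * 4L + (out[3L] - 1L) + 1L
  for (i in 4:n) {
    b <- 1L + (u[i] > cp1[s]) + (u[i] > cp2[s]) + (u[i] > cp3[s])
    out[i] <- b
    s <- ((s - 1L) %% 16L) * 4L + (b - 1L) + 1L
  }
  paste(bases[out], collapse = "")
}

# Expected intra-genome link rate at genomic distance d.
intra_lambda <- function(cfg, d) {
  cfg$intra_rate * (1 + d / cfg$decay_bp)^(-cfg$decay_power)
}

#' Simulate a synthetic community with ground truth
#'
#' @param config A [sim_config()].
#' @return An object of class `community_sim`: list with `scaffolds` (data
#'   frame `id`, `length`, `depth_mean`, `depth_var`, `genome`, `start`),
#'   `seqs` (named [Biostrings::DNAStringSet]), `linkmap` (a [linkmap()])
#'   and `truth` (list: `genomes`, `scenario`, `params`).
#' @export
simulate_community <- function(config = sim_config()) {
  cfg <- config
  with_seed(cfg$seed, {
    r1 <- cfg$scaffold_len_range[1L]
    r2 <- cfg$scaffold_len_range[2L]
    gm_depths <- exp(seq(log(cfg$depth_range[1L]), log(cfg$depth_range[2L]),
                         length.out = cfg$n_genomes))
    sc_list <- vector("list", cfg$n_genomes)
    seq_chunks <- character(0)
    for (g in seq_len(cfg$n_genomes)) {
      gid <- sprintf("genome_%02d", g)
      glen <- round(cfg$genome_len_bp * stats::runif(1, 0.85, 1.15))
      gseq <- if (cfg$order3_markov) {
        P <- matrix(stats::rgamma(64L * 4L, shape = 1), 64L, 4L)
        markov_seq(glen, P / rowSums(P))
      } else {
        paste(sample(c("A", "C", "G", "T"), glen, replace = TRUE),
              collapse = "")
      }
      lens <- integer(0)
      total <- 0
      while (total < glen) {
        L <- round(stats::runif(1, r1, r2))
        lens <- c(lens, L)
        total <- total + L
      }
      lens[length(lens)] <- lens[length(lens)] - (total - glen)
      if (length(lens) > 1L && lens[length(lens)] < r1) {
        lens[length(lens) - 1L] <- lens[length(lens) - 1L] + lens[length(lens)]
        lens <- lens[-length(lens)]
      }
      starts <- cumsum(c(0L, utils::head(lens, -1L)))
      ids <- sprintf("%s_s%03d", gid, seq_along(lens))
      gm <- gm_depths[g]
      depth <- pmax(stats::rnorm(length(lens), gm, cfg$depth_noise * gm), 0.01)
      dvar <- (cfg$depth_noise * gm)^2 * stats::runif(length(lens), 0.7, 1.3)
      sc_list[[g]] <- data.frame(id = ids, length = as.integer(lens),
                                 depth_mean = depth, depth_var = dvar,
                                 genome = gid, start = as.numeric(starts),
                                 stringsAsFactors = FALSE)
      seq_chunks <- c(seq_chunks,
                      stats::setNames(substring(gseq, starts + 1, starts + lens),
                                      ids))
    }
    scaffolds <- do.call(rbind, sc_list)
    rownames(scaffolds) <- NULL
    seqs <- Biostrings::DNAStringSet(seq_chunks)
    cmb <- utils::combn(nrow(scaffolds), 2L)
    i <- cmb[1L, ]
    j <- cmb[2L, ]
    same <- scaffolds$genome[i] == scaffolds$genome[j]
    mid <- scaffolds$start + scaffolds$length / 2
    lambda <- rep(cfg$inter_rate, length(i))
    lambda[same] <- intra_lambda(cfg, abs(mid[i[same]] - mid[j[same]]))
    cnt <- stats::rpois(length(lambda), lambda)
    nz <- cnt > 0L
    lm <- linkmap(scaffolds$id[i[nz]], scaffolds$id[j[nz]], cnt[nz],
                  scaffold_ids = scaffolds$id)
    truth <- list(genomes = split(scaffolds$id, scaffolds$genome),
                  scenario = "none", params = cfg)
    structure(list(scaffolds = scaffolds, seqs = seqs, linkmap = lm,
                   truth = truth),
              class = "community_sim")
  })
}

#' Degrade a truth binning into a test scenario
#'
#' `split` cuts each genome's bin into two contiguous halves (the typical
#' incomplete-binning failure); `holdout` moves `floor(frac * n)` randomly
#' chosen scaffolds of each genome to the unbinned set; `mixed` does both.
#'
#' @param sim A [simulate_community()] result.
#' @param scenario `"split"`, `"holdout"` or `"mixed"`.
#' @param frac Held-out fraction per genome, in (0, 1).
#' @param seed Integer seed for the holdout draw.
#' @return A [binning()]; ground truth stays in `sim$truth`.
#' @export
perturb_binning <- function(sim, scenario = c("split", "holdout", "mixed"),
                            frac = 0.3, seed = 42) {
  scenario <- match.arg(scenario)
  if (scenario != "split" && (frac <= 0 || frac >= 1))
    stop("frac must be in (0, 1)")
  genomes <- sim$truth$genomes
  asg <- character(0)
  with_seed(sub_seed(seed, 41L), {
    for (gid in names(genomes)) {
      m <- genomes[[gid]]  # positional order along the genome
      v <- if (scenario %in% c("split", "mixed")) {
        h <- ceiling(length(m) / 2)
        c(rep(paste0(gid, "_A"), h), rep(paste0(gid, "_B"), length(m) - h))
      } else {
        rep(gid, length(m))
      }
      names(v) <- m
      if (scenario %in% c("holdout", "mixed")) {
        k <- floor(frac * length(m))
        if (k > 0L) v[sample(length(m), k)] <- "unbinned"
      }
      asg <- c(asg, v)
    }
  })
  binning(asg)
}

#' Score a binning against simulator ground truth
#'
#' For each bin, the dominant genome is the genome contributing the most
#' base pairs; completeness is the dominant genome's bp in the bin divided
#' by that genome's total bp, and purity is the dominant genome's bp divided
#' by the bin's bp.
#'
#' @param bn A [binning()].
#' @param truth `sim$truth` from [simulate_community()].
#' @param scaffolds Scaffold data frame (for lengths).
#' @return List with `per_bin` (data frame `bin`, `dominant`,
#'   `completeness`, `purity`), `median_completeness`, `median_purity`.
#' @export
score_against_truth <- function(bn, truth, scaffolds) {
  if (!length(bn$bins)) stop("empty binning")
  genome_of <- stats::setNames(
    rep(names(truth$genomes), lengths(truth$genomes)),
    unlist(truth$genomes)
  )
  missing_ids <- setdiff(unlist(bn$bins), names(genome_of))
  if (length(missing_ids))
    stop("scaffold '", missing_ids[1L], "' is absent from the ground truth")
  bp <- stats::setNames(scaffolds$length, scaffolds$id)
  genome_bp <- tapply(bp[names(genome_of)], genome_of, sum)
  per_bin <- do.call(rbind, lapply(names(bn$bins), function(b) {
    m <- bn$bins[[b]]
    by_g <- tapply(bp[m], genome_of[m], sum)
    dom <- names(by_g)[order(-by_g, names(by_g))][1L]
    data.frame(bin = b, dominant = dom,
               completeness = unname(by_g[dom] / genome_bp[dom]),
               purity = unname(by_g[dom] / sum(by_g)),
               stringsAsFactors = FALSE)
  }))
  list(per_bin = per_bin,
       median_completeness = stats::median(per_bin$completeness),
       median_purity = stats::median(per_bin$purity))
}

#' Write a simulated community in the pipeline's on-disk formats
#'
#' @param sim A [simulate_community()] result.
#' @param outdir Output directory (created if needed).
#' @param bn Optional [binning()] to write as `bins.tsv`.
#' @param write_sam Also emit the link map as a SAM file (default TRUE).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_community <- function(sim, outdir, bn = NULL, write_sam = TRUE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(assembly = file.path(outdir, "assembly.fasta"),
             depth = file.path(outdir, "depth.tsv"),
             truth = file.path(outdir, "truth.json"))
  Biostrings::writeXStringSet(sim$seqs, paths[["assembly"]])
  write_depth_table(sim$scaffolds, paths[["depth"]])
  jsonlite::write_json(
    list(scenario = sim$truth$scenario,
         genomes = sim$truth$genomes,
         params = unclass(sim$truth$params)),
    paths[["truth"]], auto_unbox = TRUE, digits = NA
  )
  if (write_sam) {
    paths[["hic"]] <- file.path(outdir, "hic.sam")
    write_linkmap_sam(sim$linkmap,
                      stats::setNames(sim$scaffolds$length, sim$scaffolds$id),
                      paths[["hic"]])
  }
  if (!is.null(bn)) {
    paths[["bins"]] <- file.path(outdir, "bins.tsv")
    write_binning(bn, paths[["bins"]])
  }
  invisible(paths)
}
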