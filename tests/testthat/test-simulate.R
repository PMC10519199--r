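test_that("the simulator is a deterministic function of its config", {
  s1 <- small_sim(seed = 7)
  s2 <- small_sim(seed = 7)
  expect_identical(s1$scaffolds, s2$scaffolds)
  expect_identical(s1$linkmap, s2$linkmap)
  expect_identical(as.character(s1$seqs), as.character(s2$seqs))
  s3 <- small_sim(seed = 8)
  expect_false(identical(s1$linkmap$pairs, s3$linkmap$pairs))
})

test_that("truth partitions the scaffolds and scores itself perfectly", {
  sim <- small_sim(seed = 7)
  expect_setequal(unlist(sim$truth$genomes), sim$scaffolds$id)
  expect_equal(sum(lengths(sim$truth$genomes)), nrow(sim$scaffolds))
  truth_bn <- binning(setNames(sim$scaffolds$genome, sim$scaffolds$id))
  sc <- score_against_truth(truth_bn, sim$truth, sim$scaffolds)
  expect_true(all(sc$per_bin$completeness == 1))
  expect_true(all(sc$per_bin$purity == 1))
  # scaffold lengths and sequences agree, and respect the 1500 bp floor
  expect_true(all(sim$scaffolds$length >= 1500))
  expect_equal(unname(Biostrings::width(sim$seqs[sim$scaffolds$id])),
               sim$scaffolds$length)
})

test_that("link totals match their Poisson expectations from the config", {
  cfg <- sim_config(n_genomes = 4, genome_len_bp = 100000, seed = 19)
  sim <- simulate_community(cfg)
  mid <- sim$scaffolds$start + sim$scaffolds$length / 2
  cmb <- combn(nrow(sim$scaffolds), 2)
  same <- sim$scaffolds$genome[cmb[1, ]] == sim$scaffolds$genome[cmb[2, ]]
  d <- abs(mid[cmb[1, ]] - mid[cmb[2, ]])[same]
  exp_intra <- sum(cfg$intra_rate * (1 + d / cfg$decay_bp)^(-cfg$decay_power))
  exp_inter <- cfg$inter_rate * sum(!same)
  g <- setNames(sim$scaffolds$genome, sim$scaffolds$id)
  obs_intra <- sum(sim$linkmap$pairs$count[g[sim$linkmap$pairs$a] ==
                                             g[sim$linkmap$pairs$b]])
  obs_inter <- sum(sim$linkmap$pairs$count) - obs_intra
  expect_lt(abs(obs_intra - exp_intra), 3 * sqrt(exp_intra))
  expect_lt(abs(obs_inter - exp_inter), 3 * sqrt(exp_inter))

  # null config: equal rates, no decay -> intra share matches the pair share
  ncfg <- sim_config(n_genomes = 4, genome_len_bp = 100000,
                     intra_rate = 0.1, inter_rate = 0.1, decay_power = 0,
                     seed = 19)
  nsim <- simulate_community(ncfg)
  ng <- setNames(nsim$scaffolds$genome, nsim$scaffolds$id)
  n_obs_intra <- sum(nsim$linkmap$pairs$count[ng[nsim$linkmap$pairs$a] ==
                                                ng[nsim$linkmap$pairs$b]])
  ncmb <- combn(nrow(nsim$scaffolds), 2)
  n_same <- sum(nsim$scaffolds$genome[ncmb[1, ]] ==
                  nsim$scaffolds$genome[ncmb[2, ]])
  n_exp <- 0.1 * n_same
  expect_lt(abs(n_obs_intra - n_exp), 3 * sqrt(n_exp))
})

test_that("perturbation scenarios degrade the truth as specified", {
  sim <- small_sim(seed = 7)
  sp <- perturb_binning(sim, "split", seed = 1)
  expect_length(sp$bins, 2L * length(sim$truth$genomes))
  expect_length(sp$unbinned, 0L)
  # contiguous halves: the A bin holds ceiling(n/2) members
  g1 <- sim$truth$genomes[[1]]
  expect_length(sp$bins[[paste0(names(sim$truth$genomes)[1], "_A")]],
                ceiling(length(g1) / 2))

  ho <- perturb_binning(sim, "holdout", frac = 0.3, seed = 1)
  for (gid in names(sim$truth$genomes)) {
    n <- length(sim$truth$genomes[[gid]])
    expect_length(intersect(ho$unbinned, sim$truth$genomes[[gid]]),
                  floor(0.3 * n))
  }
  expect_identical(perturb_binning(sim, "holdout", frac = 0.3, seed = 1)$unbinned,
                   ho$unbinned)
  mx <- perturb_binning(sim, "mixed", frac = 0.2, seed = 1)
  expect_gt(length(mx$unbinned), 0L)
  expect_length(mx$bins, 2L * length(sim$truth$genomes))
  expect_error(perturb_binning(sim, "holdout", frac = 1.2), "frac")
})

test_that("completeness and purity follow the base-pair definitions", {
  truth <- list(genomes = list(gA = c("a1", "a2"), gB = c("b1")))
  sc <- data.frame(id = c("a1", "a2", "b1"),
                   length = c(90000L, 90000L, 10000L),
                   depth_mean = 1, depth_var = 1, stringsAsFactors = FALSE)
  # bin = half of genome A by bp
  half <- binning(c(a1 = "bin1"), scaffold_ids = c("a1", "a2", "b1"))
  s1 <- score_against_truth(half, truth, sc)
  expect_equal(s1$per_bin$completeness, 0.5)
  expect_equal(s1$per_bin$purity, 1.0)
  # bin = 90 kb of A + 10 kb of B
  mixed <- binning(c(a1 = "bin1", b1 = "bin1"))
  s2 <- score_against_truth(mixed, truth, sc)
  expect_equal(s2$per_bin$dominant, "gA")
  expect_equal(s2$per_bin$purity, 0.9)
  expect_equal(s2$per_bin$completeness, 0.5)
  expect_error(score_against_truth(binning(c(zz = "b")), truth, sc),
               "absent from the ground truth")
})

test_that("TNF separates the simulated genomes (composition signal)", {
  sim <- small_sim(seed = 31)
  bn <- binning(setNames(sim$scaffolds$genome, sim$scaffolds$id))
  tnfm <- tnf_matrix(sim$seqs)
  tnfs <- lapply(setNames(names(bn$bins), names(bn$bins)),
                 function(b) bin_tnf(bn, sim$scaffolds, tnfm, b))
  gids <- names(bn$bins)
  inter <- combn(gids, 2)
  inter_cos <- mapply(function(i, j) tnf_score(tnfs[[i]], tnfs[[j]]),
                      inter[1, ], inter[2, ])
  # within a genome, the two contiguous halves are compositionally alike
  sp <- perturb_binning(sim, "split", seed = 1)
  sp_tnfs <- lapply(setNames(names(sp$bins), names(sp$bins)),
                    function(b) bin_tnf(sp, sim$scaffolds, tnfm, b))
  intra_cos <- vapply(gids, function(g)
    tnf_score(sp_tnfs[[paste0(g, "_A")]], sp_tnfs[[paste0(g, "_B")]]),
    numeric(1))
  expect_gt(mean(intra_cos), mean(inter_cos))
  expect_true(all(intra_cos > 0.95))
})

test_that("the simulated SAM round-trips through the alignment reader", {
  sim <- simulate_community(sim_config(n_genomes = 2, genome_len_bp = 40000,
                                       intra_rate = 1, inter_rate = 0.05,
                                       seed = 5))
  sam <- tempfile(fileext = ".sam")
  write_linkmap_sam(sim$linkmap,
                    setNames(sim$scaffolds$length, sim$scaffolds$id), sam)
  back <- read_hic_alignments(sam)
  expect_identical(back$pairs, sim$linkmap$pairs)
  expect_identical(back$degree, sim$linkmap$degree)
})
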