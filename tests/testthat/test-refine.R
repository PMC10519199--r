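make_predicate <- function(a, b) {
  pair_predicate(data.frame(a = a, b = b, prob = 1, stringsAsFactors = FALSE),
                 minscore = 0.5)
}

test_that("lr_score counts connected cross pairs over all cross pairs", {
  bi <- c("s1", "s2")
  bj <- c("s3", "s4", "s5")
  pred <- make_predicate(c("s1", "s2"), c("s3", "s4"))
  expect_equal(lr_score(bi, bj, pred), 2 / 6)
  all6 <- expand.grid(a = bi, b = bj, stringsAsFactors = FALSE)
  expect_equal(lr_score(bi, bj, make_predicate(all6$a, all6$b)), 1)
  expect_equal(lr_score(bi, bj, make_predicate("s9", "s8")), 0)
  expect_error(lr_score(bi, c("s2", "s7"), pred), "overlap")
  expect_error(lr_score(character(0), bj, pred), "empty bin")
})

test_that("lr_score matches exhaustive double-loop counting on random bins", {
  set.seed(77)
  pool <- sprintf("t%02d", 1:20)
  for (i in 1:25) {
    bi <- sample(pool, sample(1:8, 1))
    bj <- sample(setdiff(pool, bi), sample(1:8, 1))
    conn <- t(combn(pool, 2))
    conn <- conn[runif(nrow(conn)) < 0.3, , drop = FALSE]
    pred <- make_predicate(conn[, 1], conn[, 2])
    hits <- 0L
    for (x in bi) for (y in bj) {
      hits <- hits + any((conn[, 1] == x & conn[, 2] == y) |
                           (conn[, 1] == y & conn[, 2] == x))
    }
    expect_identical(lr_score(bi, bj, pred), hits / (length(bi) * length(bj)))
  }
})

test_that("depth_score is the two-sided Welch p-value with explicit degeneracies", {
  expect_equal(depth_score(c(10, 10, 10), c(10, 10, 10)), 1)
  expect_equal(depth_score(c(10, 10, 10), c(30, 30, 30)), 0)
  d1 <- c(8, 10, 12)
  d2 <- c(9, 10, 11)
  expect_equal(depth_score(d1, d2), welch_p_oracle(d1, d2), tolerance = 1e-12)
  # single-scaffold bin borrows the other bin's variance (pooled test)
  p <- depth_score(5, c(9, 10, 11))
  expect_equal(p, stats::t.test(5, c(9, 10, 11), var.equal = TRUE)$p.value)
  expect_message(p1 <- depth_score(5, c(9, 9, 9)), "set to 1")
  expect_equal(p1, 1)
  expect_equal(depth_score(5, 5), 1)
  expect_equal(depth_score(5, 6), 0)
  expect_error(depth_score(numeric(0), d1), "empty depth profile")
})

test_that("depth_score agrees with an independent Welch implementation", {
  set.seed(13)
  for (i in 1:50) {
    x <- rnorm(sample(2:10, 1), mean = runif(1, 5, 50), sd = runif(1, 0.5, 5))
    y <- rnorm(sample(2:10, 1), mean = runif(1, 5, 50), sd = runif(1, 0.5, 5))
    expect_equal(depth_score(x, y), welch_p_oracle(x, y), tolerance = 1e-9)
  }
})

test_that("tnf_score is the cosine similarity", {
  u <- c(1, 0, 0, 0)
  expect_equal(tnf_score(u, u), 1)
  expect_equal(tnf_score(u, c(0, 1, 0, 0)), 0)
  expect_equal(tnf_score(u, c(1, 1, 0, 0) / sum(c(1, 1))), 1 / sqrt(2))
  set.seed(3)
  x <- runif(136); y <- runif(136)
  expect_equal(tnf_score(x, y), sum(x * y) / sqrt(sum(x^2) * sum(y^2)),
               tolerance = 1e-14)
  expect_error(tnf_score(rep(0, 4), u), "zero-norm")
})

toy_scores <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(bin_i = r[[1]], bin_j = r[[2]], lr = as.numeric(r[[3]]),
               depth_p = as.numeric(r[[4]]), tnf_cos = as.numeric(r[[5]]),
               stringsAsFactors = FALSE)
  }))
}

test_that("merges require all three scores and propagate transitively", {
  bn <- binning(setNames(paste0("b", c(1, 1, 2, 2, 3, 3)), paste0("s", 1:6)))
  th <- c(lr_min = 0.1, depth_min = 0.05, tnf_min = 0.90)
  sc <- toy_scores(list("b1", "b2", 0.5, 0.9, 0.99),
                   list("b2", "b3", 0.3, 0.5, 0.95),
                   list("b1", "b3", 0.0, 0.9, 0.99))
  plan <- plan_merges(bn, sc, th)
  expect_equal(plan$partitions, list(c("b1", "b2", "b3")))

  # one failing score vetoes the edge
  sc2 <- toy_scores(list("b1", "b2", 0.5, 0.01, 0.99),
                    list("b2", "b3", 0.3, 0.5, 0.5),
                    list("b1", "b3", 0.05, 0.9, 0.99))
  plan2 <- plan_merges(bn, sc2, th)
  expect_equal(plan2$partitions, list("b1", "b2", "b3"))
  merged2 <- apply_merges(bn, plan2)
  expect_identical(merged2$bins, bn$bins)
})

test_that("apply_merges unions partitions and conserves scaffold counts", {
  asg <- setNames(c(rep("b1", 5), rep("b2", 4), rep("b3", 3)),
                  sprintf("s%02d", 1:12))
  bn <- binning(asg, scaffold_ids = c(names(asg), "u1"))
  plan <- plan_merges(bn, toy_scores(list("b1", "b2", 1, 1, 1)),
                      c(lr_min = 0.1, depth_min = 0.05, tnf_min = 0.9))
  out <- apply_merges(bn, plan)
  expect_equal(sort(lengths(out$bins), decreasing = TRUE), c(9L, 3L),
               ignore_attr = TRUE)
  expect_equal(length(out$assignment), length(bn$assignment))
  expect_equal(out$unbinned, "u1")
  expect_equal(attr(out, "merges")[[1]]$parents, c("b1", "b2"))
  # merged membership survives a write/read round trip
  f <- tempfile(fileext = ".tsv")
  write_binning(out, f)
  expect_identical(read_binning(f)$bins, out$bins)

  bad <- plan
  bad$partitions <- list(c("b1", "zzz"))
  expect_error(apply_merges(bn, bad), "unknown bin")
})

test_that("recruitment follows the single-known-bin rule and never reassigns", {
  # component 1: unbinned u1 with two b1 scaffolds -> recruited to b1
  # component 2: u2 bridges b1 and b2 -> ambiguous, stays unbinned
  # component 3: u3-u4 alone -> no known bin, stays unbinned
  bn <- binning(c(a1 = "b1", a2 = "b1", c1 = "b2"),
                scaffold_ids = c("a1", "a2", "c1", "u1", "u2", "u3", "u4"))
  probs <- data.frame(
    a = c("u1", "u1", "u2", "u2", "u3", "a1"),
    b = c("a1", "a2", "a2", "c1", "u4", "a2"),
    prob = c(0.9, 0.8, 0.9, 0.9, 0.9, 0.3),
    stringsAsFactors = FALSE
  )
  out <- recruit_unbinned(bn, probs, minscore = 0.5, algorithm = "lpa", seed = 1)
  expect_equal(unname(out$assignment["u1"]), "b1")
  expect_true(all(c("u3", "u4") %in% out$unbinned))
  expect_identical(out$assignment[names(bn$assignment)], bn$assignment)
  expect_equal(attr(out, "recruited"), "u1")
  # u2 may be pulled only if its whole component sees one bin; here it sees two
  expect_true("u2" %in% out$unbinned)

  out2 <- recruit_unbinned(bn, probs, algorithm = "louvain", seed = 1)
  expect_equal(unname(out2$assignment["u1"]), "b1")
  expect_error(recruit_unbinned(bn, probs, algorithm = "infomap"),
               "should be one of")
})

test_that("raising any merge threshold never increases the amount of merging", {
  set.seed(21)
  bins <- paste0("b", 1:8)
  bn <- binning(setNames(rep(bins, each = 2), paste0("s", 1:16)))
  cmb <- t(combn(bins, 2))
  sc <- data.frame(bin_i = cmb[, 1], bin_j = cmb[, 2],
                   lr = runif(nrow(cmb)), depth_p = runif(nrow(cmb)),
                   tnf_cos = runif(nrow(cmb)), stringsAsFactors = FALSE)
  merged_bins <- function(th) {
    parts <- plan_merges(bn, sc, th)$partitions
    length(bins) - length(parts)
  }
  grid <- c(0.2, 0.5, 0.8)
  for (d in grid) for (t in grid) {
    vals <- vapply(grid, function(l)
      merged_bins(c(lr_min = l, depth_min = d, tnf_min = t)), numeric(1))
    expect_true(all(diff(vals) <= 0))
  }
  for (l in grid) for (t in grid) {
    vals <- vapply(grid, function(d)
      merged_bins(c(lr_min = l, depth_min = d, tnf_min = t)), numeric(1))
    expect_true(all(diff(vals) <= 0))
  }
})
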