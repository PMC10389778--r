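test_that("log2_fold_change handles identity, known ratios and zeros", {
  expect_equal(log2_fold_change(7, 7), 0)
  expect_equal(log2_fold_change(31, 7), 2)
  expect_equal(log2_fold_change(0, 0), 0)
  expect_equal(log2_fold_change(c(7, 31), c(7, 7)), c(0, 2))
  expect_error(log2_fold_change(1, 1, pseudocount = 0), "pseudocount")
})

test_that("two_group_test matches the closed-form Welch oracle and is symmetric", {
  a <- c(1.1, 1.3, 0.9)
  b <- c(3.2, 2.8, 3.1)
  expect_equal(two_group_test(a, b), welch_closed_form(a, b)$p)
  expect_equal(two_group_test(a, b), two_group_test(b, a))
  expect_equal(two_group_test(c(1, 2, 3), c(1, 2, 3)), 1)
  set.seed(4)
  for (i in 1:10) {
    x <- rnorm(4 + i); y <- rnorm(5, 0.5)
    expect_equal(two_group_test(x, y), welch_closed_form(x, y)$p)
  }
})

test_that("two_group_test agrees with a permutation test at moderate n", {
  set.seed(8)
  x <- rnorm(8, 0.8)
  y <- rnorm(8, 0)
  p_welch <- two_group_test(x, y)
  pool <- c(x, y)
  obs <- abs(mean(x) - mean(y))
  perm <- replicate(4000, {
    idx <- sample(16, 8)
    abs(mean(pool[idx]) - mean(pool[-idx]))
  })
  p_perm <- mean(perm >= obs)
  # same order of magnitude / decision at alpha = 0.1
  expect_lt(abs(p_welch - p_perm), 0.05)
})

test_that("degenerate replicate structures resolve as documented", {
  expect_warning(p <- two_group_test(1, c(2, 3)), "Fewer than 2")
  expect_equal(p, 1)
  expect_equal(two_group_test(c(2, 2, 2), c(2, 2, 2)), 1)  # no variance, equal
  expect_equal(two_group_test(c(4, 4, 4), c(2, 2, 2)), 0)  # no variance, shifted
  expect_gt(two_group_test(c(4, 4, 4), c(2, 2.1, 1.9)), 0) # one-sided variance ok
})

test_that("bh_adjust equals the brute-force step-up definition", {
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.2, 1.4)), "\\[0, 1\\]")
  set.seed(19)
  for (i in 1:25) {
    p <- runif(sample(1:20, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_bruteforce(p))
    expect_true(all(adj >= p - 1e-12) && all(adj <= 1))
    # rejection set at a random level matches the textbook step-up rule
    alpha <- runif(1, 0.01, 0.2)
    expect_identical(which(adj <= alpha), bh_reject_bruteforce(p, alpha))
  }
})

test_that("classify_induction applies the threshold rules on both presets", {
  rec <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    log2fc = c(1.32, -1.4, 3, 0.9),
    adj_p = c(0.01, 0.04, 0.2, 0.01)
  )
  out <- classify_induction(rec)
  expect_equal(out$status, c("up", "down", "ns", "ns"))
  # looser dysregulation preset: 1.5-fold either way
  loose <- classify_induction(rec, up_fc = 1.5, down_fc = 0.66)
  expect_equal(loose$status, c("up", "down", "ns", "up"))
  expect_error(classify_induction(rec, up_fc = 0.9), "up_fc")
  # invariant: order of rows does not matter
  perm <- sample(nrow(rec))
  expect_equal(classify_induction(rec[perm, ])$status, out$status[perm])
})

test_that("noise-free simulation yields perfect induction classification", {
  sim <- simulate_experiment(
    n_genes = 300, n_replicates = 3, frac_induced = 0.05,
    dispersion = 0, library_size_log_sd = 0,
    induction_log2fc_range = c(1.2, 4), seed = 2
  )
  cpm <- normalize_expression(sim$counts, "counts", "cpm")
  de <- induction_test(cpm, sim$design, "WT", min_expression = 0)
  joined <- dplyr::inner_join(de, sim$truth, by = "gene_id")
  expect_equal(nrow(joined), 300)
  expect_true(all(joined$status[joined$induced] == "up"))
  expect_true(all(joined$status[!joined$induced] == "ns"))
  expect_true(all(joined$adj_p >= joined$p_value))
})

test_that("median centring removes library-composition bias in fold changes", {
  sim <- simulate_experiment(
    n_genes = 500, n_replicates = 3, frac_induced = 0.3,
    dispersion = 0, library_size_log_sd = 0,
    induction_log2fc_range = c(2, 3), seed = 6
  )
  cpm <- normalize_expression(sim$counts, "counts", "cpm")
  raw <- induction_test(cpm, sim$design, "WT", center_fc = FALSE)
  cen <- induction_test(cpm, sim$design, "WT", center_fc = TRUE)
  truth <- sim$truth[match(raw$gene_id, sim$truth$gene_id), ]
  err_raw <- abs(raw$log2fc - truth$true_log2fc_bg1)
  err_cen <- abs(cen$log2fc - truth$true_log2fc_bg1)
  # with 30% of the transcriptome induced the uncentred estimates are
  # systematically deflated; centring removes the bulk of that bias
  expect_gt(median(err_raw), 0.4)
  expect_lt(median(err_cen), 0.05)
})
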